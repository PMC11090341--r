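# NIfTI / CSV / JSON artifact output.

#' Write a map as NIfTI
#'
#' 2D maps are promoted to a single-slice 3D volume; logical masks are
#' written as 0/1.
#'
#' @param x Numeric/logical array (2D, 3D, or 3D+time).
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel size in mm.
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(x, path, voxel_mm = 1) {
  arr <- x * 1
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_mm, min(3, length(dim(arr)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume or series
#'
#' @param path NIfTI file.
#' @param drop Drop singleton dimensions (default TRUE).
#' @return Numeric array.
#' @export
read_nifti_map <- function(path, drop = TRUE) {
  arr <- as.array(RNifti::readNifti(path))
  if (drop) arr <- drop(arr)
  arr
}

# expand a masked vector back into a full-shape array (NA outside)
unmask <- function(v, mask, fill = NA_real_) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- v
  out
}

#' Write all artifacts of a pipeline report
#'
#' NIfTI statistical and phase maps per scheme, tissue maps, the design
#' matrix and convergence trace as CSV, and a JSON report plus manifest.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- report$phantom
  vm <- ph$voxel_mm
  write_nifti_map(ph$gm, file.path(dir, "tissue_gm.nii.gz"), vm)
  write_nifti_map(ph$wm, file.path(dir, "tissue_wm.nii.gz"), vm)
  write_nifti_map(ph$csf, file.path(dir, "tissue_csf.nii.gz"), vm)
  write_nifti_map(ph$roi, file.path(dir, "roi.nii.gz"), vm)

  for (scheme in c("spark", "epi")) {
    res <- report[[scheme]]
    write_nifti_map(unmask(res$eoi$F, ph$support, 0),
                    file.path(dir, paste0(scheme, "_F.nii.gz")), vm)
    write_nifti_map(unmask(res$eoi$z, ph$support, 0),
                    file.path(dir, paste0(scheme, "_z.nii.gz")), vm)
    write_nifti_map(unmask(res$phase$phi, ph$support),
                    file.path(dir, paste0(scheme, "_phase.nii.gz")), vm)
    for (st in names(res$masks)) {
      write_nifti_map(res$masks[[st]],
                      file.path(dir, paste0(scheme, "_mask_", st, ".nii.gz")), vm)
    }
  }

  utils::write.csv(report$design$X, file.path(dir, "design_matrix.csv"),
                   row.names = FALSE)
  if (!is.null(report$recon_trace)) {
    utils::write.csv(data.frame(iter = seq_along(report$recon_trace),
                                objective = report$recon_trace),
                     file.path(dir, "convergence.csv"), row.names = FALSE)
  }
  export_pattern(report$pattern, file.path(dir, "trajectory.csv"))

  clean <- function(x) {
    if (is.list(x)) lapply(x, clean) else unclass(x)
  }
  jsonlite::write_json(clean(report$metrics),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(clean(report$manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
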