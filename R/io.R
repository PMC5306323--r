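#' Write a volume to NIfTI
#'
#' @param values Numeric or logical 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Numeric length-3 spacing in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, path, voxel_size_mm) {
  stopifnot(length(dim(values)) == 3L, length(voxel_size_mm) == 3L)
  img <- RNifti::asNifti(values * 1)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A numeric array with attribute `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot parse volume file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
  out
}

#' Write a phantom-truth bundle
#'
#' One NIfTI file per map plus a plain-text `manifest.txt` of
#' `key: value` lines describing the bundle.
#'
#' @param truth A [build_phantom()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- c("pve_gm", "pve_wm", "pve_csf", "region_labels", "true_cbf")
  for (m in maps)
    write_volume(truth[[m]], file.path(dir, paste0(m, ".nii.gz")),
                 truth$voxel_size_mm)
  cfg <- truth$config
  lines <- c(paste0("grid_shape: ", paste(cfg$grid_shape, collapse = " ")),
             paste0("voxel_size_mm: ", paste(cfg$voxel_size_mm, collapse = " ")),
             paste0("true_wm_cbf: ", cfg$true_wm_cbf),
             paste0("noise_sd_fraction: ", cfg$noise_sd_fraction),
             paste0("seed: ", cfg$seed),
             vapply(names(cfg$true_gm_cbf_by_region), function(r)
               paste0("true_gm_cbf_", r, ": ", cfg$true_gm_cbf_by_region[[r]]),
               ""),
             paste0("maps: ", paste(maps, collapse = " ")))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .check_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the fixed schema: `subject_id`, `visit_time_years` and `mmse`
#' are required; covariate and `cbf_*` columns are carried through.
#'
#' @param path CSV path.
#' @return A cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit_time_years", "mmse")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  d
}
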