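# File interchange: waveform CSV + JSON header, DWI volumes as NIfTI with
# FSL-style .bval/.bvec sidecars, phantom region maps as NIfTI labels.

#' Write a gradient waveform to CSV + JSON header
#'
#' The CSV has columns `time_s` (midpoint sample times) and
#' `amplitude_T_per_m`; the JSON header records `dt`, `refocus_index`,
#' `axis`, the achieved b-value and the effective moments.
#'
#' @param wf A [gradient_waveform()].
#' @param path CSV output path; the header is written next to it with
#'   extension `.json`.
#' @param gamma Gyromagnetic ratio used for the recorded b-value.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path, gamma = GAMMA_PROTON) {
  stopifnot(inherits(wf, "gradient_waveform"))
  df <- data.frame(time_s = sample_times(wf), amplitude_T_per_m = wf$samples)
  utils::write.csv(df, path, row.names = FALSE)
  m <- gradient_moments(wf)
  hdr <- list(dt = wf$dt,
              refocus_index = wf$refocus_index,
              axis = wf$axis,
              gamma = gamma,
              b_value_s_per_mm2 = numerical_bvalue(wf, gamma),
              moments = list(m0 = m$m0, m1 = m$m1, m2 = m$m2))
  jsonlite::write_json(hdr, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a gradient waveform written by [write_waveform()]
#'
#' @param path CSV path (the JSON header is expected alongside).
#' @return A [gradient_waveform()].
#' @export
read_waveform <- function(path) {
  df <- utils::read.csv(path)
  hdr <- jsonlite::read_json(sub("\\.[^.]*$", ".json", path),
                             simplifyVector = TRUE)
  gradient_waveform(df$amplitude_T_per_m, dt = hdr$dt,
                    refocus_index = hdr$refocus_index,
                    axis = hdr$axis)
}

#' Write a DWI dataset as NIfTI + bval/bvec sidecars
#'
#' Writes `<prefix>.nii.gz` (4-D volumes), `<prefix>_mask.nii.gz`,
#' `<prefix>.bval` (one row of b-values) and `<prefix>.bvec` (three rows:
#' x, y, z components), the FSL sidecar convention.
#'
#' @param dwi A `dwi_dataset`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  img <- RNifti::asNifti(dwi$volumes)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  msk <- RNifti::asNifti(array(as.integer(dwi$mask), dim(dwi$mask)))
  RNifti::pixdim(msk) <- dwi$voxel_size
  RNifti::writeNifti(msk, paste0(prefix, "_mask.nii.gz"))
  writeLines(paste(format(dwi$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  bv <- t(dwi$bvecs)   # 3 x n
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read a DWI dataset from NIfTI + bval/bvec sidecars
#'
#' @param prefix Path prefix as used by [write_dwi()]; `<prefix>_mask.nii.gz`
#'   is optional (all-true mask if absent).
#' @return A `dwi_dataset`.
#' @export
read_dwi <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  vols <- array(as.numeric(img), dim(img))
  if (length(dim(vols)) == 3) dim(vols) <- c(dim(vols), 1L)
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvec_rows <- as.matrix(utils::read.table(paste0(prefix, ".bvec")))
  bvecs <- t(bvec_rows)   # n x 3
  stopifnot(length(bvals) == dim(vols)[4], nrow(bvecs) == length(bvals))
  mask_path <- paste0(prefix, "_mask.nii.gz")
  mask <- if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    array(as.numeric(m) > 0, dim(vols)[1:3])
  } else array(TRUE, dim(vols)[1:3])
  vx <- RNifti::pixdim(img)[1:3]
  structure(list(volumes = vols, bvals = bvals, bvecs = bvecs, mask = mask,
                 voxel_size = vx),
            class = "dwi_dataset")
}

#' Write a scalar map as NIfTI
#'
#' @param map A `scalar_map`.
#' @param path Output `.nii.gz` path.
#' @param voxel_size Voxel edge lengths (mm).
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(map, path, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(map, "scalar_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a phantom's region map as a NIfTI label volume
#'
#' @param phantom A [phantom_spec()].
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  img <- RNifti::asNifti(phantom$region_map)
  RNifti::pixdim(img) <- phantom$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize a phantom specification (without voxel data) to JSON
#'
#' Records the region table, voxel size, grid and motion state — the
#' provenance needed to regenerate or document a phantom.
#'
#' @param phantom A [phantom_spec()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_phantom_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  obj <- list(grid = dim(phantom$region_map),
              voxel_size_mm = phantom$voxel_size,
              regions = phantom$region_table,
              motion = unclass(phantom$motion))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
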