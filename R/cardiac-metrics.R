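# Non-diffusion quantitative cardiac analyses: left-ventricular volumes and
# ejection fraction by Simpson disk summation, and extracellular volume
# fraction from pre/post-contrast T1 and hematocrit.

#' Ventricular volume by Simpson's disk summation
#'
#' Volume = sum of slice areas times slice thickness; 1 mm^3 = 1 uL.
#'
#' @param slice_areas Per-slice cavity areas (mm^2), >= 0.
#' @param thickness Slice thickness (mm), > 0.
#' @return Volume in uL.
#' @export
simpson_volume <- function(slice_areas, thickness) {
  if (length(slice_areas) == 0) stop("at least one slice area is required")
  stopifnot(all(slice_areas >= 0), thickness > 0)
  sum(slice_areas) * thickness
}

#' Left-ventricular ejection fraction
#'
#' LVEF (%) = 100 * (EDV - ESV) / EDV.
#'
#' @param edv End-diastolic volume (uL), > 0.
#' @param esv End-systolic volume (uL), 0 <= ESV <= EDV.
#' @return Ejection fraction in percent.
#' @export
ejection_fraction <- function(edv, esv) {
  stopifnot(edv > 0, esv >= 0)
  if (esv > edv) stop("end-systolic volume cannot exceed end-diastolic volume")
  100 * (edv - esv) / edv
}

#' Myocardial extracellular volume fraction
#'
#' The standard hematocrit-corrected relaxation-rate ratio:
#' ECV (%) = 100 * (1 - Hct) * (1/T1_myo_post - 1/T1_myo_pre) /
#' (1/T1_blood_post - 1/T1_blood_pre).
#'
#' @param t1_myo_pre,t1_myo_post Native and post-contrast myocardial T1 (ms).
#' @param t1_blood_pre,t1_blood_post Native and post-contrast blood-pool T1 (ms).
#' @param hct Hematocrit (fraction in (0, 1)).
#' @return ECV in percent.
#' @export
ecv_fraction <- function(t1_myo_pre, t1_myo_post,
                         t1_blood_pre, t1_blood_post, hct) {
  stopifnot(t1_myo_pre > 0, t1_myo_post > 0, t1_blood_pre > 0,
            t1_blood_post > 0, hct > 0, hct < 1)
  if (t1_myo_post > t1_myo_pre || t1_blood_post > t1_blood_pre)
    stop("post-contrast T1 must not exceed native T1")
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_pre
  if (dr1_blood <= 0) stop("blood Delta-R1 must be positive")
  dr1_myo <- 1 / t1_myo_post - 1 / t1_myo_pre
  100 * (1 - hct) * dr1_myo / dr1_blood
}
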