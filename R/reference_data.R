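# Published summary tables of the ALS FDG-PET/CT reference cohort (62
# patients, 56 with follow-up) that the package defaults are calibrated
# against. Only printed summary numbers are reproduced here — the
# underlying scans and per-subject records are not publicly deposited.

#' Reference cohort: median-split subgroup counts and Cox results
#'
#' Per stratification variable, the printed subgroup sizes, death counts
#' and univariate hazard ratios of the 56-patient follow-up cohort, split
#' at each variable's median (\code{group} "low" = at or below the
#' median, the reference level). The spinal cord N-SUV split is the one
#' retained by the multivariate step-down model (HR 5.17, CI 1.74-15.38).
#'
#' @return data.frame with columns \code{variable}, \code{median_value},
#'   \code{group}, \code{n}, \code{deaths}, \code{hazard_ratio},
#'   \code{ci95_low}, \code{ci95_high}, \code{p_value} (HR columns NA on
#'   reference rows).
#' @seealso [mortalityRate()], [outcomeTable()]
#' @export
referenceOutcomeCounts <- function() {
  data.frame(
    variable = rep(c("age_years", "psoas_volume_mL_per_kg", "psoas_n_suv",
                     "ba4_suv", "alsfrs_r", "psoas_vc_suv_pct",
                     "spinal_cord_n_suv"), each = 2L),
    median_value = rep(c(63, 3.4, 0.42, 5.48, 40, 6.59, 0.92), each = 2L),
    group = rep(c("low", "high"), 7L),
    n = rep(28L, 14L),
    deaths = c(7L, 14L, 13L, 8L, 9L, 12L, 14L, 7L, 10L, 11L, 6L, 15L,
               4L, 17L),
    hazard_ratio = c(NA, 2.37, 2.17, NA, NA, 1.58, 3.38, NA, NA, 1.36,
                     NA, 4.23, NA, 9.27),
    ci95_low = c(NA, 0.77, 0.717, NA, NA, 0.53, 1.09, NA, NA, 0.46,
                 NA, 1.31, NA, 2.5),
    ci95_high = c(NA, 7.32, 6.550, NA, NA, 4.71, 10.55, NA, NA, 4.06,
                  NA, 13.62, NA, 34.1),
    p_value = c(NA, 0.1, 0.17, NA, NA, 0.41, 0.03, NA, NA, 0.57,
                NA, 0.016, NA, 0.001))
}

#' Reference cohort: overall follow-up counts
#'
#' @return list with \code{n} (56 patients with follow-up data),
#'   \code{deaths} (21) and \code{lostToFollowup} (6 of the original 62).
#' @export
referenceFollowup <- function() {
  list(n = 56L, deaths = 21L, lostToFollowup = 6L)
}

#' Reference cohort: FDG uptake summary statistics
#'
#' Printed mean, SD, median and quartiles of the liver-normalized uptake
#' (N-SUV; raw SUV for the brain rows) per region and cohort.
#'
#' @return data.frame with columns \code{region}, \code{cohort}
#'   (\code{"ALS"} / \code{"control"}), \code{mean}, \code{sd},
#'   \code{median}, \code{q1}, \code{q3}, \code{iqr} (as printed).
#' @export
referenceUptakeSummary <- function() {
  data.frame(
    region = rep(c("spinal_cord", "cervical_spinal_cord",
                   "dorsal_spinal_cord", "ba4", "whole_brain", "psoas"),
                 each = 2L),
    cohort = rep(c("ALS", "control"), 6L),
    mean = c(0.76, 0.66, 0.96, 0.73, 0.69, 0.64, 5.59, 6.67, 5.11, 5.95,
             0.45, 0.29),
    sd = c(0.2, 0.12, 0.3, 0.2, 0.22, 0.11, 1.3, 0.3, 1.3, 0.2,
           0.19, 0.09),
    median = c(0.74, 0.65, 0.94, 0.70, 0.65, 0.66, 5.03, 6.3, 5.08, 5.98,
               0.43, 0.28),
    q1 = c(0.59, 0.59, 0.74, 0.64, 0.53, 0.25, 4.75, 6.29, 4.52, 5.64,
           0.36, 0.23),
    q3 = c(0.86, 0.79, 1.15, 0.96, 0.79, 0.40, 6.48, 7.18, 6.54, 6.41,
           0.55, 0.35),
    iqr = c(0.27, 0.20, 0.41, 0.32, 0.26, 0.15, 1.73, 0.89, 2.02, 0.77,
            0.19, 0.12))
}
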