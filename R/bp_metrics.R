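#' Average two blood-pressure readings
#'
#' Visit-level SBP/DBP are the arithmetic mean of the two readings taken at
#' the assessment.
#'
#' @param r1,r2 readings in mmHg (must be positive).
#' @return mean pressure, mmHg.
#' @export
average_readings <- function(r1, r2) {
  if (any(!is.finite(r1) | !is.finite(r2) | r1 <= 0 | r2 <= 0))
    stop("blood-pressure readings must be positive and finite")
  (r1 + r2) / 2
}

#' Mean arterial pressure
#'
#' MAP = (SBP + 2 DBP) / 3, i.e. one third systolic plus two thirds
#' diastolic pressure.
#'
#' @param sbp,dbp systolic / diastolic pressure, mmHg.
#' @return MAP, mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) (sbp + 2 * dbp) / 3

#' Classify hypertension
#'
#' A visit is hypertensive when mean SBP is higher than 140 mmHg, mean DBP is
#' higher than 90 mmHg (both strict), or the participant is on
#' anti-hypertensive medication.
#'
#' @param sbp,dbp visit pressures, mmHg.
#' @param on_med logical/0-1 flag for anti-hypertensive medication use.
#' @param sbp_threshold,dbp_threshold strict cutoffs, mmHg.
#' @return logical flag.
#' @export
classify_hypertension <- function(sbp, dbp, on_med = FALSE,
                                  sbp_threshold = 140, dbp_threshold = 90) {
  sbp > sbp_threshold | dbp > dbp_threshold | as.logical(on_med)
}

#' Classify optimal blood pressure
#'
#' Optimal BP is SBP below 115 mmHg and DBP below 75 mmHg (both strict),
#' the range associated with minimal cardiovascular risk.
#'
#' @param sbp,dbp visit pressures, mmHg.
#' @param sbp_threshold,dbp_threshold strict cutoffs, mmHg.
#' @return logical flag.
#' @export
classify_optimal_bp <- function(sbp, dbp, sbp_threshold = 115,
                                dbp_threshold = 75) {
  sbp < sbp_threshold & dbp < dbp_threshold
}

#' Center a blood-pressure value on its minimum-risk threshold
#'
#' Model coefficients are expressed per mmHg above the measure-specific
#' centering constant: 90 for MAP, 114 for SBP, 74 for DBP.
#'
#' @param value pressure, mmHg.
#' @param measure one of `"MAP"`, `"SBP"`, `"DBP"` (case-insensitive).
#' @return mmHg above the threshold (can be negative).
#' @export
center_bp <- function(value, measure) {
  centers <- c(MAP = 90, SBP = 114, DBP = 74)
  m <- toupper(measure)
  if (any(!m %in% names(centers)))
    stop("unknown BP measure label: ", paste(setdiff(m, names(centers)),
                                             collapse = ", "))
  value - unname(centers[m])
}

#' Flag blood-pressure outliers beyond k standard deviations
#'
#' Flags values whose absolute deviation from the sample mean exceeds
#' `k` sample standard deviations.  With all-identical values no flags are
#' raised (a warning notes the degenerate sample).
#'
#' @param values numeric vector, mmHg.
#' @param k SD multiplier (default 3).
#' @return logical vector of exclusion flags.
#' @export
flag_bp_outliers <- function(values, k = 3) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) return(rep(FALSE, length(values)))
  s <- sd(values)
  if (s == 0) {
    warning("all values identical; SD is zero, no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  if (is.infinite(k)) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > k * s
}

#' Append derived blood-pressure columns to a visit table
#'
#' Computes visit-level SBP/DBP (mean of the two readings), MAP, the
#' hypertension and optimal-BP classifications, and threshold-centered
#' pressures.
#'
#' @param visits visit table with `sbp_reading_1/2`, `dbp_reading_1/2` and
#'   (for the hypertension rule) `on_bp_med`.
#' @return `visits` with columns `sbp`, `dbp`, `map`, `hypertensive`,
#'   `optimal`, `map_c`, `sbp_c`, `dbp_c` appended.
#' @export
add_bp_measures <- function(visits) {
  need <- c("sbp_reading_1", "sbp_reading_2", "dbp_reading_1", "dbp_reading_2")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visits is missing column(s): ",
                         paste(miss, collapse = ", "))
  visits$sbp <- average_readings(visits$sbp_reading_1, visits$sbp_reading_2)
  visits$dbp <- average_readings(visits$dbp_reading_1, visits$dbp_reading_2)
  visits$map <- mean_arterial_pressure(visits$sbp, visits$dbp)
  on_med <- visits$on_bp_med %||% FALSE
  visits$hypertensive <- as.integer(classify_hypertension(visits$sbp,
                                                          visits$dbp, on_med))
  visits$optimal <- as.integer(classify_optimal_bp(visits$sbp, visits$dbp))
  visits$map_c <- center_bp(visits$map, "MAP")
  visits$sbp_c <- center_bp(visits$sbp, "SBP")
  visits$dbp_c <- center_bp(visits$dbp, "DBP")
  visits
}
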