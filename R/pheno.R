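#' Body mass index
#'
#' @param weight_kg Weight in kilograms (> 0).
#' @param height_cm Height in centimeters (> 0).
#' @return BMI in kg/m^2 (vectorized).
#' @export
#' @examples
#' bmi(20, 100) # 20
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_cm <= 0, na.rm = TRUE)) {
    stop_invalid("weight and height must be positive")
  }
  weight_kg / (height_cm / 100)^2
}

#' Read an age- and sex-specific reference table
#'
#' TSV with columns `sex` (M/F), `age_years`, then either `L`, `M`, `S`
#' (LMS growth reference) or `cutoff` (dichotomization threshold). The age
#' grid must be strictly increasing within sex. Reference tables (IOTF,
#' British growth, NHANES) are third-party data supplied by the user; the
#' package ships only a small synthetic reference for its simulated
#' pipeline.
#'
#' @param path TSV path.
#' @return A tibble with class `reference_table`.
#' @export
read_reference_table <- function(path) {
  ref <- readr::read_tsv(path, show_col_types = FALSE)
  validate_reference_table(ref)
}

#' Validate (and class) a reference table built in code
#'
#' @param ref Data frame with columns `sex`, `age_years` and `L`,`M`,`S` or
#'   `cutoff`.
#' @return The validated tibble with class `reference_table`.
#' @export
validate_reference_table <- function(ref) {
  ref <- tibble::as_tibble(ref)
  if (!all(c("sex", "age_years") %in% names(ref))) {
    stop_invalid("reference table needs columns sex, age_years")
  }
  has_lms <- all(c("L", "M", "S") %in% names(ref))
  has_cut <- "cutoff" %in% names(ref)
  if (!has_lms && !has_cut) {
    stop_invalid("reference table needs either L,M,S or cutoff columns")
  }
  if (!all(ref$sex %in% c("M", "F"))) stop_invalid("sex must be M or F")
  if (has_lms && (any(ref$M <= 0) || any(ref$S <= 0))) {
    stop_invalid("reference M and S must be positive")
  }
  for (s in unique(ref$sex)) {
    a <- ref$age_years[ref$sex == s]
    if (any(diff(a) <= 0)) stop_invalid("age grid must be strictly increasing within sex")
  }
  class(ref) <- c("reference_table", class(ref))
  ref
}

# linearly interpolate reference columns at (age, sex); no extrapolation
interp_reference <- function(reference, age, sex, cols) {
  out <- matrix(NA_real_, length(age), length(cols),
                dimnames = list(NULL, cols))
  for (s in unique(sex[!is.na(sex)])) {
    sub <- reference[reference$sex == s, ]
    if (nrow(sub) == 0) stop_invalid(paste("no reference rows for sex", s))
    sel <- which(sex == s)
    a <- age[sel]
    if (any(a < min(sub$age_years) - 1e-9 | a > max(sub$age_years) + 1e-9,
            na.rm = TRUE)) {
      rlang::abort(paste0("age outside the reference grid [",
                          min(sub$age_years), ", ", max(sub$age_years),
                          "] for sex ", s),
                   class = "prsgxe_out_of_range")
    }
    for (cl in cols) {
      out[sel, cl] <- stats::approx(sub$age_years, sub[[cl]], xout = a,
                                    rule = 1)$y
    }
  }
  out
}

#' LMS z-score
#'
#' Converts a raw anthropometric value to an age- and sex-specific z-score
#' with the LMS transformation: `z = ((value/M)^L - 1) / (L S)` for `L != 0`
#' and `z = log(value/M) / S` at `L = 0`, with L, M, S linearly interpolated
#' on the reference age grid.
#'
#' @param value Positive measurement (e.g. BMI, waist circumference).
#' @param age Age in years (inside the reference grid).
#' @param sex `"M"` / `"F"`.
#' @param reference A `reference_table` with L, M, S columns.
#' @return Numeric z-score (vectorized).
#' @export
lms_zscore <- function(value, age, sex, reference) {
  if (any(value <= 0, na.rm = TRUE)) stop_invalid("value must be positive")
  lms <- interp_reference(reference, age, sex, c("L", "M", "S"))
  L <- unname(lms[, "L"]); M <- unname(lms[, "M"]); S <- unname(lms[, "S"])
  as.numeric(ifelse(abs(L) < 1e-12,
                    log(value / M) / S,
                    ((value / M)^L - 1) / (L * S)))
}

#' Age- and sex-specific dichotomization
#'
#' `classify_obese()` flags BMI at or above the interpolated obesity cutoff
#' (e.g. 19.76 for 6.0-year-old boys, 19.62 for girls under the extended
#' IOTF criteria); `classify_wc_top_quartile()` applies the same rule to
#' waist circumference against top-quartile reference cutoffs (58.3 /
#' 57.2 cm at age 6.0).
#'
#' @param bmi,wc Raw measurement.
#' @param age Age in years.
#' @param sex `"M"` / `"F"`.
#' @param cutoffs A `reference_table` with a `cutoff` column.
#' @return Integer 0/1 (NA propagates).
#' @export
classify_obese <- function(bmi, age, sex, cutoffs) {
  cut <- unname(interp_reference(cutoffs, age, sex, "cutoff")[, 1])
  as.integer(bmi >= cut)
}

#' @rdname classify_obese
#' @export
classify_wc_top_quartile <- function(wc, age, sex, cutoffs) {
  cut <- unname(interp_reference(cutoffs, age, sex, "cutoff")[, 1])
  as.integer(wc >= cut)
}

#' Fruit and vegetable score from FFQ frequencies
#'
#' Relative weekly consumption frequency of fruit/vegetable items among all
#' reported food items, in percent.
#'
#' @param ffq_frequencies Named (or positional) nonnegative vector of weekly
#'   item frequencies.
#' @param fruit_veg_items Indices or names of the fruit/vegetable items.
#' @return Percent in `[0, 100]`; `NA` (with a message) when nothing was
#'   reported.
#' @export
fruit_veg_score <- function(ffq_frequencies, fruit_veg_items) {
  if (any(ffq_frequencies < 0, na.rm = TRUE)) {
    stop_invalid("FFQ frequencies must be nonnegative")
  }
  total <- sum(ffq_frequencies, na.rm = TRUE)
  if (total <= 0) {
    inform("total FFQ frequency is zero; fruit/veg score set to missing")
    return(NA_real_)
  }
  100 * sum(ffq_frequencies[fruit_veg_items], na.rm = TRUE) / total
}

#' Fiber density from 24-hour recalls
#'
#' Fiber relative to total energy intake, mg/kcal, averaged over the
#' available recalls of one visit.
#'
#' @param fiber_g Fiber intake per recall, grams/day.
#' @param energy_kcal Energy intake per recall, kcal/day (> 0).
#' @return Mean mg/kcal across recalls; `NA` (with a message) if no recall
#'   has positive energy.
#' @export
fiber_density <- function(fiber_g, energy_kcal) {
  if (length(fiber_g) != length(energy_kcal)) {
    stop_invalid("fiber and energy vectors must have equal length")
  }
  ok <- !is.na(fiber_g) & !is.na(energy_kcal) & energy_kcal > 0
  if (!any(ok)) {
    inform("no recall with positive energy intake; fiber density set to missing")
    return(NA_real_)
  }
  mean(1000 * fiber_g[ok] / energy_kcal[ok])
}

#' Daily screen time from weekday/weekend device hours
#'
#' Per device, daily hours = (5 * weekday + 2 * weekend) / 7; device totals
#' (TV and computer/console) are summed and capped at 8 h/day. The 5:2
#' weekday:weekend weighting is the standard week-structure weighting and
#' is configurable.
#'
#' @param weekday_hours,weekend_hours Numeric vectors of per-device usual
#'   hours per day (nonnegative), aligned by device.
#' @param weights Length-2 `(weekday, weekend)` day counts, default `c(5, 2)`.
#' @param cap Upper bound in h/day, default 8.
#' @return Total daily screen time in hours.
#' @export
screen_time_daily <- function(weekday_hours, weekend_hours,
                              weights = c(5, 2), cap = 8) {
  if (any(c(weekday_hours, weekend_hours) < 0, na.rm = TRUE)) {
    stop_invalid("screen time components must be nonnegative")
  }
  if (length(weekday_hours) != length(weekend_hours)) {
    stop_invalid("weekday and weekend vectors must align by device")
  }
  per_device <- (weights[1] * weekday_hours + weights[2] * weekend_hours) /
    sum(weights)
  min(sum(per_device), cap)
}

#' Daily MVPA hours from per-minute accelerometer counts
#'
#' A day is valid when it has at least `min_wear_min` valid worn minutes; a
#' child-visit needs at least `min_days` valid days, otherwise the value is
#' missing. MVPA minutes are minutes with counts at or above `cutpoint`
#' (default 2296 counts/min, the Evenson threshold), averaged over valid
#' days and expressed in hours/day.
#'
#' @param epoch_counts List with one numeric vector of per-minute counts per
#'   measurement day (NA = non-wear minute).
#' @param cutpoint Counts/min defining MVPA.
#' @param min_days Minimum number of valid days (default 3).
#' @param min_wear_min Minimum valid minutes per day (default 360).
#' @return Hours/day, or `NA` when the wear criteria fail.
#' @export
mvpa_hours <- function(epoch_counts, cutpoint = 2296, min_days = 3,
                       min_wear_min = 360) {
  if (length(epoch_counts) == 0) {
    inform("no accelerometer days supplied; MVPA set to missing")
    return(NA_real_)
  }
  day_valid <- vapply(epoch_counts, function(d) sum(!is.na(d)) >= min_wear_min,
                      logical(1))
  if (sum(day_valid) < min_days) return(NA_real_)
  daily <- vapply(epoch_counts[day_valid],
                  function(d) sum(d >= cutpoint, na.rm = TRUE) / 60,
                  numeric(1))
  mean(daily)
}

#' Build a synthetic LMS reference from a sample of measurements
#'
#' Fits, per sex and a coarse age grid, the median and coefficient of
#' variation of the supplied measurements (L fixed at 1, i.e. a normal
#' approximation). This is a toy reference for simulated pipelines only —
#' it is NOT a substitute for published growth references and is labelled
#' synthetic wherever written.
#'
#' @param data Data frame with columns `age`, `sex` and the measurement
#'   named by `var`.
#' @param var Measurement column name.
#' @param age_breaks Grid spacing in years (default 1).
#' @return A `reference_table` with L, M, S columns.
#' @export
synthetic_lms_reference <- function(data, var, age_breaks = 1) {
  grid <- seq(floor(min(data$age)), ceiling(max(data$age)), by = age_breaks)
  out <- tidyr::expand_grid(sex = c("M", "F"), age_years = grid)
  out$L <- 1
  ms <- purrr::pmap_dfr(out, function(sex, age_years, L) {
    sel <- data$sex == sex & abs(data$age - age_years) <= age_breaks
    x <- data[[var]][sel]
    x <- x[!is.na(x)]
    if (length(x) < 5) return(tibble::tibble(M = NA_real_, S = NA_real_))
    tibble::tibble(M = stats::median(x), S = max(sd(x), 1e-6) / stats::median(x))
  })
  out <- dplyr::bind_cols(out, ms)
  out <- tidyr::fill(dplyr::group_by(out, .data$sex), "M", "S",
                     .direction = "downup")
  validate_reference_table(dplyr::ungroup(out))
}
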