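test_that("bmi arithmetic and preconditions", {
  expect_equal(bmi(20, 100), 20.0)
  expect_equal(bmi(30, 125), 19.2)  # 30 / 1.5625
  expect_error(bmi(0, 100), class = "prsgxe_invalid_argument")
  expect_error(bmi(20, -5), class = "prsgxe_invalid_argument")
})

test_that("LMS z-scores: definition, L = 1 algebra, L -> 0 continuity", {
  ref <- toy_lms_reference()
  # value at the median is z = 0 at any grid age
  for (a in c(2, 6, 16)) {
    M <- ref$M[ref$sex == "F" & ref$age_years == a]
    expect_equal(lms_zscore(M, a, "F", ref), 0, tolerance = 1e-12)
  }
  # L = 1 reduces to (value - M) / (M * S)
  ref1 <- validate_reference_table(tibble::tibble(
    sex = "M", age_years = c(4, 8), L = 1, M = c(15, 16), S = c(0.1, 0.12)))
  expect_equal(lms_zscore(18, 4, "M", ref1), (18 - 15) / (15 * 0.1),
               tolerance = 1e-12)
  # interpolation at age 6: L,M,S averaged
  expect_equal(lms_zscore(17, 6, "M", ref1), (17 - 15.5) / (15.5 * 0.11),
               tolerance = 1e-12)
  # continuity at L -> 0
  refL <- function(L) validate_reference_table(tibble::tibble(
    sex = "M", age_years = c(4, 8), L = L, M = 15, S = 0.1))
  expect_lt(abs(lms_zscore(18, 5, "M", refL(1e-6)) - log(18 / 15) / 0.1), 1e-4)
  # strictly increasing in value
  z <- lms_zscore(seq(12, 22, by = 0.5), 6, "M", ref)
  expect_true(all(diff(z) > 0))
  expect_error(lms_zscore(17, 30, "M", ref), class = "prsgxe_out_of_range")
  expect_error(lms_zscore(-1, 6, "M", ref), class = "prsgxe_invalid_argument")
})

test_that("obesity and waist-circumference cutoffs at age six", {
  bc <- toy_bmi_cutoffs()
  expect_equal(classify_obese(19.76, 6, "M", bc), 1L)
  expect_equal(classify_obese(19.62, 6, "F", bc), 1L)
  expect_equal(classify_obese(19.75, 6, "M", bc), 0L)
  wc <- toy_wc_cutoffs()
  expect_equal(classify_wc_top_quartile(58.3, 6, "M", wc), 1L)
  expect_equal(classify_wc_top_quartile(57.2, 6, "F", wc), 1L)
  expect_equal(classify_wc_top_quartile(57.1, 6, "F", wc), 0L)
  # monotone in the measurement under interpolation
  flags <- classify_obese(seq(15, 30, by = 0.5), 7.3, "F", bc)
  expect_true(all(diff(flags) >= 0))
  expect_error(classify_obese(20, 30, "M", bc), class = "prsgxe_out_of_range")
})

test_that("fruit/vegetable score is a relative frequency in percent", {
  expect_equal(fruit_veg_score(c(5, 10, 55), integer(0)), 0)
  expect_equal(fruit_veg_score(c(10, 20, 40), 1), 100 * 10 / 70,
               tolerance = 1e-12)
  expect_equal(fruit_veg_score(c(3, 7), c(1, 2)), 100)
  expect_message(out <- fruit_veg_score(c(0, 0), 1), "missing")
  expect_true(is.na(out))
  expect_error(fruit_veg_score(c(-1, 2), 1), class = "prsgxe_invalid_argument")
})

test_that("fiber density in mg/kcal, averaged over recalls", {
  expect_equal(fiber_density(16.34, 2000), 8.17)
  expect_equal(fiber_density(0, 2000), 0)
  expect_equal(fiber_density(c(16, 25), c(2000, 2500)), mean(c(8, 10)))
  expect_message(out <- fiber_density(10, 0), "missing")
  expect_true(is.na(out))
})

test_that("screen time uses 5:2 week weighting with an 8 h cap", {
  expect_equal(screen_time_daily(c(0, 0), c(0, 0)), 0)
  expect_equal(screen_time_daily(c(1, 1), c(3, 1)), 11 / 7 + 1,
               tolerance = 1e-12)
  expect_equal(screen_time_daily(c(8, 8), c(8, 8)), 8)  # capped
  expect_error(screen_time_daily(c(-1, 0), c(0, 0)),
               class = "prsgxe_invalid_argument")
})

test_that("MVPA wear-time rules", {
  day_min <- function(mvpa_min, total = 400) {
    c(rep(3000, mvpa_min), rep(100, total - mvpa_min))
  }
  # 2 valid days only (min_days = 3) -> missing
  expect_true(is.na(mvpa_hours(list(day_min(30), day_min(30), rep(100, 100)))))
  # 3 valid days with 60 MVPA minutes each -> 1 h/day
  expect_equal(mvpa_hours(list(day_min(60), day_min(60), day_min(60))), 1)
  # everything below the cutpoint -> 0
  expect_equal(mvpa_hours(rep(list(rep(100, 400)), 3)), 0)
  expect_message(out <- mvpa_hours(list()), "missing")
  expect_true(is.na(out))
})

test_that("reference tables validate and round-trip through TSV", {
  expect_error(validate_reference_table(tibble::tibble(
    sex = "M", age_years = 1)), class = "prsgxe_invalid_argument")
  expect_error(validate_reference_table(tibble::tibble(
    sex = c("M", "M"), age_years = c(2, 2), cutoff = c(1, 2))),
    class = "prsgxe_invalid_argument")
  expect_error(validate_reference_table(tibble::tibble(
    sex = "M", age_years = 1, L = 1, M = -2, S = 0.1)),
    class = "prsgxe_invalid_argument")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_bmi_cutoffs(), tmp)
  back <- read_reference_table(tmp)
  expect_equal(back$cutoff, toy_bmi_cutoffs()$cutoff)

  shipped <- read_reference_table(
    system.file("extdata", "synthetic_bmi_cutoffs.tsv", package = "prsgxe"))
  expect_s3_class(shipped, "reference_table")
})

test_that("a synthetic LMS reference reproduces its source distribution", {
  set.seed(1)
  n <- 4000
  dat <- tibble::tibble(
    age = runif(n, 2, 12),
    sex = sample(c("M", "F"), n, TRUE),
    bmi = rnorm(n, 16 + 0.3 * age, 1.5)
  )
  ref <- synthetic_lms_reference(dat, "bmi")
  z <- lms_zscore(dat$bmi, dat$age, dat$sex, ref)
  expect_lt(abs(median(z)), 0.1)
})
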