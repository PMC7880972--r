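test_that("NFS formula: hand evaluation, intercept limit, monotonicity", {
  # whole-cohort means through the printed formula, by hand:
  # -1.675 + 0.037*46 + 0.094*26.02 + 1.13 + 0.99*(52/77)
  #   - 0.013*210 - 0.66*4.7 = -1.5605
  expect_equal(nfs(46, bmi = 26.02, dm = 1, ast = 52, alt = 77,
                   platelets = 210, albumin = 4.7),
               -1.561, tolerance = 5e-4)
  # algebraic intercept limit
  eps <- 1e-9
  expect_equal(nfs(eps, bmi = eps, dm = 0, ast = eps, alt = 1,
                   platelets = eps, albumin = 1.0) + 0.66,
               -1.675, tolerance = 1e-6)
  # platelets strictly decrease the score
  s1 <- nfs(50, bmi = 25, dm = 0, ast = 40, alt = 50, platelets = 150,
            albumin = 4)
  s2 <- nfs(50, bmi = 25, dm = 0, ast = 40, alt = 50, platelets = 250,
            albumin = 4)
  expect_lt(s2, s1)
  # monotone directions across all covariates
  base <- list(age = 50, bmi = 25, dm = 0, ast = 40, alt = 50,
               platelets = 200, albumin = 4)
  f <- function(l) nfs(l$age, bmi = l$bmi, dm = l$dm, ast = l$ast,
                       alt = l$alt, platelets = l$platelets,
                       albumin = l$albumin)
  up <- function(nm, delta) { l <- base; l[[nm]] <- l[[nm]] + delta; f(l) }
  expect_gt(up("age", 5), f(base))
  expect_gt(up("bmi", 2), f(base))
  expect_gt(up("dm", 1), f(base))
  expect_gt(up("ast", 10), f(base))   # raises AST/ALT
  expect_lt(up("platelets", 50), f(base))
  expect_lt(up("albumin", 0.5), f(base))
})

test_that("NFS albumin unit guard", {
  expect_error(nfs(46, bmi = 26, dm = 0, ast = 40, alt = 50,
                   platelets = 200, albumin = 47), "units")
  rec <- clinical_record(46, "female", 26, FALSE, 40, 50, 200, 47,
                         albumin_unit = "g/L")
  expect_equal(rec$albumin, 4.7)
  expect_error(clinical_record(46, "female", 26, FALSE, 40, 50, 200, 47,
                               albumin_unit = "g/dL"), "g/L")
})

test_that("FIB-4: hand evaluation, zero AST, linearity in age", {
  expect_equal(fib4(46, ast = 52, alt = 77, platelets = 210),
               1.298, tolerance = 5e-4)
  expect_equal(fib4(46, ast = 1e-12, alt = 77, platelets = 210), 0,
               tolerance = 1e-10)
  expect_equal(fib4(92, ast = 52, alt = 77, platelets = 210),
               2 * fib4(46, ast = 52, alt = 77, platelets = 210))
  expect_error(fib4(46, ast = 52, alt = 0, platelets = 210), "positive")
})

test_that("LSM reliability rule", {
  mk <- function(median, iqr_ratio, n) {
    # symmetric three-point series with prescribed median and IQR/median
    half <- iqr_ratio * median / 2
    base <- rep(c(median - half, median, median + half), length.out = n)
    base
  }
  r1 <- lsm_reliable(mk(9.0, 0.25, 10))
  expect_true(r1$reliable)
  r2 <- lsm_reliable(mk(6.5, 0.40, 10))
  expect_true(r2$reliable)        # second clause: median < 7.1
  r3 <- lsm_reliable(mk(9.0, 0.40, 10))
  expect_false(r3$reliable)
  r4 <- lsm_reliable(mk(9.0, 0.10, 9))
  expect_false(r4$reliable)       # < 10 measurements
  expect_error(lsm_reliable(numeric()), "empty")
})

test_that("score band boundaries", {
  expect_equal(as.character(fib4_band(c(1.29, 1.3, 3.25, 3.26))),
               c("low", "intermediate", "intermediate", "high"))
  expect_equal(as.character(nfs_band(c(-1.456, -1.455, 0.672, 0.673))),
               c("low", "intermediate", "intermediate", "high"))
  expect_equal(as.character(lsm_band(c(7.99, 8, 9.99, 10))),
               c("low", "intermediate", "intermediate", "high"))
})

test_that("exhaustive stratification truth table over band cross-product", {
  # representative score values per band, including every boundary
  fib4_vals <- list(low = c(0.5, 1.29), intermediate = c(1.3, 2.0, 3.25),
                    high = c(3.26, 5))
  nfs_vals <- list(low = c(-3, -1.456), intermediate = c(-1.455, 0, 0.672),
                   high = c(0.673, 2))
  lsm_vals <- list(low = c(5, 7.99), intermediate = c(8, 9.99),
                   high = c(10, 15))
  sev <- c(low = 1, intermediate = 2, high = 3)
  for (fb in names(fib4_vals)) for (nb in names(nfs_vals)) {
    for (fv in fib4_vals[[fb]]) for (nv in nfs_vals[[nb]]) {
      fl <- first_line_band(fv, nv)
      expected_fl <- if (fb == "low" || nb == "low") "low"
                     else names(sev)[max(sev[fb], sev[nb])]
      expect_equal(as.character(fl), expected_fl,
                   info = sprintf("fib4=%s nfs=%s", fv, nv))
      for (lb in names(lsm_vals)) for (lv in lsm_vals[[lb]]) {
        final <- if (expected_fl == "low") "low" else lb
        expect_equal(as.character(two_step_band(fv, nv, lv)), final,
                     info = sprintf("fib4=%s nfs=%s lsm=%s", fv, nv, lv))
      }
    }
  }
})

test_that("stratify on records: rules, basis and error paths", {
  lsm_series <- function(med) rep(c(med * 0.95, med, med * 1.05),
                                  length.out = 12)
  base <- function(lsm, ...) {
    # covariates tuned to land FIB-4 / NFS where each case needs them
    clinical_record(..., lsm_values = lsm)
  }
  # FIB-4 1.0-ish and NFS very low -> low, LSM never consulted
  r1 <- stratify(clinical_record(30, "female", 20, FALSE, 30, 60, 250, 4.5,
                                 lsm_values = numeric()))
  expect_equal(as.character(r1$final), "low")
  expect_equal(r1$basis, "first-line")
  expect_false(r1$binary)
  # non-low first line + LSM 12 -> high, binary TRUE
  rec2 <- clinical_record(60, "male", 33, TRUE, 80, 60, 150, 4.0,
                          lsm_values = lsm_series(12))
  r2 <- stratify(rec2)
  expect_equal(as.character(r2$final), "high")
  expect_true(r2$binary)
  # same labs, LSM 7 -> second line downgrades to low
  rec3 <- clinical_record(60, "male", 33, TRUE, 80, 60, 150, 4.0,
                          lsm_values = lsm_series(7))
  r3 <- stratify(rec3)
  expect_equal(as.character(r3$final), "low")
  expect_false(r3$binary)
  # non-low first line without (or with unreliable) LSM -> error
  rec4 <- clinical_record(60, "male", 33, TRUE, 80, 60, 150, 4.0,
                          lsm_values = numeric())
  expect_error(stratify(rec4), "no LSM")
  rec5 <- clinical_record(60, "male", 33, TRUE, 80, 60, 150, 4.0,
                          lsm_values = c(8, 9, 16, 30, 9, 8, 20, 9, 25))
  expect_error(stratify(rec5), "unreliable|excluded")
})

test_that("stratify_cohort round-trips the generator's latent labels", {
  cs <- cohort_spec(n_subjects = 53, frac_intermediate_high = 20 / 53,
                    rng_seed = 5L)
  gc <- generate_cohort(cs)
  expect_equal(sum(gc$cohort$group == "high"), 20)
  expect_equal(sum(gc$cohort$group == "low"), 33)
  risk <- stratify_cohort(gc$cohort)
  expect_equal(as.logical(risk$binary), gc$cohort$group == "high")
})
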