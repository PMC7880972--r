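test_that("univariate_compare gates on normality", {
  set.seed(1)
  # identical small groups: Mann-Whitney or t, p near 1
  x <- c(1, 2, 3, 4, 5)
  r0 <- univariate_compare(list(x, x))
  expect_gt(r0$p, 0.9)
  # lognormal data takes the Mann-Whitney branch
  a <- exp(rnorm(50, 0, 1.5)); b <- exp(rnorm(50, 0.3, 1.5))
  expect_lt(shapiro.test(a)$p.value, 0.05)  # oracle for the gate
  rl <- univariate_compare(list(a, b))
  expect_equal(rl$test, "mann-whitney")
  # clean normal data takes the t branch
  an <- rnorm(40); bn <- rnorm(40, 0.2)
  if (shapiro.test(an)$p.value > 0.05 && shapiro.test(bn)$p.value > 0.05) {
    rn <- univariate_compare(list(an, bn))
    expect_equal(rn$test, "t")
  }
  # constant group falls through to Mann-Whitney with a note
  rc <- univariate_compare(list(rep(1, 10), rnorm(10)))
  expect_equal(rc$test, "mann-whitney")
  expect_match(rc$note, "undefined")
  expect_error(univariate_compare(list(1:2, 1:5)), "at least 3")
})

test_that("univariate power: 2-SD shift at n=30/group", {
  set.seed(7)
  hits <- mean(vapply(1:200, function(i) {
    a <- rnorm(30, 0, 1); b <- rnorm(30, 2, 1)
    univariate_compare(list(a, b))$p < 0.001
  }, logical(1)))
  expect_gte(hits, 0.95)
})

test_that("roc_with_youden: separation, identity, null coverage", {
  # perfect separation
  r <- roc_with_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden, 1.0)
  expect_equal(r$youden, youden_index(r$sensitivity, r$specificity))
  # Youden identity on every curve row
  set.seed(2)
  s <- rnorm(60); y <- rbinom(60, 1, plogis(s))
  r2 <- roc_with_youden(s, y)
  expect_equal(r2$curve$youden,
               r2$curve$sensitivity + r2$curve$specificity - 1)
  expect_true(r2$ci_low <= r2$auc && r2$auc <= r2$ci_high)
  # constant scores
  rc <- roc_with_youden(rep(1, 20), rep(c(0, 1), 10))
  expect_equal(rc$auc, 0.5)
  expect_true(is.na(rc$cutoff) && isTRUE(rc$cutoff_undefined))
  expect_error(roc_with_youden(1:5, rep(1, 5)), "both classes")
})

test_that("AUC properties: complement and monotone invariance", {
  set.seed(3)
  for (i in 1:10) {
    s <- rnorm(40); y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    a1 <- roc_with_youden(s, y)$auc
    expect_equal(a1 + roc_with_youden(-s, y)$auc, 1, tolerance = 1e-12)
    expect_equal(roc_with_youden(exp(s / 2) + 5, y)$auc, a1,
                 tolerance = 1e-12)
  }
})

test_that("null ROC: AUC CI covers 0.5 about 95% of the time", {
  set.seed(11)
  cover <- mean(vapply(1:200, function(i) {
    s <- rnorm(200); y <- rbinom(200, 1, 0.5)
    r <- roc_with_youden(s, y)
    r$ci_low <= 0.5 && 0.5 <= r$ci_high
  }, logical(1)))
  expect_gt(cover, 0.90); expect_lt(cover, 0.99)
})

test_that("delong_compare: trivial identities and component oracle", {
  set.seed(4)
  s <- rnorm(30); y <- rbinom(30, 1, 0.5)
  d0 <- delong_compare(s, s, y)
  expect_equal(d0$difference, 0); expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  # monotone transform: AUC rank-invariant
  d1 <- delong_compare(s, exp(s), y)
  expect_equal(d1$difference, 0)
  # small paired example vs independent structural-components oracle
  for (i in 1:5) {
    sa <- rnorm(20); sb <- 0.5 * sa + rnorm(20)
    yy <- rbinom(20, 1, 0.5)
    if (sum(yy) < 2 || sum(1 - yy) < 2) next
    d <- delong_compare(sa, sb, yy)
    expect_equal(d$z, oracle_delong_z(sa, sb, yy), tolerance = 1e-8)
  }
  expect_error(delong_compare(1:4, 1:4, c(1, 0, 0, 0)), "at least 2")
})

test_that("stepwise_logistic: informative feature retrieved, null sane", {
  set.seed(5)
  # one true effect among 5 noise features
  hits <- mean(vapply(1:100, function(i) {
    n <- 400
    X <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("f", 1:6))))
    eta <- -0.3 + 1.0 * X$f1
    y <- rbinom(n, 1, plogis(eta))
    m <- stepwise_logistic(X, y, direction = "backward")
    "f1" %in% m$selected_features
  }, logical(1)))
  expect_gte(hits, 0.90)
  # null: forward selection stays (mostly) empty
  set.seed(6)
  empty <- mean(vapply(1:100, function(i) {
    n <- 150
    X <- as.data.frame(matrix(rnorm(n * 3), n,
                              dimnames = list(NULL, paste0("f", 1:3))))
    y <- rbinom(n, 1, 0.5)
    m <- stepwise_logistic(X, y, direction = "forward")
    length(m$selected_features) == 0
  }, logical(1)))
  expect_gte(empty, 0.75)  # approx (1 - 0.05)^3 = 0.857 with slack
})

test_that("stepwise deviance matches the best same-size subset", {
  set.seed(8)
  n <- 200
  X <- as.data.frame(matrix(rnorm(n * 3), n,
                            dimnames = list(NULL, c("a", "b", "c"))))
  y <- rbinom(n, 1, plogis(0.8 * X$a - 0.6 * X$b))
  m <- stepwise_logistic(X, y, direction = "backward")
  k <- length(m$selected_features)
  combos <- combn(names(X), k, simplify = FALSE)
  best <- min(vapply(combos, function(cc) {
    glm(y ~ ., data = cbind(y = y, X[, cc, drop = FALSE]),
        family = binomial())$deviance
  }, numeric(1)))
  expect_lt(abs(m$deviance - best), 1e-6)
  # nesting property: adding a feature never increases deviance
  d_full <- glm(y ~ ., data = cbind(y = y, X), family = binomial())$deviance
  expect_lte(d_full, m$deviance + 1e-10)
})

test_that("stepwise_logistic flags perfect separation", {
  X <- data.frame(x = c(-(10:1), 1:10))
  y <- c(rep(0, 10), rep(1, 10))
  expect_warning(m <- stepwise_logistic(X, y, direction = "backward"),
                 "separation")
  expect_true(m$separation)
  expect_true(all(is.finite(m$coefficients)))
  expect_error(stepwise_logistic(X, rep(1, 20)), "both classes")
})

test_that("hosmer_lemeshow: exact calibration, grouping, errors", {
  # observed = expected exactly at every probability level (levels chosen
  # so p * 10 is integral; any merging of adjacent levels preserves O = E)
  lv <- seq(0.1, 0.9, by = 0.1)
  p <- rep(lv, each = 10)
  y <- unlist(lapply(lv, function(pp) rep(c(1, 0),
                                          c(round(pp * 10),
                                            10 - round(pp * 10)))))
  hl <- hosmer_lemeshow(p, y)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)
  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)), "in \\(0,1\\)")
  # few distinct probabilities: groups merged, flagged
  hl2 <- hosmer_lemeshow(rep(c(0.15, 0.3, 0.5, 0.7, 0.85), each = 20),
                         rbinom(100, 1, 0.5))
  expect_true(hl2$merged)
  expect_lt(hl2$n_groups_used, 10)
})

test_that("hosmer_lemeshow: miscalibration is detected", {
  set.seed(9)
  rej <- mean(vapply(1:100, function(i) {
    n <- 500
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(x))
    fit <- glm(y ~ x, family = binomial())
    # squash fitted probabilities -> systematic miscalibration
    hosmer_lemeshow(fitted(fit)^2, y)$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.5)
})

test_that("ICC(3,1): trivial identities and ANOVA oracle", {
  set.seed(10)
  x <- rnorm(8, 10, 3)
  # duplicate columns
  r1 <- icc_two_way_mixed(cbind(x, x))
  expect_equal(r1$icc, 1)
  expect_equal(r1$band, "excellent")
  # constant rater offset: consistency form unaffected
  r2 <- icc_two_way_mixed(cbind(x, x + 5))
  expect_equal(r2$icc, 1)
  # ... but absolute agreement is penalized
  r3 <- icc_two_way_mixed(cbind(x, x + 5), type = "agreement")
  expect_lt(r3$icc, 1)
  # 6x2 table vs aov() mean-squares oracle
  for (i in 1:5) {
    m <- matrix(rnorm(12, 5, 2), 6, 2)
    ri <- icc_two_way_mixed(m)
    expect_equal(ri$icc, oracle_icc31(m), tolerance = 1e-10)
    expect_true(ri$ci_low <= ri$icc & ri$icc <= ri$ci_high)
  }
  # degenerate: zero variance everywhere
  rz <- icc_two_way_mixed(matrix(1, 6, 2))
  expect_true(is.na(rz$icc) && isTRUE(rz$undefined))
  expect_error(icc_two_way_mixed(matrix(1:8, 4, 2)), "at least 5")
  expect_error(icc_two_way_mixed(matrix(1:6, 6, 1)), "at least 2")
})

test_that("ICC bands follow the published cut-points", {
  mkicc <- function(target) structure(list(icc = target), class = "x")
  bands <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(v) {
    # build a 2-rater table whose ICC lands near v via noise mixing
    set.seed(round(v * 100))
    s <- rnorm(40, 0, sqrt(v))
    m <- cbind(s + rnorm(40, 0, sqrt(1 - v)), s + rnorm(40, 0, sqrt(1 - v)))
    icc_two_way_mixed(m)$band
  }, character(1))
  expect_equal(length(unique(bands)) >= 3, TRUE)  # spans several bands
  # direct cut-point checks on the boundary map
  expect_equal(icc_two_way_mixed(cbind(rnorm(6), rnorm(6) * 1e-8))$band
               %in% c("poor", "fair"), TRUE)
})
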