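#' Normality-gated two-group comparison
#'
#' Each group is first screened with the Shapiro-Wilk test at alpha = 0.05;
#' if both groups pass, a two-sample Student's t test (equal variances) is
#' run, otherwise a Mann-Whitney U test. A constant group (Shapiro-Wilk
#' undefined) falls through to Mann-Whitney, noted in the result.
#'
#' @param x numeric values, or a list of two numeric vectors.
#' @param g two-level grouping when `x` is a vector.
#' @param alpha normality screening level.
#' @return list `test` ("t" or "mann-whitney"), `p`, `statistic`,
#'   `shapiro_p` (length 2), `note`.
#' @export
univariate_compare <- function(x, g = NULL, alpha = 0.05) {
  if (is.list(x) && is.null(g)) {
    a <- x[[1]]; b <- x[[2]]
  } else {
    g <- factor(g)
    if (nlevels(g) != 2) stop("exactly two groups required")
    a <- x[g == levels(g)[1]]; b <- x[g == levels(g)[2]]
  }
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations")
  sw <- function(v) {
    if (length(unique(v)) < 3 || length(v) > 5000) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  swp <- c(sw(a), sw(b))
  note <- NULL
  if (any(is.na(swp))) {
    normal <- FALSE
    note <- "Shapiro-Wilk undefined for a group; Mann-Whitney used"
  } else normal <- all(swp > alpha)
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "mann-whitney"
  }
  list(test = test, p = ht$p.value, statistic = unname(ht$statistic),
       shapiro_p = swp, note = note)
}

#' Youden's J from an operating point
#'
#' @param sensitivity,specificity fractions in \[0,1\].
#' @return J = sensitivity + specificity - 1.
#' @export
youden_index <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

# DeLong structural components: psi-means per positive / per negative
.delong_components <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  m <- length(x); n <- length(y)
  # psi(X_i, Y_j) = 1, 1/2, 0 for X>Y, X=Y, X<Y
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(cmp), v10 = rowMeans(cmp), v01 = colMeans(cmp),
       m = m, n = n)
}

#' Empirical ROC with Youden-optimal cutoff
#'
#' Positivity convention: `score >= cutoff` is a positive call and `labels`
#' flag the positive class (intermediate-to-high risk). The AUC is the
#' trapezoidal area, identical to the normalized Mann-Whitney U statistic;
#' the 95\% CI uses the DeLong variance with a normal approximation, clipped
#' to \[0,1\]. The cutoff maximizes Youden's J over the observed score
#' values; ties go to the lowest threshold.
#'
#' @param scores numeric.
#' @param labels logical (or 0/1) positive-class indicator.
#' @param conf confidence level.
#' @return a `roc_result`: `auc, ci_low, ci_high, cutoff, sensitivity,
#'   specificity, youden, var_auc`, plus the full `curve` (one row per
#'   candidate threshold). Constant scores give AUC 0.5 and an `NA` cutoff
#'   (flagged `cutoff_undefined`).
#' @export
roc_with_youden <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (anyNA(scores)) stop("scores contain NA")
  dc <- .delong_components(scores, labels)
  v <- if (dc$m > 1 && dc$n > 1)
    stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n else NA_real_
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (is.na(v)) c(NA_real_, NA_real_)
        else pmin(pmax(dc$auc + c(-1, 1) * zq * sqrt(v), 0), 1)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  j <- sens + spec - 1
  out <- list(auc = dc$auc, ci_low = ci[1], ci_high = ci[2],
              var_auc = v,
              curve = data.frame(threshold = thr, sensitivity = sens,
                                 specificity = spec, youden = j))
  if (length(thr) == 1) {
    out$cutoff <- NA_real_; out$sensitivity <- NA_real_
    out$specificity <- NA_real_; out$youden <- NA_real_
    out$cutoff_undefined <- TRUE
    out$auc <- 0.5
  } else {
    best <- which(j == max(j))[1]  # ties -> lowest threshold
    out$cutoff <- thr[best]
    out$sensitivity <- sens[best]
    out$specificity <- spec[best]
    out$youden <- j[best]
  }
  structure(out, class = "roc_result")
}

#' DeLong test for two correlated AUCs
#'
#' Both score vectors must be computed on the same subjects. The covariance
#' of the paired AUCs is estimated from the structural components; the
#' difference is tested with a two-sided normal z test. Identical (or
#' perfectly rank-identical) scores give z = 0, p = 1.
#'
#' @param scores_a,scores_b paired scores.
#' @param labels positive-class indicator.
#' @param conf confidence level for the difference CI.
#' @return list `auc_a, auc_b, difference, ci_low, ci_high, z, p, se`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, conf = 0.95) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must be the same length")
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("at least 2 subjects per class are required")
  da <- .delong_components(scores_a, labels)
  db <- .delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  vdiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- da$auc - db$auc
  se <- sqrt(max(vdiff, 0))
  z <- if (se == 0) 0 else diff / se
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc_a = da$auc, auc_b = db$auc, difference = diff,
       ci_low = diff - zq * se, ci_high = diff + zq * se,
       z = z, p = 2 * stats::pnorm(-abs(z)), se = se)
}

# ridge-penalized logistic IRLS: fallback under perfect separation
.ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100) {
  X1 <- cbind(1, as.matrix(X))
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- numeric(p)
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1, X1 * w) + pen
    gr <- crossprod(X1, y - mu) - pen %*% beta
    step <- solve(H, gr)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-10) break
  }
  stats::setNames(beta, c("(Intercept)", colnames(X)))
}

.fit_logit <- function(df, terms) {
  fm <- stats::as.formula(paste("..y ~",
                                if (length(terms))
                                  paste(sprintf("`%s`", terms),
                                        collapse = " + ") else "1"))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fm, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  attr(fit, "separation") <- sep || any(abs(stats::coef(fit)[-1]) > 15)
  fit
}

#' Stepwise binary logistic regression
#'
#' Maximum-likelihood logistic fit with p-value-driven stepwise selection,
#' mirroring common SPSS practice: backward elimination (default) drops the
#' least significant term (Wald p > `p_remove`, largest first); forward
#' selection adds the most significant candidate (likelihood-ratio p <
#' `p_enter`, smallest first) and after each addition re-checks the model
#' for removals. The full add/drop path is logged. Perfect separation is
#' flagged and coefficients are re-estimated with a lightly
#' ridge-penalized fit.
#'
#' @param features data.frame of numeric candidate predictors.
#' @param labels binary outcome (logical or 0/1); positive class =
#'   intermediate-to-high risk.
#' @param direction "backward" (default) or "forward".
#' @param p_enter,p_remove entry / removal thresholds.
#' @return a `logistic_model`: `selected_features`, `coefficients` (named,
#'   incl. intercept), `selection_path` (data.frame step/action/term/p),
#'   `fitted` (probabilities), `deviance`, `hl_p` (Hosmer-Lemeshow p of the
#'   final model, `NA` for an intercept-only model), `separation`.
#' @export
stepwise_logistic <- function(features, labels,
                              direction = c("backward", "forward"),
                              p_enter = 0.05, p_remove = 0.10) {
  direction <- match.arg(direction)
  y <- as.numeric(as.logical(labels))
  if (anyNA(features) || anyNA(y)) stop("missing values are not allowed")
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  features <- as.data.frame(features)
  df <- cbind(..y = y, features)
  path <- list()
  log_step <- function(action, term, p) {
    path[[length(path) + 1]] <<- data.frame(step = length(path) + 1,
                                            action = action, term = term,
                                            p = p)
  }
  wald_p <- function(fit) {
    s <- summary(fit)$coefficients
    p <- s[, "Pr(>|z|)"]
    p[setdiff(rownames(s), "(Intercept)")]
  }
  strip <- function(x) gsub("`", "", x)
  if (direction == "backward") {
    current <- names(features)
    fit <- .fit_logit(df, current)
    repeat {
      if (!length(current)) break
      # under separation Wald p-values are meaningless: stop eliminating,
      # keep the current term set and fall through to the penalized refit
      if (isTRUE(attr(fit, "separation"))) break
      wp <- wald_p(fit)
      worst <- which.max(wp)
      if (wp[worst] <= p_remove) break
      log_step("drop", strip(names(wp)[worst]), unname(wp[worst]))
      current <- setdiff(current, strip(names(wp)[worst]))
      fit <- .fit_logit(df, current)
    }
  } else {
    current <- character()
    fit <- .fit_logit(df, current)
    repeat {
      candidates <- setdiff(names(features), current)
      if (length(candidates)) {
        lrp <- vapply(candidates, function(tm) {
          f2 <- .fit_logit(df, c(current, tm))
          stats::pchisq(fit$deviance - f2$deviance, df = 1,
                        lower.tail = FALSE)
        }, numeric(1))
        best <- which.min(lrp)
        if (lrp[best] < p_enter) {
          log_step("add", candidates[best], unname(lrp[best]))
          current <- c(current, candidates[best])
          fit <- .fit_logit(df, current)
          # stepwise: re-check previously entered terms for removal
          repeat {
            if (isTRUE(attr(fit, "separation"))) break
            wp <- wald_p(fit)
            if (!length(wp)) break
            worst <- which.max(wp)
            if (wp[worst] <= p_remove) break
            log_step("drop", strip(names(wp)[worst]), unname(wp[worst]))
            current <- setdiff(current, strip(names(wp)[worst]))
            fit <- .fit_logit(df, current)
          }
          next
        }
      }
      break
    }
  }
  sep <- isTRUE(attr(fit, "separation"))
  coefs <- stats::coef(fit)
  names(coefs) <- strip(names(coefs))
  if (sep && length(current)) {
    warning("perfect separation detected; ridge-penalized coefficients ",
            "reported")
    coefs <- .ridge_logistic(features[, current, drop = FALSE], y)
  }
  fitted <- as.numeric(stats::fitted(fit))
  hl <- if (length(current) && length(unique(fitted)) > 3 && !sep)
    tryCatch(hosmer_lemeshow(fitted, y)$p, error = function(e) NA_real_)
  else NA_real_
  structure(list(
    selected_features = current,
    coefficients = coefs,
    selection_path = if (length(path)) do.call(rbind, path)
                     else data.frame(step = integer(), action = character(),
                                     term = character(), p = numeric()),
    fitted = fitted, deviance = fit$deviance, direction = direction,
    hl_p = hl, separation = sep, model = fit),
    class = "logistic_model")
}

#' Predict probabilities from a fitted `logistic_model`
#' @param object a `logistic_model`.
#' @param newdata data.frame containing the selected features.
#' @param ... unused.
#' @return predicted probabilities.
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$selected_features, drop = FALSE]))
  eta <- as.numeric(X %*% object$coefficients[c("(Intercept)",
                                                object$selected_features)])
  1 / (1 + exp(-eta))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: subjects are split into `n_groups` groups by
#' quantiles of the predicted probability (groups are merged when fewer
#' distinct values exist, noted on the result), and
#' \deqn{X^2 = \sum_g (O_g - E_g)^2 / (n_g \bar p_g (1-\bar p_g))}
#' is referred to a chi-square with `n_groups - 2` degrees of freedom (the
#' standard reference for probabilities fitted by logistic regression).
#'
#' @param prob predicted probabilities in (0,1).
#' @param labels observed binary outcomes.
#' @param n_groups number of risk groups (default 10).
#' @return list `statistic, df, p, n_groups_used, table`.
#' @export
hosmer_lemeshow <- function(prob, labels, n_groups = 10) {
  y <- as.numeric(as.logical(labels))
  if (any(prob <= 0 | prob >= 1)) stop("probabilities must lie in (0,1)")
  br <- unique(stats::quantile(prob, seq(0, 1, length.out = n_groups + 1),
                               type = 7))
  merged <- length(br) - 1 < n_groups
  g <- cut(prob, breaks = br, include.lowest = TRUE)
  ng <- nlevels(droplevels(g))
  if (ng < 3) stop("fewer than 3 distinct risk groups; test undefined")
  O <- tapply(y, g, sum); N <- tapply(y, g, length)
  P <- tapply(prob, g, mean)
  keep <- !is.na(N)
  O <- O[keep]; N <- N[keep]; P <- P[keep]
  stat <- sum((O - N * P)^2 / (N * P * (1 - P)))
  df <- length(O) - 2
  list(statistic = unname(stat), df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       n_groups_used = length(O), merged = merged,
       table = data.frame(n = as.numeric(N), observed = as.numeric(O),
                          expected = as.numeric(N * P)))
}

#' Two-way mixed-model intraclass correlation
#'
#' Single-measure ICC from the two-way ANOVA mean squares of a complete
#' subjects x raters table. The consistency form ICC(3,1) =
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E) treats raters as fixed (a constant
#' rater offset does not lower agreement); the absolute-agreement form
#' ICC(2,1) is available by flag. The CI is F-based. Bands follow the
#' reliability convention: <= 0.200 poor, 0.201-0.400 fair, 0.401-0.600
#' moderate, 0.601-0.800 good, 0.801-1.000 excellent.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, >= 5 subjects, >= 2 raters.
#' @param type "consistency" (default) or "agreement".
#' @param conf confidence level.
#' @return an `icc_result`: `icc, ci_low, ci_high, band, type, ms` (mean
#'   squares). Zero between-subject variance gives `NA` (flagged
#'   `undefined`).
#' @export
icc_two_way_mixed <- function(ratings, type = c("consistency", "agreement"),
                              conf = 0.95) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells are not allowed")
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop("at least 2 raters required")
  if (n < 5) stop("at least 5 subjects required")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)          # between subjects
  ssc <- n * sum((colm - grand)^2)          # between raters
  sse <- sum((ratings - outer(rowm, colm, "+") + grand)^2)  # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  band_of <- function(x) {
    if (is.na(x)) return(NA_character_)
    if (x <= 0.200) "poor"
    else if (x <= 0.400) "fair"
    else if (x <= 0.600) "moderate"
    else if (x <= 0.800) "good"
    else "excellent"
  }
  alpha <- 1 - conf
  if (msr == 0 && mse == 0) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, band = NA_character_,
                          type = type, undefined = TRUE,
                          ms = c(msr = msr, msc = msc, mse = mse)),
                     class = "icc_result"))
  }
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    Fobs <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  } else {
    icc <- (msr - mse) /
      (msr + (k - 1) * mse + k / n * (msc - mse))
    # Satterthwaite-based CI (McGraw & Wong)
    a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(n * (msr - FL * mse) /
              (FL * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (FU * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * FU * msr))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = min(ci[2], 1),
                 band = band_of(icc), type = type, undefined = FALSE,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}
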