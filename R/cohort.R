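#' Specification of a synthetic clinical cohort
#'
#' Emulates the population structure of the clinical study: two latent
#' groups (low vs intermediate-to-high risk of advanced fibrosis), with
#' group-conditional distributions for demographics, labs, liver stiffness
#' and the 12 imaging features. Lab defaults are the published group means
#' and SDs; labs are drawn as truncated normals (floored at a physiologic
#' minimum) and sex/diabetes as Bernoulli with the published prevalences.
#' Liver stiffness series are log-normal around a group-dependent median so
#' the IQR/median reliability rule stays exercisable.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param frac_intermediate_high latent intermediate-to-high fraction
#'   (default 20/53).
#' @param clinical per-group clinical distributions; see
#'   [default_clinical_distributions()].
#' @param feature_effects per-feature group-conditional normal parameters
#'   for feature-level simulation; see [default_feature_effects()].
#' @param phantom_effects per-group phantom-parameter shifts used when
#'   rendering per-subject phantoms; see [default_phantom_effects()].
#' @param label_fidelity probability that a subject's two-step
#'   stratification is made to agree with its latent group (default 1: the
#'   latent group IS the stratification outcome; lower values inject label
#'   noise for robustness experiments).
#' @param rng_seed integer seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 53,
                        frac_intermediate_high = 20 / 53,
                        clinical = default_clinical_distributions(),
                        feature_effects = default_feature_effects(),
                        phantom_effects = default_phantom_effects(),
                        label_fidelity = 1,
                        rng_seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (frac_intermediate_high < 0 || frac_intermediate_high > 1)
    stop("frac_intermediate_high must lie in [0, 1]")
  if (label_fidelity < 0 || label_fidelity > 1)
    stop("label_fidelity must lie in [0, 1]")
  for (g in c("low", "high")) for (nm in names(clinical[[g]])) {
    p <- clinical[[g]][[nm]]
    if (length(p) == 2 && is.na(match(nm, c("male", "dm"))) && p[2] < 0)
      stop("distribution SDs must be >= 0 (", nm, ")")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 frac_intermediate_high = frac_intermediate_high,
                 clinical = clinical, feature_effects = feature_effects,
                 phantom_effects = phantom_effects,
                 label_fidelity = label_fidelity,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Published group-conditional clinical distributions
#'
#' Mean/SD pairs (or prevalences) per latent group, with truncation floors
#' applied at draw time. Albumin is in g/L as reported (converted on
#' ingest). LSM parameters are log-scale: `lsm_log_median` is the log of
#' the group's typical median stiffness; `lsm_sigma_between` the
#' between-subject, `lsm_sigma_within` the within-series log-SD.
#' @return nested list with elements `low` and `high`.
#' @export
default_clinical_distributions <- function() {
  list(
    low = list(age = c(46, 15), male = 0.545, bmi = c(25.38, 2.70),
               dm = 0.121, ast = c(46, 34), alt = c(69, 62),
               platelets = c(227, 48), albumin_gL = c(47, 3),
               fat_fraction = c(12.98, 7),
               lsm_log_median = log(5.5), lsm_sigma_between = 0.25,
               lsm_sigma_within = 0.12),
    high = list(age = c(43, 15), male = 0.65, bmi = c(27.07, 2.98),
                dm = 0.45, ast = c(62, 23), alt = c(89, 53),
                platelets = c(183, 73), albumin_gL = c(47, 3),
                fat_fraction = c(19.31, 7),
                lsm_log_median = log(12), lsm_sigma_between = 0.25,
                lsm_sigma_within = 0.12))
}

#' Published group-conditional feature marginals
#'
#' Mean/SD per feature and group, used for feature-level simulation
#' (fast statistical experiments that skip phantom rendering). Values are
#' the published whole-liver marginals of the two risk groups.
#' @return named list; each element `c(mean_low, sd_low, mean_high,
#'   sd_high)`.
#' @export
default_feature_effects <- function() {
  list(volume = c(1075.88, 318.75, 1485.41, 531.52),
       mean = c(954.25, 278.17, 1265.9, 351.06),
       sd = c(290.09, 178.64, 481.60, 244.44),
       median = c(915.83, 257.46, 1176.91, 315.55),
       p5 = c(627.51, 176.85, 744.78, 152.82),
       p95 = c(1359.80, 605.78, 2079.55, 967.95),
       skewness = c(3.31, 2.52, 2.49, 1.61),
       kurtosis = c(34.58, 24.71, 17.84, 16.10),
       entropy = c(2.07, 0.43, 2.63, 0.44),
       contrast = c(6.01, 6.88, 13.27, 11.08),
       diff_entropy = c(1.27, 0.27, 1.67, 0.35),
       diff_variance = c(2.37, 2.42, 4.56, 3.67))
}

#' Per-group phantom-parameter shifts
#'
#' When rendering per-subject phantoms, the intermediate-to-high group gets
#' a higher, more dispersed T1 field (published group marginals) and a
#' shorter correlation length, which raises entropy/diff-entropy in the
#' published direction.
#' @return list with elements `low` and `high` (each `t1_mean, t1_sd,
#'   het_len` plus between-subject SDs `t1_mean_sd, t1_sd_sd`).
#' @export
default_phantom_effects <- function() {
  list(low = list(t1_mean = 954.25, t1_mean_sd = 120, t1_sd = 278.17,
                  t1_sd_sd = 60, het_len = 8,
                  geom_scale = 1.00, geom_scale_sd = 0.05),
       high = list(t1_mean = 1265.9, t1_mean_sd = 120, t1_sd = 481.6,
                   t1_sd_sd = 80, het_len = 5,
                   geom_scale = 1.11, geom_scale_sd = 0.05))
}

rtnorm <- function(n, mean, sd, lower) pmax(stats::rnorm(n, mean, sd), lower)

#' Generate a synthetic cohort
#'
#' Draws latent group labels (exactly `round(n * frac)` intermediate-to-high
#' subjects), group-conditional clinical variables, a reliable liver
#' stiffness series per subject, and per-subject [phantom_spec()]s with
#' group-shifted T1 parameters. When a subject is selected for label
#' recovery (probability `label_fidelity`), its draws are adjusted so the
#' two-step stratification reproduces the latent label: intermediate-to-high
#' subjects get a non-low first line (diabetes set, AST inflated if
#' needed) and a stiffness median >= 8 kPa; low-risk subjects get a
#' stiffness median < 8 kPa (sufficient, whatever the first line says).
#' Non-recovered subjects draw stiffness from the opposite band.
#'
#' @param spec a [cohort_spec()].
#' @param phantom_template a [phantom_spec()] whose non-T1 parameters are
#'   reused for every subject (default `phantom_spec()`).
#' @return list with `cohort` (data.frame, one row per subject; albumin in
#'   g/dL, LSM series semicolon-packed) and `phantoms` (list of
#'   [phantom_spec()]).
#' @export
generate_cohort <- function(spec, phantom_template = phantom_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_subjects
  n_high <- round(n * spec$frac_intermediate_high)
  group <- rep("low", n)
  if (n_high > 0) group[sample(n, n_high)] <- "high"
  recover <- stats::runif(n) < spec$label_fidelity
  rows <- vector("list", n)
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    g <- spec$clinical[[group[i]]]
    age <- round(rtnorm(1, g$age[1], g$age[2], 18))
    sex <- if (stats::runif(1) < g$male) "male" else "female"
    bmi <- rtnorm(1, g$bmi[1], g$bmi[2], 15)
    dm <- stats::runif(1) < g$dm
    ast <- rtnorm(1, g$ast[1], g$ast[2], 10)
    alt <- rtnorm(1, g$alt[1], g$alt[2], 10)
    plt <- rtnorm(1, g$platelets[1], g$platelets[2], 30)
    alb_gdl <- rtnorm(1, g$albumin_gL[1], g$albumin_gL[2], 25) / 10
    ff <- rtnorm(1, g$fat_fraction[1], g$fat_fraction[2], 0.5)
    want_high <- (group[i] == "high") == recover[i]
    # realized target: latent label when recovered, the opposite otherwise
    if (want_high) {
      # first line must be non-low: neither FIB-4 < 1.3 nor NFS < -1.455
      for (try in 1:12) {
        f4 <- fib4(age, ast = ast, alt = alt, platelets = plt)
        nf <- nfs(age, bmi = bmi, dm = dm, ast = ast, alt = alt,
                  platelets = plt, albumin = alb_gdl)
        if (f4 >= 1.3 && nf >= -1.455) break
        if (!dm) dm <- TRUE else ast <- ast * 1.35
      }
      lsm_med <- exp(spec$clinical$high$lsm_log_median +
                       stats::rnorm(1, 0, spec$clinical$high$lsm_sigma_between))
      lsm_med <- max(lsm_med, 8.6)
    } else {
      lsm_med <- exp(spec$clinical$low$lsm_log_median +
                       stats::rnorm(1, 0, spec$clinical$low$lsm_sigma_between))
      lsm_med <- min(lsm_med, 7.4)
    }
    nser <- 10 + stats::rpois(1, 1)
    lsm <- exp(log(lsm_med) +
                 stats::rnorm(nser, 0, spec$clinical[[group[i]]]$lsm_sigma_within))
    # centre the realized series median on the drawn target
    lsm <- lsm * lsm_med / stats::median(lsm)
    pe <- spec$phantom_effects[[group[i]]]
    ph <- phantom_template
    ph$t1_liver_mean <- rtnorm(1, pe$t1_mean, pe$t1_mean_sd, 400)
    ph$t1_liver_sd <- rtnorm(1, pe$t1_sd, pe$t1_sd_sd, 30)
    ph$heterogeneity_length <- pe$het_len
    gsc <- min(rtnorm(1, pe$geom_scale, pe$geom_scale_sd, 0.8),
               pe$geom_scale + 3 * pe$geom_scale_sd)
    ph$liver_geometry <- lapply(ph$liver_geometry, function(e)
      list(center = e$center * gsc, semi = e$semi * gsc))
    ph$rng_seed <- (spec$rng_seed + 7919L * i) %% .Machine$integer.max
    phantoms[[i]] <- ph
    rows[[i]] <- data.frame(
      subject = i, group = group[i], age = age, sex = sex, bmi = bmi,
      dm = dm, ast = ast, alt = alt, platelets = plt, albumin = alb_gdl,
      fat_fraction = ff, lsm_values = format_lsm(round(lsm, 2)),
      stringsAsFactors = FALSE)
  }
  list(cohort = do.call(rbind, rows), phantoms = phantoms)
}

#' Feature-level simulation of the 12 whole-liver features
#'
#' Draws each feature from its group-conditional normal (see
#' [default_feature_effects()]), bypassing phantom rendering. This is the
#' fast path for statistical experiments (power, selection frequency) where
#' only the feature-level group structure matters.
#'
#' @param group character vector of latent groups ("low"/"high").
#' @param effects feature-effect map; features absent from it are skipped.
#' @param null_features optional character vector of extra pure-noise
#'   features to append (standard normal, no group effect).
#' @return data.frame, one row per subject.
#' @export
simulate_features <- function(group, effects = default_feature_effects(),
                              null_features = character()) {
  n <- length(group)
  hi <- group == "high"
  out <- lapply(effects, function(e) {
    v <- numeric(n)
    v[!hi] <- stats::rnorm(sum(!hi), e[1], e[2])
    v[hi] <- stats::rnorm(sum(hi), e[3], e[4])
    v
  })
  out <- as.data.frame(out)
  for (nf in null_features) out[[nf]] <- stats::rnorm(n)
  out
}
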