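#' One subject's clinical record
#'
#' Holds the variables entering the NFS and FIB-4 blood fibrosis scores and
#' the liver stiffness series used as the second-line test. Albumin is
#' stored internally in g/dL (the unit of the NFS formula); laboratory
#' reports in g/L are converted on ingest with `albumin_unit = "g/L"`.
#'
#' @param age years.
#' @param sex "male" or "female" (not used by the scores; carried through).
#' @param bmi kg/m^2.
#' @param dm impaired glucose tolerance or diabetes mellitus (TRUE/FALSE).
#' @param ast,alt IU/L.
#' @param platelets 10^9/L.
#' @param albumin albumin in `albumin_unit`.
#' @param albumin_unit "g/dL" (default) or "g/L".
#' @param lsm_values liver stiffness measurements, kPa (>= 10 valid values
#'   for a successful examination).
#' @param fat_fraction MR spectroscopy fat fraction, percent (optional
#'   covariate).
#' @return a `clinical_record`.
#' @export
clinical_record <- function(age, sex = NA_character_, bmi, dm, ast, alt,
                            platelets, albumin, albumin_unit = "g/dL",
                            lsm_values = numeric(), fat_fraction = NA_real_) {
  albumin_unit <- match.arg(albumin_unit, c("g/dL", "g/L"))
  if (albumin_unit == "g/L") albumin <- albumin * 0.1
  for (v in c(age = age, bmi = bmi, ast = ast, alt = alt,
              platelets = platelets, albumin = albumin))
    if (!is.finite(v) || v <= 0)
      stop("age, bmi, ast, alt, platelets and albumin must all be positive")
  if (albumin < 1 || albumin > 7)
    stop(sprintf(paste0("albumin = %.3g g/dL is outside [1, 7]; a g/L value",
                        " was probably passed as g/dL (use albumin_unit",
                        " = 'g/L')"), albumin))
  if (length(lsm_values) && any(lsm_values <= 0))
    stop("lsm_values must be positive (kPa)")
  structure(list(age = age, sex = sex, bmi = bmi, dm = isTRUE(dm) || dm == 1,
                 ast = ast, alt = alt, platelets = platelets,
                 albumin = albumin, lsm_values = as.numeric(lsm_values),
                 fat_fraction = fat_fraction),
            class = "clinical_record")
}

#' NAFLD Fibrosis Score (NFS)
#'
#' \deqn{-1.675 + 0.037\,age + 0.094\,BMI + 1.13\,DM + 0.99\,AST/ALT
#'       - 0.013\,platelets - 0.66\,albumin}
#' with age in years, BMI in kg/m^2, DM coded 1/0, platelets in 10^9/L and
#' albumin in g/dL.
#'
#' @param record a [clinical_record()], or age when passing components.
#' @param bmi,dm,ast,alt,platelets,albumin components when `record` is
#'   numeric age.
#' @return the score (unitless log-odds scale).
#' @export
nfs <- function(record, bmi = NULL, dm = NULL, ast = NULL, alt = NULL,
                platelets = NULL, albumin = NULL) {
  if (inherits(record, "clinical_record")) {
    r <- record
  } else {
    r <- list(age = record, bmi = bmi, dm = dm, ast = ast, alt = alt,
              platelets = platelets, albumin = albumin)
    if (any(r$albumin < 1 | r$albumin > 7))
      stop("albumin outside [1, 7] g/dL; check units (g/L vs g/dL)")
  }
  if (any(r$alt <= 0)) stop("alt must be positive (AST/ALT ratio)")
  -1.675 + 0.037 * r$age + 0.094 * r$bmi + 1.13 * as.numeric(r$dm) +
    0.99 * (r$ast / r$alt) - 0.013 * r$platelets - 0.66 * r$albumin
}

#' Fibrosis-4 index (FIB-4)
#'
#' \deqn{age \times AST / (platelets \times \sqrt{ALT})}
#'
#' @inheritParams nfs
#' @export
fib4 <- function(record, ast = NULL, alt = NULL, platelets = NULL) {
  if (inherits(record, "clinical_record")) r <- record
  else r <- list(age = record, ast = ast, alt = alt, platelets = platelets)
  if (any(r$alt <= 0) || any(r$platelets <= 0))
    stop("alt and platelets must be positive")
  r$age * r$ast / (r$platelets * sqrt(r$alt))
}

#' Reliability of a transient-elastography series
#'
#' An examination is successful with at least 10 valid measurements and
#' reliable if IQR/median <= 30\%, or if the median stiffness is below
#' 7.1 kPa when IQR/median exceeds 30\%.
#'
#' @param lsm_values kPa.
#' @return list `reliable`, `median`, `iqr_ratio`, `n`.
#' @export
lsm_reliable <- function(lsm_values) {
  lsm_values <- lsm_values[is.finite(lsm_values)]
  if (!length(lsm_values)) stop("empty LSM series")
  med <- stats::median(lsm_values)
  iqr_ratio <- unname(stats::IQR(lsm_values, type = 7) / med)
  list(reliable = length(lsm_values) >= 10 &&
         (iqr_ratio <= 0.30 || med < 7.1),
       median = med, iqr_ratio = iqr_ratio, n = length(lsm_values))
}

#' Risk bands for the two-step stratification
#'
#' Boundary semantics (tested exhaustively): FIB-4 1.3 and 3.25 belong to
#' the intermediate band; NFS -1.455 and 0.672 to the intermediate band;
#' LSM 8 kPa is intermediate and 10 kPa is high.
#'
#' @param x score / stiffness value(s).
#' @return factor with levels low < intermediate < high.
#' @name risk_bands
NULL

.band <- function(x, lo, hi, hi_closed_low = TRUE) {
  out <- ifelse(x < lo, "low", ifelse(
    if (hi_closed_low) x <= hi else x < hi, "intermediate", "high"))
  factor(out, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' @rdname risk_bands
#' @export
fib4_band <- function(x) .band(x, 1.3, 3.25, hi_closed_low = TRUE)

#' @rdname risk_bands
#' @export
nfs_band <- function(x) .band(x, -1.455, 0.672, hi_closed_low = TRUE)

#' @rdname risk_bands
#' @export
lsm_band <- function(x) .band(x, 8, 10, hi_closed_low = FALSE)

#' First-line band from the two blood scores
#'
#' The guideline wording is an "or": a subject is low risk if EITHER score
#' falls in its low band. When both are non-low the more severe of the two
#' bands is taken (configurable to the less severe for sensitivity
#' analyses; the original study does not state how discordance was
#' resolved).
#'
#' @param fib4_score,nfs_score numeric; either may be `NA` if the other is
#'   available.
#' @param discordance "either-low-then-max" (default) or
#'   "either-low-then-min".
#' @return ordered factor low/intermediate/high.
#' @export
first_line_band <- function(fib4_score, nfs_score,
                            discordance = c("either-low-then-max",
                                            "either-low-then-min")) {
  discordance <- match.arg(discordance)
  if (is.na(fib4_score) && is.na(nfs_score))
    stop("at least one first-line score is required")
  bands <- c(if (!is.na(fib4_score)) fib4_band(fib4_score),
             if (!is.na(nfs_score)) nfs_band(nfs_score))
  lv <- c("low", "intermediate", "high")
  if (any(bands == "low")) return(factor("low", levels = lv, ordered = TRUE))
  pick <- if (discordance == "either-low-then-max") max(as.integer(bands))
          else min(as.integer(bands))
  factor(lv[pick], levels = lv, ordered = TRUE)
}

#' Pure two-step band rule
#'
#' The decision rule stripped of record handling: first-line band from the
#' two blood scores ([first_line_band()]); if low, final is low and the
#' stiffness is ignored, otherwise the final band is the stiffness band.
#'
#' @param fib4_score,nfs_score first-line scores (either may be `NA`).
#' @param lsm_median median liver stiffness, kPa (may be `NA` when the
#'   first line is low).
#' @param discordance see [first_line_band()].
#' @return ordered factor low/intermediate/high.
#' @export
two_step_band <- function(fib4_score, nfs_score, lsm_median,
                          discordance = "either-low-then-max") {
  fl <- first_line_band(fib4_score, nfs_score, discordance)
  if (fl == "low") return(fl)
  if (is.na(lsm_median))
    stop("first-line band is not low and no LSM median is available")
  lsm_band(lsm_median)
}

#' Two-step risk stratification of advanced fibrosis
#'
#' Step 1: blood fibrosis scores (FIB-4 / NFS). A low first-line band is
#' final (liver stiffness is never consulted). Otherwise step 2 assigns the
#' final band solely from the liver stiffness median: < 8 kPa low,
#' 8 to < 10 kPa intermediate, >= 10 kPa high. The binarized outcome is
#' low vs intermediate-to-high (`binary = final != "low"`), the positive
#' class of the ROC analyses. Subjects needing the second line without a
#' reliable stiffness series are an error (the clinical protocol excludes
#' them).
#'
#' @param record a [clinical_record()].
#' @param discordance see [first_line_band()].
#' @return a `risk_label`: `first_line`, `final`, `binary`, `basis`,
#'   `fib4`, `nfs`, `lsm_median`.
#' @export
stratify <- function(record, discordance = "either-low-then-max") {
  stopifnot(inherits(record, "clinical_record"))
  f4 <- fib4(record)
  nf <- nfs(record)
  fl <- first_line_band(f4, nf, discordance)
  lv <- levels(fl)
  if (fl == "low") {
    out <- list(first_line = fl, final = fl, binary = FALSE,
                basis = "first-line", fib4 = f4, nfs = nf,
                lsm_median = NA_real_)
    return(structure(out, class = "risk_label"))
  }
  if (!length(record$lsm_values))
    stop("first-line band is not low and no LSM series is available")
  rel <- lsm_reliable(record$lsm_values)
  if (!rel$reliable)
    stop(sprintf(paste0("first-line band is not low and the LSM series is",
                        " unreliable (n=%d, IQR/median=%.2f, median=%.1f",
                        " kPa); such subjects are excluded"),
                 rel$n, rel$iqr_ratio, rel$median))
  final <- two_step_band(f4, nf, rel$median, discordance)
  structure(list(first_line = fl, final = final,
                 binary = final != "low", basis = "second-line (LSM)",
                 fib4 = f4, nfs = nf, lsm_median = rel$median),
            class = "risk_label")
}

#' Stratify every subject of a cohort table
#'
#' @param cohort data.frame with columns `age, sex, bmi, dm, ast, alt,
#'   platelets, albumin` (g/dL unless `albumin_unit = "g/L"`) and
#'   `lsm_values` (semicolon-separated kPa series per row).
#' @param albumin_unit unit of the albumin column.
#' @param discordance see [first_line_band()].
#' @return data.frame with scores, bands, final label, binary outcome and
#'   basis, one row per subject.
#' @export
stratify_cohort <- function(cohort, albumin_unit = "g/dL",
                            discordance = "either-low-then-max") {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    rec <- clinical_record(
      age = r$age, sex = as.character(r$sex), bmi = r$bmi, dm = r$dm,
      ast = r$ast, alt = r$alt, platelets = r$platelets,
      albumin = r$albumin, albumin_unit = albumin_unit,
      lsm_values = parse_lsm(r$lsm_values),
      fat_fraction = if ("fat_fraction" %in% names(r)) r$fat_fraction
                     else NA_real_)
    s <- stratify(rec, discordance)
    data.frame(subject = if ("subject" %in% names(r)) r$subject else i,
               fib4 = s$fib4, nfs = s$nfs, lsm_median = s$lsm_median,
               first_line = as.character(s$first_line),
               final = as.character(s$final), binary = s$binary,
               basis = s$basis)
  })
  do.call(rbind, rows)
}

#' Parse / format a semicolon-separated LSM series
#' @param x character scalar like `"5.1;5.4;..."` or numeric vector.
#' @return numeric vector (`parse_lsm`) or character scalar (`format_lsm`).
#' @export
parse_lsm <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}

#' @rdname parse_lsm
#' @export
format_lsm <- function(x) paste(x, collapse = ";")
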