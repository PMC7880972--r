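#' Default end-to-end run configuration
#'
#' One JSON-serializable list drives the whole chain: cohort simulation,
#' phantom rendering + VFA fit + random-walker segmentation + feature
#' extraction, two-step risk stratification, and the statistical report
#' (univariate table, ROC table with Youden cutoffs, stepwise model with
#' DeLong comparisons, optional repeat-read ICC). Defaults are sized for a
#' desktop smoke run (20 subjects, 32^3 phantoms, a few minutes on one
#' CPU).
#'
#' @param n_subjects cohort size.
#' @param grid_shape phantom grid (per axis).
#' @param rng_seed master seed; every stage derives its stream from it.
#' @param imaging render phantoms and extract features through the full
#'   imaging chain (`TRUE`) or draw features from the group-conditional
#'   marginals (`FALSE`, fast path).
#' @param stages character vector of enabled stages, a subset of
#'   `c("cohort", "features", "stratify", "stats")`.
#' @param icc_subjects number of subjects re-read with jittered seeds for
#'   the ICC table (0 disables; imaging mode only).
#' @param beta,solver_tol random-walker parameters.
#' @param n_levels GLCM gray levels.
#' @param stepwise_direction "backward" or "forward".
#' @return a `run_config` list.
#' @export
default_config <- function(n_subjects = 20, grid_shape = c(32, 32, 32),
                           rng_seed = 1L, imaging = TRUE,
                           stages = c("cohort", "features", "stratify",
                                      "stats"),
                           icc_subjects = 5, beta = 130, solver_tol = 1e-5,
                           n_levels = 32, stepwise_direction = "backward") {
  structure(list(n_subjects = n_subjects, grid_shape = grid_shape,
                 rng_seed = as.integer(rng_seed), imaging = imaging,
                 stages = stages, icc_subjects = icc_subjects, beta = beta,
                 solver_tol = solver_tol, n_levels = n_levels,
                 stepwise_direction = stepwise_direction),
            class = "run_config")
}

config_hash <- function(config) {
  # stage toggles are excluded: disabling a stage must not invalidate the
  # cache of the stages that already ran
  cfg <- unclass(config)
  cfg$stages <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a run configuration from JSON
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

# imaging chain for one subject: phantom -> fit -> segment -> extract
.subject_features <- function(ph, beta, solver_tol, n_levels,
                              seed_jitter = 0L) {
  bundle <- generate_phantom(ph)
  t1 <- fit_t1_vfa(bundle$spgr_low, bundle$spgr_high, bundle$b1_map,
                   acq = ph$acq)
  seeds <- bundle$seeds
  if (seed_jitter != 0L) {
    # emulate a second reader: shift foreground seeds by one voxel in x
    fg <- seeds$labels == "foreground"
    co <- seeds$coords
    shifted <- pmin(pmax(co[fg, 1] + seed_jitter, 1),
                    dim(bundle$spgr_high$values)[1])
    # keep jittered foreground seeds off background-seeded voxels
    bg_key <- paste(co[!fg, 1], co[!fg, 2], co[!fg, 3])
    new_key <- paste(shifted, co[fg, 2], co[fg, 3])
    ok <- !(new_key %in% bg_key)
    row_fg <- which(fg)[ok]
    co[row_fg, 1] <- shifted[ok]
    seeds <- seed_set(co, seeds$labels)
  }
  seg <- random_walker_segment(bundle$spgr_high, seeds, beta = beta,
                               solver_tol = solver_tol)
  mask <- propagate_mask(seg$mask, t1)
  extract_all(t1, mask, feature_config(n_levels = n_levels))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, persisting each stage's artifacts
#' under `out_dir` (stage-numbered subfolders) together with a manifest
#' (config, config hash, package version, seed). A re-run with an
#' unchanged config hash re-uses the cached feature table when the
#' `features` stage is disabled. A stage failure aborts with the stage name
#' while completed artifacts remain on disk.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output directory.
#' @return list with `cohort`, `features`, `risk`, `report` (univariate /
#'   ROC / model / DeLong / ICC tables) and `manifest_path`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, enabled, f) {
    if (!enabled) return(NULL)
    tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  paths <- list(cohort = file.path(out_dir, "01_cohort", "cohort.csv"),
                features = file.path(out_dir, "02_features", "features.csv"),
                risk = file.path(out_dir, "03_risk", "risk.csv"),
                report = file.path(out_dir, "04_report"))
  manifest_path <- file.path(out_dir, "manifest.json")

  # -- stage 1: cohort ------------------------------------------------
  cs <- cohort_spec(n_subjects = config$n_subjects,
                    rng_seed = config$rng_seed)
  ph_template <- phantom_spec(grid_shape = config$grid_shape)
  cohort_out <- NULL
  if ("cohort" %in% config$stages) {
    cohort_out <- stage("cohort", TRUE, function() {
      gc <- generate_cohort(cs, ph_template)
      dir.create(dirname(paths$cohort), showWarnings = FALSE,
                 recursive = TRUE)
      utils::write.csv(gc$cohort, paths$cohort, row.names = FALSE)
      gc
    })
  } else if (file.exists(paths$cohort)) {
    cohort_out <- list(cohort = utils::read.csv(paths$cohort),
                       phantoms = generate_cohort(cs, ph_template)$phantoms)
  } else stop("pipeline stage 'cohort' disabled but no cached cohort found")

  # -- stage 2: features ----------------------------------------------
  cached_ok <- file.exists(paths$features) && file.exists(manifest_path) &&
    identical(jsonlite::read_json(manifest_path)$config_hash, hash)
  feats <- if ("features" %in% config$stages) {
    stage("features", TRUE, function() {
      f <- if (config$imaging) {
        do.call(rbind, lapply(cohort_out$phantoms, function(ph)
          as.data.frame(.subject_features(ph, config$beta,
                                          config$solver_tol,
                                          config$n_levels))))
      } else {
        set.seed(config$rng_seed + 1L)
        simulate_features(cohort_out$cohort$group)
      }
      f <- cbind(subject = cohort_out$cohort$subject, f)
      dir.create(dirname(paths$features), showWarnings = FALSE,
                 recursive = TRUE)
      utils::write.csv(f, paths$features, row.names = FALSE)
      f
    })
  } else if (cached_ok) {
    utils::read.csv(paths$features)
  } else stop("pipeline stage 'features' disabled and no valid cache ",
              "(manifest hash mismatch or missing)")

  # -- stage 3: stratify ----------------------------------------------
  risk <- stage("stratify", "stratify" %in% config$stages, function() {
    r <- stratify_cohort(cohort_out$cohort)
    dir.create(dirname(paths$risk), showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(r, paths$risk, row.names = FALSE)
    r
  })
  if (is.null(risk) && file.exists(paths$risk))
    risk <- utils::read.csv(paths$risk)

  # -- stage 4: stats report ------------------------------------------
  report <- stage("stats", "stats" %in% config$stages, function() {
    y <- as.logical(risk$binary)
    fnames <- intersect(feature_names(), names(feats))
    uni <- do.call(rbind, lapply(fnames, function(nm) {
      u <- univariate_compare(feats[[nm]], ifelse(y, "high", "low"))
      data.frame(parameter = nm,
                 mean_low = mean(feats[[nm]][!y]),
                 sd_low = stats::sd(feats[[nm]][!y]),
                 mean_high = mean(feats[[nm]][y]),
                 sd_high = stats::sd(feats[[nm]][y]),
                 test = u$test, p = u$p)
    }))
    signif_f <- uni$parameter[uni$p < 0.05]
    roc_tab <- do.call(rbind, lapply(fnames, function(nm) {
      r <- roc_with_youden(feats[[nm]], y)
      data.frame(parameter = nm, auc = r$auc, ci_low = r$ci_low,
                 ci_high = r$ci_high, cutoff = r$cutoff,
                 youden = r$youden, sensitivity = r$sensitivity,
                 specificity = r$specificity)
    }))
    model <- NULL; delong_tab <- NULL
    if (length(signif_f) >= 1 && sum(y) >= 5 && sum(!y) >= 5) {
      model <- stepwise_logistic(feats[, signif_f, drop = FALSE], y,
                                 direction = config$stepwise_direction)
      if (length(model$selected_features)) {
        mscore <- model$fitted
        mroc <- roc_with_youden(mscore, y)
        roc_tab <- rbind(roc_tab, data.frame(
          parameter = "multivariate model", auc = mroc$auc,
          ci_low = mroc$ci_low, ci_high = mroc$ci_high,
          cutoff = mroc$cutoff, youden = mroc$youden,
          sensitivity = mroc$sensitivity, specificity = mroc$specificity))
        delong_tab <- do.call(rbind, lapply(fnames, function(nm) {
          dl <- delong_compare(mscore, feats[[nm]], y)
          data.frame(parameter = nm, difference = dl$difference,
                     ci_low = dl$ci_low, ci_high = dl$ci_high,
                     z = dl$z, p = dl$p)
        }))
      }
    }
    icc_tab <- NULL
    if (config$imaging && config$icc_subjects >= 5) {
      ns <- min(config$icc_subjects, length(cohort_out$phantoms))
      reread <- do.call(rbind, lapply(seq_len(ns), function(i)
        as.data.frame(.subject_features(cohort_out$phantoms[[i]],
                                        config$beta, config$solver_tol,
                                        config$n_levels,
                                        seed_jitter = 1L))))
      icc_tab <- do.call(rbind, lapply(fnames, function(nm) {
        ic <- icc_two_way_mixed(cbind(feats[[nm]][seq_len(ns)],
                                      reread[[nm]]))
        data.frame(parameter = nm, icc = ic$icc, ci_low = ic$ci_low,
                   ci_high = ic$ci_high, band = ic$band)
      }))
    }
    dir.create(paths$report, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(uni, file.path(paths$report, "univariate.csv"),
                     row.names = FALSE)
    utils::write.csv(roc_tab, file.path(paths$report, "roc.csv"),
                     row.names = FALSE)
    if (!is.null(delong_tab))
      utils::write.csv(delong_tab, file.path(paths$report, "delong.csv"),
                       row.names = FALSE)
    if (!is.null(icc_tab))
      utils::write.csv(icc_tab, file.path(paths$report, "icc.csv"),
                       row.names = FALSE)
    if (!is.null(model))
      jsonlite::write_json(
        list(selected = model$selected_features,
             coefficients = as.list(model$coefficients),
             direction = model$direction, hl_p = model$hl_p,
             separation = model$separation),
        file.path(paths$report, "model.json"), auto_unbox = TRUE,
        digits = NA)
    list(univariate = uni, roc = roc_tab, model = model,
         delong = delong_tab, icc = icc_tab)
  })

  manifest <- list(config = unclass(config), config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("t1liver")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort_out$cohort, features = feats, risk = risk,
                 report = report, manifest_path = manifest_path,
                 out_dir = out_dir))
}
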