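# End-to-end orchestration: simulate -> uncertainty -> masks -> features ->
# stability -> discrimination, with deterministic seeding and optional file
# output.

#' Assemble a pipeline run configuration
#'
#' @param cohort a [cohort_params()].
#' @param profiles named list of [model_profile()]s (e.g. calibrated vs
#'   miscalibrated variants).
#' @param T_rep replicates per scan.
#' @param thresholds confidence levels (percent), ascending.
#' @param radiomics a [radiomics_config()].
#' @param icc_cutoff stability cutoff (default 0.8).
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_params(),
                       profiles = list(calibrated = model_profile(calibration = 1),
                                       miscalibrated = model_profile(calibration = 0.2)),
                       T_rep = 50, thresholds = seq(10, 100, by = 10),
                       radiomics = radiomics_config(), icc_cutoff = 0.8,
                       seed = 1, out_dir = NULL) {
  stopifnot(!is.unsorted(thresholds), length(profiles) >= 1, !is.null(names(profiles)))
  structure(list(cohort = cohort, profiles = profiles, T_rep = T_rep,
                 thresholds = thresholds, radiomics = radiomics,
                 icc_cutoff = icc_cutoff, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `cohort`, `profiles`
#' (a named map of profile parameter maps) and `radiomics` are nested maps.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_params, y$cohort)
  if (!is.null(y$profiles)) {
    args$profiles <- lapply(y$profiles, function(p) do.call(model_profile, p))
  }
  if (!is.null(y$radiomics)) args$radiomics <- do.call(radiomics_config, y$radiomics)
  for (k in c("T_rep", "thresholds", "icc_cutoff", "seed", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

# ICC table for a non-thresholded baseline: ICC_S between GT and the
# deterministic-analog (MP) features; ICC_A over repeats of `source` features.
baseline_stability <- function(features, source, cutoff, groups) {
  icc_a <- icc_a_per_feature(features, source)
  res <- lapply(groups, function(g) {
    icc_s <- icc_s_per_feature(features, "MP", g)
    icc_a_g <- unname(icc_a[names(icc_s)])
    tibble::tibble(group = g, feature = names(icc_s), icc_s = unname(icc_s),
                   icc_a = icc_a_g,
                   class = classify_stability(unname(icc_s), icc_a_g, cutoff))
  })
  dplyr::bind_rows(res)
}

repeatable_set <- function(icc_tbl, th_opt = NULL) {
  # features with ICC_A >= cutoff (class 1 or 3) in every group, at the
  # group-specific threshold when one is given
  split_g <- split(icc_tbl, icc_tbl$group)
  sets <- lapply(names(split_g), function(g) {
    t_ <- split_g[[g]]
    if (!is.null(th_opt)) t_ <- t_[t_$th == th_opt[[g]], ]
    t_$feature[t_$class %in% c(1L, 3L)]
  })
  Reduce(intersect, sets)
}

classifier_stage <- function(rows, repeatable, seed, n_boot = 500) {
  # shape_MeshVolume is always carried through the volume-correlation filter,
  # but only counts as a candidate when it is itself repeatable
  keep <- intersect(c("subject_id", "group", "repeat_index", "mask_source",
                      union(repeatable, "shape_MeshVolume")), names(rows))
  tbl <- rows[, keep]
  tbl <- filter_features(tbl)
  if (!"shape_MeshVolume" %in% repeatable) {
    tbl$shape_MeshVolume <- NULL
  }
  fc <- feature_cols(tbl)
  if (length(fc) < 5) {
    return(list(error = sprintf("only %d usable features after filtering", length(fc))))
  }
  sel <- mrmr_bootstrap(tbl, tbl$group, n_boot = n_boot, k = 5, seed = seed)
  rep_ <- fit_eval_lopo(tbl, sel$selected)
  list(selected = sel$selected, frequency = sel$frequency, report = rep_)
}

#' Run the full stability-and-discrimination pipeline
#'
#' Simulates the cohort once, then for each model profile: simulates replicate
#' stacks, derives mean-prediction and confidence-level masks, scores
#' segmentation accuracy (3-D Dice) and uncertainty quality (KL
#' separability), extracts the feature table over all mask sources, runs the
#' threshold scan with optimal-threshold selection, compares ICC
#' distributions to the ground-truth and deterministic-analog baselines
#' (Wilcoxon), and fits the group classifier on the repeatable features.
#' Re-running with the same config reproduces every output bit-identically.
#'
#' @param config a [run_config()].
#' @param n_boot bootstrap resamples for feature selection (default 500).
#' @param verbose print stage progress.
#' @return object of class `radstab_run`: list with `cohort_summary`,
#'   `profiles` (per-profile results), and `config`.
#' @export
run_pipeline <- function(config = run_config(), n_boot = 500, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating cohort")
  cohort <- simulate_cohort(config$cohort)
  groups <- sort(unique(cohort$group))
  profile_results <- list()
  for (pi in seq_along(config$profiles)) {
    pname <- names(config$profiles)[pi]
    profile <- config$profiles[[pi]]
    say("profile %s: replicate stacks and masks", pname)
    scan_metrics <- vector("list", nrow(cohort))
    mask_list <- vector("list", nrow(cohort))
    for (s in seq_len(nrow(cohort))) {
      stack <- simulate_prob_stack(cohort[s, ], profile, T_rep = config$T_rep,
                                   seed = child_seed(config$seed, pi * 10000 + s))
      mp <- mean_prediction(stack)
      unc <- uncertainty_decompose(stack)
      cl <- confidence_masks(stack, config$thresholds)
      gt <- cohort$gt_mask[[s]]
      kl <- tryCatch(
        kl_uncertainty_separability(unc$predictive, mp$mp_mask, gt),
        radstab_undefined_divergence = function(e) NA_real_
      )
      scan_metrics[[s]] <- tibble::tibble(
        subject_id = cohort$subject_id[s], group = cohort$group[s],
        repeat_index = cohort$repeat_index[s],
        dsc_3d = dice_score(mp$mp_mask, gt), kl_divergence = kl
      )
      mask_list[[s]] <- c(list(MP = mp$mp_mask), cl$masks)
    }
    metrics <- dplyr::bind_rows(scan_metrics)
    say("profile %s: feature extraction (%d scans x %d masks)", pname,
        nrow(cohort), 1 + length(mask_list[[1]]))
    features <- cohort_feature_table(cohort, mask_list, config$radiomics)
    say("profile %s: stability analysis", pname)
    scan <- threshold_scan(features, config$thresholds, config$icc_cutoff)
    base_gt <- baseline_stability(features, "GT", config$icc_cutoff, groups)
    base_mp <- baseline_stability(features, "MP", config$icc_cutoff, groups)
    icc_opt <- dplyr::bind_rows(lapply(groups, function(g) {
      x <- scan$icc[scan$icc$group == g & scan$icc$th == scan$th_opt[[g]], ]
    }))
    wilcox <- dplyr::bind_rows(lapply(groups, function(g) {
      a_opt <- icc_opt$icc_a[icc_opt$group == g]
      tibble::tibble(
        group = g,
        vs = c("GT", "MP"),
        p_value = c(
          wilcoxon_compare(base_gt$icc_a[base_gt$group == g], a_opt)$p_value,
          wilcoxon_compare(base_mp$icc_a[base_mp$group == g], a_opt)$p_value
        )
      )
    }))
    say("profile %s: classification", pname)
    rep_cl <- repeatable_set(scan$icc, scan$th_opt)
    cls_rows <- dplyr::bind_rows(lapply(groups, function(g) {
      src <- sprintf("CL_%d", as.integer(scan$th_opt[[g]]))
      features[features$group == g & features$mask_source == src, ]
    }))
    classifier <- if (length(rep_cl) >= 5) {
      classifier_stage(cls_rows, rep_cl, seed = child_seed(config$seed, 777 + pi),
                       n_boot = n_boot)
    } else {
      list(error = sprintf("only %d repeatable features", length(rep_cl)))
    }
    profile_results[[pname]] <- list(
      profile = profile, scan_metrics = metrics, features = features,
      threshold_scan = scan, baseline_gt = base_gt, baseline_mp = base_mp,
      wilcoxon = wilcox, repeatable_features = rep_cl, classifier = classifier
    )
  }
  run <- structure(list(
    cohort_summary = dplyr::count(cohort, .data$group,
                                  name = "n_scans"),
    profiles = profile_results, config = config
  ), class = "radstab_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.radstab_run <- function(x, ...) {
  cat("<radstab_run>", length(x$profiles), "profile(s)\n")
  for (nm in names(x$profiles)) {
    p <- x$profiles[[nm]]
    auc <- if (!is.null(p$classifier$report)) round(p$classifier$report$auc, 3) else NA
    cat(sprintf("  %s: mean DSC_3D %.3f, mean KL %.3f, th_opt [%s], %d repeatable, AUC %s\n",
                nm, mean(p$scan_metrics$dsc_3d),
                mean(p$scan_metrics$kl_divergence, na.rm = TRUE),
                paste(names(p$threshold_scan$th_opt), p$threshold_scan$th_opt,
                      sep = "=", collapse = ", "),
                length(p$repeatable_features), auc))
  }
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' CSVs for scan metrics, feature tables, per-feature ICC/class tables and
#' class counts; one JSON report with headline quantities; and a manifest of
#' seeds, settings and written files.
#'
#' @param run a `radstab_run`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, name)
  }
  report <- list()
  for (nm in names(run$profiles)) {
    p <- run$profiles[[nm]]
    put_csv(p$scan_metrics, sprintf("%s_scan_metrics.csv", nm))
    put_csv(p$features, sprintf("%s_features.csv", nm))
    put_csv(p$threshold_scan$icc, sprintf("%s_icc_by_threshold.csv", nm))
    put_csv(p$threshold_scan$counts, sprintf("%s_class_counts.csv", nm))
    put_csv(p$wilcoxon, sprintf("%s_wilcoxon.csv", nm))
    report[[nm]] <- list(
      mean_dsc_3d = mean(p$scan_metrics$dsc_3d),
      mean_kl = mean(p$scan_metrics$kl_divergence, na.rm = TRUE),
      th_opt = as.list(p$threshold_scan$th_opt),
      n_repeatable = length(p$repeatable_features),
      auc = if (!is.null(p$classifier$report)) p$classifier$report$auc else NA,
      selected_features = p$classifier$selected %||% character(0)
    )
  }
  jsonlite::write_json(report, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, "report.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("radstab")),
    seed = run$config$seed, T_rep = run$config$T_rep,
    thresholds = run$config$thresholds,
    feature_manifest = feature_manifest(run$config$radiomics),
    files = written
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
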