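# Reproducible end-to-end pipeline: synth -> extract -> screen.
# Every stage is pure given (inputs, config, seed); manifests record the
# seed and a hash of the configuration so re-runs are byte-identical.

#' Read a pipeline configuration file
#'
#' A single YAML document with one block per stage (`cohort`, `segmentation`,
#' `if_fit`, `features`, `screening`) plus a top-level `seed`. Missing
#' blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such config file: ", path))
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean, surfacing in R as a list
  # element named "FALSE"; restore the intended cohort-size key
  fix_names <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "n", nm)
    lapply(x, fix_names)
  }
  structure(fix_names(cfg %||% list()), class = "pipeline_config")
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, stage, cfg, seed, extra = list()) {
  man <- c(list(stage = stage, seed = seed,
                config_hash = config_hash(cfg),
                package = "ifscreen",
                version = as.character(utils::packageVersion("ifscreen"))),
           extra)
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Synthesize a cohort to disk
#'
#' Writes one waveform CSV per subject, the ground-truth table and a
#' manifest. Deterministic: identical configs produce byte-identical files.
#'
#' @param cfg A [cohort_config()] (or a plain list of its arguments).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
pipeline_synth <- function(cfg, out_dir) {
  if (!inherits(cfg, "cohort_config")) cfg <- do.call(cohort_config, cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_data(paste0("cannot create ", out_dir))
  cohort <- gen_cohort(cfg)
  paths <- vapply(cohort$waveforms, function(w) {
    p <- file.path(out_dir, paste0(w$subject_id, ".csv"))
    write_waveform(w, p)
    p
  }, character(1))
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "synth", unclass(cfg), cfg$seed,
                 list(n_subjects = cfg$n))
  invisible(c(paths, truth_path))
}

#' Extract subject features from a directory of recordings
#'
#' For every subject in the metadata table: read the recording, detect
#' beats, segment into cycles, select the best three to five by quality,
#' fit the intrinsic-frequency model to each, and average into one feature
#' row. Subjects with no usable cycles are excluded with a machine-parsable
#' reason code (`NO_BEATS`, `NO_USABLE_CYCLES`, `FIT_FAILED`, `NO_FILE`)
#' logged and written alongside the feature table.
#'
#' @param in_dir Directory holding `<subject_id>.csv` recordings.
#' @param metadata Data frame with `subject_id`, `age` and (optionally)
#'   `lvef`; defaults to reading `truth.csv` from `in_dir`.
#' @param out_dir Where to write `features.csv` and `exclusions.csv`
#'   (default `in_dir`).
#' @param seg_cfg A [segment_config()].
#' @param fit_cfg A [fit_config()].
#' @param verbose Emit one log line per exclusion.
#' @return The feature table (one row per retained subject), invisibly
#'   carrying attribute `exclusions`.
#' @export
pipeline_extract <- function(in_dir, metadata = NULL, out_dir = in_dir,
                             seg_cfg = segment_config(),
                             fit_cfg = fit_config(refine_T0 = TRUE,
                                                  refine_onset = TRUE),
                             verbose = TRUE) {
  if (is.null(metadata)) {
    tp <- file.path(in_dir, "truth.csv")
    if (!file.exists(tp)) abort_data("no metadata given and no truth.csv found")
    metadata <- utils::read.csv(tp, stringsAsFactors = FALSE)
  }
  if (!all(c("subject_id", "age") %in% names(metadata)))
    abort_data("metadata needs columns subject_id and age")
  rows <- list(); excl <- list()
  note <- function(id, code, detail = "") {
    excl[[length(excl) + 1L]] <<- data.frame(subject_id = id, reason = code,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
    if (verbose) message(sprintf("[exclude] %s %s %s", id, code, detail))
  }
  for (k in seq_len(nrow(metadata))) {
    id <- as.character(metadata$subject_id[k])
    path <- file.path(in_dir, paste0(id, ".csv"))
    if (!file.exists(path)) { note(id, "NO_FILE", path); next }
    w <- read_waveform(path, id)
    onsets <- detect_beats(w, seg_cfg)
    if (length(onsets) < 2L) { note(id, "NO_BEATS"); next }
    cycles <- suppressWarnings(segment_cycles(w, onsets))
    if (length(cycles) == 0L) { note(id, "NO_USABLE_CYCLES"); next }
    sel <- select_cycles(cycles)
    feats <- NULL
    for (cy in sel) {
      f <- fit_cycle_robust(cy, fit_cfg)
      if (!is.null(f)) feats <- rbind(feats, cycle_features(f))
    }
    if (is.null(feats)) { note(id, "FIT_FAILED"); next }
    feats <- filter_fits_by_residual(feats)
    lv <- if ("lvef" %in% names(metadata)) metadata$lvef[k] else NA_real_
    rows[[length(rows) + 1L]] <-
      aggregate_subject(feats, id, metadata$age[k], lv)
  }
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), reason = character(0),
               detail = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(features))
      utils::write.csv(features, file.path(out_dir, "features.csv"),
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (is.null(features)) abort_data("no subject produced usable features")
  attr(features, "exclusions") <- exclusions
  invisible(features)
}

# Fit one cycle, retrying from canonical systolic-fraction starting points
# when the first fit is clearly off (relative residual above `retry_resid`):
# a badly misplaced notch estimate can strand the T0 refinement in the
# wrong basin, and a fresh start recovers it.
fit_cycle_robust <- function(cy, fit_cfg, retry_resid = 0.05) {
  f <- tryCatch(fit_if(cy, fit_cfg), error = function(e) NULL)
  if (!is.null(f) && f$residual <= retry_resid) return(f)
  if (isTRUE(fit_cfg$refine_T0)) {
    for (frac in c(0.3, 0.35, 0.4, 0.45)) {
      alt <- cy
      alt$T0 <- frac * cy$T
      g <- tryCatch(fit_if(alt, fit_cfg), error = function(e) NULL)
      if (!is.null(g) && (is.null(f) || g$objective < f$objective)) f <- g
    }
  }
  f
}

# Drop fitted cycles whose residual is far above the subject's typical
# level; such fits are wrong-basin outliers, not noise. At least two cycles
# are always retained (the protocol tolerates fewer than three with a flag).
filter_fits_by_residual <- function(feats, ratio = 1.5, floor = 0.015) {
  if (is.null(feats) || nrow(feats) <= 2L) return(feats)
  med <- stats::median(feats$residual)
  keep <- feats$residual <= pmax(ratio * med, floor)
  if (sum(keep) < 2L) keep <- rank(feats$residual, ties.method = "first") <= 2L
  feats[keep, , drop = FALSE]
}

report_to_list <- function(rep) {
  list(confusion = rep$confusion[c("TP", "FP", "TN", "FN")],
       metrics = rep$metrics, auc = rep$auc,
       per_subject = rep$per_subject)
}

#' Screen a feature table and write a report
#'
#' Applies the two published fixed rules and (when both classes are
#' present) trains the constrained CART with leave-one-out
#' cross-validation, pooling held-out scores into one ROC. Writes
#' `report.json` and `roc_loocv.csv`.
#'
#' @param features Feature table from [pipeline_extract()] (or a path to
#'   its CSV). Needs a logical/0-1 `label` column for evaluation.
#' @param out_dir Output directory (NULL to skip writing).
#' @param predictors Predictors for the trained tree.
#' @return List of class `screen_result` with components `fixed_A`,
#'   `fixed_B` (each a `screening_report` when labels are available, else
#'   predicted labels only) and `cart_loocv`.
#' @export
pipeline_screen <- function(features, out_dir = NULL,
                            predictors = c("omega1_bpm", "omegai1")) {
  if (is.character(features))
    features <- utils::read.csv(features, stringsAsFactors = FALSE)
  needed <- c("omega1_bpm", "omegai1", "phi1", "age")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols))
    abort_data(paste0("feature table lacks: ", paste(missing_cols, collapse = ", ")))
  predA <- classify_fixed_tree_A(features$omega1_bpm, features$age,
                                 features$phi1)
  predB <- classify_fixed_tree_B(features$omega1_bpm, features$omegai1)
  have_labels <- "label" %in% names(features) && !anyNA(features$label)
  both_classes <- have_labels && length(unique(as.logical(features$label))) == 2L
  as_rep <- function(pred) {
    if (!have_labels) return(list(predicted = pred$label))
    cm <- confusion_matrix(pred$label == "low", as.logical(features$label))
    list(predicted = pred$label, confusion = cm, metrics = metrics(cm))
  }
  out <- list(fixed_A = as_rep(predA), fixed_B = as_rep(predB),
              cart_loocv = NULL)
  if (both_classes && nrow(features) >= 3L) {
    cv <- loocv(features, predictors)
    out$cart_loocv <- screening_report(cv$score, cv$truth, cv$subject_id)
  } else if (have_labels) {
    warning("single-class table: CART training and ROC skipped", call. = FALSE)
  }
  class(out) <- "screen_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rep <- list(schema = "ifscreen-report/1",
                fixed_A = if (have_labels) list(
                  confusion = out$fixed_A$confusion[c("TP", "FP", "TN", "FN")],
                  metrics = out$fixed_A$metrics) else NULL,
                fixed_B = if (have_labels) list(
                  confusion = out$fixed_B$confusion[c("TP", "FP", "TN", "FN")],
                  metrics = out$fixed_B$metrics) else NULL,
                cart_loocv = if (!is.null(out$cart_loocv))
                  report_to_list(out$cart_loocv) else NULL)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(out$cart_loocv) && !is.null(out$cart_loocv$roc_points))
      utils::write.csv(out$cart_loocv$roc_points,
                       file.path(out_dir, "roc_loocv.csv"),
                       row.names = FALSE, quote = FALSE)
  }
  out
}

#' Run the full pipeline: synthesize, extract, screen
#'
#' @param cfg A [cohort_config()] or argument list.
#' @param out_dir Working directory for all stage outputs.
#' @return The `screen_result`, invisibly; all artifacts are on disk.
#' @export
pipeline_run_all <- function(cfg, out_dir) {
  pipeline_synth(cfg, out_dir)
  features <- pipeline_extract(out_dir, verbose = FALSE)
  invisible(pipeline_screen(features, out_dir))
}
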