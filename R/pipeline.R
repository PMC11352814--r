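#' Build model feature matrices from a processed, screened cohort
#'
#' Two feature sets are supported, mirroring the two modeling modes:
#' \describe{
#'   \item{conventional}{Features restricted to the differentially abundant
#'     proteins: imputed log2 values for quantitative DAPs and binary
#'     detection indicators for qualitative DAPs.}
#'   \item{free-choice}{The model may draw on every protein: imputed log2
#'     values for proteins with 100\% coverage in all patients (avoiding any
#'     influence of imputation), plus detection indicators for all proteins
#'     whose detection pattern varies.}
#' }
#'
#' @param pm Imputed \code{processed_matrix}.
#' @param daps Screening result from \code{\link{screen_all}}.
#' @param mode \code{"conventional"} or \code{"free-choice"}.
#' @param restrict_group Optional functional category; features are then
#'   restricted to proteins mapped to that category (requires an annotated
#'   \code{daps} for conventional mode, or a \code{map} argument).
#' @param map Optional named category vector used with
#'   \code{restrict_group} in free-choice mode.
#' @return Numeric feature matrix, patients as rows. Indicator columns are
#'   suffixed \code{"|detected"}.
#' @export
build_features <- function(pm, daps, mode = c("conventional", "free-choice"),
                           restrict_group = NULL, map = NULL) {
  mode <- match.arg(mode)
  lv <- pm$log2_values
  # original detection pattern, unaffected by imputation
  det <- if (!is.null(pm$detected)) pm$detected else !is.na(lv)
  if (mode == "conventional") {
    sig <- daps[daps$significant, , drop = FALSE]
    quant_prots <- sig$protein[sig$branch == "quantitative"]
    qual_prots <- sig$protein[sig$branch == "qualitative"]
    if (!is.null(restrict_group)) {
      if (!"functional_group" %in% names(sig))
        stop("group restriction needs annotated screening records")
      keep <- sig$protein[sig$functional_group == restrict_group]
      quant_prots <- intersect(quant_prots, keep)
      qual_prots <- intersect(qual_prots, keep)
    }
  } else {
    full_cov <- colnames(lv)[colSums(det) == nrow(lv) &
                               pm$branch == "quantitative"]
    varying <- colnames(lv)[colSums(det) > 0 & colSums(det) < nrow(lv)]
    quant_prots <- full_cov
    qual_prots <- varying
    if (!is.null(restrict_group)) {
      if (is.null(map)) stop("group restriction in free-choice mode needs a map")
      bare <- function(p) sub(":[a-z]+$", "", p)
      quant_prots <- quant_prots[map[bare(quant_prots)] %in% restrict_group]
      qual_prots <- qual_prots[map[bare(qual_prots)] %in% restrict_group]
    }
  }
  blocks <- list()
  if (length(quant_prots))
    blocks$quant <- lv[, quant_prots, drop = FALSE]
  if (length(qual_prots)) {
    ind <- det[, qual_prots, drop = FALSE] * 1
    colnames(ind) <- paste0(qual_prots, "|detected")
    blocks$qual <- ind
  }
  if (!length(blocks))
    stop("no features available under the requested mode/restriction")
  X <- do.call(cbind, blocks)
  # quantitative block may still hold NA outside the quantitative branch in
  # conventional mode; those columns are DAPs, hence imputed already
  stopifnot(!anyNA(X))
  X
}

#' Run the full prognostic pipeline on a cohort
#'
#' Orchestrates every stage: cohort simulation (or file ingestion), coverage
#' routing and imputation, two-branch differential-abundance screening,
#' functional annotation, conformal random-forest modeling of both the
#' categorical (4-year mortality) and continuous (days of survival) outcomes
#' in conventional and free-choice modes, and performance summarization with
#' prevalence re-adjustment.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{simulate}{List of \code{\link{cohort_spec}} arguments, or
#'       \code{NULL} when reading files.}
#'     \item{abundance,metadata}{File paths, used when \code{simulate} is
#'       absent.}
#'     \item{map}{Optional path to a functional-map TSV.}
#'     \item{model}{List of \code{\link{model_config}} overrides.}
#'     \item{modes}{Character subset of
#'       \code{c("conventional", "free-choice")}.}
#'     \item{targets}{Character subset of
#'       \code{c("categorical", "continuous")}.}
#'     \item{restrict_group}{Optional functional category restriction.}
#'     \item{exclude_anticoagulated}{Drop patients flagged as on
#'       antiaggregant/anticoagulant therapy before modeling.}
#'     \item{coverage_threshold,imputation_factor,alpha}{Screening tunables.}
#'     \item{out_dir}{Optional output directory for TSV/JSON reports.}
#'   }
#' @return A list of class \code{protomort_report}: \code{cohort_rates},
#'   \code{screening} (annotated table), \code{category_counts},
#'   \code{models} (per mode/target: cross-validation output, fitted-model
#'   resubstitution metrics, performance summaries), and the resolved
#'   configuration.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_model <- do.call(model_config, config$model %||% list())
  modes <- config$modes %||% c("conventional", "free-choice")
  targets <- config$targets %||% c("categorical", "continuous")
  alpha <- config$alpha %||% 0.05
  thr <- config$coverage_threshold %||% 0.80
  imp <- config$imputation_factor %||% 0.95

  if (!is.null(config$simulate) && !is.null(config$abundance))
    stop("config must give exactly one input source: 'simulate' or files")
  if (!is.null(config$simulate) || is.null(config$abundance)) {
    spec <- do.call(cohort_spec, config$simulate %||% list())
    cohort <- generate_cohort(spec)
    abundance <- cohort$abundance
    metadata <- cohort$metadata
    map <- make_synthetic_map(colnames(abundance), seed = spec$seed)
  } else {
    abundance <- read_abundance(config$abundance)
    metadata <- utils::read.table(config$metadata, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    map <- if (!is.null(config$map)) load_functional_map(config$map)
           else load_functional_map()
    cohort <- NULL
  }
  if (isTRUE(config$exclude_anticoagulated) &&
      "anticoagulated" %in% names(metadata)) {
    keep <- !metadata$anticoagulated
    abundance <- abundance[keep, , drop = FALSE]
    metadata <- metadata[keep, , drop = FALSE]
  }
  stopifnot(all(rownames(abundance) == metadata$patient))

  pm <- compute_coverage_and_route(abundance, metadata$status,
                                   threshold = thr)
  pm <- impute_min95(pm, factor = imp)
  daps <- screen_all(pm, alpha = alpha)
  daps <- annotate_daps(daps, map)

  rates <- cohort_rates(metadata)

  restrict <- config$restrict_group %||% NULL
  models <- list()
  for (mode in modes) {
    X <- build_features(pm, daps, mode = mode, restrict_group = restrict,
                        map = map)
    for (target in targets) {
      key <- paste(mode, target, sep = ".")
      if (target == "categorical") {
        y <- factor(metadata$status, levels = c("survivor", "non-survivor"))
        mc <- cfg_model; mc$rebalance <- "instance-hardness-threshold"
        cv <- cross_validate(X, y, mc, folds = 5L)
        perf <- confusion_metrics(cv$predictions, metadata$status)
        # resubstitution fit on the full cohort
        feats <- select_k_best(X, y, mc$k_best)
        fit <- fit_acp_classifier(X[, feats, drop = FALSE], y, mc)
        fit_pred <- predict_set(fit, X[, feats, drop = FALSE])
        fit_perf <- confusion_metrics(fit_pred, metadata$status)
        models[[key]] <- list(
          cv = cv, performance = perf, summary = summarize_model(perf),
          fit_performance = fit_perf, selected = feats)
      } else {
        y <- as.numeric(metadata$days_survival)
        mc <- cfg_model; mc$rebalance <- "all-knn"
        strata <- factor(metadata$status)
        cv <- cross_validate(X, y, mc, folds = 5L, strata = strata)
        feats <- select_k_best(X, y, mc$k_best)
        fit <- fit_acp_regressor(X[, feats, drop = FALSE], y, mc)
        fit_pred <- predict_interval(fit, X[, feats, drop = FALSE])
        metrics <- regression_metrics(
          y, yhat_fit = fit_pred$predicted,
          yhat_oof = cv$predictions$predicted,
          intervals = cv$predictions)
        models[[key]] <- list(cv = cv, metrics = metrics, selected = feats)
      }
    }
  }

  report <- list(
    cohort_rates = rates,
    screening = daps,
    category_counts = category_counts(daps),
    n_quantitative = sum(pm$branch == "quantitative"),
    n_dap = attr(daps, "n_dap"),
    models = models,
    processed = pm,
    metadata = metadata,
    cohort = cohort,
    config = list(model = cfg_model, modes = modes, targets = targets,
                  alpha = alpha, coverage_threshold = thr,
                  imputation_factor = imp, restrict_group = restrict)
  )
  class(report) <- "protomort_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.protomort_report <- function(x, ...) {
  cat("protomort_report\n")
  cat(sprintf("  cohort: n = %d; year-4 mortality %d%%\n",
              x$cohort_rates$n,
              x$cohort_rates$yearly_mortality_pct[["year4"]]))
  cat(sprintf("  screening: %d quantitative-branch proteins, %d DAPs\n",
              x$n_quantitative, x$n_dap))
  for (key in names(x$models)) {
    m <- x$models[[key]]
    if (!is.null(m$performance))
      cat(sprintf("  %s: Se %.2f Sp %.2f MCC %.2f Cov %.2f\n", key,
                  m$performance$se, m$performance$sp, m$performance$mcc,
                  m$performance$coverage))
    else
      cat(sprintf("  %s: R2 %.2f Q2 %.2f conformal accuracy %.2f\n", key,
                  m$metrics$r2, m$metrics$q2, m$metrics$conformal_accuracy))
  }
  invisible(x)
}

#' Write a pipeline report to TSV/JSON files
#'
#' @param report A \code{protomort_report}.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dap_table(report$screening, file.path(dir, "dap_table.tsv"))
  summaries <- lapply(names(report$models), function(key) {
    m <- report$models[[key]]
    if (!is.null(m$summary)) cbind(model = key, m$summary)
    else cbind(model = key, as.data.frame(m$metrics))
  })
  cls <- Filter(function(d) "se" %in% names(d), summaries)
  reg <- Filter(function(d) "r2" %in% names(d), summaries)
  if (length(cls))
    utils::write.table(do.call(rbind, cls),
                       file.path(dir, "categorical_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(reg))
    utils::write.table(do.call(rbind, reg),
                       file.path(dir, "continuous_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cohort_rates = report$cohort_rates,
         category_counts = as.list(report$category_counts),
         n_quantitative = report$n_quantitative,
         n_dap = report$n_dap),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
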