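#' Specification of a synthetic two-platform plasma proteomics cohort
#'
#' Describes the geometry and signal structure of a simulated cohort of stable
#' COPD patients followed for four years: group sizes, protein counts per
#' platform (label-free LC-MS and multiplex immunoassay), planted quantitative
#' and presence/absence effects, missingness mechanism, and follow-up length.
#'
#' The defaults reproduce the geometry of a 34-patient pilot cohort
#' (23 survivors, 11 non-survivors) profiled on 300 LC-MS proteins and 63
#' multiplex analytes, 363 features in all.
#'
#' @param n_survivors Number of 4-year survivors.
#' @param n_nonsurvivors Number of 4-year non-survivors.
#' @param n_proteins_lcms Number of LC-MS (label-free quantification) proteins.
#' @param n_proteins_mux Number of multiplex immunoassay analytes.
#' @param n_quant_dap Number of planted quantitative group effects.
#' @param n_qual_dap Number of planted presence/absence effects.
#' @param effect_log2fc Planted quantitative effect size, in log2 units
#'   (absolute shift of the non-survivor group mean; sign drawn per protein).
#' @param detect_prob_present Detection probability of a presence/absence
#'   protein in its "present" group.
#' @param detect_prob_absent Detection probability in the other group.
#' @param missing_rate Baseline missing-at-random dropout probability per cell.
#' @param censor_quantile Left-censoring quantile: per protein, generated
#'   values below this quantile of the protein's abundance distribution are
#'   set missing (mimics LC-MS detection limits, missing-not-at-random).
#' @param followup_days Administrative follow-up horizon in days.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class \code{cohort_spec}.
#' @examples
#' spec <- cohort_spec(seed = 46)
#' spec$n_survivors + spec$n_nonsurvivors
#' @export
cohort_spec <- function(n_survivors = 23L,
                        n_nonsurvivors = 11L,
                        n_proteins_lcms = 300L,
                        n_proteins_mux = 63L,
                        n_quant_dap = 10L,
                        n_qual_dap = 10L,
                        effect_log2fc = 2,
                        detect_prob_present = 0.9,
                        detect_prob_absent = 0.1,
                        missing_rate = 0.03,
                        censor_quantile = 0.12,
                        followup_days = 1460L,
                        seed = 46L) {
  spec <- list(
    n_survivors = as.integer(n_survivors),
    n_nonsurvivors = as.integer(n_nonsurvivors),
    n_proteins_lcms = as.integer(n_proteins_lcms),
    n_proteins_mux = as.integer(n_proteins_mux),
    n_quant_dap = as.integer(n_quant_dap),
    n_qual_dap = as.integer(n_qual_dap),
    effect_log2fc = as.numeric(effect_log2fc),
    detect_prob_present = as.numeric(detect_prob_present),
    detect_prob_absent = as.numeric(detect_prob_absent),
    missing_rate = as.numeric(missing_rate),
    censor_quantile = as.numeric(censor_quantile),
    followup_days = as.integer(followup_days),
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  counts <- c("n_survivors", "n_nonsurvivors", "followup_days")
  for (f in counts) {
    if (is.na(spec[[f]]) || spec[[f]] <= 0L)
      stop(sprintf("cohort_spec field '%s' must be a positive count", f))
  }
  if (spec$n_proteins_lcms < 0L || spec$n_proteins_mux < 0L ||
      spec$n_proteins_lcms + spec$n_proteins_mux == 0L)
    stop("total protein count must be a positive count")
  if (spec$n_quant_dap < 0L || spec$n_qual_dap < 0L)
    stop("planted effect counts must be non-negative")
  probs <- c("detect_prob_present", "detect_prob_absent", "missing_rate",
             "censor_quantile")
  for (f in probs) {
    if (is.na(spec[[f]]) || spec[[f]] < 0 || spec[[f]] > 1)
      stop(sprintf("cohort_spec field '%s' must lie in [0, 1]", f))
  }
  n_prot <- spec$n_proteins_lcms + spec$n_proteins_mux
  if (spec$n_quant_dap + spec$n_qual_dap > n_prot)
    stop(sprintf(
      "infeasible spec: %d planted effects requested but only %d proteins",
      spec$n_quant_dap + spec$n_qual_dap, n_prot))
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d survivors + %d non-survivors, %d proteins (%d lcms / %d mux)\n",
    x$n_survivors, x$n_nonsurvivors,
    x$n_proteins_lcms + x$n_proteins_mux, x$n_proteins_lcms, x$n_proteins_mux))
  cat(sprintf("  planted: %d quantitative (|log2FC| = %.2f), %d presence/absence\n",
              x$n_quant_dap, x$effect_log2fc, x$n_qual_dap))
  cat(sprintf("  missingness: censor quantile %.2f + MCAR rate %.2f; seed %d\n",
              x$censor_quantile, x$missing_rate, x$seed))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a patients-by-proteins linear-scale abundance matrix with planted
#' group effects and structured missingness, plus linked survival metadata.
#'
#' Per protein, log2 abundances are Gaussian around a protein-specific
#' baseline. Planted quantitative effects shift the non-survivor mean by
#' \code{effect_log2fc} log2 units (random sign, recorded in the truth table).
#' Planted presence/absence proteins are detected with probability
#' \code{detect_prob_present} in one group (chosen at random) and
#' \code{detect_prob_absent} in the other. Missingness is the union of
#' left-censoring below the per-protein \code{censor_quantile} (missing not at
#' random, as at an LC-MS detection limit) and uniform dropout at
#' \code{missing_rate}.
#'
#' Days of survival for non-survivors follow an exponential waiting time,
#' truncated to the follow-up horizon, whose rate increases log-linearly in a
#' latent risk score built from the planted marker log2 values; survivors are
#' administratively censored at \code{followup_days}. A frequent-exacerbator
#' flag is drawn with outcome-dependent probability (7/23 in survivors, 7/11
#' in non-survivors in expectation) so stratified mortality summaries are
#' exercisable.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return An object of class \code{synthetic_cohort} with elements
#'   \code{abundance} (patients x proteins linear-scale matrix, \code{NA} =
#'   missing, column names tagged \code{":lcms"} / \code{":mux"}),
#'   \code{metadata} (data.frame: \code{patient}, \code{status},
#'   \code{days_survival}, \code{frequent_exacerbator}), and \code{truth}
#'   (planted effect identities and directions).
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 46))
#' dim(coh$abundance)
#' table(coh$metadata$status)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_s <- spec$n_survivors
  n_d <- spec$n_nonsurvivors
  n <- n_s + n_d
  p_lcms <- spec$n_proteins_lcms
  p_mux <- spec$n_proteins_mux
  p <- p_lcms + p_mux

  proteins <- c(
    if (p_lcms > 0) paste0("LCMS", formatC(seq_len(p_lcms), width = 4, flag = "0"), ":lcms"),
    if (p_mux > 0) paste0("MUX", formatC(seq_len(p_mux), width = 3, flag = "0"), ":mux")
  )
  patients <- paste0("P", formatC(seq_len(n), width = 3, flag = "0"))
  status <- c(rep("survivor", n_s), rep("non-survivor", n_d))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  # protein baselines on the log2 scale
  base_mu <- stats::runif(p, min = 10, max = 20)
  base_sd <- stats::runif(p, min = 0.6, max = 1.4)

  # planted effect assignment: disjoint quantitative / qualitative sets
  planted <- sample.int(p, spec$n_quant_dap + spec$n_qual_dap)
  quant_idx <- planted[seq_len(spec$n_quant_dap)]
  qual_idx <- planted[spec$n_quant_dap + seq_len(spec$n_qual_dap)]
  quant_sign <- if (spec$n_quant_dap > 0)
    sample(c(-1, 1), spec$n_quant_dap, replace = TRUE) else numeric(0)
  # direction = +1: protein present/elevated in non-survivors
  qual_sign <- if (spec$n_qual_dap > 0)
    sample(c(-1, 1), spec$n_qual_dap, replace = TRUE) else numeric(0)

  log2_vals <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  log2_vals <- sweep(log2_vals, 2, base_sd, `*`)
  log2_vals <- sweep(log2_vals, 2, base_mu, `+`)
  is_dead <- status == "non-survivor"
  for (k in seq_along(quant_idx)) {
    j <- quant_idx[k]
    log2_vals[is_dead, j] <- log2_vals[is_dead, j] +
      quant_sign[k] * spec$effect_log2fc
  }

  detected <- matrix(TRUE, nrow = n, ncol = p)
  for (k in seq_along(qual_idx)) {
    j <- qual_idx[k]
    present_in_dead <- qual_sign[k] > 0
    pr <- ifelse(is_dead == present_in_dead,
                 spec$detect_prob_present, spec$detect_prob_absent)
    detected[, j] <- stats::runif(n) < pr
  }

  # MNAR left-censoring at the per-protein theoretical quantile of the
  # baseline distribution, then MCAR dropout
  if (spec$censor_quantile > 0) {
    lod <- stats::qnorm(spec$censor_quantile, mean = base_mu, sd = base_sd)
    censored <- sweep(log2_vals, 2, lod, `<`)
    detected <- detected & !censored
  }
  if (spec$missing_rate > 0) {
    mcar <- matrix(stats::runif(n * p) < spec$missing_rate, nrow = n)
    detected <- detected & !mcar
  }

  abundance <- 2^log2_vals
  abundance[!detected] <- NA_real_
  dimnames(abundance) <- list(patients, proteins)

  # latent risk: standardized planted-marker log2 values, qualitative
  # proteins contribute their detection indicator
  risk <- numeric(n)
  if (length(quant_idx) > 0) {
    z <- scale(log2_vals[, quant_idx, drop = FALSE])
    risk <- risk + as.numeric(z %*% quant_sign) / max(1, length(quant_idx))
  }
  if (length(qual_idx) > 0) {
    d <- detected[, qual_idx, drop = FALSE] * 1
    d <- sweep(d, 2, colMeans(d), `-`)
    risk <- risk + as.numeric(d %*% qual_sign) / max(1, length(qual_idx))
  }

  # exponential waiting times, rate log-linear in risk, truncated to follow-up
  fu <- spec$followup_days
  base_rate <- 1 / (0.6 * fu)
  rate <- base_rate * exp(risk[is_dead])
  days <- rep(fu, n)
  if (n_d > 0) {
    u <- stats::runif(n_d)
    # inverse-CDF draw from Exp(rate) truncated to (0, fu)
    trunc_p <- 1 - exp(-rate * fu)
    raw <- -log(1 - u * trunc_p) / rate
    days[is_dead] <- pmax(1L, pmin(fu - 1L, as.integer(round(raw))))
  }

  fe_prob <- ifelse(is_dead, 7 / 11, 7 / 23)
  fe <- stats::runif(n) < fe_prob

  metadata <- data.frame(
    patient = patients,
    status = status,
    days_survival = as.integer(days),
    frequent_exacerbator = fe,
    anticoagulated = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE
  )

  truth <- list(
    quantitative = data.frame(
      protein = proteins[quant_idx],
      log2fc = quant_sign * spec$effect_log2fc,
      direction = ifelse(quant_sign > 0, "up-in-nonsurvivors",
                         "down-in-nonsurvivors"),
      stringsAsFactors = FALSE
    ),
    qualitative = data.frame(
      protein = proteins[qual_idx],
      direction = ifelse(qual_sign > 0, "present-in-nonsurvivors",
                         "present-in-survivors"),
      stringsAsFactors = FALSE
    )
  )

  out <- list(abundance = abundance, metadata = metadata, truth = truth,
              spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients x %d proteins (%.1f%% missing)\n",
              nrow(x$abundance), ncol(x$abundance),
              100 * mean(is.na(x$abundance))))
  cat(sprintf("  %d survivors / %d non-survivors; %d + %d planted effects\n",
              sum(x$metadata$status == "survivor"),
              sum(x$metadata$status == "non-survivor"),
              nrow(x$truth$quantitative), nrow(x$truth$qualitative)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the abundance matrix (patients as rows, proteins as columns with
#' platform-tagged headers, empty cell = missing) and metadata as TSV, and the
#' planted-effect truth table as JSON.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  ab <- data.frame(patient = rownames(cohort$abundance),
                   cohort$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(ab, paths[["abundance"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(cohort$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
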