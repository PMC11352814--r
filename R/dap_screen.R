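#' Barnard's unconditional exact test for a 2x2 table
#'
#' Tests equality of two binomial proportions without conditioning on the
#' table margins. Tables are ordered by the pooled-variance Wald z statistic;
#' the two-sided p-value is the supremum, over the nuisance common success
#' probability, of the total probability of tables at least as extreme as the
#' observed one. The supremum is taken over a dense grid on (0, 1)
#' (step 0.001, boundaries excluded), which is the standard practical
#' evaluation of the unconditional test.
#'
#' @param x1 Successes in group 1 (out of \code{n1}).
#' @param n1 Size of group 1.
#' @param x2 Successes in group 2 (out of \code{n2}).
#' @param n2 Size of group 2.
#' @param grid_step Nuisance-parameter grid step, default 0.001.
#' @return A list with \code{p_value}, \code{statistic} (observed Wald z) and
#'   \code{pi_max} (grid point attaining the supremum).
#' @examples
#' barnard_test(9, 23, 0, 11)$p_value
#' @export
barnard_test <- function(x1, n1, x2, n2, grid_step = 0.001) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 >= 1, n2 >= 1)
  z_obs <- wald_pooled_z(x1, n1, x2, n2)
  if (!is.finite(z_obs) || z_obs == 0) {
    # degenerate: pooled proportion 0 or 1, or identical proportions;
    # every table is at least as extreme under the two-sided ordering
    return(list(p_value = 1, statistic = 0, pi_max = NA_real_))
  }
  a <- rep(0:n1, times = n2 + 1)
  c_ <- rep(0:n2, each = n1 + 1)
  z_all <- wald_pooled_z(a, n1, c_, n2)
  extreme <- abs(z_all) >= abs(z_obs) - 1e-12
  a_e <- a[extreme]
  c_e <- c_[extreme]
  pis <- seq(grid_step / 2, 1 - grid_step / 2, by = grid_step)
  # tail probability at each nuisance value; supremum over the grid
  d1 <- outer(pis, 0:n1, function(p, k) stats::dbinom(k, n1, p))
  d2 <- outer(pis, 0:n2, function(p, k) stats::dbinom(k, n2, p))
  tail_p <- rowSums(d1[, a_e + 1, drop = FALSE] * d2[, c_e + 1, drop = FALSE])
  i <- which.max(tail_p)
  list(p_value = min(1, tail_p[i]), statistic = z_obs, pi_max = pis[i])
}

# pooled-variance Wald z for difference of proportions; 0 when pooled
# proportion is degenerate (variance estimate 0)
wald_pooled_z <- function(x1, n1, x2, n2) {
  p_pool <- (x1 + x2) / (n1 + n2)
  v <- p_pool * (1 - p_pool) * (1 / n1 + 1 / n2)
  z <- (x2 / n2 - x1 / n1) / sqrt(v)
  z[v == 0] <- 0
  z
}

#' Phi (Matthews) coefficient of a 2x2 detection table
#'
#' Signed so that positive values mean the protein is more often present (or
#' more abundant) in non-survivors. Degenerate margins give 0.
#'
#' @param present_surv,n_surv Detections and group size among survivors.
#' @param present_nonsurv,n_nonsurv Same for non-survivors.
#' @return The phi coefficient in [-1, 1].
#' @export
phi_coefficient <- function(present_surv, n_surv, present_nonsurv, n_nonsurv) {
  a <- present_surv; b <- n_surv - present_surv
  c_ <- present_nonsurv; d <- n_nonsurv - present_nonsurv
  denom <- sqrt(as.numeric(n_surv) * n_nonsurv * (a + c_) * (b + d))
  if (denom == 0) return(0)
  (c_ * b - a * d) / denom
}

#' Quantitative differential-abundance test for one protein
#'
#' Compares log2 abundances between survivors and non-survivors. Each group
#' is checked for normality (Shapiro-Wilk at \code{alpha_normality}); when
#' both groups pass, a pooled-variance two-sample t-test is used, otherwise
#' the Mann-Whitney test. The effect is the log2 fold change, non-survivor
#' mean minus survivor mean, with the equivalent percent change.
#'
#' @param x_surv,x_nonsurv Numeric vectors of log2 abundances (length >= 2).
#' @param alpha_normality Shapiro-Wilk significance level gating the test
#'   choice, default 0.05.
#' @return A one-row data.frame: \code{branch}, \code{test},
#'   \code{statistic}, \code{p_value}, \code{log2fc}, \code{pct_change},
#'   \code{direction}.
#' @examples
#' quantitative_test(c(10, 11, 12, 13), c(14, 15, 16, 17))
#' @export
quantitative_test <- function(x_surv, x_nonsurv, alpha_normality = 0.05) {
  stopifnot(length(x_surv) >= 2, length(x_nonsurv) >= 2)
  log2fc <- mean(x_nonsurv) - mean(x_surv)
  if (stats::sd(x_surv) == 0 && stats::sd(x_nonsurv) == 0) {
    p <- if (log2fc == 0) 1 else 0
    return(quant_record("degenerate", 0, p, log2fc))
  }
  normal <- function(x) {
    if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value >= alpha_normality
  }
  if (normal(x_surv) && normal(x_nonsurv)) {
    ht <- stats::t.test(x_nonsurv, x_surv, var.equal = TRUE)
    quant_record("t", unname(ht$statistic), ht$p.value, log2fc)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x_nonsurv, x_surv, exact = FALSE, correct = TRUE))
    quant_record("mann-whitney", unname(ht$statistic), ht$p.value, log2fc)
  }
}

quant_record <- function(test, stat, p, log2fc) {
  data.frame(
    branch = "quantitative", test = test, statistic = stat, p_value = p,
    log2fc = log2fc, pct_change = (2^log2fc - 1) * 100,
    mcc = NA_real_,
    direction = if (log2fc > 0) "higher-in-nonsurvivors"
                else if (log2fc < 0) "lower-in-nonsurvivors" else "none",
    stringsAsFactors = FALSE
  )
}

#' Qualitative presence/absence test for one protein
#'
#' Barnard's unconditional exact test on the 2x2 detection table, with the
#' phi (Matthews) coefficient as effect size; positive phi means the protein
#' is more often present in non-survivors. Degenerate tables (detected in
#' nobody, or in everybody of both groups) return phi = 0, p = 1.
#'
#' @param present_surv Number of survivors with the protein detected.
#' @param n_surv Number of survivors.
#' @param present_nonsurv Detections among non-survivors.
#' @param n_nonsurv Number of non-survivors.
#' @return A one-row data.frame in the same layout as
#'   \code{\link{quantitative_test}} with \code{mcc} filled in.
#' @examples
#' qualitative_test(9, 23, 0, 11)
#' @export
qualitative_test <- function(present_surv, n_surv, present_nonsurv, n_nonsurv) {
  stopifnot(present_surv >= 0, present_nonsurv >= 0,
            present_surv <= n_surv, present_nonsurv <= n_nonsurv)
  phi <- phi_coefficient(present_surv, n_surv, present_nonsurv, n_nonsurv)
  bt <- barnard_test(present_surv, n_surv, present_nonsurv, n_nonsurv)
  data.frame(
    branch = "qualitative", test = "barnard",
    statistic = bt$statistic, p_value = bt$p_value,
    log2fc = NA_real_, pct_change = NA_real_, mcc = phi,
    direction = if (phi > 0) "present-in-nonsurvivors"
                else if (phi < 0) "present-in-survivors" else "none",
    stringsAsFactors = FALSE
  )
}

#' Screen every protein for differential abundance
#'
#' Runs the quantitative branch (t / Mann-Whitney on imputed log2 values) on
#' every protein with at least 80\% coverage in both groups, and the
#' qualitative branch (Barnard test on the detection table) on every
#' remaining protein whose detection pattern qualifies as presence/absence:
#' detected in at least \code{presence_min} of one group and at most
#' \code{absence_max} of the other. Proteins failing both are reported with
#' branch \code{"excluded"} and no test.
#'
#' Significance is two-sided unadjusted p < \code{alpha}; a
#' Benjamini-Hochberg adjusted column is emitted for reference but does not
#' drive the differentially-abundant set.
#'
#' @param pm An imputed \code{processed_matrix} (see
#'   \code{\link{impute_min95}}).
#' @param alpha Significance level, default 0.05.
#' @param presence_min,absence_max Presence/absence eligibility fractions,
#'   defaults 0.80 / 0.20.
#' @return A data.frame of per-protein records (one row per tested protein,
#'   plus excluded rows with NA statistics), with attribute \code{"n_dap"}.
#' @export
screen_all <- function(pm, alpha = 0.05, presence_min = 0.80,
                       absence_max = 0.20) {
  stopifnot(inherits(pm, "processed_matrix"))
  if (!pm$imputed && any(is.na(pm$log2_values[, pm$branch == "quantitative"])))
    stop("quantitative branch contains missing values; run impute_min95() first")
  is_s <- pm$group == "survivor"
  is_d <- pm$group == "non-survivor"
  lv <- pm$log2_values
  rows <- vector("list", ncol(lv))
  for (j in seq_len(ncol(lv))) {
    prot <- colnames(lv)[j]
    if (pm$branch[j] == "quantitative") {
      rec <- quantitative_test(lv[is_s, j], lv[is_d, j])
    } else {
      det <- !is.na(lv[, j])
      f_s <- mean(det[is_s]); f_d <- mean(det[is_d])
      eligible <- (f_s >= presence_min && f_d <= absence_max) ||
                  (f_d >= presence_min && f_s <= absence_max)
      if (eligible) {
        rec <- qualitative_test(sum(det[is_s]), sum(is_s),
                                sum(det[is_d]), sum(is_d))
      } else {
        rec <- data.frame(branch = "excluded", test = NA_character_,
                          statistic = NA_real_, p_value = NA_real_,
                          log2fc = NA_real_, pct_change = NA_real_,
                          mcc = NA_real_, direction = NA_character_,
                          stringsAsFactors = FALSE)
      }
    }
    rows[[j]] <- cbind(data.frame(protein = prot, stringsAsFactors = FALSE),
                       rec)
  }
  res <- do.call(rbind, rows)
  tested <- !is.na(res$p_value)
  res$p_adjusted <- NA_real_
  res$p_adjusted[tested] <- stats::p.adjust(res$p_value[tested], "BH")
  res$significant <- tested & res$p_value < alpha
  attr(res, "n_dap") <- sum(res$significant)
  res
}

#' Write a differential-abundance table to TSV
#'
#' Columns mirror the usual reporting layout: protein, branch, percent change
#' (quantitative) or MCC (qualitative), and p-value.
#'
#' @param daps Screening result from \code{\link{screen_all}} (typically
#'   after \code{\link{annotate_daps}}).
#' @param path Output file.
#' @export
write_dap_table <- function(daps, path) {
  cols <- intersect(
    c("protein", "branch", "functional_group", "pct_change", "mcc",
      "p_value", "significant"),
    names(daps))
  utils::write.table(daps[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
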