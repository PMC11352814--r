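#' Read an abundance table from delimited text
#'
#' Reads a patients-by-proteins table in the dialect written by
#' \code{\link{write_cohort}}: first column holds patient identifiers, the
#' remaining columns one protein each (optionally tagged with a platform
#' suffix such as \code{":lcms"}), empty cells meaning missing. Both TSV and
#' CSV are accepted.
#'
#' @param path File path.
#' @param platform Optional platform tag appended (as \code{":tag"}) to any
#'   column name that does not already carry one.
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @return A numeric matrix, patients as rows, `NA` for missing cells.
#' @export
read_abundance <- function(path, platform = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (!is.null(platform)) {
    untagged <- !grepl(":", colnames(m), fixed = TRUE)
    colnames(m)[untagged] <- paste0(colnames(m)[untagged], ":", platform)
  }
  if (any(m[!is.na(m)] <= 0))
    stop("abundance values must be strictly positive where observed")
  m
}

#' Merge two platform abundance matrices
#'
#' Joins measurements from two platforms over an identical patient set. A
#' protein measured on both platforms is kept as two distinct tagged columns;
#' measurements are never averaged across platforms. Patient (row) order of
#' the first matrix is preserved.
#'
#' @param lcms,mux Numeric matrices, patients as rows, proteins as columns.
#'   Either may have zero columns.
#' @return The merged matrix.
#' @export
merge_platforms <- function(lcms, mux) {
  if (ncol(mux) == 0) return(lcms)
  if (ncol(lcms) == 0) return(mux)
  missing_in_mux <- setdiff(rownames(lcms), rownames(mux))
  missing_in_lcms <- setdiff(rownames(mux), rownames(lcms))
  if (length(missing_in_mux) || length(missing_in_lcms))
    stop("patient sets differ between platforms: ",
         paste(c(missing_in_mux, missing_in_lcms), collapse = ", "))
  mux <- mux[rownames(lcms), , drop = FALSE]
  dup <- intersect(colnames(lcms), colnames(mux))
  if (length(dup))
    stop("duplicate tagged protein identifiers across platforms: ",
         paste(dup, collapse = ", "))
  cbind(lcms, mux)
}

#' Compute per-group detection coverage and route proteins to branches
#'
#' Log2-transforms the merged linear-scale matrix and computes, for every
#' protein, the fraction of patients in each outcome group with an observed
#' value. Proteins observed in at least \code{threshold} of the patients of
#' \emph{both} groups enter the quantitative branch; all others become
#' qualitative candidates (tested later as presence/absence patterns if they
#' qualify, reported as excluded otherwise).
#'
#' @param m Linear-scale abundance matrix (`NA` = missing).
#' @param group Character vector, one of `"survivor"` / `"non-survivor"` per
#'   patient (row of `m`).
#' @param threshold Coverage threshold, default 0.80.
#' @return An object of class \code{processed_matrix}: \code{log2_values}
#'   (with missing cells), \code{coverage} (per-protein data.frame),
#'   \code{branch} (named character: `"quantitative"` or
#'   `"qualitative-candidate"`), \code{group}, \code{threshold}.
#' @export
compute_coverage_and_route <- function(m, group, threshold = 0.80) {
  stopifnot(nrow(m) == length(group))
  group <- as.character(group)
  bad <- setdiff(unique(group), c("survivor", "non-survivor"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  is_s <- group == "survivor"
  is_d <- group == "non-survivor"
  if (!any(is_s) || !any(is_d))
    stop("both outcome groups must be non-empty")
  obs <- !is.na(m)
  cov_s <- colMeans(obs[is_s, , drop = FALSE])
  cov_d <- colMeans(obs[is_d, , drop = FALSE])
  branch <- ifelse(cov_s >= threshold & cov_d >= threshold,
                   "quantitative", "qualitative-candidate")
  names(branch) <- colnames(m)
  out <- list(
    log2_values = log2(m),
    detected = obs,
    coverage = data.frame(
      protein = colnames(m),
      coverage_survivor = unname(cov_s),
      coverage_nonsurvivor = unname(cov_d),
      stringsAsFactors = FALSE
    ),
    branch = branch,
    group = group,
    threshold = threshold,
    imputed = FALSE
  )
  class(out) <- "processed_matrix"
  out
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("processed_matrix: %d patients x %d proteins\n",
              nrow(x$log2_values), ncol(x$log2_values)))
  cat(sprintf("  quantitative branch (coverage >= %.0f%% in both groups): %d\n",
              100 * x$threshold, sum(x$branch == "quantitative")))
  cat(sprintf("  qualitative candidates: %d; imputed: %s\n",
              sum(x$branch == "qualitative-candidate"), x$imputed))
  invisible(x)
}

#' Minimum-based imputation for the quantitative branch
#'
#' Each missing cell of a quantitative-branch protein receives a fixed
#' fraction (default 95\%) of that protein's minimum observed linear-scale
#' value, placing imputed values just below the protein's apparent detection
#' limit. Observed cells are never altered; qualitative-candidate proteins
#' are left untouched.
#'
#' @param pm A \code{processed_matrix} from
#'   \code{\link{compute_coverage_and_route}}.
#' @param factor Fraction of the per-protein observed minimum used for
#'   imputation, default 0.95.
#' @return The \code{processed_matrix} with quantitative-branch missing cells
#'   filled in (on the log2 scale) and \code{imputed = TRUE}.
#' @export
impute_min95 <- function(pm, factor = 0.95) {
  stopifnot(inherits(pm, "processed_matrix"))
  lv <- pm$log2_values
  quant <- which(pm$branch == "quantitative")
  for (j in quant) {
    miss <- is.na(lv[, j])
    if (!any(miss)) next
    obs_min <- min(lv[!miss, j])  # routing guarantees >= threshold observed
    lv[miss, j] <- obs_min + log2(factor)
  }
  pm$log2_values <- lv
  pm$imputed <- TRUE
  pm$imputation_factor <- factor
  pm
}
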