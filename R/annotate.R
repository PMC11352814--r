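#' Functional categories used for protein classification
#' @keywords internal
functional_categories <- function() {
  c("lipid-metabolism", "hemostasis", "cytokine", "complement",
    "adaptive-immunity", "other-immune", "orphan")
}

#' Load a protein-to-functional-group mapping
#'
#' Reads a two-column TSV (\code{protein_id}, \code{category}). The packaged
#' default covers the plasma proteins recurrently reported as mortality
#' markers in stable COPD (coagulation factors, complement components,
#' cytokines/chemokines, immunoglobulin fractions, and assorted orphans),
#' classified into seven functional categories following Reactome/UniProt
#' annotation.
#'
#' @param path TSV path; defaults to the packaged map.
#' @return A named character vector, protein id to category.
#' @export
load_functional_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "functional_map.tsv",
                        package = "protomort", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("protein_id", "category") %in% names(df)))
  bad <- setdiff(unique(df$category), functional_categories())
  if (length(bad))
    stop("unknown functional categories in map: ", paste(bad, collapse = ", "))
  stats::setNames(df$category, df$protein_id)
}

#' Attach functional categories to screening records
#'
#' Looks up each protein (platform tags such as \code{":lcms"} are stripped
#' before matching) in the functional map; proteins absent from the map fall
#' back to the \code{"orphan"} category with a warning.
#'
#' @param daps Data.frame from \code{\link{screen_all}} (or any data.frame
#'   with a \code{protein} column).
#' @param map Named character vector from \code{\link{load_functional_map}}.
#' @return \code{daps} with a \code{functional_group} column appended.
#' @export
annotate_daps <- function(daps, map = load_functional_map()) {
  if (nrow(daps) == 0) {
    daps$functional_group <- character(0)
    return(daps)
  }
  bare <- sub(":[a-z]+$", "", daps$protein)
  cat_ <- unname(map[bare])
  unknown <- is.na(cat_)
  if (any(unknown))
    warning(sprintf("%d proteins not in the functional map, assigned 'orphan': %s",
                    sum(unknown),
                    paste(utils::head(unique(bare[unknown]), 5),
                          collapse = ", ")))
  cat_[unknown] <- "orphan"
  daps$functional_group <- cat_
  daps
}

#' Per-category counts over the significant records
#'
#' @param daps Annotated screening result.
#' @return Named integer vector over the seven categories (zeros included),
#'   restricted to rows flagged significant when the column is present.
#' @export
category_counts <- function(daps) {
  rows <- if ("significant" %in% names(daps)) daps[daps$significant, ] else daps
  tab <- table(factor(rows$functional_group,
                      levels = functional_categories()))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Export a protein-protein edge list for external network rendering
#'
#' Writes a tab-separated file of node pairs with a score column and the
#' functional category of each endpoint, suitable for import into a network
#' viewer. Differentially abundant proteins that appear in no supplied edge
#' are emitted as singleton rows (empty second node), so the node set always
#' equals the protein set.
#'
#' @param daps Annotated screening result (significant rows are used when a
#'   \code{significant} column is present).
#' @param edges Optional data.frame with columns \code{node1}, \code{node2}
#'   and optionally \code{score}; edges whose endpoints are not both in the
#'   protein set are dropped.
#' @param path Output TSV path.
#' @return Invisibly, the data.frame written.
#' @export
export_edges <- function(daps, edges = NULL, path) {
  rows <- if ("significant" %in% names(daps)) daps[daps$significant, ] else daps
  prots <- sub(":[a-z]+$", "", rows$protein)
  cats <- if ("functional_group" %in% names(rows)) rows$functional_group
          else rep("orphan", length(prots))
  cat_of <- stats::setNames(cats, prots)
  out <- data.frame(node1 = character(0), node2 = character(0),
                    score = numeric(0), category1 = character(0),
                    category2 = character(0), stringsAsFactors = FALSE)
  linked <- character(0)
  if (!is.null(edges) && nrow(edges) > 0) {
    keep <- edges$node1 %in% prots & edges$node2 %in% prots
    e <- edges[keep, , drop = FALSE]
    if (nrow(e)) {
      out <- data.frame(
        node1 = e$node1, node2 = e$node2,
        score = if ("score" %in% names(e)) e$score else NA_real_,
        category1 = unname(cat_of[e$node1]),
        category2 = unname(cat_of[e$node2]),
        stringsAsFactors = FALSE)
      linked <- unique(c(e$node1, e$node2))
    }
  }
  singles <- setdiff(prots, linked)
  if (length(singles)) {
    out <- rbind(out, data.frame(
      node1 = singles, node2 = "", score = NA_real_,
      category1 = unname(cat_of[singles]), category2 = "",
      stringsAsFactors = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Generate a synthetic functional map for simulated proteins
#'
#' Assigns each simulated protein a functional category at random (seeded),
#' so group-restricted modeling can be exercised on synthetic cohorts. The
#' assignment is synthetic and carries no biological meaning.
#'
#' @param proteins Character vector of (possibly platform-tagged) protein
#'   identifiers.
#' @param seed Integer seed.
#' @return Named character vector, bare protein id to category.
#' @export
make_synthetic_map <- function(proteins, seed = 46L) {
  bare <- sub(":[a-z]+$", "", proteins)
  cats <- with_seed(seed, sample(functional_categories(), length(bare),
                                 replace = TRUE))
  stats::setNames(cats, bare)
}
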