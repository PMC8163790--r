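## Blood-cell contamination screening.
##
## Plasma routinely carries variable amounts of intracellular erythrocyte
## and platelet proteins introduced during collection and processing. A
## shared, sample-level carry-over component makes those proteins strongly
## correlated with one another across samples, so correlation clustering at
## |r| >= 0.8 recovers the contamination structure, suggests panel
## extensions (proteins that co-vary with the panel without being on it),
## and lets differential hits on panel proteins be audited: if the other
## panel members co-trend in the same contrast, the "signal" is sample
## handling, not biology. Platelet proteins are clustered and reported but
## never auto-flagged: platelet-rich plasma makes them part of the sample.

#' Protein-protein correlation matrix
#'
#' Pairwise-complete Pearson (or Spearman) correlations between protein
#' columns. Pairs with fewer than 3 complete observations are reported as
#' `NA`. The diagonal is 1 and the matrix is symmetric.
#'
#' @param matrix a `concentration_matrix` or a plain numeric matrix
#'   (samples x proteins).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A proteins x proteins correlation matrix.
#' @export
correlation_matrix <- function(matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (inherits(matrix, "concentration_matrix")) matrix$values else matrix
  stopifnot(is.matrix(v), is.numeric(v))
  r <- suppressWarnings(cor(v, use = "pairwise.complete.obs",
                            method = method))
  n_pairs <- crossprod(!is.na(v))
  r[n_pairs < 3] <- NA_real_
  diag(r) <- 1
  r
}

#' Cluster proteins by correlation threshold
#'
#' Builds a graph with an edge wherever `|r| >= threshold` and returns its
#' connected components with at least 2 members (singletons are omitted).
#' Components -- not complete subgraphs -- are the weakest defensible
#' reading of a thresholded correlation matrix; tighten `threshold` for
#' stricter clusters.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param threshold minimum `|r|` for an edge (default 0.8).
#' @param panel optional character vector of panel protein ids; populates
#'   the per-cluster panel-overlap count.
#' @return A list of clusters, each with `members`, `n_members`,
#'   `panel_overlap`, and `mean_abs_r` (mean `|r|` over within-cluster
#'   edges).
#' @export
cluster_by_threshold <- function(corr, threshold = 0.8, panel = character(0)) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  a <- abs(corr)
  a[is.na(a)] <- 0
  adj <- a >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- list()
  for (cid in seq_len(comp$no)) {
    members <- colnames(corr)[comp$membership == cid]
    if (length(members) < 2) next
    sub <- a[members, members]
    edges <- sub[upper.tri(sub)]
    edges <- edges[edges >= threshold]
    clusters[[length(clusters) + 1]] <- list(
      members = members, n_members = length(members),
      panel_overlap = length(intersect(members, panel)),
      mean_abs_r = if (length(edges) > 0) mean(edges) else NA_real_)
  }
  clusters[order(vapply(clusters, `[[`, integer(1), "n_members"),
                 decreasing = TRUE)]
}

#' Propose contamination-panel extensions
#'
#' Ranks non-panel proteins by their median absolute correlation to the
#' panel members; proteins at or above `threshold` are proposed as likely
#' sharing the panel's origin (the way an unexpected intracellular protein
#' can be recognized as erythrocyte-derived purely from its co-variation
#' with the erythrocyte panel).
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param panel character vector of panel protein ids; at least one must be
#'   present in `corr`.
#' @param threshold minimum median `|r|` (default 0.8).
#' @return A data.frame of candidates with `protein_id` and
#'   `median_abs_r`, ranked by decreasing `median_abs_r`.
#' @export
propose_panel_extension <- function(corr, panel, threshold = 0.8) {
  present <- intersect(panel, colnames(corr))
  if (length(present) == 0) {
    stop("no panel member present in the correlation matrix")
  }
  candidates <- setdiff(colnames(corr), panel)
  med <- vapply(candidates, function(p) {
    median(abs(corr[p, present]), na.rm = TRUE)
  }, numeric(1))
  keep <- !is.na(med) & med >= threshold
  out <- data.frame(protein_id = candidates[keep],
                    median_abs_r = unname(med[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$median_abs_r), , drop = FALSE]
}

#' Audit differential panel proteins for contamination origin
#'
#' For every significantly altered protein of the (extended) contamination
#' panel in a contrast, checks whether the other panel members show a
#' similar trend: at least `co_trend_fraction` of them moving in the same
#' direction with `|log2FC| >= co_trend_min_lfc` yields the verdict
#' `contaminant_origin`; fewer co-trending members yields `biological`;
#' fewer than 3 other panel members measured yields `indeterminate`.
#' Non-panel proteins are never flagged.
#'
#' @param results differential results from [run_contrast()].
#' @param panel character vector: the (extended) contamination panel.
#' @param co_trend_fraction fraction of other panel members that must
#'   co-trend (default 0.5).
#' @param co_trend_min_lfc minimum same-sign `|log2FC|` that counts as
#'   co-trending (default 0.5).
#' @return A data.frame of verdicts for the significantly altered panel
#'   proteins: `protein_id`, `verdict`, `n_other_measured`,
#'   `co_trend_fraction_observed`.
#' @export
flag_differential_contaminants <- function(results, panel,
                                           co_trend_fraction = 0.5,
                                           co_trend_min_lfc = 0.5) {
  stopifnot(is.data.frame(results),
            all(c("protein_id", "significant", "log2_fc") %in%
                  names(results)))
  panel_res <- results[results$protein_id %in% panel, ]
  hits <- panel_res[panel_res$significant %in% TRUE, ]
  verdicts <- lapply(seq_len(nrow(hits)), function(i) {
    p <- hits$protein_id[i]
    own_lfc <- hits$log2_fc[i]
    others <- panel_res[panel_res$protein_id != p &
                          is.finite(panel_res$log2_fc), ]
    n_other <- nrow(others)
    if (n_other < 3) {
      return(data.frame(protein_id = p, verdict = "indeterminate",
                        n_other_measured = n_other,
                        co_trend_fraction_observed = NA_real_,
                        stringsAsFactors = FALSE))
    }
    co <- sign(others$log2_fc) == sign(own_lfc) &
      abs(others$log2_fc) >= co_trend_min_lfc
    frac <- mean(co)
    data.frame(protein_id = p,
               verdict = if (frac >= co_trend_fraction) "contaminant_origin"
                         else "biological",
               n_other_measured = n_other,
               co_trend_fraction_observed = frac, stringsAsFactors = FALSE)
  })
  if (length(verdicts) == 0) {
    return(data.frame(protein_id = character(0), verdict = character(0),
                      n_other_measured = integer(0),
                      co_trend_fraction_observed = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, verdicts)
}
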