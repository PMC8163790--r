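## Over-representation analysis.
##
## A protein list (differential hits, LASSO discriminators, or their union)
## is tested against user-supplied gene-set collections with the one-sided
## hypergeometric tail test, using the quantified protein panel -- not the
## genome -- as the background. Identifier mapping (e.g. mouse proteins to
## human orthologs for disease resources) is the caller's responsibility
## via an explicit two-column table applied before testing.

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `x` annotated items when `n` items are
#' drawn without replacement from a background of `N` items of which `K`
#' are annotated:
#' \deqn{p = \sum_{k=x}^{\min(K,n)} \binom{K}{k}\binom{N-K}{n-k} /
#'   \binom{N}{n}.}
#'
#' @param N background size.
#' @param K annotated items in the background.
#' @param n list size.
#' @param x observed overlap.
#' @return The one-sided enrichment p-value.
#' @export
#' @examples
#' hypergeometric_tail(20, 5, 4, 3)  # 155/4845
hypergeometric_tail <- function(N, K, n, x) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(x) == 1)
  if (!(x >= 0 && x <= n && n <= N && K >= 0 && K <= N)) {
    stop("require 0 <= x <= n <= N and 0 <= K <= N")
  }
  if (x > K) stop("overlap x cannot exceed K")
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Run over-representation analysis
#'
#' Sets are intersected with the background before testing; sets with fewer
#' than `min_set_size` background members are skipped; BH adjustment is
#' applied across the sets tested within the collection. List members
#' outside the background are dropped with a warning giving their count.
#'
#' @param protein_list character vector of proteins of interest.
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param background character vector: the quantified proteins.
#' @param min_set_size minimum annotated-in-background size (default 3).
#' @param id_map optional data.frame with columns `from`, `to`; applied to
#'   both list and background before testing (unmapped ids are kept as-is).
#' @return A data.frame with one row per tested set: `set_name`,
#'   `description`, `N`, `K`, `n`, `x`, `p_raw`, `p_adjusted`,
#'   `overlap_ids` (semicolon-separated), sorted by `p_raw`.
#' @export
run_ora <- function(protein_list, collection, background, min_set_size = 3,
                    id_map = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(protein_list) == 0) stop("empty protein list")
  if (!is.null(id_map)) {
    stopifnot(all(c("from", "to") %in% names(id_map)))
    remap <- function(ids) {
      i <- match(ids, id_map$from)
      ifelse(is.na(i), ids, id_map$to[i])
    }
    protein_list <- remap(protein_list)
    background <- remap(background)
  }
  protein_list <- unique(protein_list)
  background <- unique(background)
  outside <- setdiff(protein_list, background)
  if (length(outside) > 0) {
    warning(length(outside), " list member(s) outside the background were ",
            "dropped")
    protein_list <- intersect(protein_list, background)
  }
  if (length(protein_list) == 0) {
    stop("protein list and background are disjoint")
  }
  N <- length(background)
  n <- length(protein_list)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]]$members, background)
    K <- length(members)
    if (K < min_set_size) return(NULL)
    overlap <- intersect(protein_list, members)
    x <- length(overlap)
    data.frame(set_name = nm, description = collection[[nm]]$description,
               N = N, K = K, n = n, x = x,
               p_raw = hypergeometric_tail(N, K, n, x),
               p_adjusted = NA_real_,
               overlap_ids = paste(overlap, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_name = character(0), description = character(0),
                      N = integer(0), K = integer(0), n = integer(0),
                      x = integer(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), overlap_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  out$p_adjusted <- benjamini_hochberg(out$p_raw)
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  out
}
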