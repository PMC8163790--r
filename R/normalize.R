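## Plate normalization against pooled references and the filtering cascade.

#' Normalize plates against pooled references
#'
#' For each (plate, protein), study values on the plate are rescaled by
#' `grand median / plate median` of the pooled-reference concentrations, so
#' every plate's pooled reference lands on the same anchor (the grand median
#' across all plates; the anchor is a global constant per protein and
#' cancels in all downstream contrasts). Below-LLOQ pooled values are
#' excluded from both medians. Exception: when more than half of a plate's
#' pooled values for a protein are below the assay LLOQ, the original
#' back-calculated values are considered more trustworthy and kept unchanged
#' (factor 1). Censor flags are recomputed against LLOQ/ULOQ after scaling.
#'
#' @param matrix study-sample `concentration_matrix`.
#' @param pooled_matrix pooled-reference `concentration_matrix`.
#' @param plate_map named character vector mapping every sample id (study
#'   and pooled) to its plate.
#' @param assays assay definitions carrying `lloq`/`uloq` per protein.
#' @return A list with `study` and `pooled` (normalized matrices) and
#'   `report`: a data.frame with one row per (plate, protein) giving the
#'   scale `factor`, `n_pooled`, `n_below_lloq`, and `exception_applied`.
#' @export
normalize_plates <- function(matrix, pooled_matrix, plate_map, assays) {
  stopifnot(inherits(matrix, "concentration_matrix"),
            inherits(pooled_matrix, "concentration_matrix"))
  proteins <- colnames(matrix$values)
  stopifnot(identical(proteins, colnames(pooled_matrix$values)))
  lloq <- setNames(assays$lloq, assays$protein_id)[proteins]
  uloq <- setNames(assays$uloq, assays$protein_id)[proteins]

  study_plate <- plate_map[rownames(matrix$values)]
  pooled_plate <- plate_map[rownames(pooled_matrix$values)]
  if (anyNA(study_plate) || anyNA(pooled_plate)) {
    stop("plate_map does not cover every sample")
  }
  plates <- sort(unique(c(study_plate, pooled_plate)))
  for (pl in plates) {
    if (sum(pooled_plate == pl) == 0) {
      stop("plate '", pl, "' has no pooled references")
    }
  }

  v_study <- matrix$values
  v_pooled <- pooled_matrix$values
  report <- vector("list", length(plates) * length(proteins))
  k <- 0
  factors <- base::matrix(1, length(plates), length(proteins),
                          dimnames = list(plates, proteins))
  for (p in proteins) {
    pooled_vals <- v_pooled[, p]
    below <- !is.na(pooled_vals) & pooled_vals < lloq[[p]]
    usable <- !is.na(pooled_vals) & !below
    grand_median <- if (any(usable)) median(pooled_vals[usable]) else NA_real_
    for (pl in plates) {
      on_plate <- pooled_plate == pl
      n_pooled <- sum(on_plate & !is.na(pooled_vals))
      n_below <- sum(on_plate & below)
      exception <- n_pooled > 0 && n_below > n_pooled / 2
      fac <- 1
      if (!exception && !is.na(grand_median)) {
        plate_median <- if (any(on_plate & usable)) {
          median(pooled_vals[on_plate & usable])
        } else NA_real_
        if (!is.na(plate_median) && plate_median > 0) {
          fac <- grand_median / plate_median
        }
      }
      factors[pl, p] <- fac
      k <- k + 1
      report[[k]] <- data.frame(plate_id = pl, protein_id = p, factor = fac,
                                n_pooled = n_pooled, n_below_lloq = n_below,
                                exception_applied = exception,
                                stringsAsFactors = FALSE)
    }
    v_study[, p] <- v_study[, p] * factors[study_plate, p]
    v_pooled[, p] <- v_pooled[, p] * factors[pooled_plate, p]
  }

  reflag <- function(v) {
    f <- base::matrix("in_range", nrow(v), ncol(v), dimnames = dimnames(v))
    lq <- rep(lloq, each = nrow(v))
    uq <- rep(uloq, each = nrow(v))
    f[!is.na(v) & v < lq] <- "below_lloq"
    f[!is.na(v) & v > uq] <- "above_uloq"
    f[is.na(v)] <- "missing"
    f
  }
  list(study = concentration_matrix(v_study, reflag(v_study)),
       pooled = concentration_matrix(v_pooled, reflag(v_pooled)),
       report = do.call(rbind, report))
}

#' Apply the detectability / quantifiability filtering cascade
#'
#' Three nested stages reduce the measured panel to the set carried into all
#' downstream analyses:
#' \enumerate{
#'   \item detectable: at least one measurement in range anywhere;
#'   \item quantifiable: at least `min_quantifiable_fraction` (default 5%)
#'     of all measurements in range;
#'   \item final: quantified within the assay's dynamic range in every
#'     member of at least one (strain, sex) group.
#' }
#' Values below the LLOQ that survive filtering are retained as
#' back-calculated numbers -- never imputed or dropped -- since the
#' downstream rank-based tests tolerate them.
#'
#' @param matrix study `concentration_matrix` (post-normalization).
#' @param annotations sample annotations resolving the strain x sex groups.
#' @param config a [proteotype_config()].
#' @return A list with `matrix` (reduced to surviving proteins) and
#'   `report`: counts `n_measured >= n_detectable >= n_quantifiable >=
#'   n_final` plus a per-protein `disposition` data.frame with the stage
#'   reached and the reason for any drop.
#' @export
filter_cascade <- function(matrix, annotations,
                           config = proteotype_config()) {
  stopifnot(inherits(matrix, "concentration_matrix"))
  f <- matrix$flags
  samples <- rownames(f)
  ann <- annotations[match(samples, annotations$sample_id), ]
  if (anyNA(ann$sample_id)) {
    stop("annotations do not cover every study sample")
  }
  group <- paste(ann$strain, ann$sex)

  in_range <- f == "in_range"
  measured <- f != "missing"
  n_meas <- colSums(measured)

  detectable <- colSums(in_range) >= 1
  frac_in_range <- ifelse(n_meas > 0, colSums(in_range) / n_meas, 0)
  quantifiable <- detectable & frac_in_range >= config$min_quantifiable_fraction

  complete_group <- apply(in_range, 2, function(col) {
    any(vapply(split(col, group), all, logical(1)))
  })
  final <- quantifiable & complete_group

  reason <- rep("kept", ncol(f))
  reason[!complete_group] <- "no complete strain-sex group in range"
  reason[!quantifiable] <- sprintf(
    "in-range fraction below %.2f", config$min_quantifiable_fraction)
  reason[!detectable] <- "never in range"
  disposition <- data.frame(protein_id = colnames(f),
                            detectable = unname(detectable),
                            quantifiable = unname(quantifiable),
                            final = unname(final),
                            in_range_fraction = unname(frac_in_range),
                            reason = reason, stringsAsFactors = FALSE)
  report <- list(n_measured = ncol(f),
                 n_detectable = sum(detectable),
                 n_quantifiable = sum(quantifiable),
                 n_final = sum(final),
                 disposition = disposition)
  class(report) <- "filter_report"
  list(matrix = matrix[, final, drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d measured -> %d detectable -> %d quantifiable -> %d final\n",
    x$n_measured, x$n_detectable, x$n_quantifiable, x$n_final))
  invisible(x)
}
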