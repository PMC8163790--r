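## Correlation of protein concentrations with clinical phenotyping tests.
##
## Protein levels are correlated with continuous clinical measurements
## (clinical chemistry, hematology, body composition). Sexual dimorphism is
## a strong confounder for such correlations, so a sex-adjusted residual
## correlation (per-sex mean removal of both variables, equivalent to
## regressing each on a sex indicator) and per-sex stratified correlations
## are reported alongside the unadjusted estimate.

#' Correlate every protein with every phenotyping test
#'
#' Pairwise-complete correlations between the protein columns of the
#' concentration matrix and the numeric columns of the phenotype table.
#' Pairs with fewer than 3 complete observations are skipped (their count
#' is returned in the `n_skipped` attribute). With `sex` supplied, the
#' sex-adjusted residual correlation and per-sex correlations are added.
#'
#' @param matrix a `concentration_matrix` or numeric matrix.
#' @param phenotypes data.frame with a `sample_id` column and numeric test
#'   columns.
#' @param method `"spearman"` (default, robust to monotone nonlinearity) or
#'   `"pearson"`.
#' @param sex optional named character vector (`"F"`/`"M"`) keyed by sample
#'   id.
#' @return A data.frame with `protein_id`, `test`, `method`, `n`, `r`, and
#'   (when `sex` is given) `sex_adjusted_r`, `r_female`, `r_male`; rankable
#'   by `|r|`.
#' @export
correlate_all <- function(matrix, phenotypes,
                          method = c("spearman", "pearson"), sex = NULL) {
  method <- match.arg(method)
  v <- if (inherits(matrix, "concentration_matrix")) matrix$values else matrix
  stopifnot("sample_id" %in% names(phenotypes))
  common <- intersect(rownames(v), phenotypes$sample_id)
  if (length(common) < 3) stop("fewer than 3 annotated samples in common")
  v <- v[common, , drop = FALSE]
  ph <- phenotypes[match(common, phenotypes$sample_id), ]
  tests <- names(ph)[vapply(ph, is.numeric, logical(1))]
  rows <- list()
  n_skipped <- 0
  for (p in colnames(v)) {
    for (te in tests) {
      ok <- complete.cases(v[, p], ph[[te]])
      if (sum(ok) < 3) {
        n_skipped <- n_skipped + 1
        next
      }
      r <- suppressWarnings(cor(v[ok, p], ph[[te]][ok], method = method))
      row <- data.frame(protein_id = p, test = te, method = method,
                        n = sum(ok), r = r, stringsAsFactors = FALSE)
      if (!is.null(sex)) {
        adj <- suppressWarnings(
          sex_adjusted_correlation(v[ok, p], ph[[te]][ok],
                                   sex[common][ok], method = method))
        row$sex_adjusted_r <- adj$r_resid
        row$r_female <- adj$r_by_sex[["F"]]
        row$r_male <- adj$r_by_sex[["M"]]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), test = character(0),
                      method = character(0), n = integer(0), r = numeric(0),
                      stringsAsFactors = FALSE)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Sex-adjusted residual correlation
#'
#' Removes the per-sex mean from both variables (equivalent to regressing
#' each on a sex indicator and keeping the residuals) and correlates the
#' residuals; per-sex stratified correlations are reported as well. With
#' only one sex present the unadjusted correlation is returned with a
#' warning. Variables constant within each sex leave no residual variance,
#' so the residual correlation is undefined (`NA`, with a warning).
#'
#' @param x,y numeric vectors (e.g. a protein and a clinical test).
#' @param sex character vector of `"F"`/`"M"` aligned with `x`/`y`.
#' @param method `"spearman"` or `"pearson"`.
#' @return A list with `r_resid`, `r_by_sex` (named numeric, `F` and `M`),
#'   and `adjusted` (FALSE when the fallback was taken).
#' @export
sex_adjusted_correlation <- function(x, y, sex,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y, sex)
  x <- x[ok]
  y <- y[ok]
  sex <- sex[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  present <- unique(sex)
  r_by_sex <- c("F" = NA_real_, "M" = NA_real_)
  for (s in intersect(c("F", "M"), present)) {
    i <- sex == s
    if (sum(i) >= 3 && sd(x[i]) > 0 && sd(y[i]) > 0) {
      r_by_sex[[s]] <- cor(x[i], y[i], method = method)
    }
  }
  if (length(present) < 2) {
    warning("only one sex present; returning unadjusted correlation")
    return(list(r_resid = cor(x, y, method = method), r_by_sex = r_by_sex,
                adjusted = FALSE))
  }
  center <- function(v) v - ave(v, sex)
  rx <- center(x)
  ry <- center(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("no within-sex variance; residual correlation undefined")
    return(list(r_resid = NA_real_, r_by_sex = r_by_sex, adjusted = TRUE))
  }
  list(r_resid = cor(rx, ry, method = method), r_by_sex = r_by_sex,
       adjusted = TRUE)
}
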