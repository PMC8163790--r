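## Two-group differential abundance and signature inference.
##
## Contrasts (sex dimorphism; knockout vs wild type) are tested per protein
## with the two-sided Mann-Whitney-Wilcoxon rank test, adjusted with
## Benjamini-Hochberg within the contrast, and summarized by the fold change
## of group means. A protein measured in one group but censored below the
## LLOQ in every sample of the other is reported with the "ablated"
## sentinel and is significant by absence -- the expected outcome for the
## knocked-out protein itself in a homozygous strain. LASSO picks the
## minimal discriminator set, PCA projects samples on the selected proteins,
## and a cross-validated logistic regression reports the C-statistic of the
## signature.

#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' Exact permutation p-value by full enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings when `n_a + n_b <= 12` (ties
#' handled by midranks; the exact null of U is symmetric about
#' `n_a * n_b / 2`, so the two-sided p is the tail probability of
#' `|U - n_a n_b / 2|`). Larger samples use the normal approximation with
#' midrank tie correction and continuity correction. When all values across
#' both groups are identical the p-value is 1.
#'
#' @param a,b numeric vectors, each with at least 2 non-missing values.
#' @return A list with `u` (the U statistic of group `a`) and `p`
#'   (two-sided).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 by exact enumeration
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n_a <- length(a)
  n_b <- length(b)
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 values")
  values <- c(a, b)
  r <- rank(values)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mid <- n_a * n_b / 2
  if (length(unique(values)) == 1) {
    return(list(u = u_obs, p = 1))
  }
  n <- n_a + n_b
  if (n <= 12) {
    labelings <- combn(n, n_a)
    u_all <- colSums(base::matrix(r[labelings], nrow = n_a)) -
      n_a * (n_a + 1) / 2
    p <- mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
  } else {
    ties <- table(values)
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mid - sign(u_obs - mid) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(u = u_obs, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: sort ascending, `q_i = p_i * m / i`,
#' enforce monotonicity from the largest rank down, cap at 1, return in
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Fold change of group means
#'
#' `fc = mean(b) / mean(a)`; when exactly one mean is zero the protein is
#' reported with the `"ablated"` sentinel (detected in one group, absent in
#' the other) and an infinite signed log fold change; both means zero is
#' undefined.
#'
#' @param a,b numeric vectors.
#' @param log_base base of the log fold change (default 2).
#' @return A list with `mean_a`, `mean_b`, `fc`, `log_fc`, and `sentinel`
#'   (`NA`, `"ablated"`, or `"undefined"`).
#' @export
fold_change <- function(a, b, log_base = 2) {
  mean_a <- mean(a, na.rm = TRUE)
  mean_b <- mean(b, na.rm = TRUE)
  if (is.nan(mean_a) || is.nan(mean_b)) stop("means are not computable")
  if (mean_a == 0 && mean_b == 0) {
    return(list(mean_a = mean_a, mean_b = mean_b, fc = NA_real_,
                log_fc = NA_real_, sentinel = "undefined"))
  }
  if (mean_a == 0 || mean_b == 0) {
    return(list(mean_a = mean_a, mean_b = mean_b,
                fc = if (mean_a == 0) Inf else 0,
                log_fc = if (mean_a == 0) Inf else -Inf,
                sentinel = "ablated"))
  }
  fc <- mean_b / mean_a
  list(mean_a = mean_a, mean_b = mean_b, fc = fc,
       log_fc = log(fc, base = log_base), sentinel = NA_character_)
}

#' Define a two-group contrast
#'
#' @param name contrast label.
#' @param group_a,group_b disjoint sample-id vectors, each of size >= 2.
#'   Convention: `group_a` is the reference (wild type; females), so
#'   positive log fold changes mean higher abundance in `group_b`.
#' @param p_threshold,fold_threshold,use_adjusted_p significance rule:
#'   (adjusted or raw) p below `p_threshold` and `|log2FC| >=
#'   log2(fold_threshold)` (or the ablation sentinel).
#' @return A `contrast` object.
#' @export
contrast <- function(name, group_a, group_b, p_threshold = 0.05,
                     fold_threshold = 2, use_adjusted_p = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            length(intersect(group_a, group_b)) == 0)
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 p_threshold = p_threshold, fold_threshold = fold_threshold,
                 use_adjusted_p = use_adjusted_p), class = "contrast")
}

#' Sex contrast (females vs males) from annotations
#'
#' @param annotations sample annotations.
#' @param config a [proteotype_config()]; supplies the sex thresholds
#'   (default raw p < 0.01, fold 2).
#' @return A `contrast` with `group_a` = females, `group_b` = males.
#' @export
sex_contrast <- function(annotations, config = proteotype_config()) {
  contrast("sex",
           annotations$sample_id[annotations$sex == "F"],
           annotations$sample_id[annotations$sex == "M"],
           p_threshold = config$sex_p_threshold,
           fold_threshold = config$sex_fold_threshold,
           use_adjusted_p = config$sex_use_adjusted_p)
}

#' Knockout-vs-control contrast for one strain
#'
#' Both sexes of the strain (n = 6 under the study design) against all
#' wild-type controls (n = 38): with only 3 mice per strain and sex the
#' minimum exact two-sided rank p is 0.1, so per-sex knockout contrasts
#' cannot reach p < 0.05 and the pooled-sexes comparison against the full
#' control group is the default.
#'
#' @param annotations sample annotations.
#' @param strain strain name.
#' @param config a [proteotype_config()]; supplies the knockout thresholds
#'   (default BH-adjusted p < 0.05, fold 2).
#' @param sex optional `"F"` or `"M"` to restrict both groups to one sex.
#' @return A `contrast` with `group_a` = wild type, `group_b` = knockout.
#' @export
strain_contrast <- function(annotations, strain,
                            config = proteotype_config(), sex = NULL) {
  ann <- annotations
  if (!is.null(sex)) ann <- ann[ann$sex == sex, ]
  ko <- ann$sample_id[ann$strain == strain]
  wt <- ann$sample_id[ann$strain == "WT"]
  if (length(ko) == 0) stop("unknown strain '", strain, "'")
  contrast(paste0("strain:", strain), wt, ko,
           p_threshold = config$ko_p_threshold,
           fold_threshold = config$ko_fold_threshold,
           use_adjusted_p = config$ko_use_adjusted_p)
}

#' Run a two-group differential contrast
#'
#' Per protein: Mann-Whitney-Wilcoxon p, BH adjustment across the proteins
#' tested in this contrast, fold change of means. Significance requires the
#' p-value rule and the fold rule together, or the ablation sentinel: a
#' protein whose non-missing values are all below the LLOQ in one group
#' while at least half the other group is in range is significant by
#' absence. Proteins missing in more than half of either group are excluded
#' and listed in the `excluded` attribute.
#'
#' @param matrix a `concentration_matrix`.
#' @param contrast a [contrast()].
#' @param config a [proteotype_config()].
#' @return A data.frame with one row per tested protein: `protein_id`,
#'   `u_statistic`, `p_raw`, `p_adjusted`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2_fc`, `sentinel`, `significant`.
#' @export
run_contrast <- function(matrix, contrast, config = proteotype_config()) {
  stopifnot(inherits(matrix, "concentration_matrix"),
            inherits(contrast, "contrast"))
  ids_a <- intersect(contrast$group_a, rownames(matrix$values))
  ids_b <- intersect(contrast$group_b, rownames(matrix$values))
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("contrast groups not resolvable in the matrix")
  }
  proteins <- colnames(matrix$values)
  rows <- vector("list", length(proteins))
  excluded <- character(0)
  for (j in seq_along(proteins)) {
    p <- proteins[j]
    va <- matrix$values[ids_a, p]
    vb <- matrix$values[ids_b, p]
    fa <- matrix$flags[ids_a, p]
    fb <- matrix$flags[ids_b, p]
    if (sum(!is.na(va)) < length(ids_a) / 2 ||
        sum(!is.na(vb)) < length(ids_b) / 2 ||
        sum(!is.na(va)) < 2 || sum(!is.na(vb)) < 2) {
      excluded <- c(excluded, p)
      next
    }
    mw <- mann_whitney(va, vb)
    fc <- fold_change(va, vb, log_base = config$log_base)

    ## absence in one group: all measured values censored below LLOQ there,
    ## while the other group is mostly quantified
    absent_b <- all(fb[!is.na(vb)] == "below_lloq") &&
      mean(fa[!is.na(va)] == "in_range") >= 0.5
    absent_a <- all(fa[!is.na(va)] == "below_lloq") &&
      mean(fb[!is.na(vb)] == "in_range") >= 0.5
    sentinel <- fc$sentinel
    log_fc <- fc$log_fc
    if (is.na(sentinel) && (absent_a || absent_b)) {
      sentinel <- "ablated"
      log_fc <- if (absent_b) -Inf else Inf
    }
    rows[[j]] <- data.frame(
      protein_id = p, u_statistic = mw$u, p_raw = mw$p,
      p_adjusted = NA_real_, mean_a = fc$mean_a, mean_b = fc$mean_b,
      fold_change = fc$fc, log2_fc = log_fc, sentinel = sentinel,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), u_statistic = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      fold_change = numeric(0), log2_fc = numeric(0),
                      sentinel = character(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    attr(out, "contrast") <- contrast$name
    return(out)
  }
  out$p_adjusted <- benjamini_hochberg(out$p_raw)
  p_eff <- if (contrast$use_adjusted_p) out$p_adjusted else out$p_raw
  fold_ok <- !is.na(out$log2_fc) &
    abs(out$log2_fc) >= log2(contrast$fold_threshold)
  ablated <- out$sentinel %in% "ablated"
  out$significant <- ablated |
    (p_eff < contrast$p_threshold & fold_ok)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "contrast") <- contrast$name
  out
}

#' Welch two-sample t-test (parametric comparator)
#'
#' Reported alongside the rank test for comparison only; the rank test is
#' the primary inference. Degenerate zero-variance input is guarded: equal
#' means give `t = 0, p = 1`; a nonzero mean difference with zero pooled
#' variance gives `p = 0` with an infinite t.
#'
#' @param a,b numeric vectors, each with at least 2 non-missing values.
#' @return A list with `t`, `df`, and two-sided `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  d <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (d == 0) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(d) * Inf, df = NA_real_, p = 0))
  }
  t <- d / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' LASSO selection of discriminating proteins
#'
#' L1-penalized logistic regression on log10-transformed, standardized
#' concentrations; the penalty is chosen by leave-one-out cross-validated
#' binomial deviance over a descending penalty grid, and the selected
#' proteins are those with nonzero coefficients at that penalty. An empty
#' selection is a legal outcome (some knockouts have no plasma
#' discriminators). Zeros in the concentrations are shifted by half the
#' smallest positive value of the protein before the log.
#'
#' @param matrix a `concentration_matrix` or numeric matrix restricted to
#'   the contrast samples (>= 4 samples).
#' @param labels two-level factor/vector aligned with the rows.
#' @param seed integer seed (the leave-one-out fold assignment is itself
#'   deterministic; the seed covers any residual randomness).
#' @return Character vector of selected protein ids (possibly empty).
#' @export
lasso_select <- function(matrix, labels, seed = 1) {
  v <- if (inherits(matrix, "concentration_matrix")) matrix$values else matrix
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  if (nrow(v) < 4) stop("LASSO selection needs at least 4 samples")
  stopifnot(nrow(v) == length(y))
  x <- log10_shifted(v)
  x <- x[, apply(x, 2, function(col) sd(col) > 0), drop = FALSE]
  if (ncol(x) == 0) return(character(0))
  x <- scale(x)
  set.seed(seed)
  if (ncol(x) == 1) {
    ## glmnet needs >= 2 columns; a single candidate is kept iff it
    ## separates better than the null model under LOO deviance
    keep <- tryCatch({
      fit <- glm(y ~ x, family = binomial())
      summary(fit)$coefficients[2, 4] < 0.05
    }, warning = function(w) TRUE, error = function(e) FALSE)
    return(if (keep) colnames(x) else character(0))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = FALSE, nfolds = nrow(x),
                          foldid = seq_len(nrow(x)),
                          type.measure = "deviance", grouped = FALSE)
  beta <- coef(cv, s = "lambda.min")[-1, 1]
  names(beta)[beta != 0]
}

## log10 with a per-column pseudo-shift for zeros (half the smallest
## positive value; columns that are entirely zero use 1).
log10_shifted <- function(v) {
  apply(v, 2, function(col) {
    pos <- col[!is.na(col) & col > 0]
    shift <- if (length(pos) > 0) min(pos) / 2 else 1
    log10(ifelse(!is.na(col) & col <= 0, shift, col))
  })
}

#' PCA projection of samples
#'
#' Concentrations are log10-transformed, missing cells mean-imputed after
#' the transform, constant proteins dropped with a warning, and each
#' protein centered and scaled to unit variance before singular value
#' decomposition.
#'
#' @param matrix a `concentration_matrix` or numeric matrix (>= 3 samples,
#'   >= 2 proteins).
#' @param n_components number of components to return (default 2).
#' @return A list with `scores` (samples x components), `variance_fraction`
#'   per returned component, and `loadings`.
#' @export
pca_project <- function(matrix, n_components = 2) {
  v <- if (inherits(matrix, "concentration_matrix")) matrix$values else matrix
  if (nrow(v) < 3 || ncol(v) < 2) {
    stop("PCA needs at least 3 samples and 2 proteins")
  }
  x <- log10_shifted(v)
  x <- apply(x, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  keep <- apply(x, 2, function(col) sd(col) > 0)
  if (any(!keep)) {
    warning("dropping constant protein(s): ",
            paste(head(colnames(x)[!keep], 5), collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 non-constant proteins")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_fraction = var_frac[seq_len(k)],
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Cross-validated logistic-regression C-statistic
#'
#' Stratified k-fold cross-validation of a ridge-stabilized (penalty 1e-6)
#' logistic regression on standardized log10 concentrations; the
#' C-statistic (area under the ROC curve) of the held-out scores is
#' computed per fold and averaged. Standardization parameters come from the
#' training part of each fold only.
#'
#' @param matrix a `concentration_matrix` or numeric matrix restricted to
#'   the signature proteins.
#' @param labels two-level factor/vector aligned with the rows.
#' @param k number of folds (default 5; must not exceed the minor class
#'   size).
#' @param seed integer seed for the fold assignment.
#' @return A list with `per_fold` C-statistics, `mean_cstat`, `k`, and
#'   `features`.
#' @export
cv_logistic_cstat <- function(matrix, labels, k = 5, seed = 1) {
  v <- if (inherits(matrix, "concentration_matrix")) matrix$values else matrix
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  if (k > min(table(y))) {
    stop("k exceeds the size of the smaller class")
  }
  x <- log10_shifted(v)
  x <- apply(x, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  per_fold <- vapply(seq_len(k), function(f) {
    train <- fold != f
    test <- !train
    mu <- colMeans(x[train, , drop = FALSE])
    sdv <- apply(x[train, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    xt <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    scores <- if (ncol(x) >= 2) {
      fit <- glmnet::glmnet(xt[train, , drop = FALSE], y[train],
                            family = "binomial", alpha = 0,
                            lambda = 1e-6, standardize = FALSE)
      as.numeric(predict(fit, xt[test, , drop = FALSE]))
    } else {
      fit <- suppressWarnings(
        glm(y ~ ., data = data.frame(y = y[train],
                                     xt[train, , drop = FALSE])),
        classes = "warning")
      as.numeric(predict(fit, data.frame(xt[test, , drop = FALSE])))
    }
    roc_auc(scores, y[test] == levels(y)[2])
  }, numeric(1))
  list(per_fold = per_fold, mean_cstat = mean(per_fold), k = k,
       features = colnames(v))
}

## Rank-based AUC (probability that a positive outscores a negative, ties
## counted half).
roc_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Volcano-plot data table
#'
#' @param results output of [run_contrast()].
#' @return A data.frame with `protein_id`, `log2_fc`, `neg_log10_p`,
#'   `significant` (infinite fold changes from ablation are passed
#'   through).
#' @export
volcano_data <- function(results) {
  data.frame(protein_id = results$protein_id, log2_fc = results$log2_fc,
             neg_log10_p = -log10(results$p_raw),
             significant = results$significant, stringsAsFactors = FALSE)
}
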