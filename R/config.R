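#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the conventions of internal-standard MRM studies: `1/x^2` calibration
#' weighting, a protein is quantifiable when at least 5% of its measurements
#' fall inside the assay range, contamination clustering at `|r| >= 0.8`, sex
#' contrasts at raw p < 0.01 and twofold change, knockout contrasts at
#' BH-adjusted p < 0.05 and twofold change.
#'
#' @param weighting_exponent exponent w of the calibration weights
#'   `1/x^w` (default 2).
#' @param min_quantifiable_fraction minimum fraction of all measurements of a
#'   protein that must be in range for it to count as quantifiable (0.05).
#' @param correlation_threshold minimum absolute Pearson correlation used for
#'   contamination clustering and panel extension (0.8).
#' @param sex_p_threshold,sex_fold_threshold,sex_use_adjusted_p significance
#'   thresholds for the sex contrast: p < 0.01 (raw by default) and fold
#'   change >= 2.
#' @param ko_p_threshold,ko_fold_threshold,ko_use_adjusted_p significance
#'   thresholds for knockout-vs-control contrasts: BH-adjusted p < 0.05 and
#'   fold change >= 2.
#' @param co_trend_fraction fraction of other panel members that must co-trend
#'   for a differential panel protein to be called contaminant-originated
#'   (0.5).
#' @param co_trend_min_lfc minimum same-sign |log2 fold change| that counts as
#'   co-trending (0.5).
#' @param log_base base of the reported log fold change (2).
#' @param cv_folds folds of the cross-validated classifier (5).
#' @param seed integer seed used by stochastic stages.
#'
#' @return An object of class `proteotype_config` (a validated named list).
#' @seealso [write_config()], [read_config()]
#' @export
#' @examples
#' cfg <- proteotype_config(sex_p_threshold = 0.05)
#' cfg$sex_p_threshold
proteotype_config <- function(weighting_exponent = 2,
                              min_quantifiable_fraction = 0.05,
                              correlation_threshold = 0.8,
                              sex_p_threshold = 0.01,
                              sex_fold_threshold = 2,
                              sex_use_adjusted_p = FALSE,
                              ko_p_threshold = 0.05,
                              ko_fold_threshold = 2,
                              ko_use_adjusted_p = TRUE,
                              co_trend_fraction = 0.5,
                              co_trend_min_lfc = 0.5,
                              log_base = 2,
                              cv_folds = 5,
                              seed = 1) {
  cfg <- list(
    weighting_exponent = as.numeric(weighting_exponent),
    min_quantifiable_fraction = as.numeric(min_quantifiable_fraction),
    correlation_threshold = as.numeric(correlation_threshold),
    sex_p_threshold = as.numeric(sex_p_threshold),
    sex_fold_threshold = as.numeric(sex_fold_threshold),
    sex_use_adjusted_p = isTRUE(as.logical(sex_use_adjusted_p)),
    ko_p_threshold = as.numeric(ko_p_threshold),
    ko_fold_threshold = as.numeric(ko_fold_threshold),
    ko_use_adjusted_p = isTRUE(as.logical(ko_use_adjusted_p)),
    co_trend_fraction = as.numeric(co_trend_fraction),
    co_trend_min_lfc = as.numeric(co_trend_min_lfc),
    log_base = as.numeric(log_base),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$weighting_exponent >= 0,
    cfg$min_quantifiable_fraction >= 0, cfg$min_quantifiable_fraction <= 1,
    cfg$correlation_threshold >= 0, cfg$correlation_threshold <= 1,
    cfg$sex_p_threshold > 0, cfg$sex_p_threshold <= 1,
    cfg$ko_p_threshold > 0, cfg$ko_p_threshold <= 1,
    cfg$sex_fold_threshold >= 1, cfg$ko_fold_threshold >= 1,
    cfg$co_trend_fraction >= 0, cfg$co_trend_fraction <= 1,
    cfg$co_trend_min_lfc >= 0,
    cfg$log_base > 1,
    cfg$cv_folds >= 2,
    !is.na(cfg$seed)
  )
  class(cfg) <- "proteotype_config"
  cfg
}

#' Serialize / parse a pipeline configuration
#'
#' The on-disk format is flat YAML. `read_config(write_config(cfg, path))`
#' is the identity for every valid configuration (types are re-normalized by
#' the [proteotype_config()] constructor on read).
#'
#' @param config a `proteotype_config` object.
#' @param path file path.
#' @return `read_config` returns a `proteotype_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "proteotype_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(proteotype_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  }
  do.call(proteotype_config, raw)
}

#' @export
print.proteotype_config <- function(x, ...) {
  cat("proteotype_config:\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}
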