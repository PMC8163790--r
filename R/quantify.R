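## Calibration-curve fitting and back-calculation.
##
## Absolute quantification follows the internal-standard convention: the
## endogenous (light) to heavy peak-area ratio is regressed on the nominal
## concentration of external calibration standards with 1/x^2 weighting, and
## endogenous concentrations are back-calculated by inverting the fitted
## line. The heavy standard is spiked at 100x the assay LLOQ, so ratios stay
## of order one across the assay range.

#' Fit a weighted linear calibration curve
#'
#' Minimizes `sum(w_i * (y_i - a*x_i - b)^2)` with `w_i = 1/x_i^exponent`
#' (default exponent 2, the standard weighting for MRM curves whose variance
#' grows with concentration; exponent 0 is ordinary least squares). The fit
#' is linear: with a heavy internal standard and a clean matrix, the
#' ratio-to-concentration response is linear across the 1-1000x LLOQ range.
#'
#' @param points data.frame with columns `nominal_conc` (x, fmol/uL, > 0)
#'   and `ratio` (y, light/heavy).
#' @param weighting_exponent non-negative weighting exponent (default 2).
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `weighting_exponent`, `r_squared` (weighted), `n_points`, `accepted`
#'   (FALSE with a warning when the slope is not positive), and `lloq`/
#'   `uloq` slots filled in by [fit_calibration_curves()].
#' @export
#' @examples
#' pts <- data.frame(nominal_conc = c(1, 10, 100), ratio = c(2, 20, 200))
#' fit_calibration(pts)$slope
fit_calibration <- function(points, weighting_exponent = 2) {
  stopifnot(is.data.frame(points),
            all(c("nominal_conc", "ratio") %in% names(points)),
            weighting_exponent >= 0)
  x <- points$nominal_conc
  y <- points$ratio
  if (length(x) < 2) stop("calibration requires at least 2 points")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("calibration concentrations must be positive")
  }
  if (length(unique(x)) < 2) {
    stop("degenerate calibration design: all concentrations identical")
  }
  w <- 1 / x ^ weighting_exponent
  fit <- lm(y ~ x, weights = w)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ybar_w <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - ybar_w)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * fit$residuals^2) / ss_tot else 1
  accepted <- slope > 0
  if (!accepted) {
    warning("calibration curve rejected: slope is not positive")
  }
  structure(list(protein_id = NA_character_, slope = slope,
                 intercept = intercept,
                 weighting_exponent = weighting_exponent,
                 r_squared = r2, n_points = length(x),
                 lloq = NA_real_, uloq = NA_real_, accepted = accepted),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve%s: ratio = %.6g * conc + %.6g (1/x^%g, R2w = %.4f, n = %d)%s\n",
    if (is.na(x$protein_id)) "" else paste0(" [", x$protein_id, "]"),
    x$slope, x$intercept, x$weighting_exponent, x$r_squared, x$n_points,
    if (x$accepted) "" else " [REJECTED]"))
  invisible(x)
}

#' Fit calibration curves for every assayed protein
#'
#' Curves are fitted once from the calibration-standard rows (which sit on
#' the first plate) and applied to all plates; plate-to-plate differences
#' are handled later by pooled-reference normalization.
#'
#' @param transitions transition records (see [read_transition_table()]).
#' @param assays assay definitions (LLOQ/ULOQ bounds are copied onto each
#'   curve).
#' @param weighting_exponent weighting exponent, default 2.
#' @return A named list of `calibration_curve` objects, one per protein with
#'   calibration rows.
#' @export
fit_calibration_curves <- function(transitions, assays,
                                   weighting_exponent = 2) {
  cal <- transitions[transitions$role == "calibration_standard", ]
  if (nrow(cal) == 0) stop("no calibration_standard rows found")
  curves <- lapply(split(cal, cal$protein_id), function(d) {
    crv <- fit_calibration(
      data.frame(nominal_conc = d$nominal_conc,
                 ratio = d$light_area / d$heavy_area),
      weighting_exponent)
    crv$protein_id <- d$protein_id[1]
    i <- match(d$protein_id[1], assays$protein_id)
    crv$lloq <- assays$lloq[i]
    crv$uloq <- assays$uloq[i]
    crv
  })
  curves[assays$protein_id[assays$protein_id %in% names(curves)]]
}

#' Back-calculate concentrations from light/heavy ratios
#'
#' Inverts the calibration line: `conc = (ratio - intercept) / slope`.
#' Negative back-calculations are clamped to 0 (concentrations are physical
#' quantities) and flagged `below_lloq`. Range flags are inclusive at both
#' limits: a value equal to the LLOQ or ULOQ is `in_range`.
#'
#' @param ratio numeric vector of light/heavy ratios.
#' @param curve an accepted `calibration_curve` with `lloq`/`uloq` set.
#' @return A data.frame with columns `conc` (fmol/uL) and `flag`.
#' @export
back_calculate <- function(ratio, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!isTRUE(curve$accepted) || curve$slope <= 0) {
    stop("refusing to back-calculate from a rejected curve (slope <= 0)")
  }
  conc <- (ratio - curve$intercept) / curve$slope
  flag <- rep("in_range", length(conc))
  flag[conc < curve$lloq] <- "below_lloq"
  flag[conc > curve$uloq] <- "above_uloq"
  below0 <- conc < 0
  conc[below0] <- 0
  flag[below0] <- "below_lloq"
  flag[is.na(conc)] <- "missing"
  data.frame(conc = conc, flag = flag, stringsAsFactors = FALSE)
}

#' Quantify a dataset against fitted calibration curves
#'
#' Back-calculates every study and pooled-reference record and assembles
#' sample x protein concentration matrices, plus a QC summary computed from
#' the pooled references (mean concentration and CV per protein over
#' in-range pooled measurements, the study's precision metric).
#'
#' @param transitions transition records.
#' @param curves named list of curves from [fit_calibration_curves()].
#' @param assays assay definitions.
#' @return A list with `study` and `pooled` (`concentration_matrix`
#'   objects), `plate_map` (named character vector sample -> plate for both),
#'   and `qc` (data.frame `protein_id`, `n_pooled`, `n_in_range`,
#'   `mean_conc`, `cv_percent`).
#' @export
quantify_dataset <- function(transitions, curves, assays) {
  keep <- transitions$role %in% c("study", "pooled_reference")
  tr <- transitions[keep, ]
  proteins <- assays$protein_id[assays$protein_id %in% names(curves)]
  missing_curves <- setdiff(unique(tr$protein_id), proteins)
  if (length(missing_curves) > 0) {
    warning("no calibration curve for protein(s): ",
            paste(head(missing_curves, 5), collapse = ", "),
            if (length(missing_curves) > 5) ", ..." else "",
            "; their cells are reported missing")
  }

  build <- function(role) {
    d <- tr[tr$role == role, ]
    samples <- unique(d$sample_id)
    v <- base::matrix(NA_real_, length(samples), length(proteins),
                      dimnames = list(samples, proteins))
    f <- base::matrix("missing", length(samples), length(proteins),
                      dimnames = list(samples, proteins))
    for (p in proteins) {
      dp <- d[d$protein_id == p, ]
      if (nrow(dp) == 0) next
      bc <- back_calculate(dp$light_area / dp$heavy_area, curves[[p]])
      v[dp$sample_id, p] <- bc$conc
      f[dp$sample_id, p] <- bc$flag
    }
    concentration_matrix(v, f)
  }
  study <- build("study")
  pooled <- build("pooled_reference")

  empty <- colnames(study$values)[colSums(!is.na(study$values)) == 0]
  if (length(empty) > 0) {
    warning("protein(s) with no study measurements: ",
            paste(head(empty, 5), collapse = ", "))
  }

  qc <- do.call(rbind, lapply(colnames(pooled$values), function(p) {
    ok <- pooled$flags[, p] == "in_range"
    vals <- pooled$values[ok, p]
    data.frame(protein_id = p, n_pooled = sum(!is.na(pooled$values[, p])),
               n_in_range = length(vals),
               mean_conc = if (length(vals) > 0) mean(vals) else NA_real_,
               cv_percent = if (length(vals) >= 2) compute_cv(vals)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL

  plate_map <- c(setNames(tr$plate_id[tr$role == "study"],
                          tr$sample_id[tr$role == "study"]),
                 setNames(tr$plate_id[tr$role == "pooled_reference"],
                          tr$sample_id[tr$role == "pooled_reference"]))
  plate_map <- plate_map[!duplicated(names(plate_map))]

  list(study = study, pooled = pooled, plate_map = plate_map, qc = qc)
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` with the n-1 sample standard deviation. Undefined
#' (returned as `NA` with a warning) when the mean is zero.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return CV in percent.
#' @export
#' @examples
#' compute_cv(c(9, 10, 11))  # 10
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) {
    warning("CV undefined: mean is zero")
    return(NA_real_)
  }
  100 * sd(values) / m
}
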