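## Domain containers and file readers/writers.
##
## The transition table is a frozen, simplified dialect of an integrated
## peak-area export: one row per sample x peptide with light and heavy peak
## areas. The pipeline's contract deliberately starts at integrated areas;
## chromatogram processing and peak integration are upstream of it.

CENSOR_LEVELS <- c("in_range", "below_lloq", "above_uloq", "missing")
ROLE_LEVELS <- c("study", "pooled_reference", "calibration_standard", "curve_qc")

TRANSITION_COLUMNS <- c("sample_id", "protein_id", "peptide_id", "light_area",
                        "heavy_area", "plate_id", "role", "nominal_conc")

#' Construct a concentration matrix
#'
#' The central container of the pipeline: a samples x proteins grid of
#' back-calculated concentrations (fmol/uL) with a congruent grid of censor
#' flags. Values outside the assay range are retained (never imputed or
#' dropped); the flag records the range status. A missing value is a missing
#' cell, encoded `NA` with flag `"missing"` -- zero is a legal concentration
#' distinct from missing.
#'
#' @param values numeric matrix (samples in rows, proteins in columns), with
#'   dimnames; non-negative or `NA`.
#' @param flags character matrix of the same shape with entries in
#'   `"in_range"`, `"below_lloq"`, `"above_uloq"`, `"missing"`.
#' @return An object of class `concentration_matrix` with components
#'   `values` and `flags`.
#' @export
#' @examples
#' v <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("pA", "pB")))
#' f <- matrix("in_range", 2, 2, dimnames = dimnames(v))
#' concentration_matrix(v, f)
concentration_matrix <- function(values, flags) {
  stopifnot(is.matrix(values), is.numeric(values), is.matrix(flags),
            identical(dim(values), dim(flags)))
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("concentration matrix requires sample and protein dimnames")
  }
  dimnames(flags) <- dimnames(values)
  bad <- setdiff(unique(as.vector(flags)), CENSOR_LEVELS)
  if (length(bad) > 0) {
    stop("invalid censor flag(s): ", paste(bad, collapse = ", "))
  }
  if (!identical(unname(is.na(values)), unname(flags == "missing"))) {
    stop("value is missing if and only if its flag is 'missing'")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  structure(list(values = values, flags = flags),
            class = "concentration_matrix")
}

#' @export
dim.concentration_matrix <- function(x) dim(x$values)

#' @export
dimnames.concentration_matrix <- function(x) dimnames(x$values)

#' @export
`[.concentration_matrix` <- function(x, i, j, ...) {
  concentration_matrix(x$values[i, j, drop = FALSE],
                       x$flags[i, j, drop = FALSE])
}

#' @export
print.concentration_matrix <- function(x, ...) {
  d <- dim(x$values)
  tab <- table(factor(x$flags, levels = CENSOR_LEVELS))
  cat(sprintf("concentration_matrix: %d samples x %d proteins (fmol/uL)\n",
              d[1], d[2]))
  cat("  flags:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a concentration matrix
#'
#' The on-disk format is a single CSV with a `#`-prefixed header line, a
#' `sample_id` column, one value column per protein, and a parallel block of
#' flag columns named `flag:<protein_id>`. Values are printed with 15
#' significant digits so that write-then-read is the identity on values,
#' flags, and row/column order.
#'
#' @param matrix a `concentration_matrix`.
#' @param path file path.
#' @return `read_concentration_matrix` returns a `concentration_matrix`;
#'   `write_concentration_matrix` returns `path` invisibly.
#' @export
write_concentration_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "concentration_matrix"))
  v <- matrix$values
  sample_id <- if (is.null(rownames(v))) character(0) else rownames(v)
  df <- data.frame(sample_id = sample_id, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (p in colnames(v)) df[[p]] <- sprintf("%.15g", v[, p])
  for (p in colnames(v)) df[[paste0("flag:", p)]] <- matrix$flags[, p]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# proteotypeR concentration_matrix v1; fmol/uL; ",
                    "flag:<protein> columns carry censor flags ",
                    "(in_range/below_lloq/above_uloq/missing); ",
                    "missing values written as NA"), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentration_matrix
#' @export
read_concentration_matrix <- function(path) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE,
                 colClasses = "character")
  if (!"sample_id" %in% names(df)) {
    stop("format error: missing column 'sample_id'")
  }
  cols <- setdiff(names(df), "sample_id")
  flag_cols <- grep("^flag:", cols, value = TRUE)
  value_cols <- setdiff(cols, flag_cols)
  if (!setequal(paste0("flag:", value_cols), flag_cols)) {
    stop("format error: value and flag column blocks do not match")
  }
  flag_cols <- paste0("flag:", value_cols)  # align order with values
  v <- sapply(df[value_cols], function(x) suppressWarnings(as.numeric(x)))
  f <- sapply(df[flag_cols], as.character)
  if (nrow(df) == 0) {
    v <- base::matrix(numeric(0), 0, length(value_cols))
    f <- base::matrix(character(0), 0, length(value_cols))
  }
  if (nrow(df) == 1) {
    v <- base::matrix(v, 1)
    f <- base::matrix(f, 1)
  }
  dimnames(v) <- list(df$sample_id, value_cols)
  dimnames(f) <- list(df$sample_id, value_cols)
  concentration_matrix(v, f)
}

#' Read assay definitions
#'
#' CSV with columns `protein_id`, `peptide_id`, `lloq`; optional
#' `heavy_spike` and `uloq` default to the study conventions of 100x and
#' 1000x the assay LLOQ (the heavy internal standard is spiked at 100x LLOQ
#' and the calibration curve spans 1 to 1000x LLOQ). One surrogate peptide
#' per protein; duplicated proteins are rejected.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `protein_id`, `peptide_id`, `lloq`,
#'   `heavy_spike`, `uloq`.
#' @export
read_assay_definitions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("protein_id", "peptide_id", "lloq")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("format error: missing column '", miss[1], "'")
  }
  if (anyDuplicated(df$protein_id)) {
    stop("validation error: multiple surrogate peptides for protein '",
         df$protein_id[duplicated(df$protein_id)][1],
         "'; one peptide per protein is required")
  }
  if (any(!is.finite(df$lloq)) || any(df$lloq <= 0)) {
    stop("validation error: lloq must be positive for all assays")
  }
  if (is.null(df$heavy_spike)) df$heavy_spike <- 100 * df$lloq
  if (is.null(df$uloq)) df$uloq <- 1000 * df$lloq
  if (any(!(df$lloq < df$heavy_spike & df$heavy_spike < df$uloq))) {
    stop("validation error: require lloq < heavy_spike < uloq")
  }
  df[c("protein_id", "peptide_id", "lloq", "heavy_spike", "uloq")]
}

#' Read a transition-level measurement table
#'
#' Tab-separated, one row per sample x peptide, with header columns
#' `sample_id`, `protein_id`, `peptide_id`, `light_area`, `heavy_area`,
#' `plate_id`, `role`, `nominal_conc`. `role` is one of `study`,
#' `pooled_reference`, `calibration_standard`, `curve_qc`; `nominal_conc`
#' (fmol/uL) is required exactly for calibration and curve-QC rows and empty
#' otherwise. Every (protein, peptide) pair must match the assay definitions.
#' Row order is preserved; malformed input is rejected with an error naming
#' the offending column or row.
#'
#' @param path TSV file path.
#' @param assay_definitions data.frame from [read_assay_definitions()].
#' @return A data.frame of validated transition records, in file order.
#' @export
read_transition_table <- function(path, assay_definitions) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                 colClasses = "character")
  miss <- setdiff(TRANSITION_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop("format error: missing column '", miss[1], "'")
  }
  df <- df[TRANSITION_COLUMNS]
  df$light_area <- suppressWarnings(as.numeric(df$light_area))
  df$heavy_area <- suppressWarnings(as.numeric(df$heavy_area))
  df$nominal_conc <- suppressWarnings(as.numeric(df$nominal_conc))
  validate_transitions(df, assay_definitions)
}

## Shared validation for transition records, whether read from file or
## simulated in memory.
validate_transitions <- function(df, assay_definitions) {
  bad_role <- which(!df$role %in% ROLE_LEVELS)
  if (length(bad_role) > 0) {
    stop("validation error: row ", bad_role[1], ": unknown role '",
         df$role[bad_role[1]], "'")
  }
  bad_heavy <- which(!is.finite(df$heavy_area) | df$heavy_area <= 0)
  if (length(bad_heavy) > 0) {
    stop("validation error: row ", bad_heavy[1],
         ": heavy_area must be positive")
  }
  bad_light <- which(!is.finite(df$light_area) | df$light_area < 0)
  if (length(bad_light) > 0) {
    stop("validation error: row ", bad_light[1],
         ": light_area must be a non-negative number")
  }
  needs_nominal <- df$role %in% c("calibration_standard", "curve_qc")
  bad_nom <- which(needs_nominal & !is.finite(df$nominal_conc))
  if (length(bad_nom) > 0) {
    stop("validation error: row ", bad_nom[1],
         ": nominal_conc is required for role '", df$role[bad_nom[1]], "'")
  }
  bad_extra <- which(!needs_nominal & is.finite(df$nominal_conc))
  if (length(bad_extra) > 0) {
    stop("validation error: row ", bad_extra[1],
         ": nominal_conc must be empty for role '", df$role[bad_extra[1]],
         "'")
  }
  key <- paste(df$protein_id, df$peptide_id)
  known <- paste(assay_definitions$protein_id, assay_definitions$peptide_id)
  bad_pep <- which(!key %in% known)
  if (length(bad_pep) > 0) {
    stop("validation error: row ", bad_pep[1], ": unknown assay peptide '",
         df$peptide_id[bad_pep[1]], "' for protein '",
         df$protein_id[bad_pep[1]], "'")
  }
  df
}

#' Write a transition table
#'
#' Emits the TSV dialect read back by [read_transition_table()].
#'
#' @param transitions data.frame of transition records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(transitions, path) {
  stopifnot(all(TRANSITION_COLUMNS %in% names(transitions)))
  out <- transitions[TRANSITION_COLUMNS]
  out$light_area <- sprintf("%.15g", out$light_area)
  out$heavy_area <- sprintf("%.15g", out$heavy_area)
  out$nominal_conc <- ifelse(is.na(out$nominal_conc), "",
                             sprintf("%.15g", out$nominal_conc))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample annotations
#'
#' CSV with columns `sample_id`, `strain` (`"WT"` for controls), `zygosity`
#' (`HOM`/`HET`/`WT`), `sex` (`F`/`M`), `plate_id`.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_sample_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("sample_id", "strain", "zygosity", "sex", "plate_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("format error: missing column '", miss[1], "'")
  if (anyDuplicated(df$sample_id)) {
    stop("validation error: duplicated sample_id '",
         df$sample_id[duplicated(df$sample_id)][1], "'")
  }
  bad <- which(!df$zygosity %in% c("HOM", "HET", "WT"))
  if (length(bad) > 0) {
    stop("validation error: row ", bad[1], ": zygosity must be HOM/HET/WT")
  }
  bad <- which(!df$sex %in% c("F", "M"))
  if (length(bad) > 0) {
    stop("validation error: row ", bad[1], ": sex must be F or M")
  }
  df[req]
}

#' Read contamination panel definitions
#'
#' Plain-text TSV with columns `protein_id` and `origin`
#' (`erythrocyte`/`platelet`/`user`). Returns one panel per origin.
#'
#' @param path TSV file path.
#' @return A named list of panels, each a list with `name`, `origin`, and
#'   `members` (character vector of protein ids).
#' @export
read_panels <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!all(c("protein_id", "origin") %in% names(df))) {
    stop("format error: panel file needs columns 'protein_id' and 'origin'")
  }
  bad <- which(!df$origin %in% c("erythrocyte", "platelet", "user"))
  if (length(bad) > 0) {
    stop("validation error: row ", bad[1], ": origin must be ",
         "erythrocyte/platelet/user")
  }
  panels <- lapply(split(df$protein_id, df$origin), unique)
  out <- lapply(names(panels), function(o) {
    list(name = o, origin = o, members = panels[[o]])
  })
  names(out) <- names(panels)
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line with tab-separated name, description, and
#' member ids. Duplicate members within a set are deduplicated; a line with
#' fewer than three fields, a duplicated set name, or a set left empty after
#' removing blank members is a format error reported with its line number.
#'
#' @param path GMT file path.
#' @return A named list of class `gene_set_collection`; each element is a
#'   list with `description` and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("format error: line ", i, ": expected at least 3 tab-separated ",
           "fields (name, description, members)")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop("format error: line ", i, ": gene set '", fields[1], "' is empty")
    }
    if (fields[1] %in% names(sets)) {
      stop("format error: line ", i, ": duplicated set name '", fields[1],
           "'")
    }
    sets[[fields[1]]] <- list(description = fields[2], members = members)
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x)))
  for (nm in head(names(x), 5)) {
    cat(sprintf("  %s (%d members)\n", nm, length(x[[nm]]$members)))
  }
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}
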