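## Synthetic-data generator.
##
## Emulates the structure of a plate-based MRM proteotyping study: knockout
## strains and wild-type controls of both sexes randomized over plates, a
## pooled reference plasma measured repeatedly on every plate, an 8-point
## external calibration curve on plate 1, and curve-QC standards on each
## plate. Every generated dataset carries a full ground-truth record so that
## downstream stages can be tested by parameter recovery.

ERYTHROCYTE_PANEL <- c("HBA", "HBB-B1", "HBZ", "CA1", "CA2", "BPGM",
                       "BLVRB", "PRDX2", "PRDX6", "SOD1", "CAT", "ALDOA")
PLATELET_PANEL <- c("PF4", "PPBP", "THBS1", "ITGA2B", "ITGB3", "VWF",
                    "SELP", "FLNA", "MYH9", "TLN1")

#' Study design for the synthetic dataset
#'
#' Defaults reproduce the shape of the emulated study: 30 knockout strains x
#' 2 sexes x 3 mice plus 19 wild-type controls per sex = 218 study samples on
#' 3 plates, 11 pooled references per plate (33 in total), 226 proteins, an
#' 8-point calibration curve spanning 1-1000x LLOQ on plate 1, and 3 curve-QC
#' standards per plate.
#'
#' @param n_strains number of knockout strains (30).
#' @param mice_per_strain_per_sex mice per strain per sex (3).
#' @param n_controls_per_sex wild-type controls per sex (19).
#' @param n_plates number of 96-well plates (3).
#' @param pooled_refs_per_plate pooled reference aliquots per plate, in
#'   9..12 (default 11).
#' @param n_proteins number of assayed proteins (226).
#' @param calibration_levels calibration standards as multiples of the assay
#'   LLOQ; 8 points spanning 1 to 1000.
#' @param qc_levels_per_plate curve-QC standards per plate, as LLOQ
#'   multiples.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_strains = 30,
                              mice_per_strain_per_sex = 3,
                              n_controls_per_sex = 19,
                              n_plates = 3,
                              pooled_refs_per_plate = 11,
                              n_proteins = 226,
                              calibration_levels = c(1, 2, 5, 10, 50, 100,
                                                     500, 1000),
                              qc_levels_per_plate = c(3, 30, 300)) {
  stopifnot(n_strains >= 1, mice_per_strain_per_sex >= 1,
            n_controls_per_sex >= 1, n_plates >= 1,
            pooled_refs_per_plate >= 9, pooled_refs_per_plate <= 12,
            n_proteins >= 2,
            length(calibration_levels) >= 2,
            min(calibration_levels) >= 1, max(calibration_levels) <= 1000)
  design <- list(n_strains = n_strains,
                 mice_per_strain_per_sex = mice_per_strain_per_sex,
                 n_controls_per_sex = n_controls_per_sex,
                 n_plates = n_plates,
                 pooled_refs_per_plate = pooled_refs_per_plate,
                 n_proteins = n_proteins,
                 calibration_levels = calibration_levels,
                 qc_levels_per_plate = qc_levels_per_plate)
  design$n_study_samples <- n_strains * 2 * mice_per_strain_per_sex +
    2 * n_controls_per_sex
  class(design) <- "simulation_design"
  design
}

#' Ground-truth configuration for the synthetic dataset
#'
#' Controls the generative model: baselines log-uniform over five orders of
#' magnitude, multiplicative log-normal measurement noise at a 9% CV,
#' per-protein-per-plate multiplicative bias with mean 1, a sparse additive
#' erythrocyte contamination component shared across the erythrocyte panel
#' (plus, by default, one extra non-panel protein that carries the same
#' loading, mirroring how an unexpected protein can co-vary with the panel),
#' an independent shared platelet component, per-protein sex effects, and
#' per-strain knockout effects including full ablation of the knocked-out
#' protein in homozygous strains.
#'
#' @param kappa measurement coefficient of variation (0.09).
#' @param biological_cv inter-individual coefficient of variation of the
#'   endogenous protein levels in study samples (0.2); pooled references
#'   measure one shared pool and carry none.
#' @param baseline_range range of baseline concentrations, fmol/uL
#'   (`c(0.3, 6e4)`).
#' @param lloq_margin_range baselines sit this factor above their assay LLOQ
#'   (log-uniform draw in `c(20, 800)`), keeping default measurements inside
#'   the 1-1000x LLOQ assay range.
#' @param plate_bias_sd log-sd of the multiplicative plate bias (0.05;
#'   0 disables it).
#' @param n_sex_affected number of sex-dimorphic proteins (20).
#' @param sex_lfc_range magnitude range of sex log2 effects (`c(1, 2)`),
#'   random sign, applied to males.
#' @param n_ko_affected_per_strain bystander proteins affected per strain
#'   (3), in addition to the strain's own target protein.
#' @param ko_lfc_range magnitude range of knockout log2 effects (`c(1, 2)`).
#' @param contamination_fraction fraction of study samples carrying
#'   erythrocyte contamination (0.25; platelet contamination is drawn
#'   independently at the same rate).
#' @param contamination_sdlog log-sd of the per-sample contamination level
#'   (1).
#' @param contamination_lambda panel-protein loading, as a multiple of the
#'   protein baseline (3).
#' @param n_contamination_extra non-panel proteins sharing the erythrocyte
#'   loading (1).
#' @param blank_fraction blank-level signal of ablated proteins, as a
#'   fraction of the LLOQ response (0.1).
#' @param heavy_area_meanlog,heavy_area_sdlog log-normal parameters of the
#'   heavy peak area.
#' @return A `truth_config` list.
#' @export
truth_config <- function(kappa = 0.09,
                         biological_cv = 0.2,
                         baseline_range = c(0.3, 6e4),
                         lloq_margin_range = c(20, 800),
                         plate_bias_sd = 0.05,
                         n_sex_affected = 20,
                         sex_lfc_range = c(1, 2),
                         n_ko_affected_per_strain = 3,
                         ko_lfc_range = c(1, 2),
                         contamination_fraction = 0.25,
                         contamination_sdlog = 1,
                         contamination_lambda = 3,
                         n_contamination_extra = 1,
                         blank_fraction = 0.1,
                         heavy_area_meanlog = log(1e5),
                         heavy_area_sdlog = 0.3) {
  stopifnot(kappa >= 0, biological_cv >= 0, all(baseline_range > 0),
            baseline_range[1] < baseline_range[2],
            all(lloq_margin_range >= 1), plate_bias_sd >= 0,
            n_sex_affected >= 0, n_ko_affected_per_strain >= 0,
            contamination_fraction >= 0, contamination_fraction <= 1,
            contamination_lambda >= 0, n_contamination_extra >= 0,
            blank_fraction > 0, blank_fraction < 1)
  structure(list(kappa = kappa, biological_cv = biological_cv,
                 baseline_range = baseline_range,
                 lloq_margin_range = lloq_margin_range,
                 plate_bias_sd = plate_bias_sd,
                 n_sex_affected = n_sex_affected,
                 sex_lfc_range = sex_lfc_range,
                 n_ko_affected_per_strain = n_ko_affected_per_strain,
                 ko_lfc_range = ko_lfc_range,
                 contamination_fraction = contamination_fraction,
                 contamination_sdlog = contamination_sdlog,
                 contamination_lambda = contamination_lambda,
                 n_contamination_extra = n_contamination_extra,
                 blank_fraction = blank_fraction,
                 heavy_area_meanlog = heavy_area_meanlog,
                 heavy_area_sdlog = heavy_area_sdlog),
            class = "truth_config")
}

#' Simulate a transition-level proteotyping dataset
#'
#' Generates everything the pipeline consumes -- transition records, sample
#' annotations, assay definitions, contamination panels -- together with the
#' ground truth used to generate them. The forward model per study or pooled
#' sample s and protein p is
#' \deqn{T = \mu_p \cdot 2^{\delta_{sex,p}[male]} \cdot
#'       2^{\delta_{ko,s,p}} \cdot b_{plate(s),p} + \lambda_p c_s}
#' and the observed light/heavy ratio is `(T / heavy_spike_p) * eps` with
#' `eps` log-normal at CV `kappa` (sdlog `sqrt(log(1 + kappa^2))`).
#' Calibration and curve-QC standards pass through the same ratio model from
#' their nominal concentration. Ablated proteins (homozygous knockout of
#' their own gene) produce a blank-level response below the LLOQ rather than
#' an exact zero, so the censoring path is exercised. Identical
#' `(design, truth, seed)` gives bit-identical output.
#'
#' @param design a [simulation_design()].
#' @param truth a [truth_config()].
#' @param seed integer seed.
#' @return A list with `transitions` (data.frame in the transition-table
#'   dialect), `annotations`, `assays`, `panels`, and `truth` (class
#'   `simulation_truth`; see Details).
#' @details The `truth` record contains the baselines `mu`, assay LLOQs, sex
#'   effects `sex_lfc`, per-strain effect maps `ko_lfc` (with `-Inf`
#'   encoding ablation), the plate-bias matrix, per-sample contamination
#'   levels and panel loadings, and the noise-free study-sample concentration
#'   matrix `true_conc` (plate bias and contamination included).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_design(n_strains = 2, n_proteins = 20,
#'                                           n_controls_per_sex = 3),
#'                         truth_config(n_sex_affected = 2,
#'                                      n_ko_affected_per_strain = 1),
#'                         seed = 1)
#' nrow(sim$annotations)
simulate_dataset <- function(design = simulation_design(),
                             truth = truth_config(), seed = 1) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(truth, "truth_config"))
  set.seed(seed)

  ## --- proteins and assays ------------------------------------------------
  n_prot <- design$n_proteins
  panel_ids <- c(ERYTHROCYTE_PANEL, PLATELET_PANEL)
  if (n_prot < length(panel_ids) + design$n_strains) {
    stop("config error: n_proteins too small for the contamination panels ",
         "and one target protein per strain")
  }
  proteins <- c(panel_ids,
                sprintf("PROT%03d", seq_len(n_prot - length(panel_ids))))
  ery_panel <- ERYTHROCYTE_PANEL
  plt_panel <- PLATELET_PANEL
  non_panel <- setdiff(proteins, panel_ids)

  mu <- 10 ^ runif(n_prot, log10(truth$baseline_range[1]),
                   log10(truth$baseline_range[2]))
  names(mu) <- proteins
  margin <- 10 ^ runif(n_prot, log10(truth$lloq_margin_range[1]),
                       log10(truth$lloq_margin_range[2]))
  lloq <- mu / margin
  names(lloq) <- proteins
  heavy_spike <- 100 * lloq
  uloq <- 1000 * lloq
  assays <- data.frame(protein_id = proteins,
                       peptide_id = paste0(proteins, "_PEP"),
                       lloq = unname(lloq),
                       heavy_spike = unname(heavy_spike),
                       uloq = unname(uloq),
                       stringsAsFactors = FALSE)

  ## --- strains, effects ---------------------------------------------------
  strains <- sprintf("KO%02d", seq_len(design$n_strains))
  zygosity <- rep(c("HOM", "HET"), length.out = design$n_strains)
  names(zygosity) <- strains

  pool <- sample(non_panel)  # effect assignment never touches the panels
  targets <- pool[seq_len(design$n_strains)]
  names(targets) <- strains

  n_sex <- truth$n_sex_affected
  if (n_sex > length(non_panel)) {
    stop("config error: more sex-affected proteins requested than available")
  }
  sex_proteins <- sample(non_panel, n_sex)
  sex_lfc <- setNames(
    runif(n_sex, truth$sex_lfc_range[1], truth$sex_lfc_range[2]) *
      sample(c(-1, 1), n_sex, replace = TRUE),
    sex_proteins)

  ko_lfc <- list()
  for (s in strains) {
    eff <- setNames(if (zygosity[s] == "HOM") -Inf else -1, targets[s])
    n_extra <- truth$n_ko_affected_per_strain
    if (n_extra > 0) {
      extra <- sample(setdiff(non_panel, targets[s]), n_extra)
      eff <- c(eff, setNames(
        runif(n_extra, truth$ko_lfc_range[1], truth$ko_lfc_range[2]) *
          sample(c(-1, 1), n_extra, replace = TRUE),
        extra))
    }
    ko_lfc[[s]] <- eff
  }

  ## --- samples ------------------------------------------------------------
  ann <- data.frame(strain = c(rep("WT", 2 * design$n_controls_per_sex),
                               rep(strains,
                                   each = 2 * design$mice_per_strain_per_sex)),
                    sex = c(rep(c("F", "M"), each = design$n_controls_per_sex),
                            rep(rep(c("F", "M"),
                                    each = design$mice_per_strain_per_sex),
                                design$n_strains)),
                    stringsAsFactors = FALSE)
  ann$zygosity <- ifelse(ann$strain == "WT", "WT", zygosity[ann$strain])
  ann$sample_id <- sprintf("S%03d", seq_len(nrow(ann)))
  ann$plate_id <- sample(paste0("P", rep(seq_len(design$n_plates),
                                         length.out = nrow(ann))))
  ann <- ann[c("sample_id", "strain", "zygosity", "sex", "plate_id")]

  plates <- paste0("P", seq_len(design$n_plates))
  pooled_ids <- unlist(lapply(plates, function(p) {
    sprintf("POOL_%s_%02d", p, seq_len(design$pooled_refs_per_plate))
  }))
  pooled_plate <- rep(plates, each = design$pooled_refs_per_plate)
  names(pooled_plate) <- pooled_ids

  ## --- nuisance structure -------------------------------------------------
  sdlog_bias <- truth$plate_bias_sd
  plate_bias <- base::matrix(
    exp(rnorm(n_prot * design$n_plates, -sdlog_bias^2 / 2, sdlog_bias)),
    n_prot, design$n_plates, dimnames = list(proteins, plates))

  study_ids <- ann$sample_id
  n_study <- length(study_ids)
  contaminated <- runif(n_study) < truth$contamination_fraction
  c_ery <- ifelse(contaminated,
                  rlnorm(n_study, 0, truth$contamination_sdlog), 0)
  names(c_ery) <- study_ids
  plt_contaminated <- runif(n_study) < truth$contamination_fraction
  c_plt <- ifelse(plt_contaminated,
                  rlnorm(n_study, 0, truth$contamination_sdlog), 0)
  names(c_plt) <- study_ids

  extra_carriers <- character(0)
  if (truth$n_contamination_extra > 0) {
    free <- setdiff(non_panel, c(targets, sex_proteins,
                                 unlist(lapply(ko_lfc, names))))
    extra_carriers <- free[seq_len(min(truth$n_contamination_extra,
                                       length(free)))]
  }
  ery_loaded <- c(ery_panel, extra_carriers)
  lambda <- setNames(truth$contamination_lambda * mu[ery_loaded], ery_loaded)
  lambda_plt <- setNames(truth$contamination_lambda * mu[plt_panel],
                         plt_panel)

  ## --- true concentrations for study samples ------------------------------
  male <- as.numeric(ann$sex == "M")
  sd_bio <- sqrt(log(1 + truth$biological_cv^2))
  bio <- base::matrix(
    if (sd_bio == 0) 1 else exp(rnorm(n_study * n_prot, -sd_bio^2 / 2,
                                      sd_bio)),
    n_study, n_prot, dimnames = list(study_ids, proteins))
  true_conc <- base::matrix(0, n_study, n_prot,
                            dimnames = list(study_ids, proteins))
  for (j in seq_len(n_prot)) {
    p <- proteins[j]
    lfc_sex <- if (p %in% names(sex_lfc)) sex_lfc[[p]] else 0
    ko <- vapply(ann$strain, function(s) {
      if (s == "WT") return(0)
      eff <- ko_lfc[[s]]
      if (p %in% names(eff)) eff[[p]] else 0
    }, numeric(1))
    base_term <- mu[[p]] * 2 ^ (lfc_sex * male) * 2 ^ ko *
      plate_bias[p, ann$plate_id] * bio[, j]
    base_term[ko == -Inf] <- 0
    contam <- 0
    if (p %in% names(lambda)) contam <- contam + lambda[[p]] * c_ery
    if (p %in% names(lambda_plt)) contam <- contam + lambda_plt[[p]] * c_plt
    true_conc[, j] <- base_term + contam
  }

  ## --- measurement model --------------------------------------------------
  sdlog_noise <- sqrt(log(1 + truth$kappa^2))
  noise <- function(n) {
    if (sdlog_noise == 0) rep(1, n) else exp(rnorm(n, 0, sdlog_noise))
  }
  measure_rows <- function(sample_ids, plate_ids, role, conc_matrix,
                           nominal = NULL) {
    n_s <- length(sample_ids)
    df <- data.frame(
      sample_id = rep(sample_ids, each = n_prot),
      protein_id = rep(proteins, n_s),
      peptide_id = rep(assays$peptide_id, n_s),
      light_area = NA_real_,
      heavy_area = rlnorm(n_s * n_prot, truth$heavy_area_meanlog,
                          truth$heavy_area_sdlog),
      plate_id = rep(plate_ids, each = n_prot),
      role = role,
      nominal_conc = if (is.null(nominal)) NA_real_ else
        as.vector(t(nominal)),
      stringsAsFactors = FALSE)
    conc <- as.vector(t(conc_matrix))  # row-major: sample-blocks of proteins
    blank <- truth$blank_fraction * rep(lloq, n_s)
    ratio_true <- ifelse(conc > 0, conc, blank) / rep(heavy_spike, n_s)
    df$light_area <- ratio_true * noise(nrow(df)) * df$heavy_area
    df
  }

  tr_study <- measure_rows(study_ids, ann$plate_id, "study", true_conc)

  pooled_conc <- base::matrix(
    rep(mu, each = length(pooled_ids)), length(pooled_ids), n_prot,
    dimnames = list(pooled_ids, proteins)) *
    t(plate_bias[, pooled_plate[pooled_ids]])
  tr_pooled <- measure_rows(pooled_ids, pooled_plate[pooled_ids],
                            "pooled_reference", pooled_conc)

  cal_levels <- design$calibration_levels
  cal_ids <- sprintf("CAL_L%d", seq_along(cal_levels))
  cal_conc <- outer(cal_levels, lloq)  # level x protein, fmol/uL
  dimnames(cal_conc) <- list(cal_ids, proteins)
  tr_cal <- measure_rows(cal_ids, rep(plates[1], length(cal_ids)),
                         "calibration_standard", cal_conc, nominal = cal_conc)

  qc_levels <- design$qc_levels_per_plate
  qc_ids <- as.vector(outer(seq_along(qc_levels), plates,
                            function(i, p) sprintf("QC_%s_L%d", p, i)))
  qc_plate <- rep(plates, each = length(qc_levels))
  qc_conc <- outer(rep(qc_levels, design$n_plates), lloq)
  dimnames(qc_conc) <- list(qc_ids, proteins)
  tr_qc <- measure_rows(qc_ids, qc_plate, "curve_qc", qc_conc,
                        nominal = qc_conc)

  transitions <- rbind(tr_study, tr_pooled, tr_cal, tr_qc)
  rownames(transitions) <- NULL

  panels <- list(
    erythrocyte = list(name = "erythrocyte", origin = "erythrocyte",
                       members = ery_panel),
    platelet = list(name = "platelet", origin = "platelet",
                    members = plt_panel))

  truth_out <- structure(list(
    mu = mu, lloq = lloq, heavy_spike = heavy_spike, uloq = uloq,
    sex_lfc = sex_lfc, ko_lfc = ko_lfc, targets = targets,
    zygosity = zygosity, plate_bias = plate_bias,
    contamination_level = c_ery, platelet_level = c_plt,
    lambda = lambda, lambda_platelet = lambda_plt,
    contamination_extra = extra_carriers,
    erythrocyte_panel = ery_panel, platelet_panel = plt_panel,
    kappa = truth$kappa, true_conc = true_conc,
    config = truth, design = design, seed = seed),
    class = "simulation_truth")

  list(transitions = transitions, annotations = ann, assays = assays,
       panels = panels, truth = truth_out)
}

#' Tabulate the planted effects of a simulation
#'
#' Lossless tabulation of the non-null planted effects: one row per
#' (protein, contrast). Ablations (log2 effect `-Inf`) are labeled with the
#' sentinel string `"ablated"`; null proteins are absent.
#'
#' @param truth a `simulation_truth` object from [simulate_dataset()].
#' @return A data.frame with columns `protein_id`, `contrast`,
#'   `log2_effect` (numeric, `-Inf` for ablation), and `label` (formatted
#'   effect or `"ablated"`).
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  rows <- list()
  if (length(truth$sex_lfc) > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = names(truth$sex_lfc), contrast = "sex",
      log2_effect = unname(truth$sex_lfc), stringsAsFactors = FALSE)
  }
  for (s in names(truth$ko_lfc)) {
    eff <- truth$ko_lfc[[s]]
    if (length(eff) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = names(eff), contrast = paste0("strain:", s),
      log2_effect = unname(eff), stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) {
    data.frame(protein_id = character(0), contrast = character(0),
               log2_effect = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out$label <- ifelse(is.infinite(out$log2_effect), "ablated",
                      sprintf("%.4f", out$log2_effect))
  rownames(out) <- NULL
  out
}

#' Simulate a clinical phenotyping table with planted correlations
#'
#' Emits one protein-linked continuous test (`HDL`, linearly coupled to the
#' true concentration of a designated unaffected protein) and one purely
#' sex-dimorphic test (`body_weight`), so that phenotype-correlation and
#' sex-adjustment behavior can be verified against a known truth.
#'
#' @param truth a `simulation_truth` from [simulate_dataset()].
#' @param annotations the matching sample annotations.
#' @param linked_protein protein driving `HDL`; default picks the first
#'   effect-free non-panel protein.
#' @param noise_sd relative noise on the linked test (0.05).
#' @param seed integer seed.
#' @return A data.frame with columns `sample_id`, `HDL`, `body_weight`, and
#'   an attribute `linked_protein`.
#' @export
simulate_phenotypes <- function(truth, annotations, linked_protein = NULL,
                                noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(seed)
  affected <- unique(c(names(truth$sex_lfc),
                       unlist(lapply(truth$ko_lfc, names)),
                       truth$erythrocyte_panel, truth$platelet_panel,
                       truth$contamination_extra))
  if (is.null(linked_protein)) {
    candidates <- setdiff(colnames(truth$true_conc), affected)
    if (length(candidates) == 0) stop("no effect-free protein available")
    linked_protein <- candidates[1]
  }
  conc <- truth$true_conc[annotations$sample_id, linked_protein]
  hdl <- 40 * conc / mean(conc) * exp(rnorm(length(conc), 0, noise_sd))
  bw <- 22 + 5 * (annotations$sex == "M") + rnorm(nrow(annotations), 0, 1.5)
  out <- data.frame(sample_id = annotations$sample_id, HDL = hdl,
                    body_weight = bw, stringsAsFactors = FALSE)
  attr(out, "linked_protein") <- linked_protein
  out
}
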