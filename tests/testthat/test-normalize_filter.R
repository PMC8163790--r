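## Small hand-built normalization scenario: 2 plates, pooled references
## with known medians.
norm_fixture <- function(pooled_a = c(40, 50, 60), pooled_b = c(80, 100, 120),
                         study_val = 10, lloq = 1) {
  pooled_ids <- c(paste0("pa", seq_along(pooled_a)),
                  paste0("pb", seq_along(pooled_b)))
  pooled <- make_cmat(matrix(c(pooled_a, pooled_b),
                             dimnames = list(pooled_ids, "prot"),
                             ncol = 1))
  study <- make_cmat(matrix(c(study_val, study_val),
                            dimnames = list(c("sa", "sb"), "prot"),
                            ncol = 1))
  plate_map <- c(sa = "A", sb = "B",
                 setNames(rep(c("A", "B"), c(length(pooled_a),
                                             length(pooled_b))),
                          pooled_ids))
  assays <- data.frame(protein_id = "prot", peptide_id = "prot_P",
                       lloq = lloq, heavy_spike = 100 * lloq,
                       uloq = 1e7, stringsAsFactors = FALSE)
  list(study = study, pooled = pooled, plate_map = plate_map,
       assays = assays)
}

test_that("plate factors are grand median over plate median", {
  fx <- norm_fixture()  # plate medians 50 and 100, grand median 70
  out <- normalize_plates(fx$study, fx$pooled, fx$plate_map, fx$assays)
  expect_equal(out$study$values["sa", "prot"], 10 * 70 / 50)
  expect_equal(out$study$values["sb", "prot"], 10 * 70 / 100)
  expect_false(any(out$report$exception_applied))

  # equal plate medians: all factors 1
  fx2 <- norm_fixture(pooled_a = c(40, 50, 60), pooled_b = c(45, 50, 55))
  out2 <- normalize_plates(fx2$study, fx2$pooled, fx2$plate_map, fx2$assays)
  expect_equal(out2$report$factor, c(1, 1))
})

test_that("majority-below-LLOQ pooled values trigger the keep-unchanged exception", {
  # 7 of 12 pooled values on plate A below LLOQ -> factor 1 on plate A
  below <- rep(0.5, 7)
  above <- c(40, 50, 60, 55, 45)
  fx <- norm_fixture(pooled_a = c(below, above), pooled_b = c(80, 100, 120),
                     lloq = 1)
  out <- normalize_plates(fx$study, fx$pooled, fx$plate_map, fx$assays)
  rep_a <- out$report[out$report$plate_id == "A", ]
  expect_true(rep_a$exception_applied)
  expect_equal(rep_a$factor, 1)
  expect_equal(out$study$values["sa", "prot"], 10)
  # plate B still normalized, with below-LLOQ values excluded from medians
  rep_b <- out$report[out$report$plate_id == "B", ]
  expect_false(rep_b$exception_applied)
  expect_equal(rep_b$factor, median(c(above, 80, 100, 120)) / 100)
})

test_that("plates without pooled references are an error", {
  fx <- norm_fixture()
  pm <- fx$plate_map
  pm[startsWith(names(pm), "pb")] <- "A"
  expect_error(normalize_plates(fx$study, fx$pooled, pm, fx$assays),
               "no pooled references")
})

test_that("normalization is idempotent", {
  sim <- simulate_dataset(small_design(), truth_config(), seed = 31)
  q <- quantify_dataset(sim$transitions,
                        fit_calibration_curves(sim$transitions, sim$assays),
                        sim$assays)
  n1 <- normalize_plates(q$study, q$pooled, q$plate_map, sim$assays)
  n2 <- normalize_plates(n1$study, n1$pooled, q$plate_map, sim$assays)
  no_exc <- !n2$report$exception_applied
  expect_true(all(abs(n2$report$factor[no_exc] - 1) < 1e-12))
})

test_that("known plate biases are removed exactly in the noise-free limit", {
  sim <- simulate_dataset(small_design(),
                          quiet_truth(plate_bias_sd = 0.2), seed = 32)
  res <- run_pipeline(sim$transitions, sim$annotations, sim$assays)
  wt <- sim$annotations$sample_id[sim$annotations$strain == "WT"]
  pre <- res$quant$study$values[wt, ]
  post <- res$normalized$study$values[wt, ]
  # before normalization the planted biases spread WT samples across
  # plates; after it, all WT values of a protein coincide exactly (the
  # per-protein anchor is a global constant and cancels in contrasts)
  spread <- function(m) apply(m, 2, function(col) diff(range(col)) /
                                median(col))
  expect_gt(max(spread(pre)), 0.1)
  expect_lt(max(spread(post)), 1e-9)
  # and the anchor is the grand median of the pooled references
  expect_equal(unname(post[1, ]),
               unname(apply(res$quant$pooled$values, 2, median)),
               tolerance = 1e-9)
})

test_that("filter cascade reproduces the staged dispositions", {
  # build 20 samples x 4 proteins: p_all always in range; p_4pct in range
  # in fewer than 5% of measurements; p_group in range only for one
  # complete strain-sex trio; p_never never in range
  samples <- sprintf("s%02d", 1:20)
  ann <- data.frame(sample_id = samples,
                    strain = rep(c("WT", "KOA"), c(14, 6)),
                    zygosity = rep(c("WT", "HOM"), c(14, 6)),
                    sex = rep(c("F", "M", "F", "M"), c(7, 7, 3, 3)),
                    plate_id = "P1", stringsAsFactors = FALSE)
  v <- matrix(10, 20, 4,
              dimnames = list(samples, c("p_all", "p_4pct", "p_group",
                                         "p_never")))
  f <- matrix("in_range", 20, 4, dimnames = dimnames(v))
  f[, "p_never"] <- "below_lloq"
  f[, "p_4pct"] <- "below_lloq"
  f[1, "p_4pct"] <- "in_range"       # 1/20 = 5% is quantifiable...
  f[, "p_group"] <- "below_lloq"
  f[ann$strain == "KOA" & ann$sex == "F", "p_group"] <- "in_range"
  m <- concentration_matrix(v, f)
  out <- filter_cascade(m, ann)
  rep <- out$report
  expect_equal(rep$n_measured, 4)
  expect_equal(rep$n_detectable, 3)  # p_never dropped
  # p_4pct at exactly 5% passes stage 2 but has no complete group
  expect_equal(rep$n_quantifiable, 3)
  expect_equal(rep$n_final, 2)       # p_all and p_group survive
  expect_setequal(colnames(out$matrix$values), c("p_all", "p_group"))
  expect_true(rep$n_measured >= rep$n_detectable &
                rep$n_detectable >= rep$n_quantifiable &
                rep$n_quantifiable >= rep$n_final)

  # below 5%: drop p_4pct at stage 2 by shrinking its in-range fraction
  f2 <- f
  v2 <- cbind(v, p_4pct2 = 10)
  f2 <- cbind(f2, p_4pct2 = "below_lloq")
  f2[1, "p_4pct2"] <- "in_range"
  big <- concentration_matrix(
    rbind(v2, matrix(10, 5, 5, dimnames = list(sprintf("x%d", 1:5),
                                               colnames(v2)))),
    rbind(f2, matrix("below_lloq", 5, 5,
                     dimnames = list(sprintf("x%d", 1:5), colnames(v2)))))
  ann2 <- rbind(ann, data.frame(sample_id = sprintf("x%d", 1:5),
                                strain = "KOB", zygosity = "HOM",
                                sex = c("F", "F", "F", "M", "M"),
                                plate_id = "P1"))
  out2 <- filter_cascade(big, ann2)
  d <- out2$report$disposition
  expect_false(d$quantifiable[d$protein_id == "p_4pct2"])  # 1/25 = 4%
})

test_that("adding in-range measurements never removes a surviving protein", {
  set.seed(33)
  samples <- sprintf("s%d", 1:12)
  ann <- data.frame(sample_id = samples, strain = rep(c("WT", "K"), each = 6),
                    zygosity = rep(c("WT", "HOM"), each = 6),
                    sex = rep(c("F", "M"), 6), plate_id = "P1",
                    stringsAsFactors = FALSE)
  v <- matrix(10, 12, 6, dimnames = list(samples, paste0("p", 1:6)))
  f <- matrix(sample(c("in_range", "below_lloq"), 72, replace = TRUE,
                     prob = c(0.4, 0.6)), 12, 6, dimnames = dimnames(v))
  before <- filter_cascade(concentration_matrix(v, f), ann)
  surv_before <- colnames(before$matrix$values)
  f2 <- f
  f2[f2 == "below_lloq" & runif(72) < 0.3] <- "in_range"
  after <- filter_cascade(concentration_matrix(v, f2), ann)
  expect_true(all(surv_before %in% colnames(after$matrix$values)))
})
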