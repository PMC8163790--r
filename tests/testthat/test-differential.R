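test_that("exact Mann-Whitney p-values match enumeration on fixed cases", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)  # 2/20
  expect_equal(mann_whitney(1:5, 6:10)$p, 2 / 252, tolerance = 1e-12)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$u, 0)
})

test_that("exact path agrees with full labeling enumeration incl. ties", {
  set.seed(71)
  for (rep in 1:60) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    # small integer support forces ties frequently
    a <- sample(1:4, n_a, replace = TRUE)
    b <- sample(1:4, n_b, replace = TRUE)
    expect_equal(mann_whitney(a, b)$p, mww_enum_oracle(a, b),
                 tolerance = 1e-12,
                 info = sprintf("a=%s b=%s", toString(a), toString(b)))
  }
})

test_that("exact path matches wilcox.test where both are exact (no ties)", {
  set.seed(72)
  for (rep in 1:20) {
    a <- rnorm(4)
    b <- rnorm(5)
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample path matches the corrected normal approximation", {
  set.seed(73)
  a <- round(rnorm(20, 10, 2), 1)
  b <- round(rnorm(25, 11, 2), 1)
  got <- mann_whitney(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$u, unname(ref$statistic))
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_equal(benjamini_hochberg(rep(0.05, 10)), rep(0.05, 10))
  set.seed(74)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is monotone in its inputs", {
  set.seed(75)
  for (rep in 1:10) {
    p <- runif(15)
    q <- benjamini_hochberg(p)
    i <- sample(15, 1)
    p2 <- p
    p2[i] <- min(1, p[i] + runif(1, 0, 1 - p[i]))
    expect_true(all(benjamini_hochberg(p2) >= q - 1e-12))
  }
})

test_that("fold change of means handles the ablation sentinel", {
  fc <- fold_change(c(1, 3), c(2, 6))
  expect_equal(fc$fc, 2)
  expect_equal(fc$log_fc, 1)
  expect_equal(fold_change(c(2, 2), c(2, 2))$log_fc, 0)
  abl <- fold_change(c(5, 7), c(0, 0))
  expect_identical(abl$sentinel, "ablated")
  expect_identical(abl$log_fc, -Inf)
  expect_identical(fold_change(c(0, 0), c(0, 0))$sentinel, "undefined")
})

test_that("Welch comparator matches the textbook formula and t.test", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.224744871, tolerance = 1e-8)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)

  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  degen <- welch_t(c(0, 0, 0), c(1, 1, 1))
  expect_equal(degen$p, 0)
  expect_equal(degen$t, -Inf)
  expect_equal(welch_t(c(2, 2), c(2, 2))$t, 0)
})

test_that("run_contrast recovers a planted shift and keeps nulls quiet", {
  set.seed(76)
  hits <- 0
  fp <- 0
  for (seed in 1:5) {
    sim <- simulate_dataset(
      simulation_design(n_strains = 1, n_controls_per_sex = 10,
                        n_proteins = 30),
      truth_config(kappa = 0.05, n_sex_affected = 1,
                   sex_lfc_range = c(2, 2), n_ko_affected_per_strain = 0,
                   contamination_fraction = 0, n_contamination_extra = 0,
                   plate_bias_sd = 0),
      seed = seed)
    res <- run_pipeline(sim$transitions, sim$annotations, sim$assays)
    ct <- contrast("sex",
                   sim$annotations$sample_id[sim$annotations$sex == "F"],
                   sim$annotations$sample_id[sim$annotations$sex == "M"],
                   p_threshold = 0.05, fold_threshold = 2,
                   use_adjusted_p = TRUE)
    dr <- run_contrast(res$matrix, ct)
    target <- names(sim$truth$sex_lfc)
    sig <- dr$protein_id[dr$significant]
    hits <- hits + (target %in% sig)
    fp <- fp + sum(!sig %in% c(target, sim$truth$targets))
  }
  expect_gte(hits, 4)   # planted 4-fold shift found in nearly every run
  expect_lte(fp, 1)     # nulls stay below the BH threshold
})

test_that("ablated proteins are significant by absence with the sentinel", {
  sim <- simulate_dataset(small_design(), truth_config(kappa = 0.05),
                          seed = 77)
  hom <- names(sim$truth$zygosity)[sim$truth$zygosity == "HOM"][1]
  res <- run_pipeline(sim$transitions, sim$annotations, sim$assays)
  dr <- run_contrast(res$matrix,
                     strain_contrast(sim$annotations, hom))
  target_row <- dr[dr$protein_id == sim$truth$targets[[hom]], ]
  expect_identical(target_row$sentinel, "ablated")
  expect_true(target_row$significant)
  expect_identical(target_row$log2_fc, -Inf)
})

test_that("empty and degenerate contrasts behave per contract", {
  v <- matrix(1:12 + 0, 6, 2,
              dimnames = list(paste0("s", 1:6), c("a", "b")))
  m <- make_cmat(v)
  expect_error(run_contrast(m, contrast("x", c("s1", "s2"), c("zz", "zy"))),
               "not resolvable")
  # protein missing in more than half of one group is excluded
  v2 <- v
  v2[4:6, "b"] <- NA
  f2 <- ifelse(is.na(v2), "missing", "in_range")
  dr <- run_contrast(concentration_matrix(v2, f2),
                     contrast("x", paste0("s", 1:3), paste0("s", 4:6)))
  expect_identical(dr$protein_id, "a")
  expect_identical(attr(dr, "excluded"), "b")
})

test_that("LASSO selects a perfect discriminator and little else", {
  found <- 0
  for (seed in 1:5) {
    set.seed(seed + 100)
    n <- 30
    y <- rep(c("A", "B"), each = n / 2)
    v <- matrix(10 ^ rnorm(n * 21, 1, 0.3), n, 21,
                dimnames = list(paste0("s", 1:n),
                                c("signal", paste0("null", 1:20))))
    v[y == "B", "signal"] <- v[y == "B", "signal"] * 8
    sel <- lasso_select(v, y, seed = seed)
    found <- found + ("signal" %in% sel)
  }
  expect_equal(found, 5)
})

test_that("LASSO under the null usually selects nothing or almost nothing", {
  sizes <- vapply(1:10, function(seed) {
    set.seed(seed + 200)
    v <- matrix(10 ^ rnorm(6 * 10, 1, 0.3), 6, 10,
                dimnames = list(paste0("s", 1:6), paste0("p", 1:10)))
    suppressWarnings(  # glmnet grumbles about leave-one-out folds at n = 6
      length(lasso_select(v, rep(c("A", "B"), 3), seed = seed)))
  }, numeric(1))
  expect_gte(mean(sizes <= 2), 0.6)
  expect_error(lasso_select(matrix(1:8, 4, 2,
                                   dimnames = list(letters[1:4],
                                                   c("x", "y"))),
                            rep("A", 4)), "two classes")
})

test_that("a duplicated feature does not inflate the LASSO selection", {
  set.seed(301)
  n <- 24
  y <- rep(c("A", "B"), each = n / 2)
  v <- matrix(10 ^ rnorm(n * 11, 1, 0.3), n, 11,
              dimnames = list(paste0("s", 1:n),
                              c("signal", paste0("null", 1:10))))
  v[y == "B", "signal"] <- v[y == "B", "signal"] * 8
  base_sel <- lasso_select(v, y, seed = 1)
  v2 <- cbind(v, signal_copy = v[, "signal"])
  dup_sel <- lasso_select(v2, y, seed = 1)
  expect_lte(length(dup_sel), length(base_sel) + 1)
})

test_that("PCA projection matches an eigendecomposition oracle", {
  set.seed(78)
  v <- matrix(10 ^ rnorm(20, 1, 0.5), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("p", 1:4)))
  pc <- pca_project(v, n_components = 2)
  x <- scale(log10(v))
  eig <- eigen(cov(x))
  oracle_scores <- x %*% eig$vectors[, 1:2]
  for (k in 1:2) {
    expect_equal(abs(cor(pc$scores[, k], oracle_scores[, k])), 1,
                 tolerance = 1e-9)
    expect_equal(abs(pc$scores[, k]), abs(oracle_scores[, k]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_equal(pc$variance_fraction,
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-9)
  expect_lte(sum(pc$variance_fraction), 1 + 1e-12)
})

test_that("PCA captures perfect anticorrelation and isotropic noise", {
  x <- 10 ^ seq(0, 2, length.out = 10)
  v <- cbind(a = x, b = rev(x))
  rownames(v) <- paste0("s", 1:10)
  pc <- pca_project(v)
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-9)

  set.seed(79)
  v2 <- matrix(10 ^ rnorm(200, 1, 0.3), 100, 2,
               dimnames = list(paste0("s", 1:100), c("a", "b")))
  pc2 <- pca_project(v2)
  expect_lt(abs(pc2$variance_fraction[1] - 0.5), 0.1)

  v3 <- cbind(v2, const = 5)
  expect_warning(pca_project(v3), "constant")
})

test_that("cross-validated C-statistic spans separable, planted, and null cases", {
  set.seed(80)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  v <- matrix(10 ^ rnorm(n * 3, 1, 0.2), n, 3,
              dimnames = list(paste0("s", 1:n), paste0("p", 1:3)))
  v[y == "B", 1] <- v[y == "B", 1] * 20
  sep <- cv_logistic_cstat(v, y, k = 5, seed = 1)
  expect_equal(sep$mean_cstat, 1)
  expect_length(sep$per_fold, 5)

  nulls <- vapply(1:10, function(s) {
    set.seed(s)
    vn <- matrix(10 ^ rnorm(100 * 3, 1, 0.2), 100, 3,
                 dimnames = list(paste0("s", 1:100), paste0("p", 1:3)))
    cv_logistic_cstat(vn, sample(rep(c("A", "B"), 50)), k = 5,
                      seed = s)$mean_cstat
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.1)

  expect_error(cv_logistic_cstat(v, y, k = 25), "smaller class")
})
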