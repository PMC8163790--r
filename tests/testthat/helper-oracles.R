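## Independent oracles used across the suite. Each deliberately takes a
## different computational route than the implementation it checks.

## Weighted least squares by the closed-form 2x2 normal equations.
wls_oracle <- function(x, y, w) {
  sw <- sum(w)
  swx <- sum(w * x)
  swy <- sum(w * y)
  swxx <- sum(w * x^2)
  swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  c(slope = slope, intercept = intercept)
}

## Two-pass Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## Exact two-sided Mann-Whitney p by enumerating every labeling; U is
## computed by pair counting (greater = 1, tie = 1/2), not via ranks.
mww_enum_oracle <- function(a, b) {
  values <- c(a, b)
  n <- length(values)
  n_a <- length(a)
  u_of <- function(idx_a) {
    va <- values[idx_a]
    vb <- values[-idx_a]
    sum(outer(va, vb, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_of(seq_len(n_a))
  mid <- n_a * (n - n_a) / 2
  all_u <- apply(combn(n, n_a), 2, u_of)
  mean(abs(all_u - mid) >= abs(u_obs - mid) - 1e-9)
}

## Hand-applied BH step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

## Hypergeometric upper tail by direct binomial summation.
hyper_oracle <- function(N, K, n, x) {
  ks <- x:min(K, n)
  ks <- ks[n - ks <= N - K]
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## Partial correlation of x and y given a binary covariate, by formula.
partial_corr_oracle <- function(x, y, z) {
  rxy <- cor(x, y)
  rxz <- cor(x, z)
  ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

## A reduced-scale simulation design used where the full study shape is not
## the point of the test.
small_design <- function(...) {
  simulation_design(n_strains = 3, mice_per_strain_per_sex = 3,
                    n_controls_per_sex = 5, n_proteins = 60, ...)
}

quiet_truth <- function(...) {
  args <- list(kappa = 0, biological_cv = 0, plate_bias_sd = 0,
               n_sex_affected = 0, n_ko_affected_per_strain = 0,
               contamination_fraction = 0, n_contamination_extra = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(truth_config, args)
}

## Small in-memory concentration matrix builder.
make_cmat <- function(values, flags = NULL) {
  if (is.null(flags)) {
    flags <- ifelse(is.na(values), "missing", "in_range")
    dim(flags) <- dim(values)
  }
  concentration_matrix(values, flags)
}
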