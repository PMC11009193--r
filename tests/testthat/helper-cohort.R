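# shared fixtures, built once per test run

# small cohort with planted structure for unit tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 150, n_clusters = 60, n_age_clusters = 8,
         n_lifestyle_clusters = 3, n_x_probes = 12, n_y_probes = 10),
    list(...)
  )
  do.call(cohort_config, args)
}

.fixtures <- new.env()

small_cohort <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- simulate_cohort(small_config(), seed = 42)
  .fixtures$small
}

# noiseless cohort: no probe-level noise or cell mixing, no planted signals,
# so probes within a cluster share their latent exactly and clusters are
# mutually uncorrelated (a shared age slope would genuinely merge clusters)
noiseless_cohort <- function() {
  if (is.null(.fixtures$noiseless)) {
    .fixtures$noiseless <- simulate_cohort(
      small_config(probe_noise_sd = 0, n_cell_types = 0,
                   n_age_clusters = 0, n_lifestyle_clusters = 0,
                   cluster_size_range = c(2L, 4L)),
      seed = 7
    )
  }
  .fixtures$noiseless
}

# hand-build a clock model without training
make_model <- function(ids, weights, intercept, total_score = 0, seed = 0) {
  structure(list(cluster_ids = ids, weights = setNames(weights, ids),
                 intercept = intercept,
                 score_components = list(rmse_term = NA_real_,
                                         lifestyle_term = NA_real_,
                                         complexity_term = length(ids)),
                 total_score = total_score, train_seed = seed),
            class = "clock_model")
}

# small M-scale matrix with named dims
m_matrix <- function(values, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("cg%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(ncol(values)))
  methylation_matrix(`dimnames<-`(values, list(probes, samples)), scale = "m")
}

# adjusted Rand index between two partitions given as membership vectors
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force step-up FDR oracle, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1)), 1)
  }
  q
}

# exact two-sided hypergeometric p for a 2x2 table (a, b, c, d):
# sum of probabilities of tables (with fixed margins) no more likely
hypergeom_2x2_p <- function(a, b, c, d) {
  m1 <- a + b
  k <- a + c
  n <- a + b + c + d
  lo <- max(0, k - (n - m1))
  hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, n - m1, k)
  sum(probs[probs <= stats::dhyper(a, m1, n - m1, k) * (1 + 1e-7)])
}
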