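test_that("least-squares weights solve exact linear systems", {
  ages <- seq(20, 60, length.out = 30)
  x1 <- ages
  m <- m_matrix(rbind(x1), probes = "c1")
  fit <- fit_weights(m, ages)
  expect_equal(unname(fit$weights), 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)

  set.seed(1)
  x1 <- rnorm(30)
  x2 <- rnorm(30)
  ages2 <- 2 * x1 - 3 * x2 + 5
  m2 <- m_matrix(rbind(x1, x2), probes = c("c1", "c2"))
  fit2 <- fit_weights(m2, ages2)
  expect_equal(unname(fit2$weights), c(2, -3), tolerance = 1e-10)
  expect_equal(fit2$intercept, 5, tolerance = 1e-10)
})

test_that("residuals are orthogonal to every predictor (normal equations)", {
  set.seed(2)
  x <- matrix(rnorm(50 * 5), 5, 50)
  ages <- rnorm(50, 40, 10)
  m <- m_matrix(x)
  fit <- fit_weights(m, ages)
  pred <- drop(t(x) %*% fit$weights) + fit$intercept
  res <- ages - pred
  for (j in 1:5) expect_lt(abs(sum(res * x[j, ])), 1e-8)
  expect_lt(abs(sum(res)), 1e-8)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  x <- rbind(1:20, 2 * (1:20))
  ages <- 3 * (1:20) + 1
  m <- m_matrix(x, probes = c("c1", "c2"))
  expect_warning(fit <- fit_weights(m, ages), "rank-deficient")
  pred <- drop(t(x) %*% fit$weights) + fit$intercept
  expect_equal(pred, ages, tolerance = 1e-8)
})

test_that("delta-age correlation p-values match the closed form and cor.test", {
  set.seed(3)
  delta <- rnorm(5)
  f <- rnorm(5)
  p_pkg <- delta_age_pvalues(delta, tibble::tibble(f = f), "f")$p_value
  r <- cor(delta, f)
  t_val <- r * sqrt(3) / sqrt(1 - r^2)
  expect_equal(p_pkg, 2 * pt(-abs(t_val), 3), tolerance = 1e-12)
  expect_equal(p_pkg, cor.test(delta, f)$p.value, tolerance = 1e-12)

  # perfect correlation floors at 1e-300 rather than returning 0 or NaN
  expect_equal(delta_age_pvalues(1:5, tibble::tibble(f = 2 * (1:5) + 1),
                                 "f")$p_value, 1e-300)
  # zero-variance factor gives p = 1 with a warning, not NaN
  expect_warning(
    p0 <- delta_age_pvalues(rnorm(10), tibble::tibble(f = rep(1, 10)), "f"),
    "zero-variance"
  )
  expect_equal(p0$p_value, 1)
})

test_that("delta-age p-values are uniform under the null", {
  set.seed(4)
  p <- replicate(1000, {
    delta_age_pvalues(rnorm(30), tibble::tibble(f = rnorm(30)), "f")$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the objective is the stated weighted sum and respects w_sig = 0", {
  co <- small_cohort()
  cmat <- average_clusters(co$matrix[unlist(unclass(co$truth_clusters)), ],
                           co$truth_clusters)
  cfg <- anneal_config(w_rmse = 1, w_sig = 1, w_cplx = 0.1,
                       sig_partial_age = FALSE, p_floor = 1e-300)
  ids <- names(co$truth$age_clusters)[1:5]
  fit <- fit_weights(cmat[ids, ], co$survey$age)
  model <- structure(list(cluster_ids = ids, weights = fit$weights,
                          intercept = fit$intercept), class = "clock_model")
  sc <- score_model(model, cmat, co$survey$age, co$survey, cfg)
  # independent recomputation of each term
  pred <- drop(t(unclass(cmat)[ids, ]) %*% fit$weights) + fit$intercept
  expect_equal(sc$rmse_term, sqrt(mean((pred - co$survey$age)^2)))
  p_each <- vapply(lifestyle_factor_names(), function(f) {
    cor.test(pred - co$survey$age, co$survey[[f]])$p.value
  }, numeric(1))
  expect_equal(sc$lifestyle_term, sum(log10(p_each)), tolerance = 1e-10)
  expect_equal(sc$complexity_term, 5)
  expect_equal(sc$total,
               1 * sc$rmse_term + 1 * sc$lifestyle_term + 0.1 * 5)

  # with w_sig = 0 the ordering reduces to accuracy + complexity
  cfg0 <- anneal_config(w_sig = 0)
  sc0 <- score_model(model, cmat, co$survey$age, co$survey, cfg0)
  expect_equal(sc0$total, sc0$rmse_term + 0.01 * 5)
})

test_that("age-adjusted significance ignores pure age leakage in delta", {
  set.seed(5)
  age <- runif(300, 18, 93)
  f <- tibble::tibble(f = pmin(pmax(0.5 + 0.3 * scale(age)[, 1] +
                                      rnorm(300, 0, 0.2), 0), 1))
  delta <- -0.5 * (age - mean(age)) + rnorm(300, 0, 1)  # pure age leak
  p_raw <- delta_age_pvalues(delta, f, "f")$p_value
  p_adj <- buccalclock:::partial_pvalues(delta, as.matrix(f), age)
  expect_lt(p_raw, 1e-6)     # unadjusted test is fooled
  expect_gt(unname(p_adj), 0.01)  # age-adjusted test is not
})

test_that("acceptance rule is exact for improvements and calibrated for worsening", {
  set.seed(6)
  expect_true(all(replicate(200, anneal_accept(-0.3, 0.5))))
  expect_true(all(replicate(200, anneal_accept(0, 0.5))))
  for (ds in c(0.2, 1)) {
    temp <- 0.8
    acc <- mean(replicate(5000, anneal_accept(ds, temp)))
    expected <- exp(-ds / temp)
    se <- sqrt(expected * (1 - expected) / 5000)
    expect_lt(abs(acc - expected), 3 * se)
  }
})

test_that("annealing is deterministic and tracks a non-increasing best score", {
  co <- small_cohort()
  cmat <- average_clusters(co$matrix[unlist(unclass(co$truth_clusters)), ],
                           co$truth_clusters)
  cfg <- anneal_config(iterations = 400)
  m1 <- anneal(cmat, co$survey$age, co$survey, cfg, seed = 11, trace = TRUE)
  m2 <- anneal(cmat, co$survey$age, co$survey, cfg, seed = 11, trace = TRUE)
  expect_identical(m1, m2)
  tr <- attr(m1, "trace")
  expect_true(all(diff(tr$best_score) <= 1e-12))
  expect_true(all(tr$best_score <= tr$current_score + 1e-12))
  expect_equal(min(tr$best_score), m1$total_score)
})

test_that("in the zero-temperature limit annealing is greedy hill-climbing", {
  co <- small_cohort()
  cmat <- average_clusters(co$matrix[unlist(unclass(co$truth_clusters)), ],
                           co$truth_clusters)
  cfg <- anneal_config(iterations = 300, t0 = 1e-12, t_min = 1e-15)
  m <- anneal(cmat, co$survey$age, co$survey, cfg, seed = 12, trace = TRUE)
  tr <- attr(m, "trace")
  expect_true(all(diff(tr$current_score) <= 1e-9))
})

test_that("repeated training yields a stable but non-degenerate score spread", {
  co <- small_cohort()
  cmat <- average_clusters(co$matrix[unlist(unclass(co$truth_clusters)), ],
                           co$truth_clusters)
  cfg <- anneal_config(iterations = 300)
  models <- train_many(cmat, co$survey$age, co$survey, cfg,
                       n_models = 10, base_seed = 50)
  scores <- vapply(models, function(m) m$total_score, numeric(1))
  models_again <- train_many(cmat, co$survey$age, co$survey, cfg,
                             n_models = 10, base_seed = 50)
  expect_identical(scores,
                   vapply(models_again, function(m) m$total_score, numeric(1)))
  expect_gt(var(scores), 0)
})
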