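test_that("ensemble weights are worst-anchored, ordered and normalised", {
  models <- list(make_model("c1", 1, 0, total_score = 1),
                 make_model("c2", 1, 0, total_score = 3),
                 make_model("c3", 1, 0, total_score = 2))
  clock <- build_ensemble(models, top_k = 3)
  # sorted ascending by score -> 1, 2, 3
  expect_equal(vapply(clock$models, function(m) m$total_score, numeric(1)),
               c(1, 2, 3))
  eps <- 1e-9 * 3
  expect_equal(clock$ensemble_weights,
               c(2 + eps, 1 + eps, eps) / (3 + 3 * eps), tolerance = 1e-12)
  expect_true(all(diff(clock$ensemble_weights) < 0))
  expect_equal(sum(clock$ensemble_weights), 1, tolerance = 1e-12)

  same <- replicate(10, make_model("c1", 1, 0, total_score = 2),
                    simplify = FALSE)
  uniform <- build_ensemble(same, top_k = 10)
  expect_equal(uniform$ensemble_weights, rep(0.1, 10), tolerance = 1e-12)
  expect_error(build_ensemble(models, top_k = 0), "top_k")
  expect_error(build_ensemble(models, top_k = 4), "top_k")
})

test_that("ensemble prediction is the weighted mean of member models", {
  x <- m_matrix(rbind(c(10, 20), c(5, 5)), probes = c("c1", "c2"),
                samples = c("s1", "s2"))
  m1 <- make_model("c1", 2, 20, total_score = 1)   # predicts 40, 60
  m2 <- make_model("c2", 2, 40, total_score = 1)   # predicts 50, 50
  clock <- build_ensemble(list(m1, m2), top_k = 2)
  pr <- predict(clock, x)
  expect_equal(pr$raw_age, c(45, 55))

  one <- build_ensemble(list(m1), top_k = 1)
  expect_equal(predict(one, x)$raw_age, c(40, 60))

  # convex combination and permutation invariance
  perm <- predict(clock, x[, c("s2", "s1")])
  expect_equal(perm$raw_age, rev(pr$raw_age))
  member <- cbind(c(40, 60), c(50, 50))
  expect_true(all(pr$raw_age >= apply(member, 1, min) - 1e-12 &
                    pr$raw_age <= apply(member, 1, max) + 1e-12))
})

test_that("missing clusters are imputed from stored training means or rejected", {
  co <- small_cohort()
  cmat <- average_clusters(co$matrix[unlist(unclass(co$truth_clusters)), ],
                           co$truth_clusters)
  ids <- names(co$truth$age_clusters)[1:3]
  fit <- fit_weights(cmat[ids, ], co$survey$age)
  model <- make_model(ids, unname(fit$weights), fit$intercept, total_score = 1)
  clock <- build_ensemble(list(model), top_k = 1, cluster_matrix = cmat)
  reduced <- cmat[setdiff(rownames(cmat), ids[1]), ]
  pr_full <- predict(clock, cmat)
  pr_imp <- predict(clock, reduced)
  expect_equal(nrow(pr_imp), ncol(cmat))
  expect_false(isTRUE(all.equal(pr_full$raw_age, pr_imp$raw_age)))

  bare <- build_ensemble(list(model), top_k = 1)
  expect_error(predict(bare, reduced), ids[1])
})

test_that("age-bias rotation inverts a known affine bias exactly", {
  age <- seq(20, 80, length.out = 40)
  expect_equal(apply_rotation(age, fit_rotation(age, age)), age,
               tolerance = 1e-10)
  raw <- 0.5 * age + 20
  rot <- fit_rotation(raw, age)
  expect_equal(rot$slope, 0.5, tolerance = 1e-10)
  expect_equal(rot$intercept, 20, tolerance = 1e-10)
  expect_equal(apply_rotation(raw, rot), age, tolerance = 1e-10)
  expect_error(fit_rotation(rep(50, 40), age), "degenerate")
})

test_that("rotation drives the training-set MAB to zero", {
  set.seed(9)
  age <- runif(100, 18, 93)
  raw <- 0.7 * age + 12 + rnorm(100, 0, 3)
  corrected <- apply_rotation(raw, fit_rotation(raw, age))
  mab <- compute_metrics(corrected, age)$mab
  expect_lt(mab, 1e-8)
})

test_that("cross-validation gives each sample one prediction and keeps
           replicate pairs in one fold", {
  co <- simulate_cohort(small_config(), seed = 21)
  aug <- add_replicates(co$matrix, co$survey, n_pairs = 12, tech_sd = 0.1,
                        seed = 22)
  cmat <- average_clusters(
    aug$matrix[unlist(unclass(co$truth_clusters)), ], co$truth_clusters
  )
  survey <- aug$survey[match(colnames(cmat), aug$survey$sample_id), ]
  cfg <- anneal_config(iterations = 200, max_size = 8)
  cv <- cross_validate(cmat, survey$age, survey, folds = 4,
                       models_per_fold = 2, config = cfg, seed = 23)
  pr <- cv$predictions
  expect_equal(nrow(pr), ncol(cmat))
  expect_setequal(pr$sample_id, colnames(cmat))
  expect_equal(sum(is.na(pr$predicted_age)), 0)
  folds_per_group <- tapply(pr$fold[match(survey$sample_id, pr$sample_id)],
                            survey$replicate_group,
                            function(x) length(unique(x)))
  expect_true(all(folds_per_group == 1, na.rm = TRUE))
  expect_error(cross_validate(cmat, survey$age, survey, folds = 1), "folds")
})

test_that("serialization round-trips bit-exactly and reproduces predictions", {
  co <- small_cohort()
  cmat <- average_clusters(co$matrix[unlist(unclass(co$truth_clusters)), ],
                           co$truth_clusters)
  cfg <- anneal_config(iterations = 150)
  models <- train_many(cmat, co$survey$age, co$survey, cfg, n_models = 3,
                       base_seed = 30)
  clock <- build_ensemble(models, top_k = 3, cluster_matrix = cmat)
  clock <- calibrate_rotation(clock, cmat, co$survey$age)
  path <- withr::local_tempfile(fileext = ".json")
  save_ensemble(clock, path)
  back <- load_ensemble(path)
  expect_equal(back$ensemble_weights, clock$ensemble_weights, tolerance = 0)
  expect_equal(back$rotation, clock$rotation, tolerance = 0)
  for (i in seq_along(clock$models)) {
    expect_identical(back$models[[i]]$weights, clock$models[[i]]$weights)
    expect_identical(back$models[[i]]$intercept, clock$models[[i]]$intercept)
  }
  expect_identical(predict(back, cmat)$predicted_age,
                   predict(clock, cmat)$predicted_age)

  # single-model clock with weight exactly 1
  single <- build_ensemble(models[1], top_k = 1, cluster_matrix = cmat)
  save_ensemble(single, path)
  expect_equal(load_ensemble(path)$ensemble_weights, 1)
})

test_that("corrupt or incompatible ensemble files fail loudly", {
  co <- small_cohort()
  cmat <- average_clusters(co$matrix[unlist(unclass(co$truth_clusters)), ],
                           co$truth_clusters)
  models <- train_many(cmat, co$survey$age, co$survey,
                       anneal_config(iterations = 100), n_models = 1,
                       base_seed = 1)
  clock <- build_ensemble(models, top_k = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_ensemble(clock, path)
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), path)
  expect_error(load_ensemble(path), "cannot load|schema|models")
  path2 <- withr::local_tempfile(fileext = ".json")
  save_ensemble(clock, path2)
  obj <- jsonlite::read_json(path2, simplifyVector = FALSE)
  obj$schema_version <- 99
  jsonlite::write_json(obj, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_ensemble(path2), "incompatible")
})
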