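test_that("binned mean trajectories track a linear CpG and flag constants", {
  set.seed(1)
  ages <- runif(200, 18, 93)
  v <- rbind(linear = 0.02 * ages, constant = rep(1, 200),
             noise = rnorm(200))
  m <- m_matrix(v, probes = c("linear", "constant", "noise"))
  prof <- binned_profile(m, ages, n_bins = 10, statistic = "mean")
  # bin means of the linear CpG equal scaled bin mean ages
  bin <- cut(ages, prof$bin_edges, include.lowest = TRUE, labels = FALSE)
  expected <- vapply(1:10, function(b) mean(0.02 * ages[bin == b]), numeric(1))
  expect_equal(unname(prof$stat["linear", ]), expected)
  r <- prof$correlations
  expect_gt(r$r[r$probe_id == "linear"], 0.99)
  expect_true(is.na(r$r[r$probe_id == "constant"]))
  # variance mode: constant CpG has zero variance in every bin
  profv <- binned_profile(m, ages, n_bins = 10, statistic = "variance")
  expect_equal(unname(profv$stat["constant", ]), rep(0, 10))
})

test_that("high trajectory correlation holds for a noiseless linear CpG at any bin count", {
  ages <- seq(20, 90, length.out = 120)
  m <- m_matrix(rbind(lin = 0.05 * ages), probes = "lin")
  for (nb in c(2, 5, 15)) {
    prof <- binned_profile(m, ages, n_bins = nb)
    expect_equal(prof$correlations$r, 1, tolerance = 1e-6)
  }
  expect_error(binned_profile(m, c(rep(20, 119), 90), n_bins = 15),
               "fewer bins")
})

test_that("correlation-window selection returns planted monotone CpGs", {
  set.seed(2)
  ages <- runif(300, 18, 93)
  v <- rbind(mono1 = 0.03 * ages + rnorm(300, 0, 0.1),
             mono2 = -0.05 * ages + rnorm(300, 0, 0.1),
             matrix(rnorm(50 * 300), 50, 300,
                    dimnames = list(sprintf("bg%02d", 1:50), NULL)))
  m <- m_matrix(v, probes = rownames(v))
  prof <- binned_profile(m, ages)
  sets <- select_by_correlation(prof)
  expect_true(all(c("mono1", "mono2") %in% sets$high))
  all_set <- select_by_correlation(prof, windows = list(all = c(0, 1)))$all
  expect_setequal(all_set,
                  prof$correlations$probe_id[!is.na(prof$correlations$r)])
})

test_that("factor top-set overlap is symmetric with sane extremes", {
  co <- small_cohort()
  survey <- co$survey
  survey$copy_of_smoking <- survey$smoking
  ov <- factor_correlation_overlap(co$matrix, survey,
                                   c("smoking", "copy_of_smoking", "age"),
                                   top_n = 50)
  expect_identical(ov$top_sets$smoking, ov$top_sets$copy_of_smoking)
  expect_equal(ov$overlap["smoking", "copy_of_smoking"], 50L)
  expect_identical(ov$overlap, t(ov$overlap))
  expect_warning(
    factor_correlation_overlap(co$matrix, survey, "age", top_n = 1e6),
    "capped"
  )
})

test_that("independent factors overlap near the hypergeometric expectation", {
  set.seed(3)
  n_feat <- 4000
  n <- 200
  m <- m_matrix(matrix(rnorm(n_feat * n), n_feat, n))
  survey <- tibble::tibble(sample_id = colnames(m), f1 = rnorm(n), f2 = rnorm(n))
  ov <- factor_correlation_overlap(m, survey, c("f1", "f2"), top_n = 100)
  expected <- 100^2 / n_feat  # 2.5
  expect_lt(abs(ov$overlap["f1", "f2"] - expected), 8)
})

test_that("context enrichment reproduces the worked 2x2 example and edge cases", {
  # 10/20 of the set in islands vs 100/400 of the rest: OR = 3
  manifest <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:420),
    chrom = "chr1", pos = 1:420,
    island_relation = c(rep("Island", 10), rep("OpenSea", 10),
                        rep("Island", 100), rep("OpenSea", 300)),
    genes = ""
  )
  cpg_set <- manifest$probe_id[1:20]
  res <- context_enrichment(cpg_set, manifest$probe_id, manifest)
  isl <- res[res$category == "Island", ]
  expect_equal(isl$odds_ratio, 3)
  expect_equal(isl$p_value,
               fisher.test(matrix(c(10, 10, 100, 300), 2, byrow = TRUE))$p.value)
  # empty category in both -> missing odds ratio
  expect_true(is.na(res$odds_ratio[res$category == "Shore"]))
  expect_error(context_enrichment(c(cpg_set, "novel"),
                                  c(manifest$probe_id, "novel"), manifest),
               "unannotated")
})

test_that("a set equal to its background shows no enrichment anywhere", {
  co <- small_cohort()
  bg <- rownames(co$matrix)
  res <- context_enrichment(bg, bg, co$manifest)
  expect_true(all(res$odds_ratio[!is.na(res$odds_ratio)] == 1))
  expect_true(all(res$p_value[!is.na(res$p_value)] == 1))
})

test_that("Fisher p-values agree with an exact hypergeometric oracle", {
  set.seed(4)
  manifest1 <- tibble::tibble(probe_id = character(), chrom = character(),
                              pos = integer(), island_relation = character(),
                              genes = character())
  for (i in 1:100) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + c_ == 0 || a + b == 0 || c_ + d == 0) next
    p_fisher <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p_fisher, hypergeom_2x2_p(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("differential variability finds planted variance inflation", {
  set.seed(5)
  n_cpg <- 600
  lo <- matrix(rnorm(n_cpg * 50), n_cpg, 50)
  hi <- matrix(rnorm(n_cpg * 50), n_cpg, 50)
  hi[1:40, ] <- hi[1:40, ] * sqrt(3)   # 3x variance inflation
  m <- m_matrix(cbind(lo, hi), probes = sprintf("cg%04d", 1:n_cpg),
                samples = sprintf("s%03d", 1:100))
  res <- differential_variability(m, low_ids = sprintf("s%03d", 1:50),
                                  high_ids = sprintf("s%03d", 51:100))
  hits <- res$probe_id[!is.na(res$q_value) & res$q_value < 0.05]
  planted <- sprintf("cg%04d", 1:40)
  expect_gt(length(intersect(hits, planted)) / max(length(hits), 1), 0.8)
  expect_gt(length(intersect(hits, planted)), 20)
  expect_true(all(res$direction[res$probe_id %in% hits] == "high_delta"))
  expect_error(differential_variability(m, sprintf("s%03d", 1:2),
                                        sprintf("s%03d", 31:60)), ">= 3")
})

test_that("per-CpG F-test matches var.test and splits groups at the stated cutoffs", {
  set.seed(6)
  m <- m_matrix(matrix(rnorm(5 * 24), 5, 24), samples = sprintf("s%02d", 1:24))
  res <- differential_variability(m, sprintf("s%02d", 1:12),
                                  sprintf("s%02d", 13:24))
  for (i in 1:5) {
    vt <- var.test(unclass(m)[i, 13:24], unclass(m)[i, 1:12])
    expect_equal(res$p_value[i], vt$p.value, tolerance = 1e-10)
  }
  pr <- tibble::tibble(sample_id = c("a", "b", "c"),
                       delta_age = c(-7, 0, 6))
  grp <- delta_age_groups(pr)
  expect_equal(grp$low_ids, "a")
  expect_equal(grp$high_ids, "c")
})
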