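#' Probe filter thresholds
#'
#' @param detection_p Maximum acceptable detection p-value; a probe is removed
#'   when its detection p exceeds this in more than `detection_frac` of
#'   samples. Ignored (with a warning) when no detection p-values are given.
#' @param detection_frac Fraction of samples allowed to fail detection.
#' @param max_missing Maximum fraction of missing values per probe.
#' @param min_variance Minimum per-probe variance (on the matrix's own scale).
#' @param drop_sex_chromosomes Remove chrX/chrY probes.
#' @param exclude Probe ids to remove unconditionally (cross-reactive / SNP
#'   lists).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(detection_p = 0.01, detection_frac = 0.05,
                              max_missing = 0.2, min_variance = 1e-4,
                              drop_sex_chromosomes = TRUE,
                              exclude = character()) {
  structure(as.list(environment()), class = "filter_thresholds")
}

#' Filter CpG probes by quality rules
#'
#' Rules are applied sequentially in a fixed, reported order: exclusion list,
#' detection p-value, missingness, sex chromosomes, variance. Each rule's
#' removals are counted so that removals plus survivors partition the input.
#'
#' @param matrix A [methylation_matrix()].
#' @param manifest Probe manifest tibble (needed for the sex-chromosome rule).
#' @param qc Optional detection p-value matrix aligned with `matrix`.
#' @param thresholds A [filter_thresholds()].
#' @return List with `matrix` (filtered) and `report`, a tibble with one row
#'   per rule (`rule`, `removed`) plus attributes `survivors` and
#'   `thresholds`.
#' @export
filter_probes <- function(matrix, manifest, qc = NULL,
                          thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  keep <- rownames(matrix)
  removed <- c(exclusion_list = 0L, detection_p = 0L, missingness = 0L,
               sex_chromosomes = 0L, variance = 0L)

  drop_rule <- function(keep, drop_ids, rule) {
    removed[rule] <<- length(drop_ids)
    setdiff(keep, drop_ids)
  }

  keep <- drop_rule(keep, intersect(keep, thresholds$exclude), "exclusion_list")

  if (is.null(qc)) {
    warn("no detection p-values supplied; detection-p rule skipped.")
  } else {
    q <- qc[keep, colnames(matrix), drop = FALSE]
    frac_fail <- rowMeans(q > thresholds$detection_p, na.rm = TRUE)
    keep <- drop_rule(keep, keep[frac_fail > thresholds$detection_frac], "detection_p")
  }

  v <- unclass(matrix)
  miss <- rowMeans(is.na(v[keep, , drop = FALSE]))
  keep <- drop_rule(keep, keep[miss > thresholds$max_missing], "missingness")

  if (thresholds$drop_sex_chromosomes) {
    sex_probes <- manifest$probe_id[manifest$chrom %in% c("chrX", "chrY", "X", "Y")]
    keep <- drop_rule(keep, intersect(keep, sex_probes), "sex_chromosomes")
  }

  pv <- apply(v[keep, , drop = FALSE], 1, var, na.rm = TRUE)
  keep <- drop_rule(keep, keep[!is.finite(pv) | pv < thresholds$min_variance], "variance")

  if (!length(keep)) abort("no probes survive filtering; relax the thresholds.")

  out <- methylation_matrix(v[keep, , drop = FALSE], scale = value_scale(matrix))
  report <- tibble(rule = names(removed), removed = as.integer(removed))
  attr(report, "survivors") <- keep
  attr(report, "thresholds") <- thresholds
  list(matrix = out, report = report)
}

#' Predict sample sex from methylation
#'
#' Summarises each sample by its median M value over chrX probes and the
#' fraction of chrY probes above a signal floor, combines the two into one
#' score, and splits the cohort by 2-class 1-D k-means. Samples closer than
#' `margin` (as a fraction of the between-centre gap) to the class boundary
#' are labelled undetermined. XX-like samples show intermediate X methylation
#' and no Y signal; XY-like samples show shifted X methylation and present Y
#' probes.
#'
#' @param matrix An M-scale [methylation_matrix()].
#' @param manifest Probe manifest with `chrom`.
#' @param y_floor M-value floor above which a Y probe counts as present.
#' @param margin Undetermined half-band, fraction of the centre gap.
#' @return Tibble with `sample_id`, `predicted_sex` in
#'   `c("XX-like", "XY-like", "undetermined")`, and the two summary
#'   statistics.
#' @export
predict_sex <- function(matrix, manifest, y_floor = -2, margin = 0.1) {
  x_probes <- intersect(rownames(matrix),
                        manifest$probe_id[manifest$chrom %in% c("chrX", "X")])
  y_probes <- intersect(rownames(matrix),
                        manifest$probe_id[manifest$chrom %in% c("chrY", "Y")])
  if (!length(x_probes) || !length(y_probes)) {
    abort("sex prediction needs both chrX and chrY probes in the matrix.")
  }
  v <- unclass(matrix)
  med_x <- apply(v[x_probes, , drop = FALSE], 2, median, na.rm = TRUE)
  frac_y <- colMeans(v[y_probes, , drop = FALSE] > y_floor, na.rm = TRUE)
  score <- as.numeric(scale(frac_y)) - as.numeric(scale(med_x))
  km <- kmeans(score, centers = range(score))
  centers <- as.numeric(km$centers)
  xy_cluster <- which.max(vapply(1:2, function(i) mean(frac_y[km$cluster == i]), 0))
  boundary <- mean(centers)
  gap <- abs(diff(centers))
  label <- ifelse(km$cluster == xy_cluster, "XY-like", "XX-like")
  label[abs(score - boundary) < margin * gap] <- "undetermined"
  tibble(sample_id = colnames(matrix), predicted_sex = label,
         median_x_m = med_x, frac_y_detected = frac_y)
}

#' Estimate cell-type proportions by constrained least squares
#'
#' Solves, per sample, a nonnegative least-squares fit of the sample's M
#' values on reference cell-type profiles, with the sum-to-one constraint
#' imposed through a heavily weighted augmentation row; proportions are then
#' renormalised to sum to exactly 1.
#'
#' @param matrix An M-scale [methylation_matrix()].
#' @param reference Probes x cell-types numeric matrix of baseline M
#'   profiles; rownames are probe ids, all present in `matrix`.
#' @return Tibble with `sample_id` and one proportion column per cell type.
#' @export
estimate_cell_proportions <- function(matrix, reference) {
  if (is.null(rownames(reference)) || ncol(reference) < 2) {
    abort("`reference` must have probe rownames and >= 2 cell-type columns.")
  }
  absent <- setdiff(rownames(reference), rownames(matrix))
  if (length(absent)) {
    abort(paste0("reference probes absent from matrix: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  v <- unclass(matrix)[rownames(reference), , drop = FALSE]
  lambda <- 1e3 * max(1, max(abs(reference)))
  props <- apply(v, 2, function(x) {
    ok <- !is.na(x)
    fit <- pracma::lsqnonneg(rbind(reference[ok, , drop = FALSE],
                                   rep(lambda, ncol(reference))),
                             c(x[ok], lambda))
    p <- fit$x
    if (sum(p) == 0) p <- rep(1 / length(p), length(p)) else p <- p / sum(p)
    p
  })
  props <- t(props)
  colnames(props) <- colnames(reference)
  out <- as_tibble(props)
  dplyr::bind_cols(tibble(sample_id = colnames(matrix)), out)
}

#' Principal-component diagnostic of the cluster inputs
#'
#' Computes the top `k` principal components of the cluster-averaged matrix
#' (samples as observations) and the Pearson correlation, with test p-value,
#' of every numeric survey variable against each PC. Used to check that age,
#' lifestyle and technical structure is visible in the model inputs before
#' training.
#'
#' @param cluster_matrix Clusters x samples matrix from [average_clusters()].
#' @param survey Survey tibble aligned by `sample_id`.
#' @param k Number of components (default 18).
#' @return List with `scores` (samples x k matrix), `sdev`, and `correlations`
#'   (tibble: `variable`, `pc`, `r`, `p_value`).
#' @export
pca_diagnostic <- function(cluster_matrix, survey, k = 18) {
  x <- t(unclass(cluster_matrix))
  if (k > min(dim(x)) - 1) abort("`k` exceeds the rank of the matrix.")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  survey <- survey[match(rownames(x), survey$sample_id), ]
  num_vars <- names(survey)[vapply(survey, is.numeric, TRUE)]
  num_vars <- setdiff(num_vars, "sample_id")
  tab <- purrr::map_dfr(num_vars, function(vn) {
    v <- survey[[vn]]
    if (sd(v, na.rm = TRUE) == 0 || all(is.na(v))) return(NULL)
    purrr::map_dfr(seq_len(k), function(j) {
      ct <- suppressWarnings(stats::cor.test(v, scores[, j]))
      tibble(variable = vn, pc = j, r = unname(ct$estimate), p_value = ct$p.value)
    })
  })
  list(scores = scores, sdev = pc$sdev, correlations = tab)
}
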