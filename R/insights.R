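#' Age-binned methylation trajectories
#'
#' Bins samples into `n_bins` equal-width chronological age bins over the
#' observed range and computes, per CpG (or cluster) and bin, the mean or the
#' variance of the methylation values, plus the Pearson correlation of that
#' statistic against the bin midpoints — a per-CpG trajectory summary across
#' the lifespan.
#'
#' @param matrix A [methylation_matrix()] (probes or clusters x samples).
#' @param ages Chronological ages aligned with columns.
#' @param n_bins Number of bins (default 15).
#' @param statistic `"mean"` or `"variance"`.
#' @return An object of class `bin_profile`: list with `bin_edges`,
#'   `midpoints`, `stat` (features x bins matrix) and `correlations` (tibble
#'   `probe_id`, `r`; NA when the trajectory is constant).
#' @export
binned_profile <- function(matrix, ages, n_bins = 15,
                           statistic = c("mean", "variance")) {
  statistic <- match.arg(statistic)
  edges <- seq(min(ages), max(ages), length.out = n_bins + 1)
  bin <- cut(ages, edges, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, n_bins)
  min_n <- if (statistic == "variance") 3 else 2
  if (any(counts < min_n)) {
    abort(sprintf("bin %d holds %d sample(s) (< %d); use fewer bins.",
                  which(counts < min_n)[1], min(counts), min_n))
  }
  v <- unclass(matrix)
  stat <- vapply(seq_len(n_bins), function(b) {
    cols <- v[, bin == b, drop = FALSE]
    if (statistic == "mean") rowMeans(cols, na.rm = TRUE)
    else apply(cols, 1, var, na.rm = TRUE)
  }, numeric(nrow(v)))
  if (is.null(dim(stat))) stat <- matrix(stat, nrow = 1)
  rownames(stat) <- rownames(v)
  mid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  r <- apply(stat, 1, function(s) {
    if (anyNA(s) || sd(s) == 0) NA_real_ else cor(s, mid)
  })
  structure(list(bin_edges = edges, midpoints = mid, stat = stat,
                 statistic = statistic,
                 correlations = tibble(probe_id = rownames(v), r = unname(r))),
            class = "bin_profile")
}

#' Select CpGs by trajectory correlation windows
#'
#' Returns the CpG sets whose absolute trajectory correlation falls inside
#' each window. Defaults pick the moderately correlated (|r| near 0.5) and
#' strongly correlated (|r| near 1) sets used for heatmap construction;
#' variance trajectories conventionally use a single window (0.5, 1\].
#'
#' @param profile A [binned_profile()] result.
#' @param windows List of 2-vectors, |r| intervals (inclusive).
#' @return Named list of character vectors of probe ids (possibly empty).
#' @export
select_by_correlation <- function(profile,
                                  windows = list(mid = c(0.45, 0.55),
                                                 high = c(0.95, 1.0))) {
  stopifnot(inherits(profile, "bin_profile"))
  if (is.null(names(windows))) {
    names(windows) <- paste0("window", seq_along(windows))
  }
  r <- profile$correlations
  lapply(windows, function(w) {
    r$probe_id[!is.na(r$r) & abs(r$r) >= w[1] & abs(r$r) <= w[2]]
  })
}

#' Top-correlated feature sets per factor and their overlap
#'
#' For each factor, takes the `top_n` features (CpGs or clusters) by absolute
#' Pearson correlation with the factor across samples, and computes the
#' pairwise intersection sizes — revealing whether factors track unique or
#' shared methylation signals.
#'
#' @param matrix Features x samples matrix.
#' @param survey Survey tibble aligned by `sample_id` with the factor columns.
#' @param factors Columns of `survey` to correlate (numeric).
#' @param top_n Set size (default 100); capped at the feature count with a
#'   warning.
#' @return List with `top_sets` (named list of probe-id vectors), `overlap`
#'   (symmetric factors x factors integer matrix) and `correlations`
#'   (features x factors matrix).
#' @export
factor_correlation_overlap <- function(matrix, survey, factors, top_n = 100) {
  survey <- survey[match(colnames(matrix), survey$sample_id), ]
  fmat <- as.matrix(survey[, factors])
  if (any(apply(fmat, 2, sd, na.rm = TRUE) == 0)) {
    abort("factors must have nonzero variance.")
  }
  v <- unclass(matrix)
  if (top_n > nrow(v)) {
    warn("`top_n` exceeds the feature count; capped.")
    top_n <- nrow(v)
  }
  cors <- cor(t(v), fmat, use = "pairwise.complete.obs")
  top_sets <- lapply(seq_along(factors), function(j) {
    rownames(v)[order(-abs(cors[, j]))[seq_len(top_n)]]
  })
  names(top_sets) <- factors
  k <- length(factors)
  ov <- matrix(0L, k, k, dimnames = list(factors, factors))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ov[i, j] <- length(intersect(top_sets[[i]], top_sets[[j]]))
  }
  list(top_sets = top_sets, overlap = ov, correlations = cors)
}

#' Genomic-context enrichment of a CpG set
#'
#' Tests, per island-relation category (Island, Shore, Shelf, OpenSea),
#' whether the CpG set is enriched relative to the background via a two-sided
#' Fisher's exact test on the 2x2 table (in set x in category, against the
#' background excluding the set). Odds ratios are the sample odds ratios;
#' p-values are BH-adjusted across the four categories.
#'
#' @param cpg_set Character vector, subset of `background_set`.
#' @param background_set Character vector of background probe ids.
#' @param manifest Probe manifest annotating every probe involved.
#' @return Tibble with `category`, counts, `odds_ratio`, `p_value`,
#'   `q_value`. Categories empty in both set and rest give NA odds ratios.
#' @export
context_enrichment <- function(cpg_set, background_set, manifest) {
  if (length(setdiff(cpg_set, background_set))) {
    abort("`cpg_set` must be a subset of `background_set`.")
  }
  unann <- setdiff(background_set, manifest$probe_id)
  if (length(unann)) {
    abort(paste0("unannotated probe(s): ", paste(head(unann, 5), collapse = ", ")))
  }
  rel <- setNames(manifest$island_relation, manifest$probe_id)
  rest <- setdiff(background_set, cpg_set)
  rows <- purrr::map_dfr(ISLAND_LEVELS, function(cat) {
    a <- sum(rel[cpg_set] == cat)
    b <- length(cpg_set) - a
    c_ <- sum(rel[rest] == cat)
    d <- length(rest) - c_
    if ((a + c_) == 0) {
      return(tibble(category = cat, set_in = a, set_out = b,
                    bg_in = c_, bg_out = d,
                    odds_ratio = NA_real_, p_value = NA_real_))
    }
    or <- (a * d) / (b * c_)
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    tibble(category = cat, set_in = a, set_out = b, bg_in = c_, bg_out = d,
           odds_ratio = or, p_value = p)
  })
  rows$q_value <- bh_fdr(rows$p_value)
  rows
}

#' Differentially variable CpGs between delta-age extremes
#'
#' Given the samples in a low delta-age group (conventionally < -5 years) and
#' a high group (> +5 years), tests each CpG for a difference in variance
#' between the groups with a two-sided F-test on the variance ratio, with BH
#' adjustment across CpGs.
#'
#' @param matrix A [methylation_matrix()].
#' @param low_ids,high_ids Sample ids of the two groups (>= 3 each).
#' @return Tibble with `probe_id`, `var_low`, `var_high`, `f_statistic`
#'   (var_high / var_low), `p_value`, `q_value`, `direction` (which group is
#'   more variable). Zero variance in both groups gives NA.
#' @export
differential_variability <- function(matrix, low_ids, high_ids) {
  if (length(low_ids) < 3 || length(high_ids) < 3) {
    abort("both groups need >= 3 samples.")
  }
  v <- unclass(matrix)
  lo <- v[, low_ids, drop = FALSE]
  hi <- v[, high_ids, drop = FALSE]
  var_lo <- apply(lo, 1, var, na.rm = TRUE)
  var_hi <- apply(hi, 1, var, na.rm = TRUE)
  n_lo <- rowSums(!is.na(lo))
  n_hi <- rowSums(!is.na(hi))
  f <- var_hi / var_lo
  p <- rep(NA_real_, length(f))
  ok <- is.finite(f) & f > 0
  pf_hi <- pf(f[ok], n_hi[ok] - 1, n_lo[ok] - 1)
  p[ok] <- 2 * pmin(pf_hi, 1 - pf_hi)
  p[ok] <- pmin(p[ok], 1)
  tibble(probe_id = rownames(v), var_low = var_lo, var_high = var_hi,
         f_statistic = f, p_value = p, q_value = bh_fdr(p),
         direction = dplyr::case_when(
           is.na(p) ~ NA_character_,
           var_hi > var_lo ~ "high_delta",
           TRUE ~ "low_delta"
         ))
}

#' Split samples into delta-age extreme groups
#'
#' @param predictions Tibble with `sample_id` and `delta_age`.
#' @param low Threshold for the low group (default -5 years).
#' @param high Threshold for the high group (default +5 years).
#' @return List with `low_ids` (delta < `low`) and `high_ids`
#'   (delta > `high`).
#' @export
delta_age_groups <- function(predictions, low = -5, high = 5) {
  list(low_ids = predictions$sample_id[predictions$delta_age < low],
       high_ids = predictions$sample_id[predictions$delta_age > high])
}
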