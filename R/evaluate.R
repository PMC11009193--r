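#' Clock evaluation metrics
#'
#' Computes the clock metric suite: RMSE and MAE of predicted versus
#' chronological age; R2 as the squared Pearson correlation; MAB (mean
#' absolute bias), the mean absolute deviation of the least-squares
#' prediction-vs-age line from the identity line, an indicator of systematic
#' age compression or expansion; and MRE (mean replicate error from the
#' mean), the mean absolute deviation of each replicate sample's prediction
#' from its replicate group's mean prediction, a test-retest reliability
#' measure.
#'
#' @param predictions Numeric vector of predicted ages.
#' @param ages Chronological ages (years).
#' @param replicate_groups Optional group ids (NA for singletons); groups of
#'   size >= 2 enter the MRE.
#' @return One-row tibble with `rmse`, `mae`, `r2`, `mab`, `mre` (NA when no
#'   replicates are given).
#' @export
compute_metrics <- function(predictions, ages, replicate_groups = NULL) {
  if (length(predictions) < 3) abort("need >= 3 samples.")
  if (length(predictions) != length(ages)) abort("length mismatch.")
  err <- predictions - ages
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  r2 <- if (sd(predictions) == 0 || sd(ages) == 0) {
    warn("zero variance in predictions or ages; R2 undefined.")
    NA_real_
  } else cor(predictions, ages)^2
  fit <- lm(predictions ~ ages)
  mab <- mean(abs(stats::fitted(fit) - ages))
  mre <- NA_real_
  if (!is.null(replicate_groups)) {
    grp <- as.character(replicate_groups)
    keep <- !is.na(grp) & grp %in% names(which(table(grp) >= 2))
    if (any(keep)) {
      gm <- tapply(predictions[keep], grp[keep], mean)
      mre <- mean(abs(predictions[keep] - gm[grp[keep]]))
    }
  }
  tibble(rmse = rmse, mae = mae, r2 = r2, mab = mab, mre = mre)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1 and
#' mapped back to input order. q-values are never below the input p and are
#' monotone in p rank.
#'
#' @param pvalues Numeric vector in \[0, 1\] (NA allowed, passed through).
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- pvalues[!is.na(pvalues)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Multivariate delta-age association model
#'
#' Models delta age as a linear combination of all supplied lifestyle/health,
#' demographic, technical and cell-composition covariates, so each factor's
#' significance is estimated with all other factors held constant. Categorical
#' covariates are one-hot encoded against a first-level reference; aliased
#' columns are dropped with a warning. Two-sided t-test per coefficient,
#' BH-adjusted across the tested variables. Under healthy-lifestyle coding,
#' protective factors are expected to carry negative coefficients.
#'
#' @param delta Numeric vector of delta ages (predicted - chronological).
#' @param covariates Data frame of covariates, one row per sample.
#' @return Tibble of class `delta_age_fit` with `variable`, `estimate`,
#'   `std_error`, `p_value`, `q_value`.
#' @export
delta_age_model <- function(delta, covariates) {
  covariates <- as.data.frame(covariates)
  chr <- vapply(covariates, function(x) is.character(x) || is.logical(x), TRUE)
  covariates[chr] <- lapply(covariates[chr], function(x) factor(x, levels = sort(unique(x))))
  if (length(delta) <= ncol(stats::model.matrix(~ ., covariates))) {
    abort("more covariate columns than samples.")
  }
  dat <- cbind(data.frame(.delta = delta), covariates)
  fit <- lm(.delta ~ ., data = dat)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased)) {
    warn(paste0("dropped aliased column(s): ", paste(aliased, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  out <- tibble(variable = rownames(sm), estimate = sm[, 1],
                std_error = sm[, 2], p_value = sm[, 4],
                q_value = bh_fdr(sm[, 4]))
  class(out) <- c("delta_age_fit", class(out))
  out
}

#' Elastic-net baseline clock with cross-validation
#'
#' The first-generation comparator: a penalized linear regression of age on
#' the cluster averages, trained per outer fold with the penalty chosen by
#' inner cross-validation, producing out-of-fold predictions and per-factor
#' delta-age correlation p/q values. The annealed clock's lifestyle advantage
#' is demonstrated against this head-to-head.
#'
#' @param cluster_matrix Clusters x samples matrix.
#' @param ages Chronological ages.
#' @param survey Survey tibble.
#' @param folds Outer folds (default 10), replicate-aware.
#' @param alpha Elastic-net mixing parameter (1 = lasso).
#' @param factors Factors for the delta-age correlation report.
#' @param seed Integer seed.
#' @return List with `predictions` (tibble: `sample_id`, `fold`, `age`,
#'   `predicted_age`, `delta_age`), `metrics` (from [compute_metrics()]) and
#'   `associations` (tibble: `factor`, `p_value`, `q_value`).
#' @export
baseline_penalized_cv <- function(cluster_matrix, ages, survey, folds = 10,
                                  alpha = 0.5,
                                  factors = lifestyle_factor_names(),
                                  seed = 1) {
  survey <- survey[match(colnames(cluster_matrix), survey$sample_id), ]
  x <- t(unclass(cluster_matrix))
  pred <- rep(NA_real_, nrow(x))
  with_rng_seed(seed, {
    fold_id <- assign_folds(survey, folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      cvfit <- glmnet::cv.glmnet(x[!test, , drop = FALSE], ages[!test],
                                 alpha = alpha)
      pred[test] <- drop(predict(cvfit, x[test, , drop = FALSE],
                                 s = "lambda.min"))
    }
  })
  delta <- pred - ages
  assoc <- delta_age_pvalues(delta, survey, factors)
  assoc$q_value <- bh_fdr(assoc$p_value)
  rg <- if ("replicate_group" %in% names(survey)) survey$replicate_group else NULL
  list(
    predictions = tibble(sample_id = colnames(cluster_matrix), fold = fold_id,
                         age = ages, predicted_age = pred, delta_age = delta),
    metrics = compute_metrics(pred, ages, rg),
    associations = assoc
  )
}
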