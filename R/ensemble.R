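#' Build a weighted ensemble clock from annealed models
#'
#' Models are sorted by total score (ascending; lower is better) and the top
#' `top_k` retained. Model i gets weight proportional to
#' `(S_worst_retained - S_i + eps)` with `eps = 1e-9 * |S_worst_retained|`,
#' normalised to sum to 1, so a strictly lower score always earns a strictly
#' higher weight; when all retained scores are equal the weights are uniform.
#' Training-set cluster means are stored for prediction-time imputation.
#'
#' @param models List of `clock_model` objects (from [train_many()]).
#' @param top_k Number of models to retain (default 100).
#' @param cluster_matrix Optional training clusters x samples matrix; if
#'   given, per-cluster training means are stored for imputation.
#' @return An `ensemble_clock`.
#' @export
build_ensemble <- function(models, top_k = 100, cluster_matrix = NULL) {
  if (top_k <= 0 || top_k > length(models)) {
    abort("`top_k` must be in 1..length(models).")
  }
  scores <- vapply(models, function(m) m$total_score, numeric(1))
  ord <- order(scores)
  keep <- ord[seq_len(top_k)]
  s <- scores[keep]
  worst <- max(s)
  eps <- 1e-9 * abs(worst)
  w <- worst - s + eps
  w <- if (sum(w) == 0) rep(1 / top_k, top_k) else w / sum(w)
  cluster_means <- NULL
  if (!is.null(cluster_matrix)) {
    used <- unique(unlist(lapply(models[keep], function(m) m$cluster_ids)))
    cluster_means <- rowMeans(unclass(cluster_matrix)[used, , drop = FALSE],
                              na.rm = TRUE)
  }
  structure(list(models = models[keep], ensemble_weights = w, rotation = NULL,
                 cluster_means = cluster_means,
                 provenance = list(n_candidates = length(models),
                                   seeds = vapply(models[keep],
                                                  function(m) m$train_seed,
                                                  numeric(1)))),
            class = "ensemble_clock")
}

#' @export
print.ensemble_clock <- function(x, ...) {
  cat(sprintf("<ensemble_clock> %d models, %s rotation\n",
              length(x$models), if (is.null(x$rotation)) "no" else "fitted"))
  invisible(x)
}

# per-model raw predictions, samples x models
member_predictions <- function(clock, cluster_matrix) {
  v <- unclass(cluster_matrix)
  used <- unique(unlist(lapply(clock$models, function(m) m$cluster_ids)))
  absent <- setdiff(used, rownames(v))
  have_means <- !is.null(clock$cluster_means)
  if (length(absent) && (!have_means || length(setdiff(absent, names(clock$cluster_means))))) {
    abort(paste0("cluster(s) absent with no stored training mean: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  x <- matrix(NA_real_, length(used), ncol(v), dimnames = list(used, colnames(v)))
  present <- intersect(used, rownames(v))
  x[present, ] <- v[present, ]
  if (have_means) {
    for (cl in used) {
      nas <- is.na(x[cl, ])
      if (any(nas)) x[cl, nas] <- clock$cluster_means[[cl]]
    }
  }
  if (anyNA(x)) abort("missing cluster values and no stored training means.")
  vapply(clock$models, function(m) {
    drop(t(x[m$cluster_ids, , drop = FALSE]) %*% m$weights) + m$intercept
  }, numeric(ncol(x)))
}

#' Predict ages with an ensemble clock
#'
#' The raw prediction is the ensemble-weighted mean of the member models'
#' linear outputs; the age-bias rotation is applied when the clock carries
#' one. Missing cluster values are imputed with the stored training means.
#'
#' @param object An `ensemble_clock`.
#' @param cluster_matrix Clusters x samples matrix on the M scale.
#' @param ages Optional chronological ages (to fill `delta_age`).
#' @param ... Unused.
#' @return Tibble with `sample_id`, `raw_age`, `predicted_age` and, when ages
#'   are given, `delta_age = predicted_age - age`.
#' @export
predict.ensemble_clock <- function(object, cluster_matrix, ages = NULL, ...) {
  preds <- member_predictions(object, cluster_matrix)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)  # single sample
  raw <- unname(drop(preds %*% object$ensemble_weights))
  corrected <- if (!is.null(object$rotation)) apply_rotation(raw, object$rotation) else raw
  out <- tibble(sample_id = colnames(cluster_matrix),
                raw_age = raw, predicted_age = corrected)
  if (!is.null(ages)) out$delta_age <- out$predicted_age - ages
  out
}

#' Fit the age-bias rotation
#'
#' Regresses raw predictions on chronological age, `raw = a * age + b`; the
#' corrected prediction `(raw - b) / a` then regresses on age with slope 1 and
#' intercept 0 on the training set, removing systematic age compression or
#' expansion.
#'
#' @param raw Raw predictions (years).
#' @param ages Chronological ages.
#' @return List with `slope` and `intercept`.
#' @export
fit_rotation <- function(raw, ages) {
  if (length(raw) < 3) abort("rotation needs >= 3 samples with known age.")
  fit <- lm(raw ~ ages)
  a <- unname(coef(fit)[2])
  if (!is.finite(a) || abs(a) < 1e-6) abort("degenerate clock: fitted slope ~ 0.")
  list(slope = a, intercept = unname(coef(fit)[1]))
}

#' Apply an age-bias rotation
#' @param raw Raw predictions.
#' @param rotation List with `slope`, `intercept` (from [fit_rotation()]).
#' @return Corrected predictions.
#' @export
apply_rotation <- function(raw, rotation) {
  (raw - rotation$intercept) / rotation$slope
}

#' Attach a rotation to an ensemble clock
#' @param clock An `ensemble_clock`.
#' @param cluster_matrix Training clusters x samples matrix.
#' @param ages Training chronological ages.
#' @return The clock with `rotation` fitted on its raw training predictions.
#' @export
calibrate_rotation <- function(clock, cluster_matrix, ages) {
  raw <- predict(clock, cluster_matrix)$raw_age
  clock$rotation <- fit_rotation(raw, ages)
  clock
}

# replicate-aware fold assignment: whole replicate groups stay together
assign_folds <- function(survey, folds) {
  grp <- survey$replicate_group
  if (is.null(grp)) grp <- rep(NA_character_, nrow(survey))
  grp[is.na(grp)] <- paste0("solo_", survey$sample_id[is.na(grp)])
  groups <- sample(unique(grp))
  fold_of_group <- setNames(rep(seq_len(folds), length.out = length(groups)), groups)
  unname(fold_of_group[grp])
}

#' Replicate-aware tenfold cross-validation of the annealed ensemble
#'
#' Per fold: train `models_per_fold` annealed models on the training split,
#' combine them into a fold ensemble, fit the age-bias rotation on the
#' training split, and predict the held-out samples. Samples sharing a
#' replicate group are always assigned to the same fold, so test-retest pairs
#' never straddle the train/test boundary.
#'
#' @param cluster_matrix Clusters x samples matrix.
#' @param ages Chronological ages aligned with columns.
#' @param survey Survey tibble (factors + optional `replicate_group`).
#' @param folds Number of folds (default 10).
#' @param models_per_fold Annealed models per fold ensemble (default 12).
#' @param config An [anneal_config()].
#' @param seed Integer seed controlling fold assignment and training.
#' @return List with `predictions` (one out-of-fold row per sample:
#'   `sample_id`, `fold`, `age`, `raw_age`, `predicted_age`, `delta_age`) and
#'   `fold_models` (list of fold ensembles).
#' @export
cross_validate <- function(cluster_matrix, ages, survey, folds = 10,
                           models_per_fold = 12, config = anneal_config(),
                           seed = 1) {
  if (folds < 2) abort("`folds` must be >= 2.")
  survey <- survey[match(colnames(cluster_matrix), survey$sample_id), ]
  fold_id <- with_rng_seed(seed, assign_folds(survey, folds))
  min_needed <- config$max_size + 2
  v <- unclass(cluster_matrix)
  preds <- vector("list", folds)
  fold_models <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (sum(test) < 1) next
    if (sum(!test) < min_needed) {
      abort(sprintf("fold %d leaves only %d training samples (< max model size + 2).",
                    f, sum(!test)))
    }
    tr_mat <- structure(v[, !test, drop = FALSE], scale = "m",
                        class = class(cluster_matrix))
    te_mat <- structure(v[, test, drop = FALSE], scale = "m",
                        class = class(cluster_matrix))
    models <- train_many(tr_mat, ages[!test], survey[!test, ], config,
                         n_models = models_per_fold,
                         base_seed = seed * 1000 + f * 100)
    clock <- build_ensemble(models, top_k = models_per_fold,
                            cluster_matrix = tr_mat)
    clock <- calibrate_rotation(clock, tr_mat, ages[!test])
    fold_models[[f]] <- clock
    p <- predict(clock, te_mat, ages = ages[test])
    p$fold <- f
    p$age <- ages[test]
    preds[[f]] <- p
  }
  predictions <- dplyr::bind_rows(preds)
  predictions <- predictions[match(colnames(cluster_matrix), predictions$sample_id), ]
  list(predictions = as_tibble(predictions), fold_models = fold_models)
}

#' Tidy an ensemble clock
#' @param x An `ensemble_clock`.
#' @param ... Unused.
#' @return Tibble with one row per member model: rank, weight, score
#'   components.
#' @export
tidy.ensemble_clock <- function(x, ...) {
  dplyr::bind_cols(
    tibble(rank = seq_along(x$models), ensemble_weight = x$ensemble_weights),
    purrr::map_dfr(x$models, glance)
  )
}

#' One-row summary of an ensemble clock
#' @param x An `ensemble_clock`.
#' @param ... Unused.
#' @return Tibble with model count, score range, rotation parameters.
#' @export
glance.ensemble_clock <- function(x, ...) {
  s <- vapply(x$models, function(m) m$total_score, numeric(1))
  tibble(n_models = length(x$models), best_score = min(s), worst_score = max(s),
         rotation_slope = x$rotation$slope %||% NA_real_,
         rotation_intercept = x$rotation$intercept %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
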