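#' Annealing configuration
#'
#' Hyperparameters for the simulated-annealing subset search. The objective is
#' a lower-is-better weighted sum: `w_rmse` x RMSE (years) + `w_sig` x sum of
#' log10 delta-age association p-values over `factors` (negative when
#' associations are significant) + `w_cplx` x number of selected clusters.
#'
#' @param w_rmse,w_sig,w_cplx Objective weights (defaults 1, 0.2, 0.01).
#' @param factors Lifestyle/health factors entering the significance term.
#' @param sig_partial_age If `TRUE` (default), the significance term uses
#'   partial correlations of delta age with each factor given chronological
#'   age. An unadjusted test lets a deliberately inaccurate clock score well:
#'   its delta tracks minus age and therefore "correlates" with every
#'   age-correlated factor. Age-adjusting closes that channel while leaving
#'   genuine lifestyle signal in the prediction untouched.
#' @param p_floor Saturation floor for per-factor p-values inside the
#'   objective (default 1e-10): each factor contributes at most
#'   `-log10(p_floor)` to the significance term. Without a floor the term is
#'   unbounded and the search can profitably destroy the clock's accuracy to
#'   push one association toward machine zero.
#' @param iterations Number of proposal steps.
#' @param t0 Initial temperature; `NULL` auto-calibrates so that about 80%
#'   of worsening moves would be accepted over a 100-proposal warm-up.
#' @param cooling Geometric cooling factor in (0, 1), applied per iteration.
#' @param t_min Temperature floor.
#' @param move_probs Probabilities of add / drop / swap proposals (sum to 1).
#' @param max_size Maximum number of clusters in a model.
#' @param init_size Size of the random starting subset.
#' @return A list of class `anneal_config`.
#' @export
anneal_config <- function(w_rmse = 1, w_sig = 0.2, w_cplx = 0.01,
                          factors = lifestyle_factor_names(),
                          sig_partial_age = TRUE, p_floor = 1e-10,
                          iterations = 2000, t0 = NULL, cooling = 0.995,
                          t_min = 1e-8,
                          move_probs = c(add = 1/3, drop = 1/3, swap = 1/3),
                          max_size = 15, init_size = 3) {
  if (cooling <= 0 || cooling >= 1) abort("`cooling` must lie in (0, 1).")
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (abs(sum(move_probs) - 1) > 1e-8 || any(move_probs < 0)) {
    abort("`move_probs` must be nonnegative and sum to 1.")
  }
  if (p_floor <= 0 || p_floor > 1) abort("`p_floor` must lie in (0, 1].")
  structure(as.list(environment()), class = "anneal_config")
}

# least squares with minimum-norm fallback under rank deficiency
ls_fit <- function(design, y) {
  qd <- qr(design)
  if (qd$rank == ncol(design)) {
    qr.coef(qd, y)
  } else {
    warn("rank-deficient design; using minimum-norm pseudo-inverse solution.")
    sv <- svd(design)
    pos <- sv$d > max(dim(design)) * .Machine$double.eps * sv$d[1]
    drop(sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
  }
}

#' Fit linear age-model weights on a cluster subset
#'
#' Ordinary least squares of chronological age on the selected cluster
#' averages. Deterministic; rank-deficient designs are solved by the
#' minimum-norm pseudo-inverse with a warning.
#'
#' @param x Clusters x samples matrix restricted to the selected clusters.
#' @param ages Chronological ages, one per sample.
#' @return List with `weights` (named per cluster) and `intercept` (years).
#' @export
fit_weights <- function(x, ages) {
  xs <- t(unclass(x))
  if (anyNA(xs)) abort("restricted cluster matrix must have no missing values.")
  if (nrow(xs) <= ncol(xs) + 1) abort("need n_samples > subset size + 1.")
  beta <- ls_fit(cbind(1, xs), ages)
  list(weights = setNames(beta[-1], rownames(x)), intercept = unname(beta[1]))
}

# vectorised two-sided Pearson correlation test of `delta` against each
# column of `fmat`, pairwise complete; zero-variance factors give p = 1
pearson_pvalues <- function(delta, fmat) {
  p <- vapply(seq_len(ncol(fmat)), function(j) {
    f <- fmat[, j]
    ok <- !is.na(f) & !is.na(delta)
    n <- sum(ok)
    if (n < 3) return(NA_real_)
    if (sd(f[ok]) == 0 || sd(delta[ok]) == 0) {
      warn("zero-variance factor in delta-age correlation; p set to 1.")
      return(1)
    }
    r <- cor(delta[ok], f[ok])
    r <- min(max(r, -1), 1)
    if (abs(r) == 1) return(1e-300)
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    max(2 * pt(-abs(tval), n - 2), 1e-300)
  }, numeric(1))
  setNames(p, colnames(fmat))
}

#' Delta-age association p-values per lifestyle factor
#'
#' Two-sided Pearson correlation test of delta age (predicted minus
#' chronological) against each factor, pairwise complete. p-values are
#' floored at 1e-300.
#'
#' @param delta Numeric vector of delta ages.
#' @param survey Survey tibble.
#' @param factors Factor column names (default the 11 lifestyle responses).
#' @return Tibble with `factor` and `p_value`.
#' @export
delta_age_pvalues <- function(delta, survey, factors = lifestyle_factor_names()) {
  miss <- setdiff(factors, names(survey))
  if (length(miss)) abort(paste0("survey lacks factor(s): ", paste(miss, collapse = ", ")))
  fmat <- as.matrix(survey[, factors])
  p <- pearson_pvalues(delta, fmat)
  tibble(factor = factors, p_value = unname(p))
}

#' Score a clock model under the multi-objective function
#'
#' Components: `rmse_term` = RMSE of the model's age prediction (years);
#' `lifestyle_term` = sum over factors of log10 delta-age association
#' p-values; `complexity_term` = number of selected clusters. The total is
#' the weighted sum under the config's weights; lower is better.
#'
#' @param model A `clock_model` (weights already fitted).
#' @param cluster_matrix Clusters x samples matrix.
#' @param ages Chronological ages.
#' @param survey Survey tibble.
#' @param config An [anneal_config()].
#' @return List with `rmse_term`, `lifestyle_term`, `complexity_term`,
#'   `total`.
#' @export
score_model <- function(model, cluster_matrix, ages, survey, config = anneal_config()) {
  if (!length(model$cluster_ids)) abort("cannot score an empty model.")
  xs <- t(unclass(cluster_matrix)[model$cluster_ids, , drop = FALSE])
  pred <- drop(xs %*% model$weights) + model$intercept
  fmat <- as.matrix(survey[, config$factors])
  score_from_pred(pred, ages, fmat, length(model$cluster_ids), config)
}

score_from_pred <- function(pred, ages, fmat, n_clusters, config) {
  rmse <- sqrt(mean((pred - ages)^2))
  delta <- pred - ages
  p <- if (isTRUE(config$sig_partial_age)) {
    partial_pvalues(delta, fmat, ages)
  } else {
    pearson_pvalues(delta, fmat)
  }
  life <- sum(log10(pmax(p, config$p_floor %||% 1e-300)), na.rm = TRUE)
  total <- config$w_rmse * rmse + config$w_sig * life + config$w_cplx * n_clusters
  list(rmse_term = rmse, lifestyle_term = life,
       complexity_term = n_clusters, total = total)
}

# two-sided test of the partial Pearson correlation of `delta` with each
# column of `fmat`, controlling for age; complete cases per factor
partial_pvalues <- function(delta, fmat, ages) {
  p <- vapply(seq_len(ncol(fmat)), function(j) {
    f <- fmat[, j]
    ok <- !is.na(f) & !is.na(delta)
    n <- sum(ok)
    if (n < 4) return(NA_real_)
    z <- ages[ok] - mean(ages[ok])
    zn2 <- sum(z^2)
    res <- function(v) {
      vc <- v - mean(v)
      if (zn2 > 0) vc - z * sum(z * vc) / zn2 else vc
    }
    fr <- res(f[ok])
    dr <- res(delta[ok])
    if (sum(fr^2) == 0 || sum(dr^2) == 0) return(1)
    r <- sum(fr * dr) / sqrt(sum(fr^2) * sum(dr^2))
    r <- min(max(r, -1), 1)
    if (abs(r) == 1) return(1e-300)
    tval <- r * sqrt(n - 3) / sqrt(1 - r^2)
    max(2 * pt(-abs(tval), n - 3), 1e-300)
  }, numeric(1))
  setNames(p, colnames(fmat))
}

#' Simulated-annealing acceptance rule
#'
#' Improving or equal moves (`delta_score <= 0`) are always accepted;
#' worsening moves are accepted with probability `exp(-delta_score / temp)`.
#'
#' @param delta_score Proposed score minus current score (lower is better).
#' @param temp Current temperature (> 0).
#' @return Logical.
#' @export
anneal_accept <- function(delta_score, temp) {
  delta_score <= 0 || runif(1) < exp(-delta_score / temp)
}

new_clock_model <- function(ids, weights, intercept, comps, seed) {
  structure(list(cluster_ids = ids, weights = weights, intercept = intercept,
                 score_components = comps[c("rmse_term", "lifestyle_term",
                                            "complexity_term")],
                 total_score = comps$total, train_seed = seed),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %d clusters, score %.4f (rmse %.3f y, lifestyle %.2f, complexity %d)\n",
              length(x$cluster_ids), x$total_score,
              x$score_components$rmse_term, x$score_components$lifestyle_term,
              x$score_components$complexity_term))
  invisible(x)
}

#' Train one clock model by simulated annealing
#'
#' Starts from a random cluster subset and, at each iteration, proposes adding,
#' dropping or swapping one cluster, refits the linear age model by least
#' squares, rescores, and accepts by the Metropolis rule under geometric
#' cooling. Returns the best-scoring model ever visited. A fixed seed gives an
#' identical trajectory and output.
#'
#' @param cluster_matrix Clusters x samples matrix ([average_clusters()]).
#' @param ages Chronological ages aligned with the matrix columns.
#' @param survey Survey tibble (for the lifestyle significance term).
#' @param config An [anneal_config()].
#' @param seed Integer seed.
#' @param trace Keep the per-iteration score trace (attribute `"trace"`).
#' @return A `clock_model`.
#' @export
anneal <- function(cluster_matrix, ages, survey, config = anneal_config(),
                   seed = 1, trace = FALSE) {
  stopifnot(inherits(config, "anneal_config"))
  v <- unclass(cluster_matrix)
  usable <- rownames(v)[rowSums(is.na(v)) == 0]
  if (length(usable) < 2) abort("need >= 2 complete clusters to anneal.")
  v <- v[usable, , drop = FALSE]
  xs_all <- t(v)
  fmat <- as.matrix(survey[, config$factors])
  n <- length(ages)
  K <- nrow(v)
  max_size <- min(config$max_size, K, n - 2)

  # vectorised scoring (identical arithmetic to score_from_pred) when the
  # factor matrix is complete; falls back to the general path otherwise
  partial <- isTRUE(config$sig_partial_age)
  complete_f <- !anyNA(fmat)
  if (complete_f) {
    fc <- sweep(fmat, 2, colMeans(fmat))
    z <- ages - mean(ages)
    zn2 <- sum(z^2)
    if (partial && zn2 > 0) fc <- fc - z %*% crossprod(z, fc) / zn2
    nrm <- sqrt(colSums(fc^2))
    complete_f <- all(nrm > 0)
    if (complete_f) fsn <- sweep(fc, 2, nrm, "/")
    df_sig <- if (partial) n - 3 else n - 2
  }
  fast_score <- function(pred, n_sel) {
    if (!complete_f) return(score_from_pred(pred, ages, fmat, n_sel, config))
    delta <- pred - ages
    rmse <- sqrt(mean(delta^2))
    dc <- delta - mean(delta)
    if (partial && zn2 > 0) dc <- dc - z * sum(z * dc) / zn2
    dn <- sqrt(sum(dc^2))
    if (dn == 0) {
      p <- rep(1, ncol(fmat))
    } else {
      r <- pmin(pmax(drop(crossprod(fsn, dc)) / dn, -1), 1)
      p <- ifelse(abs(r) == 1, 1e-300,
                  pmax(2 * pt(-abs(r) * sqrt(df_sig) / sqrt(1 - r^2), df_sig),
                       1e-300))
    }
    life <- sum(log10(pmax(p, config$p_floor %||% 1e-300)))
    list(rmse_term = rmse, lifestyle_term = life, complexity_term = n_sel,
         total = config$w_rmse * rmse + config$w_sig * life +
           config$w_cplx * n_sel)
  }

  fit_and_score <- function(sel) {
    design <- cbind(1, xs_all[, sel, drop = FALSE])
    beta <- ls_fit(design, ages)
    pred <- drop(design %*% beta)
    comps <- fast_score(pred, length(sel))
    list(beta = beta, comps = comps)
  }

  with_rng_seed(seed, {
    sel <- sample.int(K, min(config$init_size, max_size))
    cur <- fit_and_score(sel)
    cur_score <- cur$comps$total
    best <- list(sel = sel, fit = cur)

    propose <- function(sel) {
      repeat {
        probs <- config$move_probs
        if (length(sel) >= max_size) probs["add"] <- 0
        if (length(sel) <= 1) {
          probs["drop"] <- 0
          probs["swap"] <- probs["swap"] * (length(sel) < K)
        }
        if (length(sel) >= K) {
          probs["add"] <- 0
          probs["swap"] <- 0
        }
        probs <- probs / sum(probs)
        mv <- sample(names(probs), 1, prob = probs)
        out <- switch(mv,
          add = c(sel, sample(setdiff(seq_len(K), sel), 1)),
          drop = sel[-sample.int(length(sel), 1)],
          swap = {
            s2 <- sel[-sample.int(length(sel), 1)]
            c(s2, sample(setdiff(seq_len(K), sel), 1))
          }
        )
        if (length(out)) return(sort(out))
      }
    }

    # warm-up calibration of T0: accept ~80% of worsening moves
    t0 <- config$t0
    if (is.null(t0)) {
      worse <- numeric(0)
      s <- sel
      sc <- cur_score
      for (i in seq_len(100)) {
        cand <- propose(s)
        cs <- fit_and_score(cand)$comps$total
        if (cs > sc) worse <- c(worse, cs - sc)
        s <- cand
        sc <- cs
      }
      t0 <- if (length(worse)) median(worse) / -log(0.8) else 1
      t0 <- max(t0, 1e-6)
    }

    temp <- t0
    tr <- if (trace) matrix(NA_real_, config$iterations, 4) else NULL
    best_score <- cur_score
    for (it in seq_len(config$iterations)) {
      cand <- propose(sel)
      cf <- fit_and_score(cand)
      if (anneal_accept(cf$comps$total - cur_score, temp)) {
        sel <- cand
        cur <- cf
        cur_score <- cf$comps$total
        if (cur_score < best_score) {
          best <- list(sel = sel, fit = cur)
          best_score <- cur_score
        }
      }
      if (trace) tr[it, ] <- c(it, temp, cur_score, best_score)
      temp <- max(temp * config$cooling, config$t_min)
    }

    ids <- rownames(v)[best$sel]
    model <- new_clock_model(
      ids, setNames(best$fit$beta[-1], ids), unname(best$fit$beta[1]),
      best$fit$comps, seed
    )
    if (trace) {
      colnames(tr) <- c("iteration", "temperature", "current_score", "best_score")
      attr(model, "trace") <- as_tibble(as.data.frame(tr))
    }
    model
  })
}

#' Train many annealed models
#'
#' Repeats [anneal()] with seeds `base_seed + 1, ..., base_seed + n_models`.
#' Runs are independent, so results do not depend on execution order.
#'
#' @inheritParams anneal
#' @param n_models Number of models (the production scale is 1098).
#' @param base_seed Base seed; model i uses `base_seed + i`.
#' @return List of `clock_model` objects.
#' @export
train_many <- function(cluster_matrix, ages, survey, config = anneal_config(),
                       n_models = 100, base_seed = 0) {
  if (n_models < 1) abort("`n_models` must be >= 1.")
  purrr::map(seq_len(n_models), function(i) {
    anneal(cluster_matrix, ages, survey, config, seed = base_seed + i)
  })
}

#' Tidy a clock model
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return Tibble of `cluster_id`, `weight` plus an intercept row.
#' @export
tidy.clock_model <- function(x, ...) {
  tibble(term = c("(Intercept)", x$cluster_ids),
         estimate = c(x$intercept, unname(x$weights)))
}

#' One-row summary of a clock model
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return Tibble with score components and total.
#' @export
glance.clock_model <- function(x, ...) {
  tibble(n_clusters = length(x$cluster_ids),
         rmse_term = x$score_components$rmse_term,
         lifestyle_term = x$score_components$lifestyle_term,
         complexity_term = x$score_components$complexity_term,
         total_score = x$total_score)
}
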