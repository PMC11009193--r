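ENSEMBLE_SCHEMA_VERSION <- 1L

# decimal-free float encoding: C99 hex literals round-trip IEEE doubles
# bit-exactly through text, unlike decimal JSON numbers
enc_num <- function(x) sprintf("%a", as.numeric(x))
dec_num <- function(x) as.numeric(unlist(x))

#' Save an ensemble clock to versioned JSON
#'
#' All floating-point fields are written both as ordinary decimal numbers (for
#' human auditing) and as hexadecimal float literals, a decimal-free encoding
#' that round-trips IEEE doubles bit-exactly; [load_ensemble()] restores from
#' the hex fields, so `load_ensemble(save_ensemble(x))` reproduces every field
#' exactly and predictions before and after a round trip are identical. The
#' file is self-contained: prediction needs only the loaded clock and a
#' matrix.
#'
#' @param clock An `ensemble_clock`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(clock, path) {
  stopifnot(inherits(clock, "ensemble_clock"))
  if (abs(sum(clock$ensemble_weights) - 1) > 1e-12) {
    abort("ensemble weights must sum to 1.")
  }
  obj <- list(
    schema_version = ENSEMBLE_SCHEMA_VERSION,
    ensemble_weights = round(clock$ensemble_weights, 10),
    ensemble_weights_hex = enc_num(clock$ensemble_weights),
    rotation = if (!is.null(clock$rotation)) {
      list(slope = clock$rotation$slope, intercept = clock$rotation$intercept,
           slope_hex = enc_num(clock$rotation$slope),
           intercept_hex = enc_num(clock$rotation$intercept))
    },
    cluster_mean_ids = names(clock$cluster_means),
    cluster_means_hex = if (!is.null(clock$cluster_means)) {
      enc_num(clock$cluster_means)
    },
    provenance = clock$provenance,
    models = lapply(clock$models, function(m) {
      list(cluster_ids = m$cluster_ids,
           weights = round(unname(m$weights), 10),
           weights_hex = enc_num(m$weights),
           intercept_hex = enc_num(m$intercept),
           score_components = m$score_components,
           total_score = m$total_score,
           total_score_hex = enc_num(m$total_score),
           train_seed = m$train_seed)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load an ensemble clock from JSON
#'
#' @param path Path written by [save_ensemble()].
#' @return An `ensemble_clock`.
#' @export
load_ensemble <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort(paste0("cannot load ensemble: ", conditionMessage(e)))
                  })
  ver <- obj$schema_version
  if (is.null(ver) || ver != ENSEMBLE_SCHEMA_VERSION) {
    abort(sprintf("incompatible ensemble schema version: %s (expected %d).",
                  if (is.null(ver)) "missing" else as.character(ver),
                  ENSEMBLE_SCHEMA_VERSION))
  }
  if (is.null(obj$models) || !length(obj$models)) {
    abort("ensemble file holds no models.")
  }
  models <- lapply(obj$models, function(m) {
    ids <- unlist(m$cluster_ids)
    structure(list(cluster_ids = ids,
                   weights = setNames(dec_num(m$weights_hex), ids),
                   intercept = dec_num(m$intercept_hex),
                   score_components = lapply(m$score_components, function(x) {
                     if (is.null(x)) NA_real_ else unlist(x)
                   }),
                   total_score = dec_num(m$total_score_hex),
                   train_seed = if (is.null(m$train_seed)) NA else m$train_seed),
              class = "clock_model")
  })
  cm <- if (length(obj$cluster_means_hex)) {
    setNames(dec_num(obj$cluster_means_hex), unlist(obj$cluster_mean_ids))
  } else NULL
  rot <- if (!is.null(obj$rotation)) {
    list(slope = dec_num(obj$rotation$slope_hex),
         intercept = dec_num(obj$rotation$intercept_hex))
  } else NULL
  structure(list(models = models,
                 ensemble_weights = dec_num(obj$ensemble_weights_hex),
                 rotation = rot, cluster_means = cm,
                 provenance = obj$provenance),
            class = "ensemble_clock")
}
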