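#' Construct a methylation matrix
#'
#' A methylation matrix holds one row per CpG probe and one column per sample,
#' on either the beta scale (methylated fraction, in \[0, 1\]) or the M scale
#' (logit2 of beta). Missing values are `NA`.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are used as probe/sample ids if `probe_ids`/`sample_ids`
#'   are not given.
#' @param scale Either `"beta"` or `"m"`.
#' @param probe_ids,sample_ids Optional character vectors overriding dimnames.
#'
#' @return An object of class `methylation_matrix`: a numeric matrix with a
#'   `scale` attribute.
#' @export
methylation_matrix <- function(values, scale = c("beta", "m"),
                               probe_ids = NULL, sample_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (probes x samples).")
  }
  if (!is.null(probe_ids)) rownames(values) <- probe_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("probe and sample ids are required (dimnames or explicit arguments).")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    abort(paste0("duplicate probe id: '", dup, "'"))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    abort(paste0("duplicate sample id: '", dup, "'"))
  }
  ok <- values[!is.na(values)]
  if (scale == "beta") {
    if (length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9)) {
      abort("beta values must lie in [0, 1] (tolerance 1e-9).")
    }
  } else if (length(ok) && any(!is.finite(ok))) {
    abort("M values must be finite.")
  }
  structure(values, scale = scale, class = c("methylation_matrix", "matrix", "array"))
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf(
    "<methylation_matrix> %d probes x %d samples, scale = %s, %d missing\n",
    nrow(x), ncol(x), attr(x, "scale"), sum(is.na(x))
  ))
  invisible(x)
}

#' @export
`[.methylation_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    structure(out, scale = attr(x, "scale"), class = class(x))
  } else {
    out
  }
}

#' Value scale of a methylation matrix
#' @param x A `methylation_matrix`.
#' @return `"beta"` or `"m"`.
#' @export
value_scale <- function(x) attr(x, "scale")

#' Read a methylation matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column `probe_id`. Empty
#' cells become missing values. Delimiter is inferred from the file extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param path File path.
#' @param scale_hint `"beta"` or `"m"`; how to interpret the values.
#' @return A [methylation_matrix()].
#' @export
read_methylation_matrix <- function(path, scale_hint = c("beta", "m")) {
  scale_hint <- match.arg(scale_hint)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.csv(path, sep = sep, check.names = FALSE, colClasses = "character",
                 na.strings = c("", "NA"))
  if (ncol(df) < 2 || tolower(names(df)[1]) != "probe_id") {
    abort("matrix file must have a 'probe_id' first column and >= 1 sample column.")
  }
  probes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-numeric cell at probe '%s', sample '%s': '%s'",
      probes[bad[1, 1]], colnames(vals)[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]
    ))
  }
  dimnames(num) <- list(probes, colnames(vals))
  methylation_matrix(num, scale = scale_hint)
}

#' Write a methylation matrix to TSV/CSV
#'
#' @param x A [methylation_matrix()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_methylation_matrix <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert beta values to M values
#'
#' M = log2(beta / (1 - beta)), with beta clipped to
#' \[`clip_eps`, 1 - `clip_eps`\] so the result is always finite. The
#' conversion is a bijection on the clipped interval.
#'
#' @param values Numeric vector/matrix of beta values in \[0, 1\], or a
#'   beta-scale [methylation_matrix()].
#' @param clip_eps Clipping epsilon in (0, 0.5). Default 1e-3.
#' @return Same shape as `values`, on the M scale.
#' @export
beta_to_m <- function(values, clip_eps = 1e-3) {
  if (!is.numeric(clip_eps) || length(clip_eps) != 1 ||
      clip_eps <= 0 || clip_eps >= 0.5) {
    abort("`clip_eps` must be a single number in (0, 0.5).")
  }
  is_mm <- inherits(values, "methylation_matrix")
  if (is_mm && value_scale(values) != "beta") {
    abort("matrix is already on the M scale.")
  }
  v <- unclass(values)
  ok <- v[!is.na(v)]
  if (length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9)) {
    abort("beta values must lie in [0, 1].")
  }
  b <- pmin(pmax(v, clip_eps), 1 - clip_eps)
  m <- log2(b / (1 - b))
  if (is_mm) {
    return(methylation_matrix(m, scale = "m"))
  }
  m
}

#' Convert M values to beta values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param values Numeric vector/matrix of M values, or an M-scale
#'   [methylation_matrix()].
#' @return Same shape, on the beta scale.
#' @export
m_to_beta <- function(values) {
  is_mm <- inherits(values, "methylation_matrix")
  if (is_mm && value_scale(values) != "m") {
    abort("matrix is already on the beta scale.")
  }
  v <- unclass(values)
  b <- 2^v / (1 + 2^v)
  if (is_mm) {
    return(methylation_matrix(b, scale = "beta"))
  }
  b
}

#' Coerce a methylation matrix to the M scale
#'
#' Beta-scale matrices are converted with [beta_to_m()]; M-scale matrices are
#' returned unchanged.
#'
#' @inheritParams beta_to_m
#' @param x A [methylation_matrix()].
#' @return An M-scale `methylation_matrix`.
#' @export
as_m_matrix <- function(x, clip_eps = 1e-3) {
  if (value_scale(x) == "m") x else beta_to_m(x, clip_eps = clip_eps)
}
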