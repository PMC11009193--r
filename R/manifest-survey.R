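ISLAND_LEVELS <- c("Island", "Shore", "Shelf", "OpenSea")

# collapse the array's directional labels (N_Shore/S_Shore, N_Shelf/S_Shelf)
# to the four categories reported for genomic-context enrichment
collapse_island_relation <- function(x) {
  x <- sub("^[NS]_", "", x)
  x[x %in% c("Open_Sea", "OpenSea", "open_sea")] <- "OpenSea"
  bad <- setdiff(unique(x), ISLAND_LEVELS)
  if (length(bad)) {
    abort(paste0("unknown island relation label(s): ", paste(bad, collapse = ", ")))
  }
  x
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos`, `island_relation`, `genes`
#' (semicolon-separated gene symbols, possibly empty). Directional island
#' labels (`N_Shore`, `S_Shelf`, ...) are collapsed to the four categories
#' Island / Shore / Shelf / OpenSea.
#'
#' @param path File path.
#' @return A tibble with one row per probe.
#' @export
read_probe_manifest <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE,
                 colClasses = "character", na.strings = c("", "NA"))
  need <- c("probe_id", "chrom", "pos", "island_relation", "genes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("manifest is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$probe_id)) {
    abort(paste0("duplicate probe id in manifest: '",
                 df$probe_id[duplicated(df$probe_id)][1], "'"))
  }
  tibble(
    probe_id = df$probe_id,
    chrom = df$chrom,
    pos = as.integer(df$pos),
    island_relation = collapse_island_relation(df$island_relation),
    genes = ifelse(is.na(df$genes), "", df$genes)
  )
}

#' Write a probe manifest
#' @param manifest Tibble as returned by [read_probe_manifest()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a survey table
#'
#' A survey table is a tibble keyed by `sample_id` with chronological
#' `age` in years, lifestyle/health responses scaled to \[0, 1\], binary
#' demographics coded -1/+1, categorical and technical covariates, and an
#' optional `replicate_group` linking repeated collections from one subject.
#'
#' @param survey A data frame.
#' @param factors Character vector of lifestyle/health response columns.
#' @param binary Character vector of -1/+1 demographic columns.
#' @return The survey as a tibble, invisibly validated.
#' @export
validate_survey <- function(survey, factors = lifestyle_factor_names(),
                            binary = "sex") {
  survey <- as_tibble(survey)
  need <- c("sample_id", "age", intersect(c(factors, binary), names(survey)))
  miss <- setdiff(c("sample_id", "age"), names(survey))
  if (length(miss)) {
    abort(paste0("survey is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(survey$sample_id)) {
    abort("duplicate sample_id in survey.")
  }
  if (any(survey$age < 0, na.rm = TRUE)) abort("chronological age must be >= 0.")
  for (f in intersect(factors, names(survey))) {
    v <- survey[[f]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort(paste0("lifestyle response '", f, "' must lie in [0, 1]."))
    }
  }
  for (b in intersect(binary, names(survey))) {
    v <- survey[[b]]
    if (!all(v %in% c(-1, 1) | is.na(v))) {
      abort(paste0("binary demographic '", b, "' must be coded -1/+1."))
    }
  }
  if ("replicate_group" %in% names(survey)) {
    grp <- survey$replicate_group[!is.na(survey$replicate_group)]
    sizes <- table(grp)
    if (length(sizes) && any(sizes < 2)) {
      abort("replicate groups must have size >= 2.")
    }
  }
  invisible(survey)
}

#' Read a survey table from CSV
#' @inheritParams validate_survey
#' @param path File path.
#' @return A validated tibble.
#' @export
read_survey_table <- function(path, factors = lifestyle_factor_names(),
                              binary = "sex") {
  df <- as_tibble(read.csv(path, check.names = FALSE))
  validate_survey(df, factors = factors, binary = binary)
  df
}

#' Default lifestyle/health factor names
#'
#' The eleven self-reported lifestyle and health responses carried by the
#' survey: self-rated health, self-perceived aging, sleep quality, stress
#' level, social satisfaction, plant-based diet fraction, exercise, smoking
#' history, alcohol consumption, relative immune health, and BMI. Each is
#' scaled to \[0, 1\].
#'
#' @return Character vector of column names.
#' @export
lifestyle_factor_names <- function() {
  c("self_rated_health", "self_perceived_aging", "sleep_quality",
    "stress_level", "social_satisfaction", "diet_plant_based",
    "exercise", "smoking", "alcohol", "immune_health", "bmi")
}
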