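# run code under a seed without disturbing the caller's RNG stream
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Synthetic cohort configuration
#'
#' Settings for [simulate_cohort()]. The defaults describe the standard
#' benchmark cohort: 500 samples aged 18-93, 300 CpG clusters of 1-8 probes,
#' 20 clusters drifting with age, 5 clusters carrying a lifestyle effect, two
#' pseudo cell types mixed with Dirichlet proportions, and Gaussian M-value
#' noise split into a cluster-shared biological component and a probe-level
#' measurement component.
#'
#' @param n_samples Number of subjects.
#' @param n_clusters Number of ground-truth CpG clusters.
#' @param cluster_size_range Integer range of probes per cluster.
#' @param n_age_clusters Clusters given a linear age slope.
#' @param n_lifestyle_clusters Clusters given an additive lifestyle effect.
#' @param age_range Chronological age range (years); ages drawn uniformly.
#' @param age_slope_range Absolute M-units-per-year slope range for age
#'   clusters; signs are random.
#' @param lifestyle_factor Survey factor carrying the planted effect.
#' @param lifestyle_effect Effect size, M units per unit response.
#' @param lifestyle_clusters_carry_age If `TRUE` (default), lifestyle-effect
#'   clusters also carry an age slope (dual-signal clusters, flagged in the
#'   truth object). Methylation loci that respond to lifestyle typically also
#'   drift with age; dual clusters are what lets a lifestyle signal reach the
#'   delta age of a least-squares age model at all, since a cluster with no
#'   age information receives a near-zero weight. The effect's sign follows
#'   each cluster's age slope, i.e. the exposure pushes methylation in the
#'   aging direction at age-responsive loci.
#' @param age_correlations Named vector of target Pearson correlations
#'   between each lifestyle response and age (signs mirror the cohort trends:
#'   smoking and stress decline with age, self-perceived aging rises).
#' @param cluster_noise_sd SD of cluster-shared biological noise (M units).
#' @param probe_noise_sd SD of probe-level measurement noise (M units).
#' @param n_cell_types Number of pseudo cell types (0 disables mixing).
#' @param dirichlet_alpha Dirichlet concentration for mixing proportions.
#' @param cell_profile_sd SD of per-probe baseline differences between cell
#'   types (M units).
#' @param n_x_probes,n_y_probes Sex-chromosome probes appended outside the
#'   cluster structure (used by sex prediction, removed by filtering).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 500,
                          n_clusters = 300,
                          cluster_size_range = c(1L, 8L),
                          n_age_clusters = 20,
                          n_lifestyle_clusters = 5,
                          age_range = c(18, 93),
                          age_slope_range = c(0.02, 0.05),
                          lifestyle_factor = "stress_level",
                          lifestyle_effect = 3,
                          lifestyle_clusters_carry_age = TRUE,
                          age_correlations = default_age_correlations(),
                          cluster_noise_sd = 0.4,
                          probe_noise_sd = 0.25,
                          n_cell_types = 2,
                          dirichlet_alpha = c(8, 2),
                          cell_profile_sd = 0.8,
                          n_x_probes = 30,
                          n_y_probes = 20) {
  if (n_age_clusters + n_lifestyle_clusters > n_clusters) {
    abort("planted age + lifestyle clusters exceed `n_clusters`.")
  }
  if (cluster_noise_sd < 0 || probe_noise_sd < 0) abort("noise SDs must be >= 0.")
  if (!lifestyle_factor %in% lifestyle_factor_names()) {
    abort(paste0("unknown lifestyle factor '", lifestyle_factor, "'."))
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Default lifestyle-response age correlations
#'
#' Target Pearson correlations between each scaled lifestyle response and
#' chronological age used by the generator. Signs follow the qualitative
#' cohort trends (smoking history and stress level decrease with age,
#' self-perceived aging increases); magnitudes are modest, as is typical for
#' self-report data.
#'
#' @return Named numeric vector over [lifestyle_factor_names()].
#' @export
default_age_correlations <- function() {
  c(self_rated_health = 0.05, self_perceived_aging = 0.20,
    sleep_quality = 0.10, stress_level = -0.25, social_satisfaction = 0.15,
    diet_plant_based = 0.10, exercise = 0.05, smoking = -0.15,
    alcohol = 0.05, immune_health = 0.05, bmi = 0.10)
}

#' Generate a synthetic methylation cohort with planted structure
#'
#' Draws ages uniformly on the configured range, lifestyle responses with the
#' configured age correlations (Gaussian copula, responses mapped to \[0, 1\]),
#' and probe M values as cell-mixture baseline + cluster age slope x centred
#' age + lifestyle effect x centred response + cluster-shared noise +
#' probe-level noise. Identical seeds give identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the only source of randomness.
#' @return A list with elements `matrix` (M-scale [methylation_matrix()]),
#'   `survey` (tibble), `manifest` (tibble), `truth_clusters`
#'   ([cluster_map()] ground truth over autosomal probes) and `truth` (list
#'   of planted parameters: age cluster ids and slopes, lifestyle cluster ids
#'   and effect, noise SDs, cell profiles and mixing proportions, seed).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_rng_seed(seed, {
    n <- config$n_samples
    sample_ids <- sprintf("s%04d", seq_len(n))
    age <- runif(n, config$age_range[1], config$age_range[2])

    # lifestyle responses: Gaussian copula against standardised age
    z_age <- as.numeric(scale(age))
    factors <- lifestyle_factor_names()
    rho <- config$age_correlations[factors]
    resp <- sapply(factors, function(f) {
      r <- rho[[f]]
      stats::pnorm(r * z_age + sqrt(1 - r^2) * rnorm(n))
    })
    colnames(resp) <- factors

    sex <- sample(c(-1, 1), n, replace = TRUE)
    race <- sample(paste0("group", 1:4), n, replace = TRUE,
                   prob = c(0.55, 0.2, 0.15, 0.1))
    education <- sample(paste0("edu", 1:4), n, replace = TRUE)
    plate <- sample(paste0("plate", 1:5), n, replace = TRUE)

    # cluster structure
    k <- config$n_clusters
    sizes <- sample(seq(config$cluster_size_range[1], config$cluster_size_range[2]),
                    k, replace = TRUE)
    cluster_ids <- sprintf("truth%04d", seq_len(k))
    probe_ids <- unlist(lapply(seq_len(k), function(i) {
      sprintf("cg%04d_%02d", i, seq_len(sizes[i]))
    }))
    probe_cluster <- rep(seq_len(k), sizes)
    n_probes <- length(probe_ids)

    age_cl <- seq_len(config$n_age_clusters)
    life_cl <- if (config$n_lifestyle_clusters > 0) {
      config$n_age_clusters + seq_len(config$n_lifestyle_clusters)
    } else integer(0)
    slopes <- numeric(k)
    sloped <- if (isTRUE(config$lifestyle_clusters_carry_age)) {
      c(age_cl, life_cl)
    } else age_cl
    slopes[sloped] <- sample(c(-1, 1), length(sloped), replace = TRUE) *
      runif(length(sloped), config$age_slope_range[1], config$age_slope_range[2])
    effects <- numeric(k)
    # the exposure shifts methylation in the direction of aging at
    # age-responsive loci, so its sign follows the cluster's age slope
    effects[life_cl] <- config$lifestyle_effect *
      ifelse(slopes[life_cl] != 0, sign(slopes[life_cl]), 1)

    # per-cluster latent signal, samples in columns
    life_resp <- resp[, config$lifestyle_factor]
    latent <- outer(slopes, age - mean(age)) +
      outer(effects, life_resp - 0.5) +
      matrix(rnorm(k * n, 0, config$cluster_noise_sd), k, n)

    # cell-type mixing acts on per-probe baselines
    base <- rnorm(n_probes, 0, 1.2)
    if (config$n_cell_types >= 2) {
      profiles <- sapply(seq_len(config$n_cell_types), function(t) {
        if (t == 1) base else base + rnorm(n_probes, 0, config$cell_profile_sd)
      })
      props <- rdirichlet(n, config$dirichlet_alpha[seq_len(config$n_cell_types)])
      baseline <- profiles %*% t(props)
    } else {
      profiles <- matrix(base, ncol = 1)
      props <- matrix(1, n, 1)
      baseline <- matrix(base, n_probes, n)
    }
    colnames(props) <- paste0("cell", seq_len(ncol(props)))
    dimnames(profiles) <- list(probe_ids, colnames(props))

    probe_offset <- rnorm(n_probes, 0, 0.3)
    values <- baseline + latent[probe_cluster, , drop = FALSE] + probe_offset +
      matrix(rnorm(n_probes * n, 0, config$probe_noise_sd), n_probes, n)

    # sex-chromosome probes outside the cluster structure
    x_ids <- sprintf("cgX%03d", seq_len(config$n_x_probes))
    y_ids <- sprintf("cgY%03d", seq_len(config$n_y_probes))
    if (config$n_x_probes > 0) {
      xv <- rnorm(config$n_x_probes, 0, 0.3) +
        outer(rep(1, config$n_x_probes), ifelse(sex == 1, -2, 0)) +
        matrix(rnorm(config$n_x_probes * n, 0, max(config$probe_noise_sd, 0.05)),
               config$n_x_probes, n)
    } else xv <- NULL
    if (config$n_y_probes > 0) {
      yv <- outer(rep(1, config$n_y_probes), ifelse(sex == 1, 1.5, -4)) +
        matrix(rnorm(config$n_y_probes * n, 0, max(config$probe_noise_sd, 0.05) + 0.3),
               config$n_y_probes, n)
    } else yv <- NULL

    all_values <- rbind(values, xv, yv)
    rownames(all_values) <- c(probe_ids, x_ids, y_ids)
    colnames(all_values) <- sample_ids
    mat <- methylation_matrix(all_values, scale = "m")

    survey <- tibble(
      sample_id = sample_ids, age = age,
      as_tibble(resp),
      sex = sex, race_ethnicity = race, education = education, plate = plate,
      replicate_group = NA_character_
    )
    survey <- dplyr::bind_cols(survey, as_tibble(props))

    manifest <- tibble(
      probe_id = rownames(all_values),
      chrom = c(paste0("chr", sample(1:22, n_probes, replace = TRUE)),
                rep("chrX", config$n_x_probes), rep("chrY", config$n_y_probes)),
      pos = sample.int(2e8, nrow(all_values)),
      island_relation = sample(ISLAND_LEVELS, nrow(all_values), replace = TRUE,
                               prob = c(0.31, 0.23, 0.10, 0.36)),
      genes = ifelse(runif(nrow(all_values)) < 0.6,
                     paste0("GENE", sample.int(5000, nrow(all_values), replace = TRUE)),
                     "")
    )

    truth_clusters <- cluster_map(setNames(split(probe_ids, probe_cluster), cluster_ids))
    truth <- list(
      age_clusters = setNames(slopes[age_cl], cluster_ids[age_cl]),
      lifestyle_clusters = setNames(effects[life_cl], cluster_ids[life_cl]),
      # dual-signal clusters: carry both an age slope and the lifestyle effect
      dual_signal = if (isTRUE(config$lifestyle_clusters_carry_age)) {
        setNames(slopes[life_cl], cluster_ids[life_cl])
      } else NULL,
      lifestyle_factor = config$lifestyle_factor,
      cluster_noise_sd = config$cluster_noise_sd,
      probe_noise_sd = config$probe_noise_sd,
      cell_profiles = profiles,
      cell_proportions = props,
      seed = seed
    )
    list(matrix = mat, survey = survey, manifest = manifest,
         truth_clusters = truth_clusters, truth = truth)
  })
}

#' Add technical replicate samples to a cohort
#'
#' Duplicates `n_pairs` randomly chosen samples with added N(0, `tech_sd`^2)
#' noise on the M values, mimicking a second swab collection within 24 h.
#' Replicate group ids are recorded in the survey; each group has size 2.
#'
#' @param matrix An M-scale [methylation_matrix()].
#' @param survey Matching survey tibble.
#' @param n_pairs Number of replicate pairs (default 190).
#' @param tech_sd Technical noise SD in M units.
#' @param seed Integer seed.
#' @return List with augmented `matrix` and `survey`.
#' @export
add_replicates <- function(matrix, survey, n_pairs = 190, tech_sd = 0.1, seed = 1) {
  if (tech_sd < 0) abort("`tech_sd` must be >= 0.")
  if (n_pairs > ncol(matrix)) abort("`n_pairs` exceeds the number of samples.")
  with_rng_seed(seed, {
    pick <- sort(sample.int(ncol(matrix), n_pairs))
    ids <- colnames(matrix)[pick]
    rep_ids <- paste0(ids, "_rep2")
    noise <- matrix(rnorm(nrow(matrix) * n_pairs, 0, tech_sd), nrow(matrix), n_pairs)
    newv <- cbind(unclass(matrix), unclass(matrix)[, pick, drop = FALSE] + noise)
    colnames(newv) <- c(colnames(matrix), rep_ids)
    aug <- methylation_matrix(newv, scale = value_scale(matrix))

    if (!"replicate_group" %in% names(survey)) survey$replicate_group <- NA_character_
    grp <- paste0("rg_", ids)
    survey$replicate_group[match(ids, survey$sample_id)] <- grp
    reps <- survey[match(ids, survey$sample_id), ]
    reps$sample_id <- rep_ids
    reps$replicate_group <- grp
    list(matrix = aug, survey = dplyr::bind_rows(survey, reps))
  })
}
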