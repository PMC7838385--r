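#' Configuration for the synthetic functional gene array generator
#'
#' Captures the study design the generator emulates: a two-group survey of
#' four lakes (two low-elevation, two high-elevation) with six samples per
#' lake, probe annotations spread over biogeochemical categories, a planted
#' multiplicative stress-response effect in the high-elevation group, planted
#' correlation modules driven by latent factors, and per-cell detection.
#'
#' Intensities are lognormal: microarray signals are positive and
#' right-skewed, so noise is multiplicative on the log scale. Probes in a
#' planted module share a per-sample latent factor; a probe's log-scale
#' deviation is `sqrt(w) * factor + sqrt(1 - w) * noise` with
#' `w = within_module_r`, so the pairwise log-scale correlation inside a
#' block equals `within_module_r`.
#'
#' @param n_lakes number of lakes (default 4).
#' @param samples_per_lake samples per lake (default 6).
#' @param group_of_lake character vector, one of `"low"`/`"high"` per lake;
#'   default splits lakes half and half.
#' @param n_probes number of (non-control) probes.
#' @param category_weights named proportions over functional categories;
#'   must sum to 1.
#' @param stress_effect multiplicative fold-change applied to the mean signal
#'   of stress-response probes in high-group samples (>= 1).
#' @param n_modules number of planted correlation blocks.
#' @param module_size probes per block; `n_modules * module_size` must not
#'   exceed `n_probes`.
#' @param within_module_r target absolute pairwise Pearson correlation inside
#'   a block, in \[0, 1\].
#' @param detection_prob per-probe per-sample Bernoulli detection probability.
#' @param noise_sd lognormal noise scale (sd of the log-scale deviation).
#' @param snr_fail_prob fraction of detected cells whose signal-to-noise
#'   ratio is drawn at or below 2, so the SNR filter has work to do.
#' @param env_driver_module planted module whose latent factor drives one
#'   environmental variable (NA for none).
#' @param env_driver_var name of the driven environmental variable.
#' @param env_driver_strength linear coupling of the driver factor into the
#'   driven variable.
#' @param seed integer seed making the emitted tables reproducible.
#'
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_lakes = 4,
                         samples_per_lake = 6,
                         group_of_lake = NULL,
                         n_probes = 400,
                         category_weights = c(
                           "carbon cycling" = 0.30,
                           "nitrogen cycling" = 0.20,
                           "phosphorus cycling" = 0.10,
                           "sulfur cycling" = 0.10,
                           "stress response" = 0.20,
                           "other" = 0.10
                         ),
                         stress_effect = 1.5,
                         n_modules = 10,
                         module_size = 12,
                         within_module_r = 0.9,
                         detection_prob = 0.9,
                         noise_sd = 0.35,
                         snr_fail_prob = 0.1,
                         env_driver_module = 1,
                         env_driver_var = "turbidity",
                         env_driver_strength = 1.5,
                         seed = 1L) {
  if (is.null(group_of_lake)) {
    group_of_lake <- rep(c("low", "high"), each = ceiling(n_lakes / 2))[seq_len(n_lakes)]
  }
  if (length(group_of_lake) != n_lakes) {
    abort("`group_of_lake` must name a group for every lake")
  }
  if (!all(group_of_lake %in% c("low", "high"))) {
    abort("`group_of_lake` entries must be 'low' or 'high'")
  }
  if (abs(sum(category_weights) - 1) > 1e-9) {
    abort("`category_weights` must sum to 1")
  }
  if (within_module_r < 0 || within_module_r > 1) {
    abort("`within_module_r` must lie in [0, 1]")
  }
  if (n_modules * module_size > n_probes) {
    abort("`module_size * n_modules` exceeds `n_probes`")
  }
  if (stress_effect < 1) abort("`stress_effect` must be >= 1")
  if (detection_prob <= 0 || detection_prob > 1) {
    abort("`detection_prob` must lie in (0, 1]")
  }
  structure(
    list(
      n_lakes = n_lakes, samples_per_lake = samples_per_lake,
      group_of_lake = group_of_lake, n_probes = n_probes,
      category_weights = category_weights, stress_effect = stress_effect,
      n_modules = n_modules, module_size = module_size,
      within_module_r = within_module_r, detection_prob = detection_prob,
      noise_sd = noise_sd, snr_fail_prob = snr_fail_prob,
      env_driver_module = env_driver_module, env_driver_var = env_driver_var,
      env_driver_strength = env_driver_strength, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# gene families per category, loosely modelled on GeoChip content
.family_pool <- list(
  "carbon cycling"     = c("amyA", "chitinase", "cellobiase", "mannanase", "vdh", "cda", "pcc", "rbcL"),
  "nitrogen cycling"   = c("napA", "nirS", "nirK", "nifH", "amoA", "glnR", "nosZ"),
  "phosphorus cycling" = c("ppx", "ppk", "phytase", "pstA"),
  "sulfur cycling"     = c("dsrA", "dsrB", "soxY", "aprA"),
  "stress response"    = c("bglP", "cydA", "ahpF", "proW", "obgE", "grpE", "pstS", "sigma_32", "clpC", "katE", "fnr"),
  "other"              = c("mer", "czcA", "pbrT", "nahA")
)

.subcategory_pool <- list(
  "carbon cycling"     = c("carbon degradation", "carbon fixation", "methane metabolism"),
  "nitrogen cycling"   = c("denitrification", "nitrification", "N fixation", "assimilatory N reduction"),
  "phosphorus cycling" = c("polyphosphate", "phytate utilization", "phosphate transport"),
  "sulfur cycling"     = c("sulfite reduction", "sulfur oxidation"),
  "stress response"    = c("glucose limitation", "oxygen limitation", "osmotic stress", "cold shock",
                           "heat shock", "nitrogen limitation", "phosphate limitation", "sigma factor",
                           "protein stress", "radiation stress"),
  "other"              = c("metal homeostasis", "organic remediation")
)

.lineage_pool <- c(
  "Bacteria;Proteobacteria;Gammaproteobacteria",
  "Bacteria;Proteobacteria;Alphaproteobacteria",
  "Bacteria;Proteobacteria;Betaproteobacteria",
  "Bacteria;Firmicutes", "Bacteria;Actinobacteria", "Bacteria;Bacteroidetes",
  "Bacteria;Cyanobacteria", "Archaea;Euryarchaeota", "Fungi;Ascomycota"
)

#' Generate a synthetic functional gene array dataset
#'
#' Emits a raw probe signal table (long: one row per detected probe/sample
#' cell with signal and SNR), a probe annotation table, the study design,
#' an environment table with group-contrasted covariates, and a ground-truth
#' ledger for parameter-recovery tests. Deterministic for a fixed seed.
#'
#' Positive-control probes are appended beyond `n_probes`, share a common
#' mean, and are detected in every sample. Environmental covariates differ
#' between groups in fixed directions (low-elevation lakes warmer, richer in
#' DOC, chlorophyll a and nutrients); one variable can additionally be driven
#' by a planted module's latent factor for eigengene-recovery tests.
#'
#' @param config a [synth_config()].
#' @return a `synth_dataset` list with elements `signal` (long tibble:
#'   probe_id, sample_id, signal, snr, is_positive_control), `annotation`,
#'   `design`, `env`, `truth` (planted modules, fold-changes, latent factors,
#'   environment directions) and `config`.
#' @export
#' @examples
#' d <- generate_dataset(synth_config(n_probes = 60, seed = 7))
#' dplyr::count(d$annotation, category)
generate_dataset <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  set.seed(config$seed)
  n_samples <- config$n_lakes * config$samples_per_lake

  ## design -----------------------------------------------------------------
  lakes <- paste0("lake", seq_len(config$n_lakes))
  elev <- ifelse(config$group_of_lake == "low",
                 525 + 5 * seq_len(config$n_lakes),
                 4560 + 12 * seq_len(config$n_lakes))
  design <- tibble::tibble(
    sample_id = paste0("L", rep(seq_len(config$n_lakes), each = config$samples_per_lake),
                       "S", rep(seq_len(config$samples_per_lake), config$n_lakes)),
    lake_id = rep(lakes, each = config$samples_per_lake),
    elevation_group = rep(config$group_of_lake, each = config$samples_per_lake),
    elevation_m = rep(elev, each = config$samples_per_lake)
  )

  ## annotation -------------------------------------------------------------
  cats <- sample(names(config$category_weights), config$n_probes,
                 replace = TRUE, prob = config$category_weights)
  annotation <- tibble::tibble(
    probe_id = sprintf("p%05d", seq_len(config$n_probes)),
    gene_family = unname(vapply(cats, function(cc) sample(.family_pool[[cc]], 1),
                                character(1))),
    subcategory = unname(vapply(cats, function(cc) sample(.subcategory_pool[[cc]], 1),
                                character(1))),
    category = cats,
    lineage = sample(.lineage_pool, config$n_probes, replace = TRUE),
    is_positive_control = FALSE
  )

  ## planted modules ---------------------------------------------------------
  module_of <- rep(NA_integer_, config$n_probes)
  if (config$n_modules > 0) {
    picked <- sample(config$n_probes, config$n_modules * config$module_size)
    module_of[picked] <- rep(seq_len(config$n_modules), each = config$module_size)
  }

  ## intensities -------------------------------------------------------------
  mu <- rnorm(config$n_probes, mean = log(2000), sd = 0.5)
  w <- config$within_module_r
  factors <- matrix(rnorm(max(config$n_modules, 1) * n_samples),
                    nrow = max(config$n_modules, 1),
                    dimnames = list(NULL, design$sample_id))
  is_stress <- annotation$category == "stress response"
  fold <- ifelse(is_stress, config$stress_effect, 1)
  high_sample <- design$elevation_group == "high"

  eps <- matrix(rnorm(config$n_probes * n_samples), nrow = config$n_probes)
  z <- eps
  in_block <- !is.na(module_of)
  if (any(in_block)) {
    z[in_block, ] <- sqrt(w) * factors[module_of[in_block], , drop = FALSE] +
      sqrt(1 - w) * eps[in_block, , drop = FALSE]
  }
  shift <- outer(log(fold), as.numeric(high_sample))
  signal <- exp(mu + shift + config$noise_sd * z)
  dimnames(signal) <- list(annotation$probe_id, design$sample_id)

  detected <- matrix(rbinom(length(signal), 1, config$detection_prob) == 1,
                     nrow = nrow(signal))
  snr_fail <- matrix(rbinom(length(signal), 1, config$snr_fail_prob) == 1,
                     nrow = nrow(signal))
  snr <- matrix(2 + rexp(length(signal), rate = 0.15), nrow = nrow(signal))
  snr[snr_fail] <- runif(sum(snr_fail), 0.2, 2)

  long <- tibble::tibble(
    probe_id = rep(rownames(signal), times = ncol(signal)),
    sample_id = rep(colnames(signal), each = nrow(signal)),
    signal = as.vector(signal),
    snr = round(as.vector(snr), 4),
    is_positive_control = FALSE
  )[as.vector(detected), ]

  ## positive controls: common mean, in every sample, high SNR ---------------
  n_pos <- max(4L, round(0.02 * config$n_probes))
  pos_signal <- exp(log(5000) + config$noise_sd *
                      matrix(rnorm(n_pos * n_samples), nrow = n_pos))
  pos_ids <- sprintf("pos%03d", seq_len(n_pos))
  pos_long <- tibble::tibble(
    probe_id = rep(pos_ids, times = n_samples),
    sample_id = rep(design$sample_id, each = n_pos),
    signal = as.vector(pos_signal),
    snr = round(10 + rexp(n_pos * n_samples, 0.2), 4),
    is_positive_control = TRUE
  )
  annotation <- dplyr::bind_rows(
    annotation,
    tibble::tibble(probe_id = pos_ids, category = "control",
                   gene_family = "positive_control", subcategory = "control",
                   lineage = "synthetic;control", is_positive_control = TRUE)
  )

  raw <- dplyr::arrange(dplyr::bind_rows(long, pos_long),
                        .data$probe_id, .data$sample_id)
  raw$signal <- round(raw$signal, 4)

  ## environment -------------------------------------------------------------
  env_means <- list( # low-group mean, high-group mean, sd
    temperature = c(18, 5, 1.0), doc = c(6, 2.5, 0.5), chl_a = c(8, 1.5, 0.6),
    po4_p = c(0.05, 0.012, 0.004), ph = c(8.2, 7.6, 0.1), turbidity = c(5, 5, 0.3),
    do = c(7.5, 6.8, 0.2), orp = c(180, 240, 10), tp = c(0.08, 0.02, 0.006)
  )
  env <- tibble::tibble(sample_id = design$sample_id)
  for (v in names(env_means)) {
    m <- env_means[[v]]
    env[[v]] <- round(ifelse(high_sample, m[2], m[1]) + rnorm(n_samples, 0, m[3]), 4)
  }
  if (!is.na(config$env_driver_module) && config$n_modules >= config$env_driver_module) {
    drv <- config$env_driver_var
    env[[drv]] <- round(env[[drv]] +
      config$env_driver_strength * factors[config$env_driver_module, ], 4)
  }
  env_directions <- tibble::tibble(
    variable = names(env_means),
    higher_group = c("low", "low", "low", "low", "low", NA, "low", "high", "low")
  )

  truth <- list(
    probe_modules = tibble::tibble(probe_id = annotation$probe_id,
                                   module = c(module_of, rep(NA_integer_, n_pos))),
    probe_fold = tibble::tibble(probe_id = annotation$probe_id,
                                fold = c(fold, rep(1, n_pos))),
    samples = design[, c("sample_id", "lake_id", "elevation_group")],
    factors = factors,
    env_directions = env_directions
  )

  structure(
    list(signal = raw, annotation = annotation, design = design, env = env,
         truth = truth, config = config),
    class = "synth_dataset"
  )
}

#' Generate a gene-by-sample matrix with block-diagonal correlation
#'
#' A direct fixture for network-inference tests: genes are split evenly into
#' blocks, genes in a block share a latent factor so the population
#' correlation inside a block is `within_r` and zero across blocks.
#'
#' @param n_genes,n_blocks,n_samples dimensions; `n_blocks >= 1`,
#'   `n_samples >= 4`.
#' @param within_r target within-block correlation in \[0, 1\]; `within_r = 1`
#'   makes block members exact copies of the factor.
#' @param seed integer seed.
#' @return numeric matrix (genes x samples) with a `block` attribute giving
#'   the planted block label of each gene.
#' @export
generate_correlated_blocks <- function(n_genes, n_blocks, within_r, n_samples, seed = 1L) {
  if (within_r < 0 || within_r > 1) abort("`within_r` must lie in [0, 1]")
  if (n_blocks < 1) abort("`n_blocks` must be >= 1")
  if (n_samples < 4) abort("`n_samples` must be >= 4")
  set.seed(as.integer(seed))
  block <- rep(seq_len(n_blocks), length.out = n_genes)
  block <- sort(block)
  f <- matrix(rnorm(n_blocks * n_samples), nrow = n_blocks)
  e <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
  x <- sqrt(within_r) * f[block, , drop = FALSE] + sqrt(1 - within_r) * e
  dimnames(x) <- list(paste0("g", seq_len(n_genes)), paste0("s", seq_len(n_samples)))
  attr(x, "block") <- block
  x
}
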