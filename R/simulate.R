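# Synthetic-data generator with known ground truth. Emulates the
# statistical structure the analysis assumes: additive log2 probe
# intensities per gene (sample effect + probe effect + noise), coherent
# exon-level skip/inclusion deviations injected at the probe-set level
# with per-sample rates and skew, splicing-factor expression negatively
# coupled to each sample's deviation burden, and survival times whose
# hazard depends on TIN status.

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: 300 genes with 4-12 probe sets
#' of 4 probes each and 80 samples (~10^6 intensity values). Deviations
#' are injected per (probe set, sample) at `base_deviation_rate`;
#' a `tin_sample_fraction` of samples receive `tin_rate_multiplier` times
#' that rate with skip:inclusion odds `skew_ratio` (non-TIN samples
#' deviate symmetrically). Splicing-factor expression decreases by
#' `sf_coupling_beta` per standard deviation of deviation burden. Event
#' hazards are exponential with a multiplicative `exp(hazard_log_hr)` for
#' TIN-positive patients and administrative censoring at `censor_time`.
#'
#' @param n_genes Number of genes.
#' @param probe_sets_per_gene Integer range `c(min, max)`; per-gene counts
#'   are drawn uniformly from it.
#' @param probes_per_set Probes per probe set.
#' @param n_samples Number of samples.
#' @param base_deviation_rate Per-(probe set, sample) deviation
#'   probability for unaffected samples.
#' @param tin_sample_fraction Fraction of samples that are TIN-positive.
#' @param tin_rate_multiplier Deviation-rate multiplier for TIN samples
#'   (>= 1).
#' @param skew_ratio Skip:inclusion odds for deviations in TIN samples
#'   (1 = symmetric).
#' @param deviation_delta Injected shift in log2 units.
#' @param noise_sigma Probe-level noise SD in log2 units.
#' @param gene_level_mean,gene_level_sd Gene/sample expression effect
#'   distribution (log2).
#' @param probe_effect_sd Probe-affinity effect SD (log2, centered per
#'   gene).
#' @param add_background Add an exponential background to the emitted
#'   linear intensities (to exercise background correction).
#' @param background_mean Mean of that exponential background.
#' @param n_sf_genes,n_null_genes Splicing-factor and uncoupled genes in
#'   the standalone expression block.
#' @param sf_coupling_beta Expression decrease (log2) per SD of deviation
#'   burden for splicing-factor genes.
#' @param sf_sigma Residual SD of the splicing-factor expression model.
#' @param sf_level_mean,sf_level_sd Baseline expression distribution.
#' @param hazard_baseline Baseline hazard (events/year).
#' @param hazard_log_hr Log hazard ratio for TIN-positive patients.
#' @param censor_time Administrative censoring time (years).
#' @param age_mean,age_sd,stage_iii_prob,msi_prob,male_prob,location_probs
#'   Covariate distributions for the clinical table.
#' @param seed Default seed used by [simulate_tin_study()].
#' @return A validated list of class `tin_sim_config`.
#' @export
sim_config <- function(n_genes = 300,
                       probe_sets_per_gene = c(4, 12),
                       probes_per_set = 4,
                       n_samples = 80,
                       base_deviation_rate = 0.015,
                       tin_sample_fraction = 0.1,
                       tin_rate_multiplier = 3,
                       skew_ratio = 4,
                       deviation_delta = 1.5,
                       noise_sigma = 0.25,
                       gene_level_mean = 8, gene_level_sd = 1.5,
                       probe_effect_sd = 0.5,
                       add_background = FALSE, background_mean = 50,
                       n_sf_genes = 280, n_null_genes = 2520,
                       sf_coupling_beta = 1, sf_sigma = 0.3,
                       sf_level_mean = 8, sf_level_sd = 1,
                       hazard_baseline = 0.07,
                       hazard_log_hr = log(3.2),
                       censor_time = 10,
                       age_mean = 66, age_sd = 11.7,
                       stage_iii_prob = 0.45, msi_prob = 0.16,
                       male_prob = 0.48,
                       location_probs = c(right = 0.31, left = 0.30, rectum = 0.39),
                       seed = NULL) {
  cfg <- as.list(environment())
  assert_scalar_number(n_genes, "n_genes", 1)
  assert_scalar_number(probes_per_set, "probes_per_set", 1)
  assert_scalar_number(n_samples, "n_samples", 1)
  if (length(probe_sets_per_gene) != 2 || any(probe_sets_per_gene < 1) ||
      probe_sets_per_gene[1] > probe_sets_per_gene[2]) {
    abort("probe_sets_per_gene must be c(min, max) with 1 <= min <= max")
  }
  assert_scalar_number(base_deviation_rate, "base_deviation_rate", 0, 1)
  assert_scalar_number(tin_sample_fraction, "tin_sample_fraction", 0, 1)
  assert_scalar_number(tin_rate_multiplier, "tin_rate_multiplier", 1)
  assert_scalar_number(skew_ratio, "skew_ratio", 0)
  assert_scalar_number(noise_sigma, "noise_sigma", 0)
  assert_scalar_number(censor_time, "censor_time", 0)
  if (max(base_deviation_rate, base_deviation_rate * tin_rate_multiplier) >= 0.5) {
    warn("deviation rate >= 0.5: deviations no longer depart from a general pattern")
  }
  structure(cfg, class = "tin_sim_config")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, max(3L, nchar(n)), seq_len(n))

#' Generate a synthetic chip definition
#'
#' @param config A `tin_sim_config`.
#' @param seed Optional seed (the per-gene probe-set counts are random).
#' @return A `chipdef` tibble.
#' @export
generate_chipdef <- function(config = sim_config(), seed = NULL) {
  with_seed_(seed, {
    if (config$n_genes < 1) abort("n_genes must be at least 1")
    genes <- pad_ids("G", config$n_genes)
    lo <- config$probe_sets_per_gene[1]; hi <- config$probe_sets_per_gene[2]
    n_sets <- lo + sample.int(hi - lo + 1L, config$n_genes, replace = TRUE) - 1L
    gene_col <- rep(genes, times = n_sets * config$probes_per_set)
    set_within <- unlist(lapply(n_sets, function(k) {
      rep(seq_len(k), each = config$probes_per_set)
    }))
    set_col <- sprintf("%s_PS%02d", gene_col, set_within)
    probe_within <- unlist(lapply(n_sets, function(k) {
      rep(seq_len(config$probes_per_set), times = k)
    }))
    probe_col <- sprintf("%s_P%d", set_col, probe_within)
    new_chipdef(tibble::tibble(probe_id = probe_col, probe_set_id = set_col,
                               gene_id = gene_col), source = "simulated chipdef")
  })
}

#' Generate probe intensities with injected splicing deviations
#'
#' Model (log2 scale): `I[k,s] = c[g(k),s] + p[k] + delta * Z[j(k),s] + eps`
#' with gene/sample effects `c ~ N(gene_level_mean, gene_level_sd^2)`,
#' per-gene-centered probe effects `p ~ N(0, probe_effect_sd^2)`, noise
#' `eps ~ N(0, noise_sigma^2)`, and `Z in {-1, 0, +1}` marking an injected
#' skipping/inclusion deviation on probe set j in sample s (all probes of
#' the set shift coherently). Emitted intensities are `2^log2`, optionally
#' plus an exponential background.
#'
#' @param chipdef A `chipdef` (e.g. from [generate_chipdef()]).
#' @param config A `tin_sim_config`.
#' @param seed Optional seed.
#' @return List with `intensities` (probes x samples, linear scale) and
#'   `truth`: injected `events` tibble (`probe_set_id`, `sample_id`,
#'   `gene_id`, `sign`), `tin_samples`, per-sample `burden` (injected
#'   event counts) and the config.
#' @export
generate_intensities <- function(chipdef, config = sim_config(), seed = NULL) {
  with_seed_(seed, {
    samples <- pad_ids("S", config$n_samples)
    genes <- unique(chipdef$gene_id)
    sets <- unique(chipdef$probe_set_id)
    n_probes <- nrow(chipdef)
    gene_of_probe <- match(chipdef$gene_id, genes)
    set_of_probe <- match(chipdef$probe_set_id, sets)
    gene_of_set <- match(chipdef$gene_id[!duplicated(chipdef$probe_set_id)], genes)

    n_tin <- round(config$tin_sample_fraction * config$n_samples)
    tin_idx <- if (n_tin > 0) sort(sample.int(config$n_samples, n_tin)) else integer(0)
    is_tin <- seq_len(config$n_samples) %in% tin_idx

    rate <- ifelse(is_tin, config$base_deviation_rate * config$tin_rate_multiplier,
                   config$base_deviation_rate)
    p_skip <- ifelse(is_tin, config$skew_ratio / (config$skew_ratio + 1), 0.5)

    n_sets <- length(sets)
    # deviation indicators and signs, per (probe set, sample)
    z <- matrix(0L, n_sets, config$n_samples)
    for (s in seq_len(config$n_samples)) {
      hit <- runif(n_sets) < rate[s]
      sign_s <- ifelse(runif(n_sets) < p_skip[s], -1L, 1L)
      z[, s] <- ifelse(hit, sign_s, 0L)
    }

    c_eff <- matrix(rnorm(length(genes) * config$n_samples,
                          config$gene_level_mean, config$gene_level_sd),
                    nrow = length(genes))
    p_eff <- rnorm(n_probes, 0, config$probe_effect_sd)
    p_eff <- p_eff - stats::ave(p_eff, gene_of_probe)

    log2i <- c_eff[gene_of_probe, , drop = FALSE] + p_eff +
      config$deviation_delta * z[set_of_probe, , drop = FALSE] +
      matrix(rnorm(n_probes * config$n_samples, 0, config$noise_sigma),
             nrow = n_probes)
    intens <- 2^log2i
    if (config$add_background) {
      intens <- intens + matrix(rexp(length(intens), rate = 1 / config$background_mean),
                                nrow = n_probes)
    }
    dimnames(intens) <- list(chipdef$probe_id, samples)

    ev <- which(z != 0, arr.ind = TRUE)
    events <- tibble::tibble(
      probe_set_id = sets[ev[, 1]], sample_id = samples[ev[, 2]],
      gene_id = genes[gene_of_set[ev[, 1]]],
      sign = as.integer(z[ev])
    )
    burden <- setNames(as.integer(colSums(z != 0)), samples)
    list(intensities = intens,
         truth = list(events = events, tin_samples = samples[tin_idx],
                      is_tin = setNames(is_tin, samples), burden = burden,
                      config = config))
  })
}

#' Generate splicing-factor-coupled gene expression
#'
#' Model: `expr[g,s] = a_g - beta * burden_std[s] * I[g coupled] +
#' N(0, sf_sigma^2)` with the per-sample deviation burden standardized to
#' unit variance. Emits coupled splicing-factor genes plus uncoupled null
#' genes.
#'
#' @param burden Named per-sample numeric vector of deviation burden
#'   (e.g. `truth$burden` from [generate_intensities()]).
#' @param config A `tin_sim_config`.
#' @param seed Optional seed.
#' @return List with `expression` (genes x samples) and `sf_genes` (the
#'   coupled identifiers).
#' @export
generate_sf_expression <- function(burden, config = sim_config(), seed = NULL) {
  if (is.null(names(burden))) abort("burden must be a named per-sample vector")
  with_seed_(seed, {
    b <- burden
    b <- if (stats::sd(b) > 0) (b - mean(b)) / stats::sd(b) else rep(0, length(b))
    n_sf <- config$n_sf_genes; n_null <- config$n_null_genes
    ids <- c(pad_ids("SF", n_sf), pad_ids("NG", n_null))
    n_genes <- n_sf + n_null
    a <- rnorm(n_genes, config$sf_level_mean, config$sf_level_sd)
    coupled <- c(rep(1, n_sf), rep(0, n_null))
    expr <- outer(a, rep(1, length(b))) -
      config$sf_coupling_beta * outer(coupled, b) +
      matrix(rnorm(n_genes * length(b), 0, config$sf_sigma), nrow = n_genes)
    dimnames(expr) <- list(ids, names(burden))
    list(expression = expr, sf_genes = ids[seq_len(n_sf)])
  })
}

#' Generate clinical outcomes from TIN status
#'
#' Exponential event times with hazard
#' `hazard_baseline * exp(hazard_log_hr * I[TIN+])`, administrative
#' censoring at `censor_time`, and covariates drawn independently from the
#' configured distributions.
#'
#' @param tin_flags Named logical vector of TIN-positive status per
#'   sample.
#' @param config A `tin_sim_config`.
#' @param seed Optional seed.
#' @return A `clinical_table` tibble.
#' @export
generate_clinical <- function(tin_flags, config = sim_config(), seed = NULL) {
  if (is.null(names(tin_flags))) abort("tin_flags must be a named logical vector")
  with_seed_(seed, {
    n <- length(tin_flags)
    hazard <- config$hazard_baseline * exp(config$hazard_log_hr * as.numeric(tin_flags))
    event_time <- rexp(n, rate = hazard)
    event <- as.integer(event_time <= config$censor_time)
    time <- pmin(event_time, config$censor_time)
    loc_p <- config$location_probs / sum(config$location_probs)
    new_clinical(tibble::tibble(
      sample_id = names(tin_flags),
      time_years = time, event = event,
      stage = ifelse(runif(n) < config$stage_iii_prob, "III", "II"),
      msi = as.integer(runif(n) < config$msi_prob),
      age = round(rnorm(n, config$age_mean, config$age_sd), 1),
      sex = ifelse(runif(n) < config$male_prob, "M", "F"),
      location = sample(names(loc_p), n, replace = TRUE, prob = loc_p)
    ), source = "simulated clinical table")
  })
}

#' Simulate a complete TIN study
#'
#' Chains [generate_chipdef()], [generate_intensities()],
#' [generate_sf_expression()] and [generate_clinical()] under a single
#' seed, so the same (config, seed) pair reproduces the study exactly.
#'
#' @param config A `tin_sim_config`.
#' @param seed Integer seed (falls back to `config$seed`).
#' @return List of class `tin_simulation`: `chipdef`, `intensities`,
#'   `sf_expression`, `sf_genes`, `clinical`, `truth`, `config`.
#' @export
simulate_tin_study <- function(config = sim_config(), seed = config$seed) {
  with_seed_(seed, {
    chipdef <- generate_chipdef(config)
    gen <- generate_intensities(chipdef, config)
    sf <- generate_sf_expression(gen$truth$burden, config)
    clinical <- generate_clinical(gen$truth$is_tin, config)
    structure(list(chipdef = chipdef, intensities = gen$intensities,
                   sf_expression = sf$expression, sf_genes = sf$sf_genes,
                   clinical = clinical, truth = gen$truth, config = config),
              class = "tin_simulation")
  })
}

#' @export
print.tin_simulation <- function(x, ...) {
  cat(sprintf("Simulated TIN study: %d probes x %d samples, %d genes, %d TIN-positive sample(s)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$chipdef$gene_id)), length(x$truth$tin_samples)))
  invisible(x)
}

#' Write a simulated study to a directory
#'
#' Emits `chipdef.tsv`, `intensities.tsv`, `sf_expression.tsv`,
#' `sf_list.txt`, `clinical.csv`, and the ground truth
#' (`truth_events.tsv`, `truth_tin_samples.txt`).
#'
#' @param sim A `tin_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "tin_simulation")) abort("`sim` must be a tin_simulation")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_chipdef(sim$chipdef, file.path(dir, "chipdef.tsv"))
  write_matrix(sim$intensities, file.path(dir, "intensities.tsv"), id_col = "probe_id")
  write_matrix(sim$sf_expression, file.path(dir, "sf_expression.tsv"), id_col = "gene_id")
  write_gene_list(sim$sf_genes, file.path(dir, "sf_list.txt"))
  write_clinical(sim$clinical, file.path(dir, "clinical.csv"))
  readr::write_tsv(sim$truth$events, file.path(dir, "truth_events.tsv"),
                   progress = FALSE)
  readr::write_lines(sim$truth$tin_samples, file.path(dir, "truth_tin_samples.txt"))
  invisible(dir)
}
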