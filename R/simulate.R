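# Synthetic methylation and expression generators. These emulate the
# statistical structure of the cohorts every downstream stage expects —
# multi-species blood (and optionally liver) panels with a planted,
# monotone-in-age methylation signal, and a small two-animal multi-tissue
# atlas with chromatin-state-dependent methylation/expression coupling —
# so clocks, EWAS and atlas analyses can be exercised and validated against
# a known truth table without any external download.

#' Default multi-species blood design
#'
#' One row per (tissue, species) cell: sample counts by sex/castration
#' status and the age range sampled uniformly. The default mirrors a
#' four-equid blood panel (horse n = 188, plains zebra 76, Grevy's zebra 5,
#' Somali wild ass 7) with horse males split into geldings and stallions.
#'
#' @return A data frame with columns `tissue`, `species`, `n_female`,
#'   `n_gelding`, `n_stallion`, `age_min`, `age_max`.
#' @export
equid_blood_design <- function() {
  data.frame(
    tissue = "blood",
    species = c("horse", "plains_zebra", "grevys_zebra", "somali_wild_ass"),
    n_female = c(127, 42, 1, 1),
    n_gelding = c(49, 0, 0, 0),
    n_stallion = c(12, 34, 4, 6),
    age_min = c(0, 0.16, 2.3, 2.4),
    age_max = c(28, 20.2, 18.5, 10),
    stringsAsFactors = FALSE
  )
}

#' Horse blood + liver design for two-tissue EWAS simulations
#'
#' @return A design data frame (see [equid_blood_design()]): horse blood
#'   n = 188 (ages 0-28) and horse liver n = 48 (ages 0-29).
#' @export
blood_liver_design <- function() {
  data.frame(
    tissue = c("blood", "liver"),
    species = "horse",
    n_female = c(127, 24),
    n_gelding = c(49, 15),
    n_stallion = c(12, 9),
    age_min = c(0, 0.04),
    age_max = c(28, 29),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for methylation datasets
#'
#' The generating model for sample i, CpG j in tissue t of species s is
#' `beta_ij = clip(mu_j + d_jt + o_js + b_jt * g(age_i) + gamma_j * gelding_i
#' + eps_ij, 0, 1)` with `g` the age scaled to \[0, 1\] over the tissue's
#' age range, `d_jt` a small tissue offset, `o_js` an optional per-species
#' baseline offset on causal CpGs, and Gaussian noise `eps`. Causal CpGs
#' receive slopes `b` calibrated so their population age correlation is
#' `effect_scale`; CpG-island causal CpGs draw slopes 1.5x larger, which
#' reproduces the stronger island age correlations by construction.
#'
#' @param n_cpgs Total CpGs.
#' @param n_causal_pos,n_causal_neg CpGs gaining / losing methylation with
#'   age.
#' @param design Data frame of (tissue, species) cells; see
#'   [equid_blood_design()].
#' @param species_table A [species_table()] covering every design species.
#' @param effect_scale Target |Pearson correlation| with age for a causal
#'   CpG at baseline (non-island) scale, in (0, 1).
#' @param shared_fraction Fraction of causal CpGs planted in every tissue;
#'   the remainder are split between tissues as tissue-specific effects.
#' @param island_fraction Fraction of CpGs labelled CpG island.
#' @param island_multiplier Slope multiplier for island causal CpGs.
#' @param n_castration_cpgs,castration_effect Number of CpGs receiving a
#'   gelding mean shift, and its magnitude (beta units).
#' @param species_offset Optional named numeric: per-species baseline beta
#'   offset added to causal CpGs (used to emulate the systematic bias a
#'   leave-one-species-out clock shows in an offset species).
#' @param noise_sd Beta-scale Gaussian noise sd.
#' @param seed Integer seed; identical configs and seeds give identical
#'   output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cpgs = 2000, n_causal_pos = 150, n_causal_neg = 150,
                       design = equid_blood_design(),
                       species_table = equid_species_table(),
                       effect_scale = 0.8, shared_fraction = 0.7,
                       island_fraction = 0.3, island_multiplier = 1.5,
                       n_castration_cpgs = 0, castration_effect = 0,
                       species_offset = NULL, noise_sd = 0.05, seed = 1) {
  cfg <- list(n_cpgs = n_cpgs, n_causal_pos = n_causal_pos,
              n_causal_neg = n_causal_neg, design = design,
              species_table = species_table, effect_scale = effect_scale,
              shared_fraction = shared_fraction,
              island_fraction = island_fraction,
              island_multiplier = island_multiplier,
              n_castration_cpgs = n_castration_cpgs,
              castration_effect = castration_effect,
              species_offset = species_offset, noise_sd = noise_sd,
              seed = seed)
  if (any(c(n_cpgs, n_causal_pos, n_causal_neg, n_castration_cpgs) < 0)) {
    eq_stop("eq_config_error", "counts must be non-negative")
  }
  if (n_causal_pos + n_causal_neg > n_cpgs) {
    eq_stop("eq_config_error", "causal CpGs exceed n_cpgs")
  }
  if (effect_scale < 0 || effect_scale >= 1) {
    eq_stop("eq_config_error", "effect_scale must lie in [0, 1)")
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    eq_stop("eq_config_error", "shared_fraction must lie in [0, 1]")
  }
  dcols <- c("tissue", "species", "n_female", "n_gelding", "n_stallion",
             "age_min", "age_max")
  if (!all(dcols %in% names(design))) {
    eq_stop("eq_config_error", "design needs columns: %s",
            paste(dcols, collapse = ", "))
  }
  if (any(design$n_female < 0 | design$n_gelding < 0 |
            design$n_stallion < 0)) {
    eq_stop("eq_config_error", "design sample counts must be non-negative")
  }
  missing_sp <- setdiff(design$species, species_table$species)
  if (length(missing_sp) > 0) {
    eq_stop("eq_config_error", "design species missing from species table: %s",
            paste(missing_sp, collapse = ", "))
  }
  if (is.null(seed)) eq_stop("eq_config_error", "a seed is required")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a methylation dataset with a planted aging signal
#'
#' @param config A [sim_config()].
#' @return A list with `beta` ([beta_matrix()]), `sheet`
#'   ([sample_sheet()]), `annot` ([cpg_annotation()]), `truth` (long data
#'   frame: `cpg_id`, `tissue`, `planted_b` — the slope on scaled age — and
#'   `planted_gamma`), and `config`.
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_methylation_impl(config))
}

simulate_methylation_impl <- function(cfg) {
  p <- cfg$n_cpgs
  cpg_ids <- sprintf("cg%05d", seq_len(p))
  n_causal <- cfg$n_causal_pos + cfg$n_causal_neg
  causal_idx <- if (n_causal > 0) sort(sample.int(p, n_causal)) else integer(0)
  pos_idx <- if (cfg$n_causal_pos > 0) {
    sort(causal_idx[sample.int(n_causal, cfg$n_causal_pos)])
  } else integer(0)
  neg_idx <- setdiff(causal_idx, pos_idx)

  island <- sample(c("island", "non-island"), p, replace = TRUE,
                   prob = c(cfg$island_fraction, 1 - cfg$island_fraction))

  # Slope magnitude calibrated so corr(beta, g) ~ effect_scale for uniform g:
  # b = r/sqrt(1-r^2) * noise_sd / sd(g), sd(uniform on [0,1]) = 1/sqrt(12).
  b0 <- cfg$effect_scale / sqrt(1 - cfg$effect_scale^2) *
    cfg$noise_sd / (1 / sqrt(12))
  b <- numeric(p)
  b[pos_idx] <- b0 * stats::runif(length(pos_idx), 0.85, 1.15)
  b[neg_idx] <- -b0 * stats::runif(length(neg_idx), 0.85, 1.15)
  b[causal_idx] <- b[causal_idx] *
    ifelse(island[causal_idx] == "island", cfg$island_multiplier, 1)

  tissues <- unique(cfg$design$tissue)
  # Which causal CpGs act in which tissue: a shared core plus
  # tissue-specific remainders split round-robin.
  n_shared <- round(cfg$shared_fraction * n_causal)
  shared <- if (n_causal > 0) {
    sort(causal_idx[sample.int(n_causal, n_shared)])
  } else integer(0)
  specific <- setdiff(causal_idx, shared)
  specific_of <- split(specific,
                       rep_len(seq_along(tissues), length(specific)))
  active <- lapply(seq_along(tissues), function(k) {
    sort(c(shared, specific_of[[as.character(k)]] %||% integer(0)))
  })
  names(active) <- tissues

  gamma <- numeric(p)
  if (cfg$n_castration_cpgs > 0) {
    pool <- setdiff(seq_len(p), causal_idx)
    gamma_idx <- sort(pool[sample.int(length(pool),
                                      min(cfg$n_castration_cpgs,
                                          length(pool)))])
    gamma[gamma_idx] <- cfg$castration_effect
  }

  # Baselines leave headroom for slope + castration shift + noise.
  margin <- 0.02 + 2.5 * cfg$noise_sd
  lo <- margin + pmax(0, -b) + pmax(0, -gamma)
  hi <- 1 - margin - pmax(0, b) - pmax(0, gamma)
  bad_room <- lo >= hi
  if (any(bad_room)) {
    eq_stop("eq_config_error",
            "effect/noise combination leaves no headroom for %d CpG(s)",
            sum(bad_room))
  }
  mu <- stats::runif(p, lo, hi)
  tissue_off <- matrix(stats::rnorm(p * length(tissues), 0, 0.015), p,
                       length(tissues), dimnames = list(NULL, tissues))

  # Samples.
  des <- cfg$design
  rows <- lapply(seq_len(nrow(des)), function(i) {
    d <- des[i, ]
    n_i <- d$n_female + d$n_gelding + d$n_stallion
    if (n_i == 0) return(NULL)
    data.frame(
      tissue = d$tissue, species = d$species,
      sex = c(rep("female", d$n_female), rep("male", d$n_gelding + d$n_stallion)),
      castrated = c(rep("not_applicable", d$n_female),
                    rep("yes", d$n_gelding), rep("no", d$n_stallion)),
      age = stats::runif(n_i, d$age_min, d$age_max),
      stringsAsFactors = FALSE
    )
  })
  sheet <- do.call(rbind, rows)
  sheet$sample_id <- sprintf("%s_%s_%03d", sheet$tissue, sheet$species,
                             stats::ave(seq_len(nrow(sheet)),
                                        paste(sheet$tissue, sheet$species),
                                        FUN = seq_along))
  n <- nrow(sheet)

  # Age scaled to [0,1] over each tissue's design range.
  t_range <- lapply(tissues, function(t) {
    r <- des[des$tissue == t, ]
    c(min(r$age_min), max(r$age_max))
  })
  names(t_range) <- tissues
  g <- vapply(seq_len(n), function(i) {
    r <- t_range[[sheet$tissue[i]]]
    (sheet$age[i] - r[1]) / (r[2] - r[1])
  }, 0)

  gelding <- as.numeric(sheet$castrated == "yes")
  off_sp <- matrix(0, p, n)
  if (!is.null(cfg$species_offset)) {
    for (sp in names(cfg$species_offset)) {
      cols <- sheet$species == sp
      off_sp[causal_idx, cols] <- cfg$species_offset[[sp]]
    }
  }

  # Per-tissue active slope matrix (p x n).
  b_eff <- matrix(0, p, n)
  for (t in tissues) {
    cols <- sheet$tissue == t
    b_eff[active[[t]], cols] <- b[active[[t]]]
  }

  eps <- matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n)
  raw <- mu + tissue_off[, sheet$tissue, drop = FALSE] + off_sp +
    b_eff * rep(g, each = p) + gamma %o% gelding + eps
  clipped <- raw < 0 | raw > 1
  if (mean(clipped) > 0.2) {
    eq_stop("eq_config_error",
            "config clips %.1f%% of beta entries (> 20%%): reduce effects or noise",
            100 * mean(clipped))
  }
  vals <- t(pmin(pmax(raw, 0), 1))
  dimnames(vals) <- list(sheet$sample_id, cpg_ids)

  genes <- sprintf("G%04d", ceiling(seq_len(p) / 4))
  annot <- cpg_annotation(data.frame(
    cpg_id = cpg_ids,
    gene = genes,
    tss_distance = as.integer(round(stats::runif(p, -20000, 20000))),
    island = island,
    position_class = sample(position_class_vocabulary(), p, replace = TRUE,
                            prob = c(0.15, 0.05, 0.2, 0.3, 0.05, 0.25)),
    chrom_state = sample(chrom_state_vocabulary(), p, replace = TRUE),
    stringsAsFactors = FALSE
  ))

  truth_rows <- lapply(tissues, function(t) {
    idx <- sort(union(active[[t]], which(gamma != 0)))
    if (length(idx) == 0) return(NULL)
    data.frame(cpg_id = cpg_ids[idx], tissue = t,
               planted_b = ifelse(idx %in% active[[t]], b[idx], 0),
               planted_gamma = gamma[idx], stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truth_rows) %||%
    data.frame(cpg_id = character(0), tissue = character(0),
               planted_b = numeric(0), planted_gamma = numeric(0))

  list(beta = beta_matrix(vals),
       sheet = sample_sheet(sheet[, c("sample_id", "age", "species", "tissue",
                                      "sex", "castrated")]),
       annot = annot, truth = truth, config = cfg)
}

#' Configuration for the multi-tissue atlas simulator
#'
#' The atlas generator emulates a small two-animal many-tissue panel in
#' which promoter methylation and gene expression are coupled with a sign
#' and strength set by the gene's chromatin state. Per gene g and tissue t,
#' promoter methylation is `m_gt = mu_g + dev_gt`; each CpG tracks `m_gt`
#' plus a CpG offset and noise, with a fidelity that optionally decays with
#' TSS distance; log2 expression is
#' `x = base_g + coupling(state_g) * m_gt + noise`.
#'
#' @param n_tissues Number of tissues (>= 3).
#' @param n_animals Animals per tissue.
#' @param n_genes Genes simulated.
#' @param cpgs_per_gene Promoter-window CpGs per gene.
#' @param distal_cpgs_per_gene CpGs per gene placed outside the promoter
#'   window (they still track promoter methylation, probing window
#'   discipline).
#' @param state_coupling Named numeric: log2-expression change per unit
#'   promoter beta, per chromatin state. Defaults plant negative couplings
#'   in enhancer states and positive couplings at bivalent promoters,
#'   polycomb targets, promoter flanks and TSSs.
#' @param beta_tissue_sd Across-tissue sd of promoter methylation.
#' @param cpg_noise_sd Within-promoter CpG-level noise sd.
#' @param expr_noise_sd Log2-expression noise sd.
#' @param distance_decay_bp If finite, each CpG's fidelity to its gene's
#'   promoter methylation decays as
#'   `exp(-|tss_distance| / distance_decay_bp)`, so coupling strength fades
#'   with distance from the TSS.
#' @param promoter_window Length-2 window (bp, signed; negative = upstream)
#'   within which CpGs count as promoter CpGs.
#' @param seed Integer seed.
#' @return A list of class `"atlas_sim_config"`.
#' @export
atlas_sim_config <- function(n_tissues = 29, n_animals = 2, n_genes = 240,
                             cpgs_per_gene = 3, distal_cpgs_per_gene = 1,
                             state_coupling = default_state_coupling(),
                             beta_tissue_sd = 0.1, cpg_noise_sd = 0.03,
                             expr_noise_sd = 0.3, distance_decay_bp = Inf,
                             promoter_window = c(-10000, 1000), seed = 1) {
  if (n_tissues < 3) eq_stop("eq_config_error", "n_tissues must be >= 3")
  if (!all(is.finite(state_coupling))) {
    eq_stop("eq_config_error", "state couplings must be finite")
  }
  unknown <- setdiff(names(state_coupling), chrom_state_vocabulary())
  if (length(unknown) > 0) {
    eq_stop("eq_config_error", "unknown chromatin state(s): %s",
            paste(unknown, collapse = ", "))
  }
  if (is.null(seed)) eq_stop("eq_config_error", "a seed is required")
  structure(list(n_tissues = n_tissues, n_animals = n_animals,
                 n_genes = n_genes, cpgs_per_gene = cpgs_per_gene,
                 distal_cpgs_per_gene = distal_cpgs_per_gene,
                 state_coupling = state_coupling,
                 beta_tissue_sd = beta_tissue_sd,
                 cpg_noise_sd = cpg_noise_sd, expr_noise_sd = expr_noise_sd,
                 distance_decay_bp = distance_decay_bp,
                 promoter_window = promoter_window, seed = seed),
            class = "atlas_sim_config")
}

#' @rdname atlas_sim_config
#' @export
default_state_coupling <- function() {
  c(TSS = 3, PromF = 2.5, BivProm = 3, ReprPC = 2.5,
    EnhA = -3, EnhWk = -2, TxEnh = -2.5,
    Tx = 0, TxEx = 0, Acet = 0, Het = 0, Quies = 0)
}

#' Simulate a multi-tissue methylation + expression atlas
#'
#' @param config An [atlas_sim_config()].
#' @return A list with `beta` ([beta_matrix()]; samples are tissue-animal
#'   pairs), `expression` (genes x samples, linear TPM-like scale so
#'   `log2(x + 1)` recovers the generated log level), `annot`
#'   ([cpg_annotation()]), `truth` (per CpG: gene, state, planted coupling,
#'   tss_distance, in_window), and `config`.
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_sim_config"))
  with_seed(config$seed, simulate_atlas_impl(config))
}

simulate_atlas_impl <- function(cfg) {
  states <- names(cfg$state_coupling)
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  gene_state <- states[rep_len(seq_along(states), cfg$n_genes)]
  coupling <- unname(cfg$state_coupling[gene_state])

  tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
  samples <- as.vector(outer(tissues, seq_len(cfg$n_animals),
                             function(t, a) sprintf("%s_a%d", t, a)))
  n <- length(samples)
  sample_tissue <- rep(tissues, times = cfg$n_animals)

  k_in <- cfg$cpgs_per_gene
  k_out <- cfg$distal_cpgs_per_gene
  k <- k_in + k_out
  p <- cfg$n_genes * k
  cpg_gene <- rep(seq_len(cfg$n_genes), each = k)
  in_window <- rep(c(rep(TRUE, k_in), rep(FALSE, k_out)), cfg$n_genes)
  w <- cfg$promoter_window
  dist <- integer(p)
  dist[in_window] <- as.integer(round(stats::runif(sum(in_window),
                                                   w[1], w[2])))
  # Distal CpGs sit well outside the window, beyond either edge.
  if (any(!in_window)) {
    side <- sample(c(-1, 1), sum(!in_window), replace = TRUE)
    dist[!in_window] <- as.integer(round(ifelse(
      side < 0, stats::runif(sum(!in_window), w[1] - 40000, w[1] - 5000),
      stats::runif(sum(!in_window), w[2] + 5000, w[2] + 40000))))
  }
  cpg_ids <- sprintf("atg%05d", seq_len(p))

  mu_g <- stats::runif(cfg$n_genes, 0.3, 0.7)
  dev <- matrix(stats::rnorm(cfg$n_genes * cfg$n_tissues, 0,
                             cfg$beta_tissue_sd),
                cfg$n_genes, cfg$n_tissues, dimnames = list(genes, tissues))
  m_gt <- mu_g + dev  # latent promoter methylation per gene x tissue

  # Each CpG tracks its gene's promoter methylation with a fidelity that
  # decays with TSS distance when a decay scale is set.
  fid <- if (is.finite(cfg$distance_decay_bp)) {
    exp(-abs(dist) / cfg$distance_decay_bp)
  } else rep(1, p)
  cpg_off <- stats::runif(p, -0.05, 0.05)
  tiss_idx <- match(sample_tissue, tissues)
  raw <- mu_g[cpg_gene] + fid * dev[cbind(rep(cpg_gene, n),
                                          rep(tiss_idx, each = p))] +
    cpg_off + matrix(stats::rnorm(p * n, 0, cfg$cpg_noise_sd), p, n)
  raw <- matrix(raw, p, n)
  clipped <- raw < 0 | raw > 1
  if (mean(clipped) > 0.2) {
    eq_stop("eq_config_error",
            "atlas config clips %.1f%% of beta entries (> 20%%)",
            100 * mean(clipped))
  }
  beta_vals <- t(pmin(pmax(raw, 0), 1))
  dimnames(beta_vals) <- list(samples, cpg_ids)

  base_g <- stats::runif(cfg$n_genes, 2, 8)
  log_expr <- base_g + coupling * m_gt[, tiss_idx, drop = FALSE] +
    matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd),
           cfg$n_genes, n)
  expr <- pmax(2^log_expr - 1, 0)
  dimnames(expr) <- list(genes, samples)

  annot <- cpg_annotation(data.frame(
    cpg_id = cpg_ids,
    gene = genes[cpg_gene],
    tss_distance = dist,
    island = sample(c("island", "non-island"), p, replace = TRUE,
                    prob = c(0.4, 0.6)),
    position_class = ifelse(in_window, "promoter", "intergenic"),
    chrom_state = gene_state[cpg_gene],
    stringsAsFactors = FALSE
  ))
  truth <- data.frame(
    cpg_id = cpg_ids, gene = genes[cpg_gene],
    chrom_state = gene_state[cpg_gene],
    state_coupling = coupling[cpg_gene],
    tss_distance = dist, in_window = in_window,
    stringsAsFactors = FALSE
  )
  list(beta = beta_matrix(beta_vals), expression = expr, annot = annot,
       truth = truth, config = cfg)
}
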