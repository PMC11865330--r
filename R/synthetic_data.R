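#' Specification of a synthetic pH-gradient community
#'
#' Defines the study design emulated by the generators: a soil survey along
#' a pH gradient with a planted "comammox-like" keystone taxon whose
#' abundance declines with pH, a cooperation block of taxa co-varying with
#' it, two environmentally structured guilds (acid- and alkaline-favoured),
#' and a pool of unstructured taxa. All downstream estimators (screening,
#' networks, cohesion, cascades, rrn/MCN, genome and SIP analyses) can be
#' exercised on the output with known ground truth.
#'
#' @param n_samples Number of soil samples (>= 6). Default 36, the scale of
#'   a three-group survey with 12 sites x 3 replicates.
#' @param n_taxa Total number of taxa in the community table.
#' @param ph_range Length-2 numeric, the pH interval covered evenly by the
#'   samples (within `[0, 14]`). Default `c(4.4, 9.7)`.
#' @param keystone_ph_slope Target Pearson correlation between the keystone
#'   taxon's abundance and pH; negative for an acid-favoured keystone.
#' @param coop_block_size Number of taxa loading on the keystone-anchored
#'   cooperation factor (`< n_taxa`).
#' @param noise_sd Standard deviation of idiosyncratic noise on the latent
#'   log-abundance scale.
#' @param sequencing_depth Reads per sample drawn multinomially from the
#'   latent composition (> 0).
#' @param seed Master integer seed; every generated artifact derives its
#'   own labelled sub-seed from it.
#' @param env_block_size Number of acid-favoured guild taxa.
#' @param alk_block_size Number of alkaline-favoured guild taxa. The
#'   default is 0: high-pH samples are then dominated by the unstructured
#'   taxa, keeping the planted cooperative structure one-sided (acid),
#'   which is the contrast the cohesion and cascade estimators target.
#' @param coop_r Target correlation between a cooperation-block taxon and
#'   the keystone's latent abundance. Block members' residuals are centred
#'   within the block (cooperators competing for the shared good), so
#'   block-block correlations stay well below the block-keystone ones and
#'   the keystone is the block's sole strong network anchor.
#' @param keystone_coop_loading Loading of the keystone on the acid-side
#'   cooperation factor; couples the keystone's abundance to the
#'   cooperative co-variation that positive cohesion measures.
#' @param coop_abundance_boost Log-abundance boost added to the
#'   cooperation block's baselines, making the cooperators an abundant
#'   community component (so sample cohesion is materially driven by the
#'   keystone-anchored block).
#' @param keystone_abundance_boost Log-abundance boost for the keystone
#'   itself (a dominant, not rare, community member).
#' @param env_ph_loading Standardised loading of both environmental guilds
#'   on the (signed) pH axis; sets the cross-guild correlation
#'   (~`-ph_loading^2`).
#' @param env_factor_loading,alk_factor_loading Loadings of the acid- and
#'   alkaline-favoured guilds on their respective shared guild factors.
#'   The acid-side default is higher: cooperative co-variation is planted
#'   to be stronger under acid stress, which is the asymmetry the
#'   downstream cohesion analysis is meant to recover.
#'
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_samples = 36, n_taxa = 100,
                           ph_range = c(4.4, 9.7),
                           keystone_ph_slope = -0.6,
                           coop_block_size = 10,
                           noise_sd = 0.5,
                           sequencing_depth = 20000,
                           seed = 1,
                           env_block_size = 20,
                           alk_block_size = 0,
                           coop_r = 0.75,
                           keystone_coop_loading = 0.55,
                           coop_abundance_boost = 0,
                           keystone_abundance_boost = 0,
                           env_ph_loading = 0.5,
                           env_factor_loading = 0.65,
                           alk_factor_loading = 0.45) {
  stop_if_not_scalar_number(n_samples, "n_samples")
  stop_if_not_scalar_number(n_taxa, "n_taxa")
  stop_if_not_scalar_number(sequencing_depth, "sequencing_depth")
  stop_if_not_scalar_number(seed, "seed")
  if (n_samples < 6) {
    stop("n_samples must be >= 6: downstream correlations are degenerate ",
         "for smaller designs", call. = FALSE)
  }
  if (length(ph_range) != 2L || any(ph_range < 0) || any(ph_range > 14) ||
      ph_range[1] >= ph_range[2]) {
    stop("ph_range must be an increasing pair within [0, 14]", call. = FALSE)
  }
  if (abs(keystone_ph_slope) >= 1) {
    stop("keystone_ph_slope is a target correlation and must lie in (-1, 1)",
         call. = FALSE)
  }
  if (coop_block_size < 0 || coop_block_size >= n_taxa) {
    stop("coop_block_size must be non-negative and smaller than n_taxa",
         call. = FALSE)
  }
  if (sequencing_depth <= 0) stop("sequencing_depth must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (coop_r <= 0 || coop_r >= 1) stop("coop_r must be in (0, 1)", call. = FALSE)
  if (env_ph_loading^2 + max(env_factor_loading, alk_factor_loading)^2 >= 1) {
    stop("env_ph_loading^2 + env_factor_loading^2 must be < 1", call. = FALSE)
  }
  num <- function(x) unname(as.numeric(x))
  structure(list(
    n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
    ph_range = num(ph_range),
    keystone_ph_slope = num(keystone_ph_slope),
    coop_block_size = as.integer(coop_block_size),
    noise_sd = num(noise_sd),
    sequencing_depth = as.integer(sequencing_depth),
    seed = as.integer(seed),
    env_block_size = as.integer(env_block_size),
    alk_block_size = as.integer(alk_block_size),
    coop_r = num(coop_r),
    env_ph_loading = num(env_ph_loading),
    env_factor_loading = num(env_factor_loading),
    alk_factor_loading = num(alk_factor_loading),
    keystone_coop_loading = num(keystone_coop_loading),
    coop_abundance_boost = num(coop_abundance_boost),
    keystone_abundance_boost = num(keystone_abundance_boost)
  ), class = "community_spec")
}

#' Assign a pH group label
#'
#' Group A: pH < 6.5; Group B: 6.5 <= pH <= 7.5; Group C: pH > 7.5.
#'
#' @param ph Numeric vector of pH values.
#' @return Character vector of group labels.
#' @export
ph_group <- function(ph) {
  ifelse(ph < 6.5, "A", ifelse(ph <= 7.5, "B", "C"))
}

#' Generate sample metadata along the pH gradient
#'
#' pH values are spaced evenly over `ph_range` and labelled A/B/C by the
#' standard boundaries (see [ph_group()]). Temperature and ammonium
#' covariates are drawn log-normally from fixed defaults.
#'
#' @param spec A [community_spec()].
#' @return A data.frame with columns `sample_id`, `ph`, `group`,
#'   `temperature_c`, `ammonium_mg_kg`.
#' @export
generate_metadata <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  n <- spec$n_samples
  ph <- seq(spec$ph_range[1], spec$ph_range[2], length.out = n)
  covar <- with_seed(sub_seed(spec$seed, "metadata"), {
    list(temperature_c = stats::rlnorm(n, meanlog = log(18), sdlog = 0.15),
         ammonium_mg_kg = stats::rlnorm(n, meanlog = log(5), sdlog = 0.5))
  })
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             ph = ph,
             group = ph_group(ph),
             temperature_c = covar$temperature_c,
             ammonium_mg_kg = covar$ammonium_mg_kg,
             stringsAsFactors = FALSE)
}

#' Taxon-by-sample abundance table
#'
#' Lightweight container pairing a non-negative count (or relative
#' abundance) matrix with a taxonomy table.
#'
#' @param counts Numeric taxon x sample matrix, non-negative, with row and
#'   column names.
#' @param taxonomy data.frame with one row per taxon (`taxon_id` plus
#'   lineage columns such as `phylum` .. `genus`); rows must match the
#'   count matrix rows.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts))) stop("counts must have taxon rownames", call. = FALSE)
  stopifnot(is.data.frame(taxonomy), "taxon_id" %in% names(taxonomy))
  if (!identical(rownames(counts), taxonomy$taxon_id)) {
    stop("taxonomy rows must match count matrix rows", call. = FALSE)
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (total %g)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# Standardised latent loadings for each planted taxon class. Every taxon's
# latent log-abundance is baseline + (noise_sd / w_noise) * z, where z is a
# unit-variance combination of the pH axis, guild factors and idiosyncratic
# noise, so pairwise latent correlations equal the loading cross-products.
community_roles <- function(spec) {
  n <- spec$n_taxa
  b <- spec$coop_block_size
  e <- spec$env_block_size
  a <- spec$alk_block_size
  if (1L + b + e + a > n) {
    stop("n_taxa too small for keystone + coop + guild blocks", call. = FALSE)
  }
  role <- rep("noise", n)
  role[1L] <- "keystone"
  if (b > 0) role[seq_len(b) + 1L] <- "coop"
  if (e > 0) role[(1L + b) + seq_len(e)] <- "acid"
  if (a > 0) role[(1L + b + e) + seq_len(a)] <- "alkaline"
  role
}

#' Generate a synthetic community with planted keystone structure
#'
#' Latent log-abundances are built from standardised loadings: the keystone
#' loads on (centred, standardised) pH with loading `keystone_ph_slope`;
#' cooperation-block taxa load on the keystone's latent abundance with
#' correlation `coop_r`; two environmental guilds load on the pH axis
#' (opposite signs) plus a shared within-guild factor; remaining taxa are
#' idiosyncratic noise. Counts are drawn multinomially at
#' `sequencing_depth` from the softmax of the latent values, so column sums
#' equal the depth exactly.
#'
#' @param spec A [community_spec()].
#' @param meta Metadata from [generate_metadata()] (its `ph` column drives
#'   the gradient).
#' @return A list with elements `table` (an [abundance_table()]) and
#'   `truth` (planted keystone id, cooperation block ids, per-taxon role,
#'   rrn copy-number map and genus-level lookup, planted SIP density shift).
#' @export
generate_community <- function(spec, meta) {
  stopifnot(inherits(spec, "community_spec"), is.data.frame(meta),
            all(c("sample_id", "ph") %in% names(meta)))
  n_s <- nrow(meta)
  n_t <- spec$n_taxa
  ph <- meta$ph
  z_ph <- as.numeric(scale(ph))          # unit-variance pH axis
  role <- community_roles(spec)
  taxon_id <- sprintf("taxon_%04d", seq_len(n_t))

  out <- with_seed(sub_seed(spec$seed, "community"), {
    f_acid <- stats::rnorm(n_s)          # shared guild factors
    f_alk <- stats::rnorm(n_s)
    baseline <- stats::rnorm(n_t, 0, 0.8)
    baseline[role == "coop"] <- baseline[role == "coop"] +
      spec$coop_abundance_boost
    baseline[role == "keystone"] <- baseline[role == "keystone"] +
      spec$keystone_abundance_boost

    w_ph <- spec$env_ph_loading
    w_f <- spec$env_factor_loading
    w_fa <- spec$alk_factor_loading
    w_n_acid <- sqrt(1 - w_ph^2 - w_f^2)
    w_n_alk <- sqrt(1 - w_ph^2 - w_fa^2)

    z <- matrix(stats::rnorm(n_t * n_s), n_t, n_s)  # idiosyncratic draws
    # noise-free limit: only the deterministic pH responses remain, so
    # planted gradients are exactly monotone in pH
    noise_free <- spec$noise_sd == 0
    if (noise_free) {
      z[] <- 0
      f_acid <- rep(0, n_s)
      f_alk <- rep(0, n_s)
    }
    lat <- matrix(0, n_t, n_s)
    # multinomial resampling and compositional closure attenuate the
    # latent correlation by ~20% at the default depth; compensate so the
    # realised Pearson(rel. abundance, pH) lands near the target slope
    s <- sign(spec$keystone_ph_slope) *
      min(0.97, abs(spec$keystone_ph_slope) * 1.2)
    g <- spec$keystone_coop_loading
    if (s^2 + g^2 >= 1) {
      stop("keystone pH and cooperation loadings must satisfy ",
           "slope^2 + loading^2 < 1", call. = FALSE)
    }
    # keystone latent = pH response + cooperation-factor coupling + noise
    w_core <- sqrt(1 - s^2 - g^2)
    z_key <- s * z_ph + g * f_acid + w_core * z[1L, ]
    # centre block residuals across the block so cooperators share the
    # keystone anchor but not each other (pairwise residual cor -1/(B-1))
    idx_coop <- which(role == "coop")
    if (length(idx_coop) > 1L) {
      eps <- z[idx_coop, , drop = FALSE]
      eps <- sweep(eps, 2, colMeans(eps)) *
        sqrt(length(idx_coop) / (length(idx_coop) - 1L))
      z[idx_coop, ] <- eps
    }
    for (i in seq_len(n_t)) {
      lat[i, ] <- switch(role[i],
        keystone = z_key,
        coop = spec$coop_r * z_key + sqrt(1 - spec$coop_r^2) * z[i, ],
        acid = -w_ph * z_ph + w_f * f_acid + w_n_acid * z[i, ],
        alkaline = w_ph * z_ph + w_fa * f_alk + w_n_alk * z[i, ],
        noise = z[i, ])
    }
    scale_fac <- if (noise_free) rep(1, n_t) else spec$noise_sd / c(
      keystone = sqrt(1 - s^2 - g^2),
      coop = sqrt(1 - spec$coop_r^2),
      acid = w_n_acid, alkaline = w_n_alk, noise = 1
    )[role]
    y <- baseline + scale_fac * lat

    counts <- matrix(0L, n_t, n_s,
                     dimnames = list(taxon_id, meta$sample_id))
    for (j in seq_len(n_s)) {
      p <- exp(y[, j] - max(y[, j]))
      counts[, j] <- stats::rmultinom(1, spec$sequencing_depth, p / sum(p))
    }
    counts
  })

  taxonomy <- build_taxonomy(taxon_id, role)
  rrn <- build_rrn(taxonomy, role, spec$seed)
  truth <- list(
    keystone_id = taxon_id[role == "keystone"],
    coop_block_ids = taxon_id[role == "coop"],
    role = stats::setNames(role, taxon_id),
    rrn_map = rrn$map,
    rrn_lookup = rrn$lookup,
    planted_shift = 0.01
  )
  list(table = abundance_table(out, taxonomy), truth = truth)
}

# Genus assignment groups taxa of the same ecological class into small
# genera so genus-level operations (core screen, rrn lookup) are exercised.
build_taxonomy <- function(taxon_id, role) {
  genus <- character(length(role))
  stem <- c(keystone = "Nitrospira", coop = "Cooperibacter",
            acid = "Acidiphilum", alkaline = "Alkaliphilum",
            noise = "Soilibacter")
  for (r in names(stem)) {
    idx <- which(role == r)
    if (!length(idx)) next
    if (r == "keystone") {
      genus[idx] <- stem[[r]]
    } else {
      genus[idx] <- sprintf("%s_%d", stem[[r]], ((seq_along(idx) - 1L) %/% 3L) + 1L)
    }
  }
  phyla <- c(keystone = "Nitrospirota", coop = "Pseudomonadota",
             acid = "Acidobacteriota", alkaline = "Bacillota",
             noise = "Actinomycetota")
  data.frame(taxon_id = taxon_id,
             domain = "Bacteria",
             phylum = unname(phyla[role]),
             family = paste0(sub("_.*", "", genus), "aceae"),
             genus = genus,
             stringsAsFactors = FALSE)
}

# rrn copy numbers encode the planted growth-strategy gradient: the
# keystone carries a single operon (as Nitrospira do), acid-favoured taxa
# are slow growers (1-2 copies), alkaline-favoured taxa fast growers (5-7),
# unstructured taxa intermediate (2-4). Values are assigned per genus.
build_rrn <- function(taxonomy, role, seed) {
  genera <- unique(data.frame(genus = taxonomy$genus,
                              role = role, stringsAsFactors = FALSE))
  copies <- with_seed(sub_seed(seed, "rrn"), {
    vapply(seq_len(nrow(genera)), function(i) {
      switch(genera$role[i],
             keystone = 1,
             coop = sample(1:2, 1),
             acid = sample(1:2, 1),
             alkaline = sample(5:7, 1),
             noise = sample(4:6, 1))
    }, numeric(1))
  })
  lookup <- data.frame(name = genera$genus, rank = "genus",
                       copies = copies, stringsAsFactors = FALSE)
  map <- stats::setNames(copies[match(taxonomy$genus, genera$genus)],
                         taxonomy$taxon_id)
  list(lookup = lookup, map = map)
}

#' Generate guild-level amoA copy-number tables
#'
#' Per-sample qPCR-style copy numbers (copies per g dry soil) for the three
#' ammonia-oxidizer guilds. The comammox guild's log10 abundance declines
#' with pH by `effects["comammox"]` log10 units per pH unit; AOA and AOB
#' are flat by default. Baselines place comammox above AOA below roughly
#' neutral pH, so comammox dominates the acidic portion of the gradient.
#'
#' @param meta Metadata from [generate_metadata()].
#' @param spec A [community_spec()] (provides the seed).
#' @param effects Named numeric, log10 copies per pH unit for each guild.
#' @param base_log10 Named numeric, guild mean log10 copies/g at the centre
#'   of the gradient.
#' @param sd_log10 Measurement noise on the log10 scale.
#' @return data.frame with `sample_id` and one strictly positive copies/g
#'   column per guild (`AOA`, `AOB`, `comammox`).
#' @export
generate_guild_amoa <- function(meta, spec,
                                effects = c(AOA = 0, AOB = 0, comammox = -0.5),
                                base_log10 = c(AOA = 6.6, AOB = 6.3,
                                               comammox = 6.8),
                                sd_log10 = 0.2) {
  stopifnot(is.data.frame(meta), "ph" %in% names(meta))
  guilds <- c("AOA", "AOB", "comammox")
  stopifnot(all(guilds %in% names(effects)), all(guilds %in% names(base_log10)))
  phc <- meta$ph - mean(meta$ph)
  n <- nrow(meta)
  vals <- with_seed(sub_seed(spec$seed, "guild_amoa"), {
    sapply(guilds, function(g) {
      10^(base_log10[[g]] + effects[[g]] * phc + stats::rnorm(n, 0, sd_log10))
    })
  })
  out <- data.frame(sample_id = meta$sample_id, vals,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", guilds)
  out
}

#' Generate a genome-by-feature table with planted cobalamin structure
#'
#' Emulates a MAG catalogue: most genomes carry at least one cobalamin
#' dependence gene (mutA/metH/rsmB), very few carry the complete synthesis
#' pathway (steps A, B and C), and the keystone genome always does. The
#' keystone genome's per-sample abundance is tied to the keystone taxon in
#' the community table; other genomes are flat in pH.
#'
#' @param spec A [community_spec()].
#' @param truth Truth list from [generate_community()].
#' @param community The community list from [generate_community()] (its
#'   table supplies the keystone abundance profile).
#' @param n_genomes Number of genomes in the catalogue.
#' @param cd_prevalence Probability a genome carries >= 1 dependence gene.
#' @param cs_prevalence Probability a non-keystone genome carries the full
#'   synthesis pathway.
#' @return List with `features` (data.frame of boolean gene/step columns
#'   and a `label` column, "comammox" for the keystone genome), `abundance`
#'   (genome x sample relative abundance matrix), and the planted
#'   `cs_genome_ids` / `cd_genome_ids`.
#' @export
generate_genome_features <- function(spec, truth, community,
                                     n_genomes = 80,
                                     cd_prevalence = 0.85,
                                     cs_prevalence = 0.03) {
  stopifnot(n_genomes >= 2)
  rel <- to_relative(community$table$counts)
  keystone_ab <- rel[truth$keystone_id, ]
  genome_id <- sprintf("MAG_%03d", seq_len(n_genomes))

  res <- with_seed(sub_seed(spec$seed, "genomes"), {
    is_cd <- stats::rbinom(n_genomes, 1, cd_prevalence) == 1
    genes <- matrix(FALSE, n_genomes, 3,
                    dimnames = list(genome_id, c("mutA", "metH", "rsmB")))
    for (i in which(is_cd)) {
      k <- sample(1:3, 1)
      genes[i, sample(3, k)] <- TRUE
    }
    is_cs <- stats::rbinom(n_genomes, 1, cs_prevalence) == 1
    is_cs[1L] <- TRUE                     # keystone genome: full pathway
    # one guaranteed non-keystone supplier (a Reyranella-like genome), so
    # the supplier share is defined whenever synthesis is possible at all
    if (cs_prevalence > 0) is_cs[2L] <- TRUE
    steps <- matrix(FALSE, n_genomes, 3,
                    dimnames = list(genome_id, c("stepA", "stepB", "stepC")))
    steps[is_cs, ] <- TRUE
    partial <- !is_cs & stats::runif(n_genomes) < 0.2
    for (i in which(partial)) {
      steps[i, sample(3, sample(1:2, 1))] <- TRUE
    }
    # non-keystone genomes: log-normal abundance, flat in pH
    base <- stats::rlnorm(n_genomes - 1L, meanlog = 0, sdlog = 1)
    noise <- matrix(stats::rlnorm((n_genomes - 1L) * length(keystone_ab),
                                  0, 0.3), n_genomes - 1L)
    others <- base * noise
    others <- sweep(others, 2, colSums(others), "/") *
      rep(1 - keystone_ab, each = n_genomes - 1L)
    list(genes = genes, steps = steps, is_cd = is_cd, is_cs = is_cs,
         others = others)
  })

  abundance <- rbind(matrix(keystone_ab, 1), res$others)
  dimnames(abundance) <- list(genome_id, names(keystone_ab))
  features <- data.frame(genome_id = genome_id,
                         res$genes, res$steps,
                         label = c("comammox", rep("other", n_genomes - 1L)),
                         stringsAsFactors = FALSE)
  list(features = features,
       abundance = abundance,
       cs_genome_ids = genome_id[res$is_cs],
       cd_genome_ids = genome_id[res$is_cd | rowSums(res$genes) > 0])
}

#' Generate DNA-SIP density-fraction profiles
#'
#' For each treatment (13C-labelled vs 12C control), guild and replicate, a
#' Gaussian peak over 16 buoyant-density fractions spanning 1.69-1.76 g/mL.
#' Labelled treatments of "active" guilds have their peak centre shifted to
#' heavier density by `truth$planted_shift`; controls and inactive guilds
#' are unshifted. Poisson measurement noise is applied to the per-fraction
#' copy numbers.
#'
#' @param spec A [community_spec()].
#' @param truth Truth list from [generate_community()] (supplies
#'   `planted_shift` in g/mL; must be >= 0).
#' @param guilds Character vector of guild names.
#' @param active_guilds Guilds that assimilate the labelled substrate.
#' @param n_replicates Replicates per treatment x guild.
#' @param n_fractions Number of density fractions (>= 10).
#' @param density_range Buoyant-density span in g/mL.
#' @param light_center Unlabelled peak centre in g/mL.
#' @param peak_sd Gaussian peak standard deviation in g/mL.
#' @param total_copies Expected total copies per profile.
#' @param noise If `FALSE` the discretised Gaussian is returned exactly.
#' @return Long data.frame: `treatment`, `condition`, `replicate`, `guild`,
#'   `fraction_index`, `density`, `copies`.
#' @export
generate_sip_profiles <- function(spec, truth,
                                  guilds = c("AOA", "AOB", "comammox"),
                                  active_guilds = c("comammox", "AOA"),
                                  n_replicates = 3,
                                  n_fractions = 16,
                                  density_range = c(1.69, 1.76),
                                  light_center = 1.705,
                                  peak_sd = 0.010,
                                  total_copies = 1e5,
                                  noise = TRUE) {
  shift <- truth$planted_shift %||% 0
  if (shift < 0) stop("planted_shift must be >= 0", call. = FALSE)
  stopifnot(n_fractions >= 10)
  density <- seq(density_range[1], density_range[2], length.out = n_fractions)
  grid <- expand.grid(treatment = c("13C", "12C"),
                      replicate = seq_len(n_replicates),
                      guild = guilds,
                      stringsAsFactors = FALSE)
  rows <- with_seed(sub_seed(spec$seed, "sip"), {
    lapply(seq_len(nrow(grid)), function(k) {
      g <- grid$guild[k]
      centre <- light_center +
        if (grid$treatment[k] == "13C" && g %in% active_guilds) shift else 0
      w <- stats::dnorm(density, centre, peak_sd)
      expected <- total_copies * w / sum(w)
      copies <- if (noise) stats::rpois(n_fractions, expected) else expected
      data.frame(treatment = grid$treatment[k],
                 condition = "microcosm",
                 replicate = grid$replicate[k],
                 guild = g,
                 fraction_index = seq_len(n_fractions),
                 density = density,
                 copies = copies,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Run the full synthetic study design
#'
#' Convenience wrapper generating metadata, community table + truth, guild
#' amoA copies, genome features and SIP profiles from one spec.
#'
#' @param spec A [community_spec()].
#' @return List of class `acidonet_simulation` with elements `spec`,
#'   `meta`, `table`, `truth`, `amoa`, `genomes`, `sip`.
#' @export
simulate_study <- function(spec = community_spec()) {
  meta <- generate_metadata(spec)
  comm <- generate_community(spec, meta)
  amoa <- generate_guild_amoa(meta, spec)
  genomes <- generate_genome_features(spec, comm$truth, comm)
  sip <- generate_sip_profiles(spec, comm$truth)
  structure(list(spec = spec, meta = meta, table = comm$table,
                 truth = comm$truth, amoa = amoa, genomes = genomes,
                 sip = sip),
            class = "acidonet_simulation")
}
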