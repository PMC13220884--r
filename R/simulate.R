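#' Configuration for the serial-transfer metacommunity simulator
#'
#' Describes a paired closed/open mesocosm experiment: communities founded
#' from distinct inocula are propagated by serial dilution transfers; in the
#' open regime a filtered cocktail pooling the phage (and only the phage) of
#' all open communities is added at every transfer. Defaults emulate the
#' study design: 10 mesocosms of two community types (type A carries the
#' phage natively, mesocosms 1, 2, 5, 6), biweekly 1/20 transfers over 48
#' weeks, sampling at weeks 0, 2, 4, 6, 8, 20, 32, 40, 48, two founder
#' genotypes differing at nine marker SNPs (G1 in mesocosm 2, G2 in 1, 5
#' and 6), two programmed recombination events and a programmed block of 61
#' novel SNPs arriving on the second recombinant after its migration into a
#' type B community.
#'
#' Phage dynamics follow a discrete per-transfer update: hosts regrow to
#' their carrying-capacity share, phage of each genotype infect susceptible
#' hosts in proportion to fitness-weighted abundance with a fixed burst
#' size, and a dilution fraction of cells and virions carries over.
#' Genotype fitness may differ between community types (host-switch
#' adaptation), which is what lets different recombinants dominate
#' different community types under migration. Observed alternative-read
#' counts are drawn binomially from the true within-sample genotype mixture
#' plus a symmetric sequencing error; per-sample depth scales with the true
#' phage read fraction.
#'
#' @param n_mesocosms Number of founding mesocosms (default 10).
#' @param community_types Named character vector mesocosm id -> "A"/"B".
#' @param transfer_interval_weeks Weeks between transfers (default 2).
#' @param total_weeks Experiment length (default 48).
#' @param dilution_factor Carry-over fraction per transfer (default 1/20).
#' @param sampling_weeks Weeks at which samples are sequenced.
#' @param founder_genotypes Named character vector mesocosm id -> founder
#'   genotype id; mesocosms absent from the map start phage-free.
#' @param marker_positions,marker_ref,marker_alt Positions and alleles of
#'   the SNPs separating the founder genotypes (defaults: the nine
#'   published marker SNPs).
#' @param recombination_events List of programmed recombination events;
#'   each a list with `mesocosm`, `regime`, `transfer`, `parents` (two
#'   genotype ids), `breakpoints` (crossover positions), `child_id`,
#'   `fitness` (scalar or `c(A=, B=)`), `seed_fraction`.
#' @param novel_blocks List of programmed novel-SNP block events; each a
#'   list with `mesocosm`, `regime`, `transfer`, `carrier`, `child_id`,
#'   `n_snps`, `interval` (two positions), `fitness`. The event instantly
#'   replaces the carrier population with the block-bearing genotype.
#' @param reads_per_sample Reads per sample for the genus count table.
#' @param mean_depth_at_peak Mean per-site depth at the sample with the
#'   highest phage read fraction (default 2000).
#' @param sequencing_error_rate Per-base error rate (default 0.001).
#' @param genome_length Phage genome length in bp (default 63535).
#' @param host_genome_length Bacterial genome length in bp (default 4 Mb).
#' @param burst_size Virions released per infected cell (default 100).
#' @param half_saturation Fitness-weighted phage density at which half the
#'   susceptible hosts are infected within one cycle (default 1e7 per ml).
#' @param carrying_capacity Total bacterial density per ml (default 1e9).
#' @param host_share Named fraction of the bacterial community that is
#'   host, per community type (default A 0.30, B 0.03).
#' @param resistant_init_frac Initial resistant fraction of the host
#'   population; resistance sweeps under predation and ends outbreaks.
#' @param resistance_reversion Fraction of the resistant population
#'   reverting to sensitivity at each regrowth (phase-variable resistance;
#'   default 0.1). Keeps a susceptible minority available, so phage
#'   persist at reduced density after the outbreak collapses.
#' @param virion_survival Fraction of unadsorbed free virions surviving a
#'   two-week cycle (default 0.2).
#' @param cocktail_efficiency Fraction of pooled cocktail virions that
#'   successfully establish in the receiving community (default 0.5);
#'   absorbs filtration losses and decay during cocktail preparation.
#' @param founder_fitness Founder genotype fitness per community type
#'   (default `c(A = 1, B = 0.02)`): the phage is adapted to the hosts of
#'   its native community type.
#' @param founder_phage Founder phage density per ml (default 1e7).
#' @param n_noise_positions Monomorphic positions carried through the
#'   observation model to exercise the variant filter (default 20).
#' @param n_genera Genera in the community count table (default 18).
#' @param rng_seed Integer seed; the full dataset is a deterministic
#'   function of the configuration and this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mesocosms = 10,
                       community_types = NULL,
                       transfer_interval_weeks = 2,
                       total_weeks = 48,
                       dilution_factor = 1 / 20,
                       sampling_weeks = c(0, 2, 4, 6, 8, 20, 32, 40, 48),
                       founder_genotypes = NULL,
                       marker_positions = NULL,
                       marker_ref = NULL,
                       marker_alt = NULL,
                       recombination_events = NULL,
                       novel_blocks = NULL,
                       reads_per_sample = 1e5,
                       mean_depth_at_peak = 2000,
                       sequencing_error_rate = 0.001,
                       genome_length = 63535,
                       host_genome_length = 4e6,
                       burst_size = 100,
                       half_saturation = 1e7,
                       carrying_capacity = 1e9,
                       host_share = c(A = 0.30, B = 0.03),
                       resistant_init_frac = 1e-5,
                       resistance_reversion = 0.1,
                       virion_survival = 0.2,
                       cocktail_efficiency = 0.5,
                       founder_fitness = c(A = 1, B = 0.02),
                       founder_phage = 1e7,
                       n_noise_positions = 20,
                       n_genera = 18,
                       rng_seed = 1) {
  meso <- as.character(seq_len(n_mesocosms))
  if (is.null(community_types)) {
    community_types <- setNames(ifelse(meso %in% c("1", "2", "5", "6"),
                                       "A", "B"), meso)
  }
  if (is.null(founder_genotypes)) {
    founder_genotypes <- c(`1` = "G2", `2` = "G1", `5` = "G2", `6` = "G2")
    founder_genotypes <- founder_genotypes[names(founder_genotypes) %in% meso]
  }
  if (is.null(marker_positions)) {
    marker_positions <- c(1276, 24224, 24375, 24378, 54689, 54853, 54856,
                          55320, 55814)
    marker_ref <- c("T", "T", "G", "T", "T", "T", "C", "A", "C")
    marker_alt <- c("G", "C", "A", "C", "C", "C", "T", "C", "T")
  }
  if (is.null(marker_ref)) {
    bases <- c("A", "C", "G", "T")
    marker_ref <- bases[(seq_along(marker_positions) - 1L) %% 4L + 1L]
    marker_alt <- c("G", "T", "A", "C")[(seq_along(marker_positions) - 1L) %% 4L + 1L]
  }
  default_design <- setequal(names(founder_genotypes), c("1", "2", "5", "6")) &&
    n_mesocosms >= 6
  if (is.null(recombination_events)) {
    recombination_events <- if (default_design) list(
      list(mesocosm = "6", regime = "open", transfer = 4,
           parents = c("G1", "G2"), breakpoints = c(24000, 24400),
           child_id = "G3", fitness = c(A = 2.5, B = 0.005),
           seed_fraction = 0.05),
      list(mesocosm = "3", regime = "open", transfer = 3,
           parents = c("G2", "G1"), breakpoints = c(2000, 55500, 55900),
           child_id = "G4base", fitness = c(A = 0.02, B = 0.05),
           seed_fraction = 0.02)
    ) else list()
  }
  if (is.null(novel_blocks)) {
    novel_blocks <- if (default_design) list(
      list(mesocosm = "3", regime = "open", transfer = 4,
           carrier = "G4base", child_id = "G4", n_snps = 61,
           interval = c(45000, 62000), fitness = c(A = 0.005, B = 3.0))
    ) else list()
  }

  cfg <- list(
    n_mesocosms = n_mesocosms, mesocosms = meso,
    community_types = community_types,
    transfer_interval_weeks = transfer_interval_weeks,
    total_weeks = total_weeks, dilution_factor = dilution_factor,
    sampling_weeks = sort(unique(sampling_weeks)),
    founder_genotypes = founder_genotypes,
    marker_positions = as.integer(marker_positions),
    marker_ref = marker_ref, marker_alt = marker_alt,
    recombination_events = recombination_events,
    novel_blocks = novel_blocks,
    reads_per_sample = reads_per_sample,
    mean_depth_at_peak = mean_depth_at_peak,
    sequencing_error_rate = sequencing_error_rate,
    genome_length = genome_length,
    host_genome_length = host_genome_length,
    burst_size = burst_size, half_saturation = half_saturation,
    carrying_capacity = carrying_capacity, host_share = host_share,
    resistant_init_frac = resistant_init_frac,
    resistance_reversion = resistance_reversion,
    virion_survival = virion_survival,
    cocktail_efficiency = cocktail_efficiency,
    founder_fitness = founder_fitness,
    founder_phage = founder_phage,
    n_noise_positions = n_noise_positions, n_genera = n_genera,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$dilution_factor <= 0 || cfg$dilution_factor >= 1) {
    abort("dilution_factor must lie in (0, 1)")
  }
  if (cfg$reads_per_sample <= 0) abort("reads_per_sample must be positive")
  if (any(cfg$sampling_weeks %% cfg$transfer_interval_weeks != 0)) {
    abort("sampling_weeks must be multiples of the transfer interval")
  }
  if (any(cfg$sampling_weeks > cfg$total_weeks)) {
    abort("sampling_weeks exceed total_weeks")
  }
  if (!all(names(cfg$founder_genotypes) %in% cfg$mesocosms)) {
    abort("founder_genotypes references unknown mesocosms")
  }
  if (!all(cfg$community_types %in% c("A", "B")) ||
      !setequal(names(cfg$community_types), cfg$mesocosms)) {
    abort("community_types must map every mesocosm to 'A' or 'B'")
  }
  n_transfers <- cfg$total_weeks / cfg$transfer_interval_weeks
  founder_ids <- unique(cfg$founder_genotypes)
  known <- c(founder_ids,
             vapply(cfg$recombination_events, function(e) e$child_id, ""))
  for (e in cfg$recombination_events) {
    lbl <- sprintf("recombination event '%s' (mesocosm %s, transfer %s)",
                   e$child_id, e$mesocosm, e$transfer)
    if (!e$mesocosm %in% cfg$mesocosms) abort(paste(lbl, "names an unknown mesocosm"))
    if (e$transfer < 1 || e$transfer > n_transfers) abort(paste(lbl, "is outside the transfer range"))
    if (length(e$parents) != 2L || e$parents[1] == e$parents[2]) {
      abort(paste(lbl, "needs two distinct parents"))
    }
    if (!all(e$parents %in% known)) abort(paste(lbl, "references unknown parent genotypes"))
  }
  known <- c(known, vapply(cfg$novel_blocks, function(e) e$child_id, ""))
  for (e in cfg$novel_blocks) {
    lbl <- sprintf("novel-block event '%s' (mesocosm %s, transfer %s)",
                   e$child_id, e$mesocosm, e$transfer)
    if (!e$mesocosm %in% cfg$mesocosms) abort(paste(lbl, "names an unknown mesocosm"))
    if (e$transfer < 1 || e$transfer > n_transfers) abort(paste(lbl, "is outside the transfer range"))
    if (!e$carrier %in% known) abort(paste(lbl, "references an unknown carrier genotype"))
    if (e$interval[1] < 1 || e$interval[2] > cfg$genome_length ||
        e$interval[1] >= e$interval[2]) {
      abort(paste(lbl, "has an invalid genomic interval"))
    }
  }
  invisible(cfg)
}

fitness_for <- function(f, type) {
  if (length(f) == 1L && is.null(names(f))) return(unname(f))
  if (!is.null(names(f)) && type %in% names(f)) return(unname(f[[type]]))
  unname(f[[1]])
}

#' Simulate a longitudinal phage metacommunity with ground truth
#'
#' Runs the serial-transfer model described in [sim_config()] and emits
#' both the observable dataset (per-sample allele-depth observations,
#' coverage summaries, sample metadata, genus count table) and the hidden
#' ground truth (true genotype haplotypes, per-sample genotype abundance
#' simplex, true phage read fractions, event log) used to validate the
#' inference stages. The output is a deterministic function of the
#' configuration, including its `rng_seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `dataset` (list: `observations`,
#'   `coverage`, `metadata`, `genus_counts`), `truth` (list: `genotypes`,
#'   `haplotypes`, `abundances`, `phage_fraction`, `event_log`,
#'   `variants`) and `config`.
#' @export
simulate_metacommunity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$rng_seed)

  # --- genotype registry -------------------------------------------------
  variants <- tibble(
    pos = cfg$marker_positions, ref = cfg$marker_ref, alt = cfg$marker_alt,
    origin = "marker"
  )
  founder_ids <- sort(unique(cfg$founder_genotypes))
  # haplotypes stored as the set of variant positions carrying the alt allele
  hap_sets <- list()
  for (g in founder_ids) hap_sets[[g]] <- integer()
  # by convention G1 is the reference; any other founder carries the markers
  nonref_founders <- setdiff(founder_ids, "G1")
  for (g in nonref_founders) hap_sets[[g]] <- cfg$marker_positions
  geno <- tibble(
    genotype = founder_ids,
    provenance = ifelse(founder_ids == "G1", "reference", "founder")
  )
  fitness <- setNames(rep(list(cfg$founder_fitness), length(founder_ids)),
                      founder_ids)

  # --- community state ---------------------------------------------------
  communities <- expand.grid(mesocosm = cfg$mesocosms,
                             regime = c("closed", "open"),
                             stringsAsFactors = FALSE) |> as_tibble()
  communities$type <- cfg$community_types[communities$mesocosm]
  communities$community <- paste0(communities$mesocosm, "_",
                                  communities$regime)
  K <- cfg$carrying_capacity
  state <- purrr::pmap(communities, function(mesocosm, regime, type,
                                             community) {
    kh <- K * cfg$host_share[[type]]
    P <- setNames(rep(0, length(founder_ids)), founder_ids)
    fg <- cfg$founder_genotypes[mesocosm]
    if (!is.na(fg)) P[fg] <- cfg$founder_phage
    list(S = kh * (1 - cfg$resistant_init_frac),
         R = kh * cfg$resistant_init_frac, P = P)
  })
  names(state) <- communities$community

  add_genotype <- function(P) {
    # align every community's phage vector with the registry
    for (nm in names(state)) {
      missing <- setdiff(geno$genotype, names(state[[nm]]$P))
      if (length(missing)) {
        state[[nm]]$P <<- c(state[[nm]]$P,
                            setNames(rep(0, length(missing)), missing))
      }
    }
  }

  snapshots <- list()
  take_snapshot <- function(week) {
    for (i in seq_len(nrow(communities))) {
      st <- state[[communities$community[i]]]
      snapshots[[length(snapshots) + 1L]] <<- list(
        community = communities$community[i],
        mesocosm = communities$mesocosm[i],
        regime = communities$regime[i],
        type = communities$type[i], week = week,
        bacteria = st$S + st$R +
          K * (1 - cfg$host_share[[communities$type[i]]]),
        P = st$P
      )
    }
  }
  take_snapshot(0)

  event_log <- list()
  n_transfers <- cfg$total_weeks / cfg$transfer_interval_weeks

  for (t in seq_len(n_transfers)) {
    week <- t * cfg$transfer_interval_weeks
    # cocktail: equal-volume phage pool of all open communities (filtered,
    # so no cells migrate)
    open_idx <- communities$community[communities$regime == "open"]
    genos <- geno$genotype
    cocktail <- setNames(rep(0, length(genos)), genos)
    for (nm in open_idx) {
      P <- state[[nm]]$P
      cocktail[names(P)] <- cocktail[names(P)] + P / length(open_idx)
    }

    # dilution transfer; open communities also receive the cocktail
    for (nm in names(state)) {
      state[[nm]]$S <- state[[nm]]$S * cfg$dilution_factor
      state[[nm]]$R <- state[[nm]]$R * cfg$dilution_factor
      state[[nm]]$P <- state[[nm]]$P * cfg$dilution_factor
      if (nm %in% open_idx) {
        state[[nm]]$P <- state[[nm]]$P +
          cocktail[names(state[[nm]]$P)] * cfg$dilution_factor *
          cfg$cocktail_efficiency
      }
    }

    # programmed recombination events
    for (e in cfg$recombination_events) {
      if (e$transfer != t) next
      nm <- paste0(e$mesocosm, "_", e$regime)
      P <- state[[nm]]$P
      if (any(P[e$parents] <= 0) || anyNA(P[e$parents])) {
        abort(sprintf(
          "recombination event '%s': parents %s do not coexist in %s at transfer %d",
          e$child_id, paste(e$parents, collapse = "/"), nm, t))
      }
      if (!e$child_id %in% geno$genotype) {
        bps <- sort(e$breakpoints)
        all_pos <- sort(unique(c(hap_sets[[e$parents[1]]],
                                 hap_sets[[e$parents[2]]])))
        seg <- findInterval(all_pos, bps)
        from_parent <- ifelse(seg %% 2 == 0, e$parents[1], e$parents[2])
        child_pos <- all_pos[purrr::map2_lgl(
          from_parent, all_pos, function(p, v) v %in% hap_sets[[p]])]
        hap_sets[[e$child_id]] <- child_pos
        geno <- bind_rows(geno, tibble(genotype = e$child_id,
                                       provenance = "recombinant"))
        fitness[[e$child_id]] <- e$fitness
        add_genotype()
      }
      P <- state[[nm]]$P
      seed <- e$seed_fraction * sum(P[e$parents])
      share <- P[e$parents] / sum(P[e$parents])
      state[[nm]]$P[e$parents] <- P[e$parents] - seed * share
      state[[nm]]$P[e$child_id] <- state[[nm]]$P[e$child_id] + seed
      event_log[[length(event_log) + 1L]] <- tibble(
        type = "recombination", mesocosm = e$mesocosm, regime = e$regime,
        transfer = t, week = week, child = e$child_id,
        details = paste0("parents=", paste(e$parents, collapse = "+")))
    }

    # programmed novel-SNP blocks (instantaneous replacement on the carrier)
    for (e in cfg$novel_blocks) {
      if (e$transfer != t) next
      nm <- paste0(e$mesocosm, "_", e$regime)
      P <- state[[nm]]$P
      if (is.na(P[e$carrier]) || P[e$carrier] <= 0) {
        abort(sprintf(
          "novel-block event '%s': carrier %s absent in %s at transfer %d",
          e$child_id, e$carrier, nm, t))
      }
      if (!e$child_id %in% geno$genotype) {
        pool <- setdiff(seq(e$interval[1], e$interval[2]), variants$pos)
        new_pos <- sort(sample(pool, e$n_snps))
        bases <- c("A", "C", "G", "T")
        ref <- sample(bases, e$n_snps, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
        variants <- bind_rows(variants, tibble(
          pos = new_pos, ref = ref, alt = unname(alt), origin = "novel"))
        hap_sets[[e$child_id]] <- sort(c(hap_sets[[e$carrier]], new_pos))
        geno <- bind_rows(geno, tibble(genotype = e$child_id,
                                       provenance = "mutational"))
        fitness[[e$child_id]] <- e$fitness
        add_genotype()
      }
      P <- state[[nm]]$P
      state[[nm]]$P[e$child_id] <- state[[nm]]$P[e$child_id] + P[e$carrier]
      state[[nm]]$P[e$carrier] <- 0
      event_log[[length(event_log) + 1L]] <- tibble(
        type = "novel_block", mesocosm = e$mesocosm, regime = e$regime,
        transfer = t, week = week, child = e$child_id,
        details = paste0("carrier=", e$carrier, ";n_snps=", e$n_snps))
    }

    # host regrowth to carrying capacity, then one round of infection
    for (i in seq_len(nrow(communities))) {
      nm <- communities$community[i]
      kh <- K * cfg$host_share[[communities$type[i]]]
      st <- state[[nm]]
      H <- st$S + st$R
      if (H > 0) {
        st$S <- st$S * kh / H
        st$R <- st$R * kh / H
        # phase-variable resistance: part of the resistant pool reverts
        rev <- st$R * cfg$resistance_reversion
        st$S <- st$S + rev
        st$R <- st$R - rev
      }
      w <- vapply(names(st$P), function(g)
        fitness_for(fitness[[g]], communities$type[i]), 1.0)
      P_eff <- sum(w * st$P)
      if (P_eff > 0 && st$S > 0) {
        theta <- P_eff / (P_eff + cfg$half_saturation)
        I <- st$S * theta
        I_g <- I * (w * st$P) / P_eff
        st$S <- st$S - I
        st$P <- cfg$virion_survival * pmax(st$P - I_g, 0) +
          cfg$burst_size * I_g
      } else {
        st$P <- cfg$virion_survival * st$P
      }
      state[[nm]] <- st
    }

    if (week %in% cfg$sampling_weeks) take_snapshot(week)
  }

  build_sim_output(cfg, communities, snapshots, geno, hap_sets, variants,
                   fitness, event_log)
}

# assemble tables and draw the observation layer
build_sim_output <- function(cfg, communities, snapshots, geno, hap_sets,
                             variants, fitness, event_log) {
  # noise positions: monomorphic sites carried through the observation model
  if (cfg$n_noise_positions > 0) {
    pool <- setdiff(seq_len(cfg$genome_length), variants$pos)
    noise_pos <- sort(sample(pool, cfg$n_noise_positions))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, cfg$n_noise_positions, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    variants <- bind_rows(variants, tibble(
      pos = noise_pos, ref = ref, alt = unname(alt), origin = "noise"))
  }
  variants <- variants |> arrange(.data$pos) |>
    mutate(variant_id = variant_id(.data$pos, .data$ref, .data$alt)) |>
    select("variant_id", "pos", "ref", "alt", "origin")

  H <- matrix(0L, nrow(geno), nrow(variants),
              dimnames = list(geno$genotype, variants$variant_id))
  for (g in geno$genotype) {
    H[g, variants$pos %in% hap_sets[[g]]] <- 1L
  }

  snap <- tibble(
    sample = vapply(snapshots, function(s)
      sprintf("%s_wk%g", s$community, s$week), ""),
    community = vapply(snapshots, `[[`, "", "community"),
    mesocosm = vapply(snapshots, `[[`, "", "mesocosm"),
    regime = vapply(snapshots, `[[`, "", "regime"),
    community_type = vapply(snapshots, `[[`, "", "type"),
    week = vapply(snapshots, `[[`, 1.0, "week"),
    bacteria = vapply(snapshots, `[[`, 1.0, "bacteria"),
    phage_total = vapply(snapshots, function(s) sum(s$P), 1.0)
  )
  P_mat <- matrix(0, nrow(snap), nrow(geno),
                  dimnames = list(snap$sample, geno$genotype))
  for (i in seq_along(snapshots)) {
    P <- snapshots[[i]]$P
    P_mat[i, names(P)] <- P
  }

  frac <- snap$phage_total * cfg$genome_length /
    (snap$phage_total * cfg$genome_length +
       snap$bacteria * cfg$host_genome_length)
  abund <- P_mat / pmax(snap$phage_total, .Machine$double.xmin)
  abund[snap$phage_total <= 0, ] <- 0

  metadata <- snap |> select("sample", "mesocosm", "regime",
                             "community_type", "week")
  peak <- max(frac)
  lambda <- if (peak > 0) cfg$mean_depth_at_peak * frac / peak else
    rep(0, length(frac))

  # observation layer: per-site depth ~ Poisson, alt reads ~ Binomial with
  # symmetric sequencing error
  ns <- nrow(snap); nv <- nrow(variants)
  f_true <- abund %*% H                         # sample x variant
  depth <- matrix(rpois(ns * nv, rep(lambda, nv)), ns, nv)
  eps <- cfg$sequencing_error_rate
  q <- f_true * (1 - eps) + (1 - f_true) * eps
  altd <- matrix(rbinom(ns * nv, as.vector(depth), as.vector(q)), ns, nv)
  observations <- tibble(
    sample = rep(snap$sample, nv),
    pos = rep(variants$pos, each = ns),
    ref = rep(variants$ref, each = ns),
    alt = rep(variants$alt, each = ns),
    ref_depth = as.vector(depth - altd),
    alt_depth = as.vector(altd)
  )

  coverage <- tibble(
    sample = snap$sample,
    mean_depth = lambda,
    breadth_1x = ppois(0, lambda, lower.tail = FALSE),
    breadth_10x = ppois(9, lambda, lower.tail = FALSE)
  )

  genus_counts <- simulate_genus_counts(cfg, communities, metadata)

  truth <- list(
    genotypes = geno |>
      mutate(fitness = purrr::map(.data$genotype, ~ fitness[[.x]])),
    haplotypes = H,
    abundances = afm_tibble(abund),
    phage_fraction = tibble(sample = snap$sample, fraction = frac,
                            present = snap$phage_total > 0),
    event_log = if (length(event_log)) bind_rows(event_log) else
      tibble(type = character(), mesocosm = character(),
             regime = character(), transfer = numeric(), week = numeric(),
             child = character(), details = character()),
    variants = variants
  )
  list(dataset = list(observations = observations, coverage = coverage,
                      metadata = metadata, genus_counts = genus_counts),
       truth = truth, config = cfg)
}

# Dirichlet-multinomial genus counts with two type-specific mean profiles;
# the mesocosm-level draw is shared between the paired closed and open
# communities (founder effect)
simulate_genus_counts <- function(cfg, communities, metadata) {
  g <- cfg$n_genera
  genera <- c("Rhodanobacter", "Cellvibrio",
              paste0("Genus", sprintf("%02d", seq_len(max(g - 2, 0)))))
  genera <- genera[seq_len(g)]
  base <- matrix(1 / g, 2, g, dimnames = list(c("A", "B"), genera))
  # type A dominated by the first genus, type B by the second, with the
  # mid-rank order reversed so the compositions separate clearly
  decay <- 0.55^(seq_len(g) - 1)
  base["A", ] <- decay / sum(decay)
  perm_b <- c(2L, 1L, rev(seq_len(g)[-(1:2)]))
  pb <- numeric(g)
  pb[perm_b] <- decay
  base["B", ] <- pb / sum(pb)

  rdirichlet1 <- function(alpha) {
    x <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(x) == 0) x <- rep(1, length(alpha))
    x / sum(x)
  }
  meso_profile <- purrr::map(cfg$mesocosms, function(m) {
    rdirichlet1(60 * base[cfg$community_types[[m]], ])
  })
  names(meso_profile) <- cfg$mesocosms

  rows <- purrr::pmap(metadata, function(sample, mesocosm, regime,
                                         community_type, week) {
    p <- rdirichlet1(250 * meso_profile[[mesocosm]])
    counts <- as.integer(rmultinom(1, cfg$reads_per_sample, p))
    tibble(sample = sample, !!!setNames(as.list(counts), genera))
  })
  bind_rows(rows)
}

#' Noise-free allele-frequency matrix implied by the simulator truth
#'
#' Computes, for every sample where the phage is present, the expected
#' alternative-allele frequency of each variant as the genotype-abundance-
#' weighted mean of the genotype alleles. Serves as the noise-free
#' reference against which observed frequencies converge as depth grows,
#' and as the oracle input for event-timing comparisons.
#'
#' @param sim Output of [simulate_metacommunity()].
#' @param drop_absent Drop samples where the phage is absent
#'   (default TRUE).
#' @return Allele-frequency tibble (`sample` column plus variant columns).
#' @export
true_afm <- function(sim, drop_absent = TRUE) {
  H <- sim$truth$haplotypes
  ab <- afm_matrix(sim$truth$abundances)
  f <- ab[, rownames(H), drop = FALSE] %*% H
  if (drop_absent) {
    present <- sim$truth$phage_fraction$present[
      match(rownames(f), sim$truth$phage_fraction$sample)]
    f <- f[present, , drop = FALSE]
  }
  afm_tibble(f)
}
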