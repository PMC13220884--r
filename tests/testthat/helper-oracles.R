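# Independent brute-force oracles and small fixture builders used across the
# test files. Everything here is deliberately written in plain loops, apart
# from the implementation code paths it checks.

# loop-based reimplementation of the sample-qualification + variant-retention
# rules, used as the filtering oracle
brute_filter <- function(observations, coverage, params = filter_params()) {
  col <- sprintf("breadth_%gx", params$breadth_depth_threshold)
  qual <- character()
  for (i in seq_len(nrow(coverage))) {
    if (coverage[[col]][i] >= params$min_breadth_fraction) {
      qual <- c(qual, coverage$sample[i])
    }
  }
  ids <- unique(sprintf("%d_%s_%s", observations$pos, observations$ref,
                        observations$alt))
  keep <- character()
  for (v in ids) {
    rows <- which(sprintf("%d_%s_%s", observations$pos, observations$ref,
                          observations$alt) == v)
    for (r in rows) {
      if (!observations$sample[r] %in% qual) next
      d <- observations$ref_depth[r] + observations$alt_depth[r]
      if (d == 0) next
      f <- observations$alt_depth[r] / d
      if (f >= params$min_allele_freq &&
          observations$alt_depth[r] >= params$min_alt_reads) {
        keep <- c(keep, v)
        break
      }
    }
  }
  list(qualifying = qual, catalog = sort(keep))
}

# random allele-depth table generator for the filter property tests
random_obs_table <- function(n_samples, n_variants, seed) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n_samples))
  pos <- sort(sample(1e4, n_variants))
  grid <- expand.grid(sample = samples, i = seq_len(n_variants),
                      stringsAsFactors = FALSE)
  obs <- tibble::tibble(
    sample = grid$sample,
    pos = pos[grid$i],
    ref = "A", alt = "T",
    ref_depth = rpois(nrow(grid), 20),
    alt_depth = rbinom(nrow(grid), 25, runif(nrow(grid), 0, 0.35))
  )
  coverage <- tibble::tibble(
    sample = samples,
    breadth_10x = runif(n_samples, 0, 1)
  )
  list(obs = obs, coverage = coverage)
}

# Needleman-Wunsch oracle: global alignment score and identity with
# match +1, mismatch -1, gap -1 (for sequences up to a few hundred bp)
nw_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + ifelse(x[i] == y[j], 1, -1),
        S[i, j + 1] - 1, S[i + 1, j] - 1
      )
    }
  }
  # traceback (one optimal path)
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(x[i] == y[j], 1, -1)) {
      matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = S[n + 1, m + 1], identity = 100 * matches / cols)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build a phage_genotypes object from named binary haplotype vectors by
# synthesising perfect clonal samples and deriving genotypes from them
genotypes_from_haplotypes <- function(haps) {
  clonal <- tibble::tibble(
    sample = paste0("ref_", names(haps)),
    n_alt = vapply(haps, sum, 1L),
    haplotype = unname(haps)
  )
  derive_genotypes(clonal)
}

# the four-genotype marker structure used in decomposition tests: ids by
# marker colour block, mirroring the published genotype table
paper_style_haplotypes <- function() {
  vars <- c("blue1", "pink1", "pink2", "pink3", "green1", "green2",
            "green3", "green4", "blue2", "y1", "y2", "y3")
  h <- function(on) setNames(as.integer(vars %in% on), vars)
  list(
    G1 = h(character()),
    G2 = h(c("blue1", "pink1", "pink2", "pink3", "green1", "green2",
             "green3", "green4", "blue2")),
    G3 = h(c("pink1", "pink2", "pink3")),
    G4 = h(c("blue1", "blue2", "y1", "y2", "y3"))
  )
}

# small paired-mesocosm simulation used where the full design is overkill
small_sim_config <- function(seed, ...) {
  args <- list(
    n_mesocosms = 2,
    community_types = c(`1` = "A", `2` = "A"),
    founder_genotypes = c(`1` = "G2", `2` = "G1"),
    recombination_events = list(), novel_blocks = list(),
    total_weeks = 16, sampling_weeks = seq(0, 16, 2),
    n_noise_positions = 5, n_genera = 8, rng_seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# map each derived genotype id to the truth genotype with the identical
# haplotype (NA when none matches)
match_genotypes_to_truth <- function(gt, truth_haplotypes) {
  common <- intersect(colnames(truth_haplotypes), colnames(gt$haplotypes))
  vapply(rownames(gt$haplotypes), function(g) {
    hit <- which(apply(truth_haplotypes[, common, drop = FALSE], 1L,
                       function(h) all(h == gt$haplotypes[g, common])))
    if (length(hit)) rownames(truth_haplotypes)[hit[1]] else NA_character_
  }, "")
}

# plain matrix view of a sample-keyed tibble (first column = sample)
afm_matrix_for_test <- function(tbl) {
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$sample
  m
}
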