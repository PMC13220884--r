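test_that("identical configurations and seeds give identical datasets", {
  a <- simulate_metacommunity(small_sim_config(99))
  b <- simulate_metacommunity(small_sim_config(99))
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth$abundances, b$truth$abundances)
  c <- simulate_metacommunity(small_sim_config(100))
  expect_false(identical(a$dataset$observations, c$dataset$observations))
})

test_that("a single reference-clone community shows no variation", {
  cfg <- sim_config(
    n_mesocosms = 1, community_types = c(`1` = "A"),
    founder_genotypes = c(`1` = "G1"),
    recombination_events = list(), novel_blocks = list(),
    total_weeks = 8, sampling_weeks = seq(0, 8, 2),
    n_noise_positions = 0, n_genera = 5, rng_seed = 17
  )
  sim <- simulate_metacommunity(cfg)
  obs <- sim$dataset$observations
  f <- obs$alt_depth / pmax(obs$ref_depth + obs$alt_depth, 1)
  # only sequencing error: frequencies at or near zero everywhere
  expect_true(all(f < 0.05))
  ab <- sim$truth$abundances
  present <- sim$truth$phage_fraction$present
  expect_true(all(ab$G1[present[match(ab$sample,
    sim$truth$phage_fraction$sample)]] == 1))
})

test_that("closed communities never acquire foreign genotypes", {
  sim <- simulate_metacommunity(sim_config(rng_seed = 23))
  ab <- sim$truth$abundances
  md <- sim$dataset$metadata
  founders <- sim$config$founder_genotypes
  closed <- md[md$regime == "closed", ]
  for (g in setdiff(colnames(ab), "sample")) {
    carriers <- names(founders)[founders == g]
    rows <- match(closed$sample, ab$sample)
    foreign <- ab[[g]][rows][!closed$mesocosm %in% carriers]
    expect_true(all(foreign == 0))
  }
})

test_that("expected frequencies equal abundance-weighted genotype alleles", {
  sim <- simulate_metacommunity(small_sim_config(3))
  # brute-force enumeration of the mixture identity per sample x variant
  H <- sim$truth$haplotypes
  ab <- sim$truth$abundances
  tr <- true_afm(sim, drop_absent = FALSE)
  for (i in seq_len(nrow(ab))) {
    a <- unlist(ab[i, rownames(H)])
    manual <- vapply(colnames(H), function(v) sum(a * H[, v]), 1.0)
    expect_equal(unlist(tr[i, names(manual)]), manual, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("observed frequencies converge to the truth as depth grows", {
  err <- function(depth, seed) {
    sim <- simulate_metacommunity(small_sim_config(
      seed, mean_depth_at_peak = depth, sequencing_error_rate = 0))
    obs <- sim$dataset$observations
    obs$vid <- sprintf("%d_%s_%s", obs$pos, obs$ref, obs$alt)
    tr <- true_afm(sim, drop_absent = FALSE)
    trm <- as.matrix(tr[, -1]); rownames(trm) <- tr$sample
    d <- obs$ref_depth + obs$alt_depth
    keep <- d >= depth / 20
    f <- obs$alt_depth[keep] / d[keep]
    ft <- trm[cbind(obs$sample[keep], obs$vid[keep])]
    mean(abs(f - ft))
  }
  shallow <- err(100, 7)
  deep <- err(20000, 7)
  expect_lt(deep, shallow)
  expect_lt(deep, 0.01)
})

test_that("depth scales with the true phage read fraction", {
  sim <- simulate_metacommunity(small_sim_config(11))
  cov <- sim$dataset$coverage
  pf <- sim$truth$phage_fraction
  ratio <- cov$mean_depth / pmax(pf$fraction[match(cov$sample, pf$sample)],
                                 1e-12)
  ratio <- ratio[pf$fraction > 0]
  expect_true(all(abs(ratio - ratio[1]) < 1e-6 * ratio[1]))
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(sim_config(dilution_factor = 1.5), "dilution")
  expect_error(sim_config(reads_per_sample = 0), "reads_per_sample")
  expect_error(sim_config(sampling_weeks = c(0, 3)), "multiples")
  expect_error(sim_config(recombination_events = list(
    list(mesocosm = "99", regime = "open", transfer = 2,
         parents = c("G1", "G2"), breakpoints = 100, child_id = "X",
         fitness = 1, seed_fraction = 0.05))), "unknown mesocosm")
  expect_error(sim_config(novel_blocks = list(
    list(mesocosm = "3", regime = "open", transfer = 2, carrier = "nope",
         child_id = "Y", n_snps = 5, interval = c(100, 200),
         fitness = 1))), "carrier")
})

test_that("events referencing absent parents fail at run time by name", {
  cfg <- small_sim_config(13, recombination_events = list(
    list(mesocosm = "2", regime = "closed", transfer = 2,
         parents = c("G1", "G2"), breakpoints = 5000, child_id = "GX",
         fitness = 1.5, seed_fraction = 0.05)))
  # mesocosm 2 is founded with G1 only and closed: G2 never coexists there
  expect_error(simulate_metacommunity(cfg), "GX")
})

test_that("novel-block SNPs are absent before their event", {
  sim <- simulate_metacommunity(sim_config(rng_seed = 29))
  ev <- sim$truth$event_log
  wk <- ev$week[ev$type == "novel_block"]
  novel <- sim$truth$variants$variant_id[sim$truth$variants$origin == "novel"]
  tr <- true_afm(sim, drop_absent = FALSE)
  md <- sim$dataset$metadata
  before <- md$sample[md$week < wk]
  sub <- as.matrix(tr[match(before, tr$sample), novel])
  expect_true(all(sub == 0))
})
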