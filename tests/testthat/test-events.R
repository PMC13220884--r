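make_meta <- function(community, weeks) {
  parts <- strsplit(community, "_")[[1]]
  tibble::tibble(
    sample = paste0(community, "_wk", weeks),
    mesocosm = parts[1], regime = parts[2], week = weeks
  )
}

test_that("a single-genotype community yields no recombination events", {
  weeks <- c(0, 2, 4, 6, 8)
  meta <- make_meta("1_closed", weeks)
  afm <- tibble::tibble(
    sample = meta$sample,
    a = rep(1, 5), b = rep(1, 5), c = rep(0, 5)
  )
  gr <- cluster_trajectories(afm)
  ev <- detect_recombination(afm, meta, gr)
  expect_equal(nrow(ev), 0L)
})

test_that("decoupling after coexistence is called with the right child", {
  # two marker groups (three HNH-like variants vs two lysis-gene variants)
  # travel together at intermediate frequency, then part ways as a
  # recombinant carrying only the first group sweeps
  weeks <- c(0, 2, 4, 6, 8)
  meta <- make_meta("6_open", weeks)
  pink <- c(0.5, 0.5, 0.55, 0.95, 1.0)
  green <- c(0.5, 0.5, 0.5, 0.15, 0.0)
  afm <- tibble::tibble(
    sample = meta$sample,
    p1 = pink, p2 = pink, p3 = pink,
    g1 = green, g2 = green
  )
  gr <- cluster_trajectories(afm)
  haps <- list(
    G1 = c(p1 = 0L, p2 = 0L, p3 = 0L, g1 = 0L, g2 = 0L),
    G2 = c(p1 = 1L, p2 = 1L, p3 = 1L, g1 = 1L, g2 = 1L),
    G3 = c(p1 = 1L, p2 = 1L, p3 = 1L, g1 = 0L, g2 = 0L)
  )
  gt <- genotypes_from_haplotypes(haps)
  ev <- detect_recombination(afm, meta, gr, gt)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$week, 6)
  expect_equal(ev$child, "G2")  # id of the pink-only haplotype in the set
  expect_true(ev$child_known)
  expect_setequal(ev$parents[[1]], c("G1", "G3"))
})

test_that("decoupling without earlier coexistence is not an event", {
  weeks <- c(0, 2, 4, 6)
  meta <- make_meta("2_open", weeks)
  # group b rises from zero: never coupled with a at intermediate freq
  afm <- tibble::tibble(
    sample = meta$sample,
    a = c(0.95, 0.96, 0.95, 0.6),
    b = c(0.0, 0.02, 0.2, 0.9)
  )
  gr <- cluster_trajectories(afm)
  ev <- detect_recombination(afm, meta, gr)
  expect_equal(nrow(ev), 0L)
})

test_that("no novel variants means no novel blocks", {
  sim <- simulate_metacommunity(small_sim_config(3))
  q <- qualify_samples(sim$dataset$coverage, filter_params())
  fl <- filter_variants(sim$dataset$observations, q)
  cl <- detect_clonal_samples(fl$afm)
  gt <- derive_genotypes(cl, fl$afm)
  nb <- detect_novel_blocks(fl$afm, sim$dataset$metadata, gt)
  expect_equal(nrow(nb$variants), 0L)
  expect_equal(nrow(nb$blocks), 0L)
})

test_that("a block shadowing a genotype's trajectory is assigned to it", {
  weeks <- c(0, 2, 4, 6, 8)
  meta <- dplyr::bind_rows(make_meta("1_closed", weeks),
                           make_meta("2_closed", weeks),
                           make_meta("3_open", weeks))
  rise <- c(0.0, 0.0, 0.3, 0.7, 0.95)
  afm <- tibble::tibble(
    sample = meta$sample,
    # carrier marker: fixed in one closed community, rises in the open one
    blue = c(rep(0, 5), rep(1, 5), rise),
    # novel SNPs copying the carrier's trajectory, absent everywhere else
    n1 = c(rep(0, 10), rise),
    n2 = c(rep(0, 10), pmin(rise + 0.02, 1)),
    # the resident genotype's marker, declining as the carrier invades
    other = c(rep(1, 5), rep(0, 5), 1 - rise)
  )
  haps <- list(
    REFG = c(blue = 0L, n1 = 0L, n2 = 0L, other = 0L),
    CAR = c(blue = 1L, n1 = 0L, n2 = 0L, other = 0L),
    OTH = c(blue = 0L, n1 = 0L, n2 = 0L, other = 1L)
  )
  gt <- genotypes_from_haplotypes(haps)
  carrier_id <- rownames(gt$haplotypes)[gt$haplotypes[, "blue"] == 1L]
  nb <- detect_novel_blocks(afm, meta, gt)
  expect_setequal(nb$variants$variant_id, c("n1", "n2"))
  expect_equal(unique(nb$variants$carrier), carrier_id)
  expect_equal(unique(nb$variants$community), "3_open")
  expect_equal(unique(nb$variants$first_week), 4)
})

test_that("simulated events are recovered at the decoupling-implied week", {
  sim <- simulate_metacommunity(sim_config(rng_seed = 21))
  q <- qualify_samples(sim$dataset$coverage, filter_params())
  fl <- filter_variants(sim$dataset$observations, q)
  cl <- detect_clonal_samples(fl$afm)
  gt <- derive_genotypes(cl, fl$afm)
  nb <- detect_novel_blocks(fl$afm, sim$dataset$metadata, gt)

  # >=95% of the programmed novel SNPs assigned to their true carrier
  truth_novel <- sim$truth$variants$variant_id[
    sim$truth$variants$origin == "novel"]
  mapping <- match_genotypes_to_truth(gt, sim$truth$haplotypes)
  carrier_truth <- mapping[nb$variants$carrier]
  expect_gte(mean(carrier_truth == "G4" &
                    nb$variants$variant_id %in% truth_novel, na.rm = FALSE),
             0.95)

  gr <- cluster_trajectories(fl$afm)
  ev <- detect_recombination(fl$afm, sim$dataset$metadata, gr, gt,
                             exclude_variants = nb$variants$variant_id)
  # oracle: the same detector on the noise-free truth frequencies over the
  # same qualifying samples
  tr <- true_afm(sim)
  tr <- tr[tr$sample %in% q, names(fl$afm)]
  grt <- cluster_trajectories(tr)
  evt <- detect_recombination(tr, sim$dataset$metadata, grt, gt,
                              exclude_variants = nb$variants$variant_id)
  expect_gt(nrow(evt), 0L)
  for (i in seq_len(nrow(evt))) {
    got <- ev$week[ev$community == evt$community[i]]
    expect_true(length(got) > 0)
    expect_lte(min(abs(got - evt$week[i])),
               sim$config$transfer_interval_weeks)
  }
})
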