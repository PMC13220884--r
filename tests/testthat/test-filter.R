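test_that("sample qualification uses an inclusive breadth boundary", {
  cov <- tibble::tibble(sample = c("at", "below"),
                        breadth_10x = c(0.30, 0.299))
  expect_equal(qualify_samples(cov, filter_params()), "at")

  cov5 <- tibble::tibble(sample = paste0("s", 1:5),
                         breadth_10x = c(0.0, 0.1, 0.3, 0.5, 1.0))
  expect_equal(qualify_samples(cov5, filter_params()),
               c("s3", "s4", "s5"))
})

test_that("missing breadth information is reported with the sample name", {
  cov <- tibble::tibble(sample = c("ok", "broken"),
                        breadth_10x = c(0.5, NA))
  expect_error(qualify_samples(cov, filter_params()), "broken")
  expect_error(
    qualify_samples(tibble::tibble(sample = "x", breadth_1x = 1),
                    filter_params()),
    "breadth_10x")
})

test_that("variant retention applies frequency and read-support rules jointly", {
  # five candidates: v1 passes; v2 max freq 0.08; v3 max alt depth 3;
  # v4 only observed in a non-qualifying sample; v5 passes at the boundary
  obs <- tibble::tribble(
    ~sample, ~pos, ~ref, ~alt, ~ref_depth, ~alt_depth,
    "q1", 100L, "A", "T", 50L, 50L,   # v1: f = 0.5
    "q1", 200L, "A", "T", 92L, 8L,    # v2: f = 0.08
    "q1", 300L, "A", "T", 3L,  3L,    # v3: f = 0.5 but 3 reads
    "bad", 400L, "A", "T", 10L, 90L,  # v4: non-qualifying sample only
    "q1", 500L, "A", "T", 36L, 4L     # v5: f = 0.10, 4 reads exactly
  )
  res <- filter_variants(obs, qualifying = "q1", filter_params())
  expect_setequal(res$catalog$pos, c(100L, 500L))
  # boundary case must be retained (inclusive thresholds)
  expect_true("500_A_T" %in% res$catalog$variant_id)
  # the matrix covers all samples; non-qualifying rows are missing
  expect_setequal(res$afm$sample, c("q1", "bad"))
  expect_true(all(is.na(unlist(res$afm[res$afm$sample == "bad", -1]))))
})

test_that("no observations give an empty catalog, negative depths error", {
  res <- filter_variants(tibble::tibble(
    sample = character(), pos = integer(), ref = character(),
    alt = character(), ref_depth = integer(), alt_depth = integer()),
    qualifying = character())
  expect_equal(nrow(res$catalog), 0L)
  expect_error(filter_variants(tibble::tibble(
    sample = "s", pos = 1L, ref = "A", alt = "T",
    ref_depth = -1L, alt_depth = 5L), "s"), "negative")
})

test_that("filtering matches the brute-force oracle on random tables", {
  for (seed in 1:12) {
    tab <- random_obs_table(n_samples = sample(3:20, 1),
                            n_variants = sample(5:50, 1), seed = seed)
    oracle <- brute_filter(tab$obs, tab$coverage)
    q <- qualify_samples(tab$coverage, filter_params())
    res <- filter_variants(tab$obs, q, filter_params())
    expect_equal(sort(q), sort(oracle$qualifying))
    expect_equal(sort(res$catalog$variant_id), oracle$catalog)
  }
})

test_that("raising any threshold never adds a catalog variant", {
  tab <- random_obs_table(12, 40, seed = 99)
  base_q <- qualify_samples(tab$coverage, filter_params())
  base <- filter_variants(tab$obs, base_q, filter_params())$catalog$variant_id
  for (p in list(filter_params(min_allele_freq = 0.2),
                 filter_params(min_alt_reads = 8),
                 filter_params(min_breadth_fraction = 0.6))) {
    q <- qualify_samples(tab$coverage, p)
    strict <- filter_variants(tab$obs, q, p)$catalog$variant_id
    expect_true(all(strict %in% base))
  }
})

test_that("filtering is idempotent", {
  tab <- random_obs_table(10, 30, seed = 7)
  q <- qualify_samples(tab$coverage, filter_params())
  first <- filter_variants(tab$obs, q, filter_params())
  kept_obs <- tab$obs[sprintf("%d_%s_%s", tab$obs$pos, tab$obs$ref,
                              tab$obs$alt) %in% first$catalog$variant_id, ]
  second <- filter_variants(kept_obs, q, filter_params())
  expect_equal(second$catalog$variant_id, first$catalog$variant_id)
  expect_equal(second$afm, first$afm[names(second$afm)])
})

test_that("parameter validation rejects out-of-range thresholds", {
  expect_error(filter_params(min_allele_freq = 1.5))
  expect_error(filter_params(min_breadth_fraction = -0.1))
})
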