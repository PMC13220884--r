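test_that("the CLR transform centers adjusted log counts", {
  # counts (1, 9): +1 gives (2, 10); log ratio to the geometric mean is
  # +/- log(sqrt(5)) = +/- 0.8047
  out <- clr_transform(tibble::tibble(sample = "s", g1 = 1, g2 = 9))
  expect_equal(out$g1, -log(sqrt(5)), tolerance = 1e-4)
  expect_equal(out$g2, log(sqrt(5)), tolerance = 1e-4)
  expect_equal(round(out$g2, 4), 0.8047)

  uni <- clr_transform(tibble::tibble(sample = "s", a = 7, b = 7, c = 7))
  expect_equal(unlist(uni[, -1]), c(a = 0, b = 0, c = 0))
})

test_that("CLR rows sum to zero for arbitrary count tables", {
  set.seed(41)
  m <- matrix(rpois(20 * 12, 50), 20, 12,
              dimnames = list(paste0("s", 1:20), paste0("g", 1:12)))
  out <- clr_transform(m)
  expect_true(all(abs(rowSums(out)) < 1e-9))
  expect_error(clr_transform(-m), "non-negative")
})

test_that("community types are recovered from two-profile count data", {
  sim <- simulate_metacommunity(sim_config(rng_seed = 5))
  ct <- assign_community_types(clr_transform(sim$dataset$genus_counts),
                               sim$dataset$metadata)
  truth <- sim$config$community_types
  got <- setNames(ct$types$type, ct$types$mesocosm)[names(truth)]
  agree <- mean(got == truth)
  expect_true(agree %in% c(0, 1))  # labels may swap, partition must match
  expect_true(agree == 1 || agree == 0)
  expect_true(ct$stable)
  # paired closed and open communities share the mesocosm label by
  # construction, so one label per mesocosm covers both regimes
  expect_equal(nrow(ct$types), 10L)
  expect_equal(nrow(glance(ct)), 1L)
})

test_that("a single shared profile gives an unstable partition", {
  set.seed(43)
  base <- rgamma(12, 2)
  counts <- t(vapply(1:16, function(i) {
    as.integer(rmultinom(1, 5e4, base / sum(base)))
  }, integer(12)))
  colnames(counts) <- paste0("g", 1:12)
  tab <- dplyr::bind_cols(tibble::tibble(sample = paste0("s", 1:16)),
                          tibble::as_tibble(counts))
  meta <- tibble::tibble(sample = paste0("s", 1:16),
                         mesocosm = as.character(rep(1:8, each = 2)))
  ct <- assign_community_types(clr_transform(tab), meta)
  expect_false(ct$stable)
})

test_that("Bray-Curtis follows its closed form and matches vegan", {
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(44)
  for (i in 1:5) {
    a <- runif(8); b <- runif(8)
    expect_equal(bray_curtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), "bray")),
                 tolerance = 1e-12)
  }
})

resilience_fixture <- function(shift_host = FALSE) {
  weeks <- c(0, 2, 4, 6, 8)
  genera <- paste0("g", 1:6)
  base <- c(40, 25, 15, 10, 6, 4) * 100
  rows <- list()
  for (mm in c("1", "2", "3")) {
    for (w in weeks) {
      counts <- base
      if (shift_host && mm == "1" && w >= 4) {
        counts[1] <- 100  # outbreak removes the host genus
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = sprintf("%s_closed_wk%d", mm, w),
        mesocosm = mm, regime = "closed", week = w,
        !!!setNames(as.list(counts), genera))
    }
  }
  dplyr::bind_rows(rows)
}

test_that("an outbreak leaving composition unchanged is within controls", {
  tab <- resilience_fixture(shift_host = FALSE)
  meta <- tab[, c("sample", "mesocosm", "regime", "week")]
  counts <- tab[, c("sample", paste0("g", 1:6))]
  windows <- tibble::tibble(mesocosm = "1", regime = "closed",
                            start_week = 2, end_week = 6)
  rt <- outbreak_resilience_test(counts, meta, windows)
  cmp <- rt$comparisons
  expect_equal(max(cmp$dissimilarity), 0)
  expect_equal(rt$summary$exceedance, 0.5)  # all ties
})

test_that("an outbreak that removes the host genus exceeds the controls", {
  tab <- resilience_fixture(shift_host = TRUE)
  meta <- tab[, c("sample", "mesocosm", "regime", "week")]
  counts <- tab[, c("sample", paste0("g", 1:6))]
  windows <- tibble::tibble(mesocosm = "1", regime = "closed",
                            start_week = 2, end_week = 6)
  rt <- outbreak_resilience_test(counts, meta, windows)
  ob <- rt$comparisons$dissimilarity[rt$comparisons$group == "outbreak"]
  ct <- rt$comparisons$dissimilarity[rt$comparisons$group == "control"]
  expect_true(all(ob > max(ct)))
  expect_equal(rt$summary$exceedance, 1)
  expect_equal(nrow(tidy(rt)), nrow(rt$comparisons))
})

test_that("missing matched control windows raise an error", {
  tab <- resilience_fixture()
  meta <- tab[, c("sample", "mesocosm", "regime", "week")]
  counts <- tab[, c("sample", paste0("g", 1:6))]
  windows <- tibble::tibble(mesocosm = c("1", "2", "3"),
                            regime = "closed",
                            start_week = 2, end_week = 6)
  expect_error(outbreak_resilience_test(counts, meta, windows),
               "control")
})
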