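afm_from_rows <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("v", seq_len(ncol(m)))
  tibble::tibble(sample = names(rows)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

test_that("near-clonal samples are recognised and read off as haplotypes", {
  nine <- c(rep(0.971, 9), rep(0, 11))
  afm <- afm_from_rows(list(
    ref_sample = rep(0, 20),
    g2_sample = nine,
    mixed = c(0.5, rep(0, 19)),
    gappy = c(NA, rep(0, 19))
  ))
  cl <- detect_clonal_samples(afm)
  expect_setequal(cl$sample, c("ref_sample", "g2_sample"))
  expect_equal(cl$n_alt[cl$sample == "ref_sample"], 0L)
  expect_equal(cl$n_alt[cl$sample == "g2_sample"], 9L)
  # a frequency exactly at the threshold is not "near fixation"
  at_thr <- afm_from_rows(list(s = c(0.97, rep(0, 19))))
  expect_equal(nrow(detect_clonal_samples(at_thr)), 0L)
})

test_that("clonality is invariant under ref/alt relabeling", {
  f <- c(0.99, 0.005, 0.98, 0)
  afm <- afm_from_rows(list(s = f))
  flipped <- afm_from_rows(list(s = c(1 - f[1], f[2:4])))
  h1 <- detect_clonal_samples(afm)$haplotype[[1]]
  h2 <- detect_clonal_samples(flipped)$haplotype[[1]]
  expect_equal(unname(h1[-1]), unname(h2[-1]))
  expect_equal(unname(h1[1]), 1L - unname(h2[1]))
})

test_that("identical clonal haplotypes collapse into one genotype", {
  afm <- afm_from_rows(list(
    a = c(0.99, 0.99, 0), b = c(0.999, 0.98, 0.001), c = rep(0, 3)
  ))
  gt <- derive_genotypes(detect_clonal_samples(afm))
  expect_equal(nrow(gt$haplotypes), 2L)
  two <- gt$genotypes[gt$genotypes$n_alt == 2L, ]
  expect_setequal(two$sources[[1]], c("a", "b"))
  expect_equal(gt$genotypes$provenance[gt$genotypes$n_alt == 0L],
               "reference")
})

test_that("the two founder haplotypes differ at the marker sites", {
  nine <- c(rep(1, 9), rep(0, 11))
  afm <- afm_from_rows(list(wk0_ref = rep(0, 20), wk6_alt = nine))
  gt <- derive_genotypes(detect_clonal_samples(afm))
  expect_equal(sum(gt$haplotypes["G1", ] != gt$haplotypes["G2", ]), 9L)
})

test_that("pigeonhole linking proposes a genotype from high-frequency sets", {
  afm <- afm_from_rows(list(
    ref = rep(0, 6),
    mixed = c(0.85, 0.9, 0.88, 0.01, 0.02, 0.0)
  ))
  gt <- derive_genotypes(detect_clonal_samples(afm), afm)
  expect_equal(nrow(gt$haplotypes), 2L)
  proposed <- gt$genotypes[gt$genotypes$n_alt == 3L, ]
  expect_equal(proposed$cooccurrence_bound, 0.85 + 0.9 + 0.88 - 2,
               tolerance = 1e-12)
  expect_equal(unname(gt$haplotypes[proposed$genotype, ]),
               c(1L, 1L, 1L, 0L, 0L, 0L))
  # an obvious two-genotype mixture must not spawn a partial haplotype
  mix <- afm_from_rows(list(
    ref = rep(0, 6),
    half = c(0.95, 0.5, 0.45, 0.5, 0.02, 0)
  ))
  gtm <- derive_genotypes(detect_clonal_samples(mix), mix)
  expect_equal(nrow(gtm$haplotypes), 1L)
})

test_that("co-occurrence lower bound follows inclusion-exclusion", {
  expect_equal(cooccurrence_lower_bound(c(0.9, 0.9)), 0.8)
  expect_equal(cooccurrence_lower_bound(c(0.8, 0.8, 0.8)), 0.4,
               tolerance = 1e-12)
  expect_equal(cooccurrence_lower_bound(c(0.6, 0.3)), 0)
  expect_error(cooccurrence_lower_bound(numeric()))
  expect_error(cooccurrence_lower_bound(c(0.5, 1.2)))
})
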