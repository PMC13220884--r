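test_that("a clonal sample decomposes to a unit vector in both modes", {
  gt <- genotypes_from_haplotypes(paper_style_haplotypes())
  vars <- colnames(gt$haplotypes)
  f <- setNames(as.numeric(gt$haplotypes["G2", ]), vars)
  for (mode in c("marker_averaging", "simplex_lsq")) {
    d <- decompose_sample(f, gt, mode = mode)
    expect_equal(d$fraction[d$genotype == "G2"], 1, tolerance = 1e-9)
    expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
  }
})

test_that("a 50/50 two-genotype mixture is resolved exactly", {
  haps <- paper_style_haplotypes()[c("G1", "G2")]
  gt <- genotypes_from_haplotypes(haps)
  f <- setNames(0.5 * gt$haplotypes["G2", ], colnames(gt$haplotypes))
  for (mode in c("marker_averaging", "simplex_lsq")) {
    d <- decompose_sample(f, gt, mode = mode)
    expect_equal(d$fraction[d$genotype == "G1"], 0.5, tolerance = 1e-9)
    expect_equal(d$fraction[d$genotype == "G2"], 0.5, tolerance = 1e-9)
  }
})

test_that("least squares recovers random simplexes from exact frequencies", {
  gt <- genotypes_from_haplotypes(paper_style_haplotypes())
  H <- gt$haplotypes
  set.seed(11)
  for (i in 1:20) {
    a <- rgamma(4, 1); a <- a / sum(a)
    names(a) <- rownames(H)
    f <- setNames(as.numeric(a %*% H), colnames(H))
    d <- decompose_sample(f, gt, mode = "simplex_lsq")
    est <- setNames(d$fraction, d$genotype)[names(a)]
    expect_equal(unname(est), unname(a), tolerance = 1e-6)
  }
})

test_that("averaging and least squares agree for exclusive-marker genotypes", {
  # mutually exclusive marker sets: averaging is exact and must match lsq
  vars <- paste0("v", 1:6)
  h <- function(on) setNames(as.integer(vars %in% on), vars)
  gt <- genotypes_from_haplotypes(list(
    R = h(character()), A = h(c("v1", "v2")), B = h(c("v3", "v4")),
    C = h(c("v5", "v6"))
  ))
  set.seed(12)
  for (i in 1:20) {
    a <- rgamma(4, 1); a <- a / sum(a)
    names(a) <- rownames(gt$haplotypes)
    f <- setNames(as.numeric(a %*% gt$haplotypes),
                  colnames(gt$haplotypes))
    d1 <- decompose_sample(f, gt, mode = "marker_averaging")
    d2 <- decompose_sample(f, gt, mode = "simplex_lsq")
    m1 <- setNames(d1$fraction, d1$genotype)
    m2 <- setNames(d2$fraction, d2$genotype)
    expect_equal(m1[names(m2)], m2, tolerance = 1e-6)
    expect_false(any(d1$flagged))
  }
})

test_that("every decomposition lands on the probability simplex", {
  gt <- genotypes_from_haplotypes(paper_style_haplotypes())
  set.seed(13)
  for (i in 1:25) {
    f <- setNames(runif(ncol(gt$haplotypes)), colnames(gt$haplotypes))
    for (mode in c("marker_averaging", "simplex_lsq")) {
      d <- decompose_sample(f, gt, mode = mode)
      expect_true(all(d$fraction >= 0))
      expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
    }
  }
})

test_that("ambiguous marker sharing falls back to least squares", {
  # nested haplotypes leave the contained genotype without exclusive markers
  vars <- paste0("v", 1:4)
  h <- function(on) setNames(as.integer(vars %in% on), vars)
  gt <- genotypes_from_haplotypes(list(
    R = h(character()), big = h(vars), nested = h(c("v1", "v2"))
  ))
  f <- setNames(c(0.9, 0.9, 0.6, 0.6), vars)
  d <- decompose_sample(f, gt, mode = "marker_averaging")
  expect_equal(unique(d$method), "simplex_lsq")
  expect_true(all(d$flagged))
})

test_that("degenerate inputs error clearly", {
  gt <- genotypes_from_haplotypes(paper_style_haplotypes())
  expect_error(decompose_sample(c(x = 0.5), gt), "overlap")
  expect_error(decompose_sample(setNames(0.5, colnames(gt$haplotypes)[1]),
                                structure(list(), class = "list")),
               "phage_genotypes")
})

test_that("decompose_samples maps every observed sample", {
  gt <- genotypes_from_haplotypes(paper_style_haplotypes())
  H <- gt$haplotypes
  afm <- dplyr::bind_cols(
    tibble::tibble(sample = c("pure2", "empty")),
    tibble::as_tibble(rbind(H["G2", ], NA_real_))
  )
  d <- decompose_samples(afm, gt, mode = "simplex_lsq")
  expect_setequal(unique(d$sample), "pure2")
  expect_equal(d$fraction[d$genotype == "G2"], 1, tolerance = 1e-9)
})
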