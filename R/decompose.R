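#' Decompose one sample's allele frequencies into genotype abundances
#'
#' Two decomposition modes are available. `"marker_averaging"` follows the
#' study-style recipe: each non-reference genotype's abundance is the mean
#' frequency of the markers exclusive to it among the genotypes present in
#' the sample (presence judged by a genotype's own exclusive markers
#' exceeding `presence_delta`), and the reference genotype absorbs the
#' complement `1 - sum(others)`, clipped at zero and renormalized. When
#' marker sharing leaves some genotype without exclusive markers the recipe
#' is ill-defined and the call falls back to `"simplex_lsq"` (the result is
#' flagged). `"simplex_lsq"` solves `f ~ H' a` by non-negative least squares
#' with the abundances constrained to the probability simplex.
#'
#' Variants observed in the sample but absent from the genotype haplotypes
#' are ignored; assign them first (see [detect_novel_blocks()]) if they
#' should contribute.
#'
#' @param freqs Named numeric vector of allele frequencies for one sample
#'   (names are variant ids; `NA` entries are dropped).
#' @param genotypes A `phage_genotypes` object.
#' @param mode `"marker_averaging"` or `"simplex_lsq"`.
#' @param presence_delta Threshold on a genotype's exclusive-marker mean used
#'   to call it present in averaging mode (default 0.10).
#' @param tol Complement tolerance: a reference complement below `-tol`
#'   flags the sample (default 0.05).
#' @return Tibble with columns `genotype`, `fraction`, `method`, `flagged`.
#'   Fractions are non-negative and sum to one.
#' @export
decompose_sample <- function(freqs, genotypes,
                             mode = c("marker_averaging", "simplex_lsq"),
                             presence_delta = 0.10, tol = 0.05) {
  mode <- match.arg(mode)
  if (!inherits(genotypes, "phage_genotypes") || nrow(genotypes$haplotypes) == 0L) {
    abort("genotypes must be a non-empty phage_genotypes object")
  }
  freqs <- freqs[!is.na(freqs)]
  H <- genotypes$haplotypes
  obs <- intersect(names(freqs), colnames(H))
  if (length(obs) == 0L) abort("no observed variants overlap the genotype haplotypes")
  f <- freqs[obs]
  H <- H[, obs, drop = FALSE]

  # guarantee a reference (all-zero) genotype to absorb the complement
  ids <- rownames(H)
  if (!any(rowSums(H) == 0)) {
    H <- rbind(H, REF = rep(0L, ncol(H)))
    ids <- rownames(H)
  }
  ref_id <- ids[rowSums(H) == 0][1]

  if (mode == "marker_averaging") {
    out <- decompose_averaging(f, H, ref_id, presence_delta, tol)
    if (!is.null(out)) return(out)
    # ambiguous marker sharing: fall back to the least-squares solution
    out <- decompose_lsq(f, H, "simplex_lsq")
    out$flagged <- TRUE
    return(out)
  }
  decompose_lsq(f, H, "simplex_lsq")
}

# averaging recipe; returns NULL when exclusivity cannot be established
decompose_averaging <- function(f, H, ref_id, presence_delta, tol) {
  nonref <- setdiff(rownames(H), ref_id)
  exclusive <- function(g, among) {
    others <- setdiff(among, g)
    v <- H[g, ] == 1L
    if (length(others)) v <- v & colSums(H[others, , drop = FALSE]) == 0L
    names(which(v))
  }
  full_excl <- lapply(setNames(nonref, nonref), exclusive, among = nonref)
  frac <- setNames(rep(0, length(nonref)), nonref)
  if (all(lengths(full_excl) > 0)) {
    # no marker sharing: the recipe is exact as is
    for (g in nonref) frac[g] <- mean(f[full_excl[[g]]])
  } else {
    # shared markers: restrict to the genotypes present in this sample
    # (presence judged by their own exclusive markers) and retry
    absent <- nonref[lengths(full_excl) > 0 &
                       vapply(full_excl, function(e)
                         length(e) > 0 && mean(f[e]) <= presence_delta,
                         TRUE)]
    present <- setdiff(nonref, absent)
    for (g in present) {
      e <- exclusive(g, present)
      if (!length(e)) return(NULL)
      frac[g] <- mean(f[e])
    }
  }
  ref <- 1 - sum(frac)
  flagged <- ref < -tol
  ref <- max(ref, 0)
  a <- c(setNames(ref, ref_id), frac)
  a <- a / sum(a)
  tibble(genotype = names(a), fraction = unname(a),
         method = "marker_averaging", flagged = flagged)
}

decompose_lsq <- function(f, H, label) {
  lambda <- 100
  A <- rbind(t(H), rep(lambda, nrow(H)))
  b <- c(f, lambda)
  x <- pracma::lsqnonneg(A, b)$x
  if (sum(x) <= 0) abort("degenerate least-squares decomposition")
  a <- x / sum(x)
  tibble(genotype = rownames(H), fraction = unname(a),
         method = label, flagged = FALSE)
}

#' Decompose every sample of an allele-frequency matrix
#'
#' Applies [decompose_sample()] to each sample that has at least one
#' observed catalog variant. Samples whose frequencies are entirely missing
#' (e.g. failed the breadth criterion) are omitted.
#'
#' @param afm Allele-frequency tibble.
#' @inheritParams decompose_sample
#' @return Long tibble: `sample`, `genotype`, `fraction`, `method`,
#'   `flagged`.
#' @export
decompose_samples <- function(afm, genotypes,
                              mode = c("marker_averaging", "simplex_lsq"),
                              presence_delta = 0.10, tol = 0.05) {
  mode <- match.arg(mode)
  m <- afm_matrix(afm)
  rows <- which(rowSums(!is.na(m)) > 0)
  purrr::map(rows, function(i) {
    decompose_sample(m[i, ], genotypes, mode = mode,
                     presence_delta = presence_delta, tol = tol) |>
      mutate(sample = rownames(m)[i], .before = 1L)
  }) |> bind_rows()
}
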