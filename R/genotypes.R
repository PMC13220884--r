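#' Clonality and linkage parameters
#'
#' @param high_threshold Frequency above which an allele counts as fixed in
#'   a near-clonal sample (default 0.97, strict).
#' @param low_threshold Frequency below which an allele counts as absent
#'   (default 0.03, strict).
#' @param high_freq_linkage_threshold Frequency above which variants in a
#'   non-clonal sample are linked onto a proposed genotype by the pigeonhole
#'   argument (default 0.8).
#' @return A list of class `clonality_params`.
#' @export
clonality_params <- function(high_threshold = 0.97, low_threshold = 0.03,
                             high_freq_linkage_threshold = 0.8) {
  stopifnot(low_threshold >= 0, high_threshold <= 1,
            low_threshold < high_threshold,
            high_freq_linkage_threshold > 0, high_freq_linkage_threshold < 1)
  structure(list(high_threshold = high_threshold,
                 low_threshold = low_threshold,
                 high_freq_linkage_threshold = high_freq_linkage_threshold),
            class = "clonality_params")
}

#' Identify near-clonal samples and their implied haplotypes
#'
#' A sample is near-clonal when every catalog allele frequency is above the
#' high threshold or below the low threshold, implying a single dominant
#' genotype whose haplotype is read off directly (1 where the frequency is
#' high). Samples with any missing frequency are never called clonal.
#'
#' @param afm Allele-frequency tibble (`sample` column plus one column per
#'   variant) from [filter_variants()].
#' @param params A [clonality_params()] object.
#' @return Tibble with columns `sample`, `n_alt` and a list-column
#'   `haplotype` of named 0/1 integer vectors over the catalog.
#' @export
detect_clonal_samples <- function(afm, params = clonality_params()) {
  m <- afm_matrix(afm)
  if (ncol(m) == 0L) return(tibble(sample = character(), n_alt = integer(),
                                   haplotype = list()))
  is_clonal <- apply(m, 1L, function(f) {
    !anyNA(f) && all(f > params$high_threshold | f < params$low_threshold)
  })
  rows <- which(is_clonal)
  tibble(
    sample = rownames(m)[rows],
    n_alt = unname(vapply(rows, function(i)
      sum(m[i, ] > params$high_threshold), 1L)),
    haplotype = purrr::map(rows, function(i) {
      setNames(as.integer(m[i, ] > params$high_threshold), colnames(m))
    })
  )
}

#' Minimum co-occurrence fraction of jointly high-frequency variants
#'
#' For k variants with frequencies `f`, at least `max(0, sum(f) - (k - 1))`
#' of the population must carry all k alternative alleles simultaneously
#' (inclusion-exclusion pigeonhole bound). A positive bound implies the
#' variants co-occur on the same genome in part of the population.
#'
#' @param frequencies Numeric vector of allele frequencies in \[0, 1\].
#' @return The lower bound, a fraction in \[0, 1\].
#' @export
#' @examples
#' cooccurrence_lower_bound(c(0.9, 0.9))       # 0.8
#' cooccurrence_lower_bound(c(0.8, 0.8, 0.8))  # 0.4
cooccurrence_lower_bound <- function(frequencies) {
  if (length(frequencies) == 0L) abort("frequencies must be non-empty")
  if (any(frequencies < 0 | frequencies > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  max(0, sum(frequencies) - (length(frequencies) - 1L))
}

new_phage_genotypes <- function(info, haplotypes) {
  structure(list(genotypes = info, haplotypes = haplotypes),
            class = "phage_genotypes")
}

#' Derive the genotype set from clonal and high-frequency evidence
#'
#' Deduplicates near-clonal haplotypes into genotypes, then scans non-clonal
#' samples for pigeonhole-linked genotypes: if a sample has several variants
#' above the high-frequency linkage threshold while every other variant is
#' effectively absent, a genotype carrying exactly those variants is
#' proposed: with the threshold above one half, any two of the high
#' variants must co-occur on the same genome in a positive fraction of the
#' population. The joint k-wise pigeonhole bound is recorded with the
#' proposal (it can be vacuously zero for large variant sets).
#'
#' Genotype ids are assigned in order of increasing alternative-allele count
#' (`G1`, `G2`, ...); the all-reference haplotype, if observed, is therefore
#' `G1`. Provenance is `"reference"` for the all-zero haplotype and
#' `"founder"` otherwise; recombination and novel-block detectors propose
#' further genotypes with their own provenance.
#'
#' @param clonal Output of [detect_clonal_samples()].
#' @param afm Optional allele-frequency tibble; when supplied, non-clonal
#'   fully observed samples are scanned for pigeonhole-linked genotypes.
#' @param params A [clonality_params()] object.
#' @param background_threshold Every variant not in the linked high-
#'   frequency set must sit below this frequency for a genotype to be
#'   proposed (default 0.10); keeps obvious genotype mixtures from
#'   spawning spurious partial haplotypes while tolerating the low-level
#'   background that migration maintains.
#' @param id_prefix Prefix for genotype ids (default `"G"`).
#' @return A `phage_genotypes` object: `$genotypes` (tibble with `genotype`,
#'   `provenance`, `n_alt`, `cooccurrence_bound`, list-column `sources`) and
#'   `$haplotypes` (genotype x variant 0/1 matrix).
#' @export
derive_genotypes <- function(clonal, afm = NULL, params = clonality_params(),
                             background_threshold = 0.10, id_prefix = "G") {
  if (nrow(clonal) == 0L) abort("no clonal haplotypes supplied")
  haps <- clonal$haplotype
  keys <- vapply(haps, paste, "", collapse = "")
  uniq <- !duplicated(keys)
  entries <- tibble(
    key = keys[uniq],
    haplotype = haps[uniq],
    sources = purrr::map(keys[uniq], ~ clonal$sample[keys == .x]),
    cooccurrence_bound = NA_real_
  )

  # pigeonhole linking from non-clonal, fully observed samples
  if (!is.null(afm)) {
    m <- afm_matrix(afm)
    m <- m[!(rownames(m) %in% clonal$sample), , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      f <- m[i, ]
      if (anyNA(f)) next
      hi <- f > params$high_freq_linkage_threshold
      lo <- f < background_threshold
      if (sum(hi) < 2L || !all(hi | lo)) next
      # with the linkage threshold above 0.5, every pair of high variants
      # must co-occur in a positive fraction of genomes; the joint k-wise
      # bound is reported but can be vacuous (0) for large variant sets
      bound <- cooccurrence_lower_bound(f[hi])
      hap <- setNames(as.integer(hi), colnames(m))
      key <- paste(hap, collapse = "")
      j <- match(key, entries$key)
      if (is.na(j)) {
        entries <- bind_rows(entries, tibble(
          key = key, haplotype = list(hap),
          sources = list(rownames(m)[i]), cooccurrence_bound = bound))
      } else {
        entries$sources[[j]] <- union(entries$sources[[j]], rownames(m)[i])
        entries$cooccurrence_bound[j] <-
          max(entries$cooccurrence_bound[j], bound, na.rm = TRUE)
      }
    }
  }

  H <- do.call(rbind, entries$haplotype)
  ord <- order(rowSums(H), match(entries$key, entries$key))
  H <- H[ord, , drop = FALSE]
  entries <- entries[ord, ]
  ids <- paste0(id_prefix, seq_len(nrow(entries)))
  rownames(H) <- ids
  info <- tibble(
    genotype = ids,
    provenance = unname(ifelse(rowSums(H) == 0, "reference", "founder")),
    n_alt = unname(as.integer(rowSums(H))),
    cooccurrence_bound = entries$cooccurrence_bound,
    sources = entries$sources
  )
  new_phage_genotypes(info, H)
}

#' @export
print.phage_genotypes <- function(x, ...) {
  cat(sprintf("phage genotype set: %d genotypes over %d variants\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  print(x$genotypes |> select(-"sources"))
  invisible(x)
}

#' @rdname derive_genotypes
#' @param x A `phage_genotypes` object.
#' @param ... Unused.
#' @export
tidy.phage_genotypes <- function(x, ...) {
  H <- x$haplotypes
  tibble(
    genotype = rep(rownames(H), each = ncol(H)),
    variant_id = rep(colnames(H), times = nrow(H)),
    allele = as.integer(t(H))
  )
}

#' @rdname derive_genotypes
#' @export
glance.phage_genotypes <- function(x, ...) {
  tibble(
    n_genotypes = nrow(x$haplotypes),
    n_variants = ncol(x$haplotypes),
    n_reference = sum(x$genotypes$provenance == "reference"),
    n_founder = sum(x$genotypes$provenance == "founder")
  )
}

#' Cluster SNP trajectories into linkage groups
#'
#' Partitions catalog variants by complete-linkage agglomerative clustering
#' on the trajectory distance `d(u, v) = max over co-observed samples of
#' |f_u - f_v|`, cut at the coupling tolerance. Variants whose trajectories
#' never depart from each other by more than the tolerance in any co-observed
#' sample end up in the same group; variants with fewer than two co-observed
#' samples are never merged and become singletons.
#'
#' @param afm Allele-frequency tibble.
#' @param delta Coupling tolerance (default 0.10).
#' @return An object of class `linkage_groups`: `$membership` (tibble
#'   `variant_id`, `group`), `$trajectories` (tibble `sample`, `group`,
#'   `freq`: per-sample mean frequency over group members) and `$delta`.
#' @export
cluster_trajectories <- function(afm, delta = 0.10) {
  m <- afm_matrix(afm)
  p <- ncol(m)
  if (p == 0L) abort("allele-frequency matrix has no variants")
  if (nrow(m) < 2L) abort("need at least two samples to cluster trajectories")

  if (p == 1L) {
    member <- tibble(variant_id = colnames(m), group = "LG01")
  } else {
    D <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(p - 1L)) {
      for (j in seq(i + 1L, p)) {
        co <- !is.na(m[, i]) & !is.na(m[, j])
        d <- if (sum(co) < 2L) 2 else max(abs(m[co, i] - m[co, j]))
        D[i, j] <- D[j, i] <- d
      }
    }
    hc <- hclust(as.dist(D), method = "complete")
    cl <- cutree(hc, h = delta)
    # stable labels: groups ordered by size (desc), then first member
    sizes <- table(cl)
    ord <- order(-as.integer(sizes), vapply(names(sizes), function(g) {
      min(which(cl == as.integer(g)))
    }, 1L))
    relabel <- setNames(seq_along(ord), names(sizes)[ord])
    member <- tibble(
      variant_id = colnames(m),
      group = sprintf("LG%02d", relabel[as.character(cl)])
    )
  }

  traj <- group_trajectories(afm, member)
  structure(list(membership = member, trajectories = traj, delta = delta),
            class = "linkage_groups")
}

# internal: per-sample mean frequency over the members of each group
group_trajectories <- function(afm, membership) {
  m <- afm_matrix(afm)
  purrr::map(split(membership$variant_id, membership$group), function(vs) {
    sub <- m[, vs, drop = FALSE]
    rowMeans(sub, na.rm = TRUE)
  }) |>
    purrr::imap(function(f, g) {
      tibble(sample = names(f), group = g,
             freq = unname(ifelse(is.nan(f), NA_real_, f)))
    }) |>
    bind_rows()
}

#' @export
print.linkage_groups <- function(x, ...) {
  sizes <- x$membership |> count(.data$group)
  cat(sprintf("linkage groups: %d groups over %d variants (delta = %g)\n",
              nrow(sizes), nrow(x$membership), x$delta))
  print(sizes)
  invisible(x)
}

#' @rdname cluster_trajectories
#' @param x A `linkage_groups` object.
#' @param ... Unused.
#' @export
tidy.linkage_groups <- function(x, ...) x$membership

#' @rdname cluster_trajectories
#' @export
glance.linkage_groups <- function(x, ...) {
  sizes <- x$membership |> count(.data$group)
  tibble(n_groups = nrow(sizes), n_variants = nrow(x$membership),
         n_singletons = sum(sizes$n == 1L), delta = x$delta)
}
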