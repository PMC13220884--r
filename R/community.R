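#' Centered log-ratio transform of a genus count table
#'
#' Per sample, counts are incremented by one (zero adjustment), logged and
#' centered on the sample's mean log count, so each output row sums to zero.
#' Compositional analyses (PCA-based community typing) operate on this
#' transform.
#'
#' @param counts Tibble with a `sample` column and one count column per
#'   genus, or a numeric matrix with samples in rows.
#' @return Same shape as the input, with CLR values.
#' @export
#' @examples
#' clr_transform(tibble::tibble(sample = "s1", g1 = 1, g2 = 9))
clr_transform <- function(counts) {
  as_mat <- is.matrix(counts)
  m <- if (as_mat) counts else afm_matrix(counts)
  if (ncol(m) == 0L) abort("count table has no genera")
  if (any(m < 0)) abort("counts must be non-negative")
  lg <- log(m + 1)
  out <- lg - rowMeans(lg)
  if (as_mat) out else afm_tibble(out)
}

#' Assign mesocosms to community types along the first principal axis
#'
#' Projects CLR-transformed samples onto the first principal component,
#' averages scores per mesocosm, and splits the mesocosms at the largest
#' gap between consecutive ordered means -- the two alternative stable
#' community compositions appear as two clusters along this axis. The
#' partition is flagged unstable when the largest gap is not clearly larger
#' than the remaining spread. Loadings of the top contributing genera on
#' the first two axes are reported.
#'
#' @param clr CLR matrix or tibble (see [clr_transform()]) with samples in
#'   rows.
#' @param metadata Tibble mapping `sample` to `mesocosm`.
#' @param min_gap_fraction The largest PC1 gap must exceed this fraction of
#'   the PC1 range for the partition to be called stable (default 0.25).
#' @param n_top Number of top loading genera reported per axis
#'   (default 10).
#' @return An object of class `community_typing`: `$types` (tibble
#'   `mesocosm`, `type`), `$scores` (per-sample PC scores), `$loadings`
#'   (top genera per axis), `$gap_fraction`, `$stable`, `$var_explained`.
#' @export
assign_community_types <- function(clr, metadata, min_gap_fraction = 0.25,
                                   n_top = 10) {
  m <- if (is.matrix(clr)) clr else afm_matrix(clr)
  stopifnot(all(c("sample", "mesocosm") %in% names(metadata)))
  meta <- metadata |> distinct(.data$sample, .data$mesocosm)
  meta <- meta[match(rownames(m), meta$sample), ]
  if (anyNA(meta$mesocosm)) abort("metadata lacks mesocosm for some samples")
  if (length(unique(meta$mesocosm)) < 2L) {
    abort("need at least two mesocosms to assign community types")
  }
  pc <- tryCatch(prcomp(m, center = TRUE, scale. = FALSE),
                 error = function(e) abort("degenerate CLR matrix"))
  if (pc$sdev[1] <= .Machine$double.eps) abort("degenerate (rank-0) CLR matrix")
  # sign convention: orient PC1 so its largest-magnitude loading is positive
  flip <- sign(pc$rotation[which.max(abs(pc$rotation[, 1])), 1])
  pc1 <- pc$x[, 1] * flip

  scores <- tibble(sample = rownames(m), mesocosm = meta$mesocosm,
                   pc1 = pc1,
                   pc2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
  means <- scores |>
    group_by(.data$mesocosm) |>
    summarise(pc1 = mean(.data$pc1), .groups = "drop") |>
    arrange(.data$pc1)
  gaps <- diff(means$pc1)
  cut_at <- which.max(gaps)
  rng <- diff(range(means$pc1))
  gap_fraction <- if (rng > 0) max(gaps) / rng else 0
  side <- c(rep("A", cut_at), rep("B", nrow(means) - cut_at))
  types <- tibble(mesocosm = means$mesocosm, type = side) |>
    arrange(.data$mesocosm)

  n_pc <- min(2L, ncol(pc$rotation))
  loadings <- purrr::map(seq_len(n_pc), function(k) {
    l <- pc$rotation[, k] * (if (k == 1) flip else 1)
    ord <- order(abs(l), decreasing = TRUE)[seq_len(min(n_top, length(l)))]
    tibble(axis = paste0("PC", k), genus = names(l)[ord],
           loading = unname(l[ord]))
  }) |> bind_rows()

  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(types = types, scores = scores, loadings = loadings,
                 gap_fraction = gap_fraction,
                 stable = gap_fraction >= min_gap_fraction,
                 var_explained = var_explained[seq_len(n_pc)]),
            class = "community_typing")
}

#' @export
print.community_typing <- function(x, ...) {
  cat(sprintf(
    "community typing: %d mesocosms, gap fraction %.2f (%s)\n",
    nrow(x$types), x$gap_fraction,
    if (x$stable) "stable" else "unstable"))
  print(x$types)
  invisible(x)
}

#' @rdname assign_community_types
#' @param x A `community_typing` object.
#' @param ... Unused.
#' @export
tidy.community_typing <- function(x, ...) x$types

#' @rdname assign_community_types
#' @export
glance.community_typing <- function(x, ...) {
  tibble(n_mesocosms = nrow(x$types),
         n_type_a = sum(x$types$type == "A"),
         n_type_b = sum(x$types$type == "B"),
         gap_fraction = x$gap_fraction, stable = x$stable,
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) >= 2) x$var_explained[2]
         else NA_real_)
}

#' @rdname assign_community_types
#' @param object A `community_typing` object.
#' @export
autoplot.community_typing <- function(object, ...) {
  df <- object$scores |> left_join(object$types, by = "mesocosm")
  ggplot(df, aes(x = .data$pc1, y = .data$pc2, colour = .data$type)) +
    geom_point() +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
         y = "PC2", colour = "community type") +
    theme_minimal()
}

#' Bray-Curtis dissimilarity between two relative-abundance vectors
#'
#' `1 - 2 * sum(min(a, b)) / sum(a + b)`; 0 for identical compositions,
#' 1 for disjoint support.
#'
#' @param a,b Non-negative abundance vectors over the same genus set.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a) + sum(b)
  if (tot == 0) abort("both vectors are all-zero")
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Compare compositional shifts across outbreak and control windows
#'
#' For each outbreak window, computes the Bray-Curtis dissimilarity between
#' the community composition at the window's start and end; control values
#' come from every sampled week pair of the same interval length in the
#' control communities. The two distributions are returned together with a
#' descriptive rank statistic: the rank sum of the outbreak values in the
#' pooled sample and the fraction of outbreak/control pairs where the
#' outbreak shift exceeds the control shift.
#'
#' @param counts Genus count (or relative abundance) tibble with a `sample`
#'   column.
#' @param metadata Tibble with `sample`, `mesocosm`, `regime`, `week`.
#' @param outbreak_windows Tibble with `mesocosm`, `regime`, `start_week`,
#'   `end_week` naming the outbreak intervals.
#' @return An object of class `resilience_test`: `$comparisons` (tibble
#'   `group`, `community`, `start_week`, `end_week`, `dissimilarity`) and
#'   `$summary` (rank sum, exceedance fraction, counts).
#' @export
outbreak_resilience_test <- function(counts, metadata, outbreak_windows) {
  meta <- check_metadata(metadata)
  m <- afm_matrix(counts)
  # work in relative abundances
  m <- m / pmax(rowSums(m), .Machine$double.eps)
  ow <- outbreak_windows |>
    mutate(community = paste0(.data$mesocosm, "_", .data$regime))
  if (nrow(ow) == 0L) abort("no outbreak windows supplied")

  bc_at <- function(comm, w1, w2) {
    s1 <- meta$sample[meta$community == comm & meta$week == w1]
    s2 <- meta$sample[meta$community == comm & meta$week == w2]
    if (!length(s1) || !length(s2)) return(NA_real_)
    bray_curtis(m[s1[1], ], m[s2[1], ])
  }

  outbreak <- ow |>
    rowwise() |>
    mutate(dissimilarity = bc_at(.data$community, .data$start_week,
                                 .data$end_week)) |>
    ungroup() |>
    transmute(group = "outbreak", community = .data$community,
              start_week = .data$start_week, end_week = .data$end_week,
              dissimilarity = .data$dissimilarity) |>
    filter(!is.na(.data$dissimilarity))

  lengths_needed <- unique(ow$end_week - ow$start_week)
  controls <- meta |>
    filter(!.data$community %in% ow$community) |>
    distinct(.data$community, .data$week)
  control <- purrr::map(unique(controls$community), function(comm) {
    wks <- sort(controls$week[controls$community == comm])
    pairs <- expand.grid(w1 = wks, w2 = wks) |>
      filter((.data$w2 - .data$w1) %in% lengths_needed)
    if (nrow(pairs) == 0L) return(NULL)
    pairs |>
      rowwise() |>
      mutate(dissimilarity = bc_at(comm, .data$w1, .data$w2)) |>
      ungroup() |>
      transmute(group = "control", community = comm,
                start_week = .data$w1, end_week = .data$w2,
                dissimilarity = .data$dissimilarity)
  }) |> bind_rows()
  if (nrow(control) == 0L) {
    abort("no matched-length control windows available")
  }
  comparisons <- bind_rows(outbreak, control)

  ranks <- rank(comparisons$dissimilarity)
  rank_sum <- sum(ranks[comparisons$group == "outbreak"])
  ob <- outbreak$dissimilarity; ct <- control$dissimilarity
  exceed <- mean(outer(ob, ct, ">") + 0.5 * outer(ob, ct, "=="))

  structure(list(
    comparisons = comparisons,
    summary = tibble(n_outbreak = length(ob), n_control = length(ct),
                     rank_sum = rank_sum, exceedance = exceed)
  ), class = "resilience_test")
}

#' @export
print.resilience_test <- function(x, ...) {
  cat("outbreak resilience comparison\n")
  print(x$summary)
  invisible(x)
}

#' @rdname outbreak_resilience_test
#' @param x A `resilience_test` object.
#' @param ... Unused.
#' @export
tidy.resilience_test <- function(x, ...) x$comparisons

#' @rdname outbreak_resilience_test
#' @export
glance.resilience_test <- function(x, ...) x$summary
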