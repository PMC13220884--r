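#' Detect recombination events from linkage-group decoupling
#'
#' Within each community (mesocosm x regime), linkage groups whose
#' trajectories ran together while both were at intermediate frequency are
#' monitored for decoupling: an event is emitted at the first sampled week
#' where two group trajectories separate by more than the decoupling
#' threshold, provided both groups were simultaneously at intermediate
#' frequency (inside `(delta, 1 - delta)`) and coupled (within `delta` of
#' each other) at some earlier sampled week -- the signature of a
#' recombinant genotype rising while its parents' marker sets part ways.
#' Pairs decoupling at the same week in the same community are merged into
#' one event. The child haplotype is proposed by rounding the sample's
#' allele frequencies at the event week.
#'
#' Novel mutation blocks rise from zero and would masquerade as decoupling;
#' exclude their variants (see [detect_novel_blocks()]) via
#' `exclude_variants`.
#'
#' @param afm Allele-frequency tibble.
#' @param metadata Sample metadata tibble with columns `sample`, `mesocosm`,
#'   `regime`, `week`.
#' @param groups A `linkage_groups` object (see [cluster_trajectories()]).
#' @param genotypes Optional `phage_genotypes` object used to name parents
#'   (the two most abundant genotypes before the event) and to match the
#'   proposed child haplotype to a known genotype.
#' @param delta Coupling tolerance (default 0.10).
#' @param decoupling Trajectory separation that triggers an event
#'   (default 0.30).
#' @param exclude_variants Variant ids excluded from the group trajectories.
#' @return Tibble with one row per event: `community`, `mesocosm`, `regime`,
#'   `week` (first decoupled week), list-column `parents`, `child`,
#'   `child_known` (whether the child matches a supplied genotype), and
#'   list-column `pairs` of decoupled group pairs.
#' @export
detect_recombination <- function(afm, metadata, groups, genotypes = NULL,
                                 delta = 0.10, decoupling = 0.30,
                                 exclude_variants = NULL) {
  stopifnot(inherits(groups, "linkage_groups"))
  meta <- check_metadata(metadata)
  member <- groups$membership |>
    filter(!.data$variant_id %in% exclude_variants)
  if (nrow(member) == 0L) return(empty_events())
  m <- afm_matrix(afm)

  events <- list()
  for (comm in unique(meta$community)) {
    sm <- meta |> filter(.data$community == comm) |> arrange(.data$week)
    sm <- sm[sm$sample %in% rownames(m), ]
    if (nrow(sm) < 2L) next
    gtraj <- group_freq_matrix(m[sm$sample, , drop = FALSE], member)
    gids <- colnames(gtraj)
    if (length(gids) < 2L) next
    for (i in seq_len(length(gids) - 1L)) {
      for (j in seq(i + 1L, length(gids))) {
        fa <- gtraj[, i]; fb <- gtraj[, j]
        co <- which(!is.na(fa) & !is.na(fb))
        if (length(co) < 2L) next
        d <- abs(fa[co] - fb[co])
        coexist <- fa[co] > delta & fa[co] < 1 - delta &
          fb[co] > delta & fb[co] < 1 - delta & d <= delta
        dec <- which(d > decoupling)
        dec <- dec[vapply(dec, function(k) any(coexist[seq_len(k - 1L)]),
                          TRUE)]
        if (!length(dec)) next
        k <- dec[1]
        events[[length(events) + 1L]] <- tibble(
          community = comm, week = sm$week[co[k]],
          group_a = gids[i], group_b = gids[j],
          pre_week = sm$week[utils::tail(co[which(coexist &
            seq_along(co) < k)], 1L)]
        )
      }
    }
  }
  if (!length(events)) return(empty_events())
  raw <- bind_rows(events)

  raw |>
    group_by(.data$community, .data$week) |>
    summarise(
      pairs = list(pick("group_a", "group_b")),
      pre_week = max(.data$pre_week), .groups = "drop"
    ) |>
    left_join(distinct(meta, .data$community, .data$mesocosm, .data$regime),
              by = "community") |>
    rowwise() |>
    mutate(annotate_event(m, meta, genotypes, .data$community, .data$week,
                          .data$pre_week, delta)) |>
    ungroup() |>
    select("community", "mesocosm", "regime", "week", "parents", "child",
           "child_known", "pairs")
}

empty_events <- function() {
  tibble(community = character(), mesocosm = character(), regime = character(),
         week = numeric(), parents = list(), child = character(),
         child_known = logical(), pairs = list())
}

check_metadata <- function(metadata) {
  req <- c("sample", "mesocosm", "regime", "week")
  if (!all(req %in% names(metadata))) {
    abort(paste("metadata needs columns:", paste(req, collapse = ", ")))
  }
  metadata |>
    mutate(community = paste0(.data$mesocosm, "_", .data$regime))
}

# weeks x groups matrix of mean member frequencies
group_freq_matrix <- function(m, membership) {
  split_vars <- split(membership$variant_id, membership$group)
  split_vars <- purrr::map(split_vars, ~ intersect(.x, colnames(m)))
  split_vars <- split_vars[lengths(split_vars) > 0]
  out <- vapply(split_vars, function(vs) {
    r <- rowMeans(m[, vs, drop = FALSE], na.rm = TRUE)
    ifelse(is.nan(r), NA_real_, r)
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(rownames(m),
                                                       names(split_vars)))
  out
}

annotate_event <- function(m, meta, genotypes, comm, week, pre_week, delta) {
  sm <- meta |> filter(.data$community == comm)
  parents <- list(character())
  if (!is.null(genotypes) && !is.na(pre_week)) {
    pre_sample <- sm$sample[sm$week == pre_week][1]
    if (!is.na(pre_sample) && pre_sample %in% rownames(m)) {
      dec <- decompose_sample(m[pre_sample, ], genotypes,
                              mode = "simplex_lsq")
      top <- dec |> filter(.data$fraction > delta) |>
        arrange(desc(.data$fraction))
      parents <- list(head(top$genotype, 2L))
    }
  }
  child <- NA_character_; known <- FALSE
  ev_sample <- sm$sample[sm$week == week][1]
  if (!is.na(ev_sample) && ev_sample %in% rownames(m)) {
    f <- m[ev_sample, ]
    f <- f[!is.na(f)]
    hap <- as.integer(f > 0.5)
    names(hap) <- names(f)
    child <- sprintf("REC_%s_wk%g", comm, week)
    if (!is.null(genotypes)) {
      H <- genotypes$haplotypes[, names(hap)[names(hap) %in%
                                               colnames(genotypes$haplotypes)],
                                drop = FALSE]
      hit <- which(apply(H, 1L, function(h) all(h == hap[colnames(H)])))
      if (length(hit)) {
        child <- rownames(H)[hit[1]]
        known <- TRUE
      }
    }
  }
  tibble(parents = parents, child = child, child_known = known)
}

#' Detect novel SNP blocks and assign them to carrier genotypes
#'
#' Finds variants that are effectively absent (below the low clonality
#' threshold) from every founding (week-0) and closed-regime sample yet
#' later reach the catalog frequency threshold somewhere -- the signature of
#' a block of new mutations arriving on an existing genome. Candidates are
#' clustered into blocks by trajectory similarity; each variant is then
#' assigned to the genotype whose abundance trajectory (decomposed from the
#' non-candidate markers, in the community where the variant first appears)
#' it shadows, using the mean absolute difference over co-observed weeks
#' from first appearance onward -- a variant fixed on one genome copies that
#' genome's abundance trajectory exactly. Variants matching no genotype
#' within the tolerance form a new block of provenance `"mutational"`.
#'
#' @param afm Allele-frequency tibble.
#' @param metadata Sample metadata (`sample`, `mesocosm`, `regime`, `week`).
#' @param genotypes A `phage_genotypes` object.
#' @param params A [clonality_params()] object (supplies the low threshold).
#' @param min_allele_freq Frequency a candidate must later reach
#'   (default 0.10).
#' @param delta Trajectory tolerance for both block clustering and carrier
#'   assignment (default 0.10).
#' @return An object of class `novel_blocks`: `$variants` (tibble
#'   `variant_id`, `block`, `community`, `first_week`, `carrier`,
#'   `distance`) and `$blocks` (tibble `block`, `n`, `community`,
#'   `first_week`, `carrier`, list-column `members`). Zero-row tibbles when
#'   nothing is found.
#' @export
detect_novel_blocks <- function(afm, metadata, genotypes,
                                params = clonality_params(),
                                min_allele_freq = 0.10, delta = 0.10) {
  meta <- check_metadata(metadata)
  m <- afm_matrix(afm)
  meta <- meta[meta$sample %in% rownames(m), ]
  baseline <- meta$sample[meta$regime == "closed" | meta$week == 0]
  later <- setdiff(meta$sample, baseline)
  if (!length(later) || ncol(m) == 0L) return(empty_novel_blocks())

  base_max <- apply(m[baseline, , drop = FALSE], 2L,
                    function(f) max(c(0, f), na.rm = TRUE))
  later_max <- apply(m[later, , drop = FALSE], 2L,
                     function(f) max(c(0, f), na.rm = TRUE))
  cand <- colnames(m)[base_max < params$low_threshold &
                        later_max >= min_allele_freq]
  if (!length(cand)) return(empty_novel_blocks())

  # first appearance per candidate
  first <- purrr::map(cand, function(v) {
    hit <- meta |>
      mutate(freq = m[.data$sample, v]) |>
      filter(!is.na(.data$freq), .data$freq >= min_allele_freq) |>
      arrange(.data$week)
    tibble(variant_id = v, community = hit$community[1],
           first_week = hit$week[1])
  }) |> bind_rows()

  # blocks: trajectory clustering restricted to the candidates
  if (length(cand) > 1L) {
    sub <- afm[c("sample", cand)]
    cl <- cluster_trajectories(sub, delta = delta)
    blocks <- cl$membership |> rename(block = "group")
  } else {
    blocks <- tibble(variant_id = cand, block = "LG01")
  }
  blocks$block <- sub("^LG", "NB", blocks$block)

  # carrier assignment against genotype abundance trajectories (decomposed
  # from the non-candidate markers) in the community of first appearance
  marker_vars <- setdiff(colnames(m), cand)
  abund_by_comm <- purrr::map(unique(first$community), function(comm) {
    sm <- meta |> filter(.data$community == comm) |> arrange(.data$week)
    sub <- afm[match(sm$sample, afm$sample), c("sample", marker_vars)]
    dec <- decompose_samples(sub, genotypes, mode = "simplex_lsq")
    # the all-reference genotype cannot carry a rising block
    ref_ids <- c("REF", rownames(genotypes$haplotypes)[
      rowSums(genotypes$haplotypes) == 0])
    dec |> filter(!.data$genotype %in% ref_ids) |>
      left_join(select(sm, "sample", "week"), by = "sample")
  })
  names(abund_by_comm) <- unique(first$community)

  res <- first |>
    left_join(blocks, by = "variant_id") |>
    rowwise() |>
    mutate(assign_carrier(m, meta, abund_by_comm[[.data$community]],
                          .data$variant_id, .data$community,
                          .data$first_week, delta)) |>
    ungroup()

  block_tab <- res |>
    group_by(.data$block) |>
    summarise(
      n = n(),
      community = .data$community[1],
      first_week = min(.data$first_week),
      carrier = carrier_mode(.data$carrier),
      members = list(.data$variant_id),
      .groups = "drop"
    )
  structure(list(variants = select(res, "variant_id", "block", "community",
                                   "first_week", "carrier", "distance"),
                 blocks = block_tab),
            class = "novel_blocks")
}

carrier_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

empty_novel_blocks <- function() {
  structure(list(
    variants = tibble(variant_id = character(), block = character(),
                      community = character(), first_week = numeric(),
                      carrier = character(), distance = numeric()),
    blocks = tibble(block = character(), n = integer(),
                    community = character(), first_week = numeric(),
                    carrier = character(), members = list())
  ), class = "novel_blocks")
}

assign_carrier <- function(m, meta, abund, v, comm, first_week, delta) {
  no_call <- tibble(carrier = NA_character_, distance = NA_real_)
  if (is.null(abund) || nrow(abund) == 0L) return(no_call)
  sm <- meta |> filter(.data$community == comm, .data$week >= first_week) |>
    arrange(.data$week)
  fv <- m[sm$sample, v]
  ok <- !is.na(fv)
  if (sum(ok) < 2L) return(no_call)
  nonref <- setdiff(unique(abund$genotype), character())
  dists <- vapply(nonref, function(g) {
    traj <- abund$fraction[abund$genotype == g][
      match(sm$sample, abund$sample[abund$genotype == g])]
    co <- ok & !is.na(traj)
    if (sum(co) < 2L) return(NA_real_)
    mean(abs(fv[co] - traj[co]))
  }, 1.0)
  if (all(is.na(dists)) || min(dists, na.rm = TRUE) > delta) return(no_call)
  best <- which.min(dists)
  tibble(carrier = names(dists)[best], distance = unname(dists[best]))
}

#' @export
print.novel_blocks <- function(x, ...) {
  cat(sprintf("novel SNP blocks: %d blocks, %d variants\n",
              nrow(x$blocks), nrow(x$variants)))
  print(x$blocks |> select(-"members"))
  invisible(x)
}

#' @rdname detect_novel_blocks
#' @param x A `novel_blocks` object.
#' @param ... Unused.
#' @export
tidy.novel_blocks <- function(x, ...) x$variants

#' @rdname detect_novel_blocks
#' @export
glance.novel_blocks <- function(x, ...) {
  tibble(n_blocks = nrow(x$blocks), n_variants = nrow(x$variants),
         n_assigned = sum(!is.na(x$variants$carrier)))
}
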