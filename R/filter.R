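#' Variant-retention parameters
#'
#' Thresholds used to build the SNP catalog from raw per-sample allele-depth
#' observations. All thresholds are inclusive: an allele at exactly the
#' minimum frequency with exactly the minimum read support passes, and a
#' sample at exactly the breadth cutoff qualifies.
#'
#' @param min_allele_freq Minimum alternative-allele frequency the allele
#'   must reach in at least one qualifying sample (default 0.10).
#' @param min_alt_reads Minimum number of reads supporting the alternative
#'   allele in that sample (default 4).
#' @param min_breadth_fraction Minimum fraction of the genome a sample must
#'   cover at the breadth depth threshold to qualify for variant evaluation
#'   (default 0.30).
#' @param breadth_depth_threshold Read depth at which breadth is evaluated
#'   (default 10).
#' @param irregular_depth_factor Variants whose site depth differs from the
#'   catalog-wide mean by more than this factor are flagged (never removed)
#'   for manual review (default 5).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_allele_freq = 0.10, min_alt_reads = 4,
                          min_breadth_fraction = 0.30,
                          breadth_depth_threshold = 10,
                          irregular_depth_factor = 5) {
  stopifnot(
    is.numeric(min_allele_freq), min_allele_freq >= 0, min_allele_freq <= 1,
    is.numeric(min_alt_reads), min_alt_reads >= 0,
    is.numeric(min_breadth_fraction), min_breadth_fraction >= 0,
    min_breadth_fraction <= 1,
    is.numeric(breadth_depth_threshold), breadth_depth_threshold >= 0,
    is.numeric(irregular_depth_factor), irregular_depth_factor >= 1
  )
  structure(
    list(min_allele_freq = min_allele_freq, min_alt_reads = min_alt_reads,
         min_breadth_fraction = min_breadth_fraction,
         breadth_depth_threshold = breadth_depth_threshold,
         irregular_depth_factor = irregular_depth_factor),
    class = "filter_params"
  )
}

#' Select samples that qualify for variant evaluation
#'
#' A sample qualifies when a sufficient fraction of the genome is covered at
#' the breadth depth threshold (inclusive boundary).
#'
#' @param coverage A tibble with columns `sample` and
#'   `breadth_<depth>x` for the configured depth threshold (e.g.
#'   `breadth_10x`), as produced by [simulate_metacommunity()] or read from a
#'   coverage TSV.
#' @param params A [filter_params()] object.
#' @return Character vector of qualifying sample ids.
#' @export
#' @examples
#' cov <- tibble::tibble(sample = c("a", "b"), breadth_10x = c(0.30, 0.29))
#' qualify_samples(cov, filter_params())   # "a"
qualify_samples <- function(coverage, params = filter_params()) {
  stopifnot(is.data.frame(coverage), "sample" %in% names(coverage))
  col <- sprintf("breadth_%gx", params$breadth_depth_threshold)
  if (!col %in% names(coverage)) {
    abort(sprintf("coverage table lacks column '%s' required by the breadth threshold", col))
  }
  b <- coverage[[col]]
  if (anyNA(b)) {
    abort(sprintf("missing breadth value for sample(s): %s",
                  paste(coverage$sample[is.na(b)], collapse = ", ")))
  }
  coverage$sample[b >= params$min_breadth_fraction]
}

#' Build the variant catalog and allele-frequency matrix
#'
#' Applies the study-style retention rules to raw allele-depth observations:
#' a variant enters the catalog iff, in at least one qualifying sample, its
#' frequency `alt / (ref + alt)` reaches `min_allele_freq` **and** its
#' alternative allele is supported by at least `min_alt_reads` reads. The
#' returned frequency matrix covers all samples present in the observations:
#' entries for non-qualifying samples, or for sites with zero depth, are
#' missing (`NA`).
#'
#' @param observations Long tibble of allele observations with columns
#'   `sample`, `pos`, `ref`, `alt`, `ref_depth`, `alt_depth` (see
#'   [read_vcf_minimal()]).
#' @param qualifying Character vector of qualifying sample ids from
#'   [qualify_samples()].
#' @param params A [filter_params()] object.
#' @return A list with `catalog` (tibble: `variant_id`, `pos`, `ref`, `alt`,
#'   `irregular_depth`) and `afm` (tibble: `sample` column plus one frequency
#'   column per catalog variant).
#' @export
filter_variants <- function(observations, qualifying,
                            params = filter_params()) {
  stopifnot(is.data.frame(observations))
  req <- c("sample", "pos", "ref", "alt", "ref_depth", "alt_depth")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    abort(paste0("observations lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  empty <- list(
    catalog = tibble(variant_id = character(), pos = integer(),
                     ref = character(), alt = character(),
                     irregular_depth = logical()),
    afm = tibble(sample = character())
  )
  if (nrow(observations) == 0L) return(empty)
  if (any(observations$ref_depth < 0 | observations$alt_depth < 0)) {
    abort("negative read depths in observations")
  }

  obs <- observations |>
    mutate(
      variant_id = variant_id(.data$pos, .data$ref, .data$alt),
      depth = .data$ref_depth + .data$alt_depth,
      freq = ifelse(.data$depth > 0, .data$alt_depth / .data$depth, NA_real_)
    )

  passing <- obs |>
    filter(.data$sample %in% .env$qualifying, !is.na(.data$freq)) |>
    filter(.data$freq >= params$min_allele_freq,
           .data$alt_depth >= params$min_alt_reads)
  catalog_ids <- unique(passing$variant_id)

  catalog <- obs |>
    distinct(.data$variant_id, .data$pos, .data$ref, .data$alt) |>
    filter(.data$variant_id %in% .env$catalog_ids) |>
    arrange(.data$pos, .data$alt)

  # depth-irregularity flag: site mean depth (over qualifying samples) far
  # from the catalog-wide mean suggests mapping artifacts worth review
  depth_by_var <- obs |>
    filter(.data$sample %in% .env$qualifying,
           .data$variant_id %in% .env$catalog_ids) |>
    group_by(.data$variant_id) |>
    summarise(mean_depth = mean(.data$depth), .groups = "drop")
  overall <- mean(depth_by_var$mean_depth)
  depth_by_var <- depth_by_var |>
    mutate(irregular_depth = overall > 0 &
             (.data$mean_depth > overall * params$irregular_depth_factor |
                .data$mean_depth < overall / params$irregular_depth_factor))
  catalog <- catalog |>
    left_join(select(depth_by_var, "variant_id", "irregular_depth"),
              by = "variant_id") |>
    mutate(irregular_depth = ifelse(is.na(.data$irregular_depth), FALSE,
                                    .data$irregular_depth))

  samples <- unique(obs$sample)
  if (nrow(catalog) == 0L) {
    return(list(catalog = empty$catalog, afm = tibble(sample = samples)))
  }

  afm <- obs |>
    filter(.data$variant_id %in% .env$catalog_ids) |>
    mutate(freq = ifelse(.data$sample %in% .env$qualifying, .data$freq,
                         NA_real_)) |>
    select("sample", "variant_id", "freq") |>
    pivot_wider(names_from = "variant_id", values_from = "freq")
  # keep catalog column order, cover samples with no retained observations
  afm <- tibble(sample = samples) |>
    left_join(afm, by = "sample")
  keep_cols <- c("sample", catalog$variant_id)
  for (v in setdiff(keep_cols, names(afm))) afm[[v]] <- NA_real_
  afm <- afm[keep_cols]

  list(catalog = catalog, afm = afm)
}
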