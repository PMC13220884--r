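#' Plot allele-frequency trajectories per community
#'
#' One line per variant over sampled weeks, facetted by community
#' (mesocosm x regime), optionally coloured by linkage group -- the
#' trajectory view in which linkage and decoupling are read.
#'
#' @param afm Allele-frequency tibble.
#' @param metadata Sample metadata (`sample`, `mesocosm`, `regime`,
#'   `week`).
#' @param groups Optional `linkage_groups` object for colouring.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(afm, metadata, groups = NULL) {
  meta <- check_metadata(metadata)
  long <- afm |>
    pivot_longer(-"sample", names_to = "variant_id", values_to = "freq") |>
    left_join(select(meta, "sample", "community", "week"), by = "sample") |>
    filter(!is.na(.data$freq))
  if (!is.null(groups)) {
    long <- long |> left_join(groups$membership, by = "variant_id")
    p <- ggplot(long, aes(x = .data$week, y = .data$freq,
                          group = .data$variant_id,
                          colour = .data$group))
  } else {
    p <- ggplot(long, aes(x = .data$week, y = .data$freq,
                          group = .data$variant_id))
  }
  p + geom_line(alpha = 0.6) +
    facet_wrap(~community) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "week", y = "alternative-allele frequency",
         colour = "linkage group") +
    theme_minimal()
}

#' Plot inferred genotype dynamics
#'
#' Stacked-area view of per-sample genotype fractions over time, facetted
#' by community.
#'
#' @param abundances Long tibble from [decompose_samples()] (`sample`,
#'   `genotype`, `fraction`).
#' @param metadata Sample metadata (`sample`, `mesocosm`, `regime`,
#'   `week`).
#' @return A ggplot object.
#' @export
plot_genotype_dynamics <- function(abundances, metadata) {
  meta <- check_metadata(metadata)
  df <- abundances |>
    left_join(select(meta, "sample", "community", "week"), by = "sample")
  ggplot(df, aes(x = .data$week, y = .data$fraction,
                 fill = .data$genotype)) +
    geom_area(position = "stack") +
    facet_wrap(~community) +
    labs(x = "week", y = "genotype fraction", fill = "genotype") +
    theme_minimal()
}
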