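#' Relative abundance of a sequence in a metagenome
#'
#' @param mapped Reads mapped to the target sequence.
#' @param total Total reads in the sample (> 0).
#' @return `mapped / total`.
#' @export
relative_abundance <- function(mapped, total) {
  stopifnot(is.numeric(mapped), is.numeric(total))
  if (any(total == 0)) abort("total reads must be positive")
  if (any(mapped < 0 | mapped > total)) {
    abort("mapped reads must lie in [0, total]")
  }
  mapped / total
}

#' Breadth of coverage at a depth threshold
#'
#' Fraction of genome positions covered by at least `min_depth` reads.
#'
#' @param depths Per-position read depth vector (length = genome length).
#' @param min_depth Depth threshold (>= 1).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' breadth_of_coverage(c(0, 0, 5, 12, 12, 0, 9, 10, 11, 0), 10)  # 0.4
breadth_of_coverage <- function(depths, min_depth = 1) {
  if (length(depths) == 0L) abort("empty coverage profile")
  stopifnot(min_depth >= 1, all(depths >= 0))
  mean(depths >= min_depth)
}

#' Presence/absence call from breadth of coverage
#'
#' A sequence is called present when its breadth of coverage at `min_depth`
#' reaches the breadth threshold (inclusive).
#'
#' @param depths Per-position read depth vector, or a single precomputed
#'   breadth value when `is_breadth = TRUE`.
#' @param breadth_threshold Minimum breadth for a presence call
#'   (default 0.5).
#' @param min_depth Depth threshold for breadth (default 1).
#' @param is_breadth Set `TRUE` when `depths` is already a breadth fraction.
#' @return `"present"` or `"absent"`.
#' @export
detection_call <- function(depths, breadth_threshold = 0.5, min_depth = 1,
                           is_breadth = FALSE) {
  stopifnot(breadth_threshold >= 0, breadth_threshold <= 1)
  b <- if (is_breadth) depths else breadth_of_coverage(depths, min_depth)
  ifelse(b >= breadth_threshold, "present", "absent")
}

#' Viral-to-bacterial genome ratio required for a read fraction
#'
#' Given that a fraction `f` of metagenome nucleotides derive from a phage
#' of genome length `phage_genome_length` and the rest from bacteria of
#' genome length `host_genome_length`, the phage genome-copy number per
#' bacterial genome must be `(f / (1 - f)) * (g_b / g_p)`. The non-phage
#' read fraction is treated as entirely bacterial (first-order
#' approximation).
#'
#' @param read_fraction Fraction of reads from the phage, in \[0, 1).
#' @param phage_genome_length Phage genome length in bp.
#' @param host_genome_length Bacterial genome length in bp (default 4 Mb).
#' @return Phage genomes per bacterial genome.
#' @export
#' @examples
#' required_genome_ratio(0.5, 63535, 63535)        # 1
#' required_genome_ratio(0.74, 63535, 4e6)         # ~179.2
required_genome_ratio <- function(read_fraction, phage_genome_length,
                                  host_genome_length = 4e6) {
  stopifnot(phage_genome_length > 0, host_genome_length > 0)
  if (any(read_fraction >= 1 | read_fraction < 0)) {
    abort("read_fraction must lie in [0, 1)")
  }
  (read_fraction / (1 - read_fraction)) *
    (host_genome_length / phage_genome_length)
}

#' Burst size implied by a genome ratio when only part of the community
#' is host
#'
#' If the phage host makes up only a fraction of the bacterial community,
#' the per-host-cell virion yield required to sustain a given
#' viral-to-bacterial genome ratio scales up by the inverse of that
#' fraction.
#'
#' @param ratio Viral-to-bacterial genome ratio
#'   (see [required_genome_ratio()]).
#' @param host_fraction Fraction of the bacterial community that is host,
#'   in (0, 1\].
#' @return Virions per host cell.
#' @export
required_burst_size <- function(ratio, host_fraction) {
  stopifnot(ratio >= 0)
  if (any(host_fraction <= 0 | host_fraction > 1)) {
    abort("host_fraction must lie in (0, 1]")
  }
  ratio / host_fraction
}
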