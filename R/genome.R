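check_sequence <- function(seq, arg = "seq") {
  if (inherits(seq, "DNAString") || inherits(seq, "DNAStringSet")) {
    seq <- as.character(seq)[1]
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) abort(sprintf("%s is empty", arg))
  if (grepl("[^ACGTN]", seq)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", arg))
  }
  seq
}

#' Detect a direct terminal repeat (DTR)
#'
#' Returns the length of the longest exact repeat shared by the start and
#' end of the sequence, the assembly-completeness signature of phage genomes
#' built from replication concatemers. The search caps the repeat length at
#' half the sequence length so prefix and suffix stay disjoint.
#'
#' @param seq Genome sequence (character string or `DNAString`).
#' @param min_len Minimum repeat length to report (default 20).
#' @return The repeat length in bp, or 0 when no terminal repeat of at
#'   least `min_len` exists.
#' @export
detect_dtr <- function(seq, min_len = 20) {
  seq <- check_sequence(seq)
  stopifnot(min_len >= 1)
  L <- nchar(seq)
  if (L < 2 * min_len) {
    abort("sequence shorter than twice the minimum repeat length")
  }
  for (k in seq(floor(L / 2), min_len)) {
    if (substr(seq, 1L, k) == substr(seq, L - k + 1L, L)) return(k)
  }
  0L
}

#' Test whether two genomes are circular permutations of each other
#'
#' True iff the sequences have equal length and one is a rotation of the
#' other (substring-of-doubled-sequence test).
#'
#' @param a,b Genome sequences (character strings or `DNAString`).
#' @return Logical.
#' @export
is_circular_permutation <- function(a, b) {
  a <- check_sequence(a, "a"); b <- check_sequence(b, "b")
  if (nchar(a) != nchar(b)) return(FALSE)
  grepl(a, paste0(b, b), fixed = TRUE)
}

#' Global percent identity between two sequences
#'
#' Percent identity computed as matches over alignment columns from an
#' exact global (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' gap -1. With `rotation_invariant = TRUE` the best identity over
#' rotations of `b` is returned, using a seeded rotation search: rotations
#' aligning an exact prefix seed of `a`, supplemented by evenly spaced
#' fallback rotations, are evaluated and the maximum identity reported.
#'
#' @param a,b Sequences (character strings or `DNAString`).
#' @param rotation_invariant Search over rotations of `b` (default FALSE).
#' @param seed_length Seed k-mer length for the rotation search
#'   (default 15).
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, rotation_invariant = FALSE,
                              seed_length = 15) {
  a <- check_sequence(a, "a"); b <- check_sequence(b, "b")
  if (!rotation_invariant) return(identity_global(a, b))
  k <- min(seed_length, floor(nchar(a) / 2), nchar(b))
  seed <- substr(a, 1L, k)
  doubled <- paste0(b, b)
  hits <- gregexpr(seed, substr(doubled, 1L, nchar(b) + k - 1L),
                   fixed = TRUE)[[1]]
  offsets <- if (hits[1] == -1L) integer() else as.integer(hits) - 1L
  # fallback rotations keep the search honest when the seed never matches
  stride <- max(1L, floor(nchar(b) / 8))
  offsets <- unique(c(offsets, seq(0L, nchar(b) - 1L, by = stride)))
  offsets <- head(offsets, 50L)
  max(vapply(offsets, function(o) {
    rb <- paste0(substr(b, o + 1L, nchar(b)), substr(b, 1L, o))
    identity_global(a, rb)
  }, 1.0))
}

identity_global <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1
  )
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Taxonomic rank demarcation from intergenomic similarity
#'
#' Applies the ICTV-style thresholds for this phage family: two genomes
#' belong to the same species, genus or subfamily at >= 95, >= 70 and
#' >= 40% intergenomic similarity respectively (inclusive boundaries); a
#' value below all thresholds marks a new subfamily candidate. Similarity
#' values are supplied externally (e.g. from an intergenomic-similarity
#' tool); this function only renders the classification decision.
#'
#' @param similarity Intergenomic similarity in percent, in \[0, 100\].
#' @param thresholds Named vector of rank thresholds.
#' @return Character vector of verdicts: `"same_species"`, `"same_genus"`,
#'   `"same_subfamily"` or `"new_subfamily_candidate"`.
#' @export
#' @examples
#' demarcate_rank(c(100, 70, 8.98))
demarcate_rank <- function(similarity,
                           thresholds = c(species = 95, genus = 70,
                                          subfamily = 40)) {
  stopifnot(all(c("species", "genus", "subfamily") %in% names(thresholds)))
  if (any(similarity < 0 | similarity > 100)) {
    abort("similarity must lie in [0, 100]")
  }
  dplyr::case_when(
    similarity >= thresholds[["species"]] ~ "same_species",
    similarity >= thresholds[["genus"]] ~ "same_genus",
    similarity >= thresholds[["subfamily"]] ~ "same_subfamily",
    TRUE ~ "new_subfamily_candidate"
  )
}
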