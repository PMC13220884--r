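#' Read a minimal single-contig VCF with per-sample allele depths
#'
#' Parses the allele-depth dialect used throughout this package: a VCFv4.x
#' header, one contig, SNP records, and a `FORMAT` containing `AD`
#' (ref,alt read depths) for every sample. Multiallelic records are split
#' into biallelic observations (the ref depth is shared). Malformed lines
#' are reported with their line numbers; a missing depth field is reported
#' with the sample and line.
#'
#' @param path Path to an uncompressed VCF file.
#' @return Long tibble with columns `sample`, `pos`, `ref`, `alt`,
#'   `ref_depth`, `alt_depth` -- one row per sample x (split) record with an
#'   available depth.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) {
    abort("no #CHROM header line found; not a VCF file or truncated")
  }
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) {
    abort(sprintf("line %d: header has no sample columns", hdr))
  }
  samples <- cols[-(1:9)]
  body <- seq_along(lines) > hdr & nzchar(lines)

  out <- purrr::map(which(body), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L + length(samples)) {
      abort(sprintf("line %d: expected %d fields, found %d",
                    i, 9L + length(samples), length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) abort(sprintf("line %d: invalid POS '%s'", i, f[2]))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ad_idx <- match("AD", fmt)
    if (is.na(ad_idx)) abort(sprintf("line %d: FORMAT lacks AD", i))
    purrr::imap(setNames(f[-(1:9)], samples), function(sf, smp) {
      parts <- strsplit(sf, ":", fixed = TRUE)[[1]]
      ad <- parts[ad_idx]
      if (is.na(ad) || ad %in% c(".", "./.")) return(NULL)
      d <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
      if (anyNA(d) || length(d) != length(alts) + 1L) {
        abort(sprintf("line %d: malformed AD '%s' for sample %s",
                      i, ad, smp))
      }
      tibble(sample = smp, pos = pos, ref = f[4], alt = alts,
             ref_depth = d[1], alt_depth = d[-1])
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(out) == 0L) {
    return(tibble(sample = character(), pos = integer(), ref = character(),
                  alt = character(), ref_depth = integer(),
                  alt_depth = integer()))
  }
  out
}

#' Write allele-depth observations as a minimal VCF
#'
#' Inverse of [read_vcf_minimal()]: one biallelic SNP record per
#' (position, ref, alt), `FORMAT=AD`, with `.` for samples lacking an
#' observation at a record.
#'
#' @param observations Long observation tibble (`sample`, `pos`, `ref`,
#'   `alt`, `ref_depth`, `alt_depth`).
#' @param path Output path.
#' @param contig Contig name written in the header (default "phage").
#' @param contig_length Optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(observations, path, contig = "phage",
                              contig_length = NULL) {
  obs <- observations |> arrange(.data$pos, .data$alt, .data$sample)
  samples <- sort(unique(obs$sample))
  recs <- obs |> distinct(.data$pos, .data$ref, .data$alt) |>
    arrange(.data$pos, .data$alt)
  key <- function(p, r, a, s) paste(p, r, a, s, sep = "\r")
  lookup <- setNames(
    paste0(obs$ref_depth, ",", obs$alt_depth),
    key(obs$pos, obs$ref, obs$alt, obs$sample)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    if (is.null(contig_length)) sprintf("##contig=<ID=%s>", contig) else
      sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(contig_length)),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- purrr::pmap_chr(recs, function(pos, ref, alt) {
    ads <- lookup[key(pos, ref, alt, samples)]
    ads[is.na(ads)] <- "."
    paste(c(contig, pos, ".", ref, alt, ".", "PASS", ".", "AD", ads),
          collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the simulated dataset as plain-text files
#'
#' Emits the observable layer of a simulation as the standard file set the
#' pipeline consumes: a minimal VCF of allele depths, a coverage TSV, a
#' metadata TSV and a genus-count TSV, plus the ground truth as JSON.
#'
#' @param sim Output of [simulate_metacommunity()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "allele_depths.vcf"),
    coverage = file.path(dir, "coverage.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    genus_counts = file.path(dir, "genus_counts.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf_minimal(sim$dataset$observations, paths["vcf"],
                    contig_length = sim$config$genome_length)
  readr::write_tsv(sim$dataset$coverage, paths["coverage"])
  readr::write_tsv(sim$dataset$metadata, paths["metadata"])
  readr::write_tsv(sim$dataset$genus_counts, paths["genus_counts"])
  truth <- sim$truth
  truth$haplotypes <- cbind(
    tibble(genotype = rownames(truth$haplotypes)),
    as_tibble(truth$haplotypes)
  )
  jsonlite::write_json(truth, paths["truth"], digits = NA)
  invisible(paths)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters with input/output locations. Unknown
#' keys are rejected, so typos surface immediately.
#'
#' @param simulate Optional [sim_config()]; when given, the pipeline runs
#'   on simulated data and ignores the input paths.
#' @param vcf,coverage,metadata Input paths (minimal VCF and TSVs) used
#'   when `simulate` is `NULL`.
#' @param out_dir Output directory.
#' @param filter A [filter_params()] object.
#' @param clonality A [clonality_params()] object.
#' @param delta Coupling tolerance for trajectory clustering and carrier
#'   assignment (default 0.10).
#' @param decoupling Decoupling threshold for recombination detection
#'   (default 0.30).
#' @param decompose_mode Decomposition mode (see [decompose_sample()]).
#' @param seed Integer seed used for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, vcf = NULL, coverage = NULL,
                            metadata = NULL, out_dir = "phagetrace_out",
                            filter = filter_params(),
                            clonality = clonality_params(),
                            delta = 0.10, decoupling = 0.30,
                            decompose_mode = "marker_averaging",
                            seed = 1L) {
  stopifnot(inherits(filter, "filter_params"),
            inherits(clonality, "clonality_params"),
            delta > 0, delta < 1, decoupling > delta, decoupling < 1)
  if (is.null(simulate) &&
      (is.null(vcf) || is.null(coverage) || is.null(metadata))) {
    abort("either a simulation config or vcf+coverage+metadata paths are required")
  }
  structure(list(simulate = simulate, vcf = vcf, coverage = coverage,
                 metadata = metadata, out_dir = out_dir, filter = filter,
                 clonality = clonality, delta = delta,
                 decoupling = decoupling, decompose_mode = decompose_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Chains the stages end to end: (optional) simulation -> sample
#' qualification -> variant filtering -> clonal-sample detection ->
#' genotype derivation -> linkage-group clustering -> novel-block
#' detection -> recombination detection (on groups excluding novel-block
#' variants) -> per-sample genotype decomposition -> catalog accounting.
#' All outputs are written to `config$out_dir` together with a manifest
#' recording every parameter, the seed and the package version; rerunning
#' with the same configuration reproduces the bundle byte for byte.
#'
#' @param config A [pipeline_config()] object.
#' @return The report bundle (a named list of the stage outputs),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      cfg <- config$simulate
      cfg$rng_seed <- config$seed
      simulate_metacommunity(cfg)
    })
    obs <- sim$dataset$observations
    coverage <- sim$dataset$coverage
    metadata <- sim$dataset$metadata
  } else {
    sim <- NULL
    obs <- stage("read_vcf", read_vcf_minimal(config$vcf))
    coverage <- stage("read_coverage", readr::read_tsv(
      config$coverage, show_col_types = FALSE))
    metadata <- stage("read_metadata", readr::read_tsv(
      config$metadata, show_col_types = FALSE,
      col_types = readr::cols(mesocosm = readr::col_character())))
  }

  qualifying <- stage("qualify", qualify_samples(coverage, config$filter))
  filtered <- stage("filter", filter_variants(obs, qualifying,
                                              config$filter))
  clonal <- stage("clonality", detect_clonal_samples(filtered$afm,
                                                     config$clonality))
  genotypes <- stage("genotypes", derive_genotypes(clonal, filtered$afm,
                                                   config$clonality))
  groups <- stage("linkage", cluster_trajectories(filtered$afm,
                                                  config$delta))
  blocks <- stage("novel_blocks", detect_novel_blocks(
    filtered$afm, metadata, genotypes, config$clonality,
    config$filter$min_allele_freq, config$delta))
  events <- stage("recombination", detect_recombination(
    filtered$afm, metadata, groups, genotypes, config$delta,
    config$decoupling, exclude_variants = blocks$variants$variant_id))
  abundances <- stage("decompose", decompose_samples(
    filtered$afm, genotypes, mode = config$decompose_mode))

  H <- genotypes$haplotypes
  catalog <- filtered$catalog
  for (g in rownames(H)) {
    catalog[[g]] <- as.logical(H[g, ][catalog$variant_id])
  }
  # observation flags per community type x regime (detected = reaches the
  # catalog frequency threshold in a qualifying sample of that category)
  if ("community_type" %in% names(metadata)) {
    m <- afm_matrix(filtered$afm)
    cats <- list(in_closed_A = c("closed", "A"), in_open_A = c("open", "A"),
                 in_closed_B = c("closed", "B"), in_open_B = c("open", "B"))
    for (nm in names(cats)) {
      smp <- metadata$sample[metadata$regime == cats[[nm]][1] &
                               metadata$community_type == cats[[nm]][2]]
      smp <- intersect(smp, rownames(m))
      sub <- m[smp, catalog$variant_id, drop = FALSE]
      catalog[[nm]] <- apply(sub, 2L, function(f) {
        any(!is.na(f) & f >= config$filter$min_allele_freq)
      })
    }
  }
  report <- stage("report", summarize_catalog(catalog))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(catalog, p("catalog.tsv"))
  readr::write_tsv(filtered$afm, p("allele_frequencies.tsv"))
  readr::write_tsv(tidy(genotypes) |>
                     pivot_wider(names_from = "genotype",
                                 values_from = "allele"),
                   p("genotypes.tsv"))
  readr::write_tsv(abundances, p("abundances.tsv"))
  readr::write_tsv(groups$membership, p("linkage_groups.tsv"))
  readr::write_tsv(blocks$variants, p("novel_blocks.tsv"))
  jsonlite::write_json(
    events |> mutate(pairs = purrr::map(.data$pairs, ~ .x)),
    p("events.json"), digits = NA)
  jsonlite::write_json(unclass(report), p("report.json"), digits = NA)

  manifest <- list(
    package = "phagetrace",
    version = as.character(packageVersion("phagetrace")),
    seed = config$seed,
    parameters = list(
      filter = unclass(config$filter),
      clonality = unclass(config$clonality),
      delta = config$delta, decoupling = config$decoupling,
      decompose_mode = config$decompose_mode,
      simulated = !is.null(config$simulate)
    ),
    counts = list(
      samples_total = nrow(coverage), samples_qualifying = length(qualifying),
      variants_catalog = nrow(filtered$catalog),
      clonal_samples = nrow(clonal),
      genotypes = nrow(genotypes$haplotypes),
      linkage_groups = length(unique(groups$membership$group)),
      recombination_events = nrow(events),
      novel_variants = nrow(blocks$variants)
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(simulation = sim, qualifying = qualifying,
                 catalog = catalog, afm = filtered$afm, clonal = clonal,
                 genotypes = genotypes, groups = groups, blocks = blocks,
                 events = events, abundances = abundances, report = report,
                 manifest = manifest))
}
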