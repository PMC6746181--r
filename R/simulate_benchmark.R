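#' Library manifest implied by a benchmark design
#'
#' Expands a [benchmark_design()] into one row per library: every
#' (source, spike level, replicate) sample plus the negative controls, each
#' taken through `preps_per_sample` independent library preparations.
#'
#' @param design a [benchmark_design()].
#' @return tibble with `library_id`, `sample_id`, `source`, `spike_level`
#'   (0 for negative controls), `replicate`, `prep`.
#' @examples
#' nrow(design_manifest(benchmark_design())) # 56
#' @export
design_manifest <- function(design) {
  spike <- tidyr::expand_grid(
    source = design$sources,
    level_idx = seq_along(design$spike_levels),
    replicate = seq_len(design$replicates_per_condition)
  )
  spike <- dplyr::mutate(
    spike,
    spike_level = design$spike_levels[.data$level_idx],
    sample_id = sprintf("%s_L%02d_r%d", .data$source, .data$level_idx,
                        .data$replicate)
  )
  neg <- tibble(
    source = "negative",
    level_idx = 0L,
    replicate = seq_len(design$negative_controls),
    spike_level = 0,
    sample_id = sprintf("NC_r%d", seq_len(design$negative_controls))
  )
  samples <- dplyr::bind_rows(spike, neg)
  out <- tidyr::expand_grid(
    dplyr::select(samples, "sample_id", "source", "spike_level", "replicate"),
    prep = seq_len(design$preps_per_sample)
  )
  dplyr::mutate(out,
                library_id = sprintf("%s_p%d", .data$sample_id, .data$prep),
                .before = 1L)
}

#' Simulate a full spike-in benchmark
#'
#' Runs [simulate_library()] for every library in the design manifest. The
#' spike level of each library is split evenly across the design's target
#' loci (so per-library truth molecules sum to the designed level);
#' negative-control libraries contain zero mutant templates and only the
#' wild-type plasma background.
#'
#' @param amplicons amplicon design tibble covering the design's alleles.
#' @param design a [benchmark_design()].
#' @param cfg a [sim_config()]; `cfg$seed` seeds the whole benchmark and
#'   per-library seeds are derived as `cfg$seed * 1000 + library index`.
#' @return list of class `benchmark_sim`:
#'   * `manifest`: one row per library;
#'   * `truth`: one row per (library, locus) with `true_template_molecules`
#'     and `true_mutant`;
#'   * `reads`: all simulated reads with a `library_id` column.
#' @export
simulate_benchmark <- function(amplicons, design = benchmark_design(),
                               cfg = sim_config()) {
  if (nrow(amplicons) < design$n_alleles) {
    abort("amplicon design has fewer loci than `design$n_alleles`")
  }
  amplicons <- amplicons[seq_len(design$n_alleles), ]
  manifest <- design_manifest(design)
  sims <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mols <- split_molecules(row$spike_level, amplicons$locus_id)
    reads <- simulate_library(amplicons, mols, cfg,
                              library_id = row$library_id,
                              seed = cfg$seed * 1000L + i)
    truth <- tibble(
      library_id = row$library_id,
      locus_id = amplicons$locus_id,
      true_template_molecules = as.integer(mols),
      true_mutant = mols > 0L
    )
    list(reads = dplyr::mutate(reads, library_id = row$library_id,
                               .before = 1L),
         truth = truth)
  })
  structure(
    list(
      manifest = manifest,
      truth = purrr::list_rbind(purrr::map(sims, "truth")),
      reads = purrr::list_rbind(purrr::map(sims, "reads"))
    ),
    class = "benchmark_sim"
  )
}

#' @export
print.benchmark_sim <- function(x, ...) {
  cat(sprintf("<benchmark_sim> %d libraries, %d reads\n",
              nrow(x$manifest), nrow(x$reads)))
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' @param reads read tibble (`read_id`, `seq`).
#' @param path output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(set), seq = unname(as.character(set)))
}

#' Write / read the per-library spike-in truth manifest (TSV)
#'
#' @param truth truth tibble (`library_id`, `locus_id`,
#'   `true_template_molecules`, `true_mutant`).
#' @param path file path.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    library_id = "c", locus_id = "c",
    true_template_molecules = "i", true_mutant = "l"
  ))
}
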