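#' Simulation configuration for synthetic cfDNA libraries
#'
#' Bundles every tunable of the read-level simulator. Defaults reflect the
#' benchtop design the simulator emulates: cell-free DNA fragments of about
#' 165 bp, inline 7-base unique molecular identifiers (UMIs), realistic
#' library-prep and sequencing error processes, and amplicon libraries
#' sequenced to a fixed per-library depth.
#'
#' @param seed integer seed; the same configuration and seed give
#'   byte-identical libraries.
#' @param fragment_len_mean,fragment_len_sd mean and standard deviation (bp)
#'   of the cfDNA fragment length distribution (normal, truncated so every
#'   read still covers its target base and never exceeds the amplicon).
#' @param umi_length number of UMI bases at the start of each read.
#' @param seq_error_rate per-base substitution probability applied
#'   independently to every sequenced base (UMI included).
#' @param prep_error_rate per-base probability of a first-cycle
#'   library-preparation error. A prep error is copied into every read of the
#'   molecule's UMI family, so it survives consensus -- exactly the artifact
#'   class the caller's two-family detection rule exists to reject.
#' @param pcr_cycles nominal number of PCR cycles (bookkeeping only; family
#'   size overdispersion is controlled by `mean_reads_per_molecule`).
#' @param capture_efficiency fraction of input template molecules converted
#'   into sequenced UMI families.
#' @param mean_reads_per_molecule expected sequenced reads per captured
#'   molecule; family sizes are geometric with this mean to mimic PCR
#'   jackpotting.
#' @param background_wt_molecules wild-type cfDNA template molecules per
#'   locus contributed by the plasma background (mutant spike-ins sit on top
#'   of this background; the caller counts but otherwise ignores wild-type
#'   families).
#' @param reads_per_library sequencing depth cap per library; when drawn
#'   family sizes exceed it the family-size vector is thinned
#'   hypergeometrically, emulating a fixed sequencer allocation.
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' sim_config(seed = 1, seq_error_rate = 0)
#' @export
sim_config <- function(seed = 1L,
                       fragment_len_mean = 165,
                       fragment_len_sd = 10,
                       umi_length = 7L,
                       seq_error_rate = 1e-3,
                       prep_error_rate = 1e-4,
                       pcr_cycles = 25L,
                       capture_efficiency = 0.5,
                       mean_reads_per_molecule = 12,
                       background_wt_molecules = 1000L,
                       reads_per_library = 1e5) {
  assert_scalar_number(seq_error_rate, "seq_error_rate", 0, 1)
  assert_scalar_number(prep_error_rate, "prep_error_rate", 0, 1)
  assert_scalar_number(capture_efficiency, "capture_efficiency", 0, 1)
  assert_scalar_number(fragment_len_mean, "fragment_len_mean", 1e-9)
  assert_scalar_number(fragment_len_sd, "fragment_len_sd", 0)
  assert_scalar_number(umi_length, "umi_length", 0)
  assert_scalar_number(mean_reads_per_molecule, "mean_reads_per_molecule", 1)
  assert_scalar_number(background_wt_molecules, "background_wt_molecules", 0)
  assert_scalar_number(reads_per_library, "reads_per_library", 0)
  if (umi_length < 1) {
    # umi_length 0 is tolerated by extract_umi() but the simulator always tags
    warn("umi_length < 1: simulated reads will carry no UMI")
  }
  structure(
    list(
      seed = as.integer(seed),
      fragment_len_mean = fragment_len_mean,
      fragment_len_sd = fragment_len_sd,
      umi_length = as.integer(umi_length),
      seq_error_rate = seq_error_rate,
      prep_error_rate = prep_error_rate,
      pcr_cycles = as.integer(pcr_cycles),
      capture_efficiency = capture_efficiency,
      mean_reads_per_molecule = mean_reads_per_molecule,
      background_wt_molecules = as.integer(background_wt_molecules),
      reads_per_library = reads_per_library
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Spike-in benchmark experimental design
#'
#' Describes the layout of a spike-in benchmarking experiment: known
#' quantities of synthetic mutant ctDNA from each genotype source are spiked
#' into plasma aliquots across log-spaced amounts, in replicate, alongside
#' negative-control aliquots, and every aliquot is taken through independent
#' library preparations. The default reproduces a two-source, six-log
#' (10^1..10^6), duplicate design with four negative controls and two preps
#' per sample: 24 spike-in samples and 56 libraries in total.
#'
#' @param sources character labels for the genotype sources providing the
#'   mutant alleles.
#' @param spike_levels strictly increasing vector of input template molecule
#'   amounts per sample.
#' @param replicates_per_condition spike-in replicates per (source, level).
#' @param negative_controls number of mutant-free control samples.
#' @param preps_per_sample independent library preparations per sample.
#' @param n_alleles number of target alleles carried by each source.
#' @return an object of class `benchmark_design`.
#' @examples
#' d <- benchmark_design()
#' n_spikein_samples(d) # 24
#' n_libraries(d)       # 56
#' @export
benchmark_design <- function(sources = c("PC3-like", "DU145-like"),
                             spike_levels = 10^(1:6),
                             replicates_per_condition = 2L,
                             negative_controls = 4L,
                             preps_per_sample = 2L,
                             n_alleles = 8L) {
  if (length(spike_levels) < 1 || any(diff(spike_levels) <= 0)) {
    abort("`spike_levels` must be strictly increasing")
  }
  if (any(spike_levels < 0)) abort("`spike_levels` must be non-negative")
  structure(
    list(
      sources = as.character(sources),
      spike_levels = as.numeric(spike_levels),
      replicates_per_condition = as.integer(replicates_per_condition),
      negative_controls = as.integer(negative_controls),
      preps_per_sample = as.integer(preps_per_sample),
      n_alleles = as.integer(n_alleles)
    ),
    class = "benchmark_design"
  )
}

#' @rdname benchmark_design
#' @param design a `benchmark_design`.
#' @export
n_spikein_samples <- function(design) {
  length(design$sources) * length(design$spike_levels) *
    design$replicates_per_condition
}

#' @rdname benchmark_design
#' @export
n_libraries <- function(design) {
  (n_spikein_samples(design) + design$negative_controls) *
    design$preps_per_sample
}

#' @export
print.benchmark_design <- function(x, ...) {
  cat("<benchmark_design>\n")
  cat("  sources:   ", paste(x$sources, collapse = ", "), "\n")
  cat("  levels:    ", paste(format(x$spike_levels, scientific = TRUE),
                             collapse = ", "), "\n")
  cat(sprintf("  replicates %d | negatives %d | preps %d | alleles %d\n",
              x$replicates_per_condition, x$negative_controls,
              x$preps_per_sample, x$n_alleles))
  cat(sprintf("  => %d spike-in samples, %d libraries\n",
              n_spikein_samples(x), n_libraries(x)))
  invisible(x)
}

#' UMI caller configuration
#'
#' Thresholds for the consensus caller. The error-rejection rule is:
#' a UMI family votes mutant only when its consensus base equals the
#' expected alternate allele, it holds at least `min_reads` reads, and at
#' least a fraction `min_agreement` of its reads agree with the consensus;
#' a locus is called detected only when at least `min_mutant_families`
#' independent mutant families support it. Library-prep errors create at
#' most isolated mutant families, so requiring two independent UMIs
#' suppresses them while single sequencing errors are removed by the
#' within-family consensus.
#'
#' @param umi_length UMI bases to strip from the read start.
#' @param min_read_length reads shorter than this (UMI included) are
#'   discarded and tallied; default `umi_length + 20`.
#' @param anchor_length length of the locus-assignment anchor k-mer matched
#'   against the read start after UMI removal.
#' @param anchor_max_mismatch maximum mismatches tolerated in the anchor.
#' @param umi_merge_distance maximum Hamming distance for directional UMI
#'   merging (sequencing errors inside the UMI otherwise inflate molecule
#'   counts).
#' @param min_reads minimum family size for a mutant vote.
#' @param min_agreement minimum fraction of family reads supporting the
#'   consensus base, in (0.5, 1].
#' @param min_mutant_families mutant families required to call a locus
#'   detected.
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(umi_length = 7L,
                          min_read_length = umi_length + 20L,
                          anchor_length = 15L,
                          anchor_max_mismatch = 1L,
                          umi_merge_distance = 1L,
                          min_reads = 2L,
                          min_agreement = 0.9,
                          min_mutant_families = 2L) {
  if (min_agreement <= 0.5 || min_agreement > 1) {
    abort("`min_agreement` must lie in (0.5, 1]")
  }
  assert_scalar_number(umi_length, "umi_length", 0)
  assert_scalar_number(min_reads, "min_reads", 1)
  assert_scalar_number(min_mutant_families, "min_mutant_families", 1)
  structure(
    list(
      umi_length = as.integer(umi_length),
      min_read_length = as.integer(min_read_length),
      anchor_length = as.integer(anchor_length),
      anchor_max_mismatch = as.integer(anchor_max_mismatch),
      umi_merge_distance = as.integer(umi_merge_distance),
      min_reads = as.integer(min_reads),
      min_agreement = min_agreement,
      min_mutant_families = as.integer(min_mutant_families)
    ),
    class = "caller_config"
  )
}

#' @export
print.caller_config <- function(x, ...) {
  cat("<caller_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
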