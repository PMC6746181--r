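# hg-like autosome lengths in Mb, used to tile a synthetic binned genome
AUTOSOME_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
                 133, 114, 107, 102, 90, 83, 80, 59, 63, 48, 51)

#' Synthetic binned autosomal genome for ULP-WGS simulation
#'
#' Tiles 22 autosomes (hg-like lengths) into fixed-width bins and assigns
#' each bin a GC fraction drawn once from a smooth profile plus noise under
#' a fixed internal seed, so the genome is a constant property, not a
#' per-simulation draw.
#'
#' @param bin_size bin width in bp (default 1 Mb).
#' @param gc_seed seed for the GC landscape (fixed default keeps the genome
#'   identical across sessions).
#' @return tibble with `chrom`, `start`, `end` (0-based half-open), `gc`.
#' @export
ulp_genome <- function(bin_size = 1e6, gc_seed = 404L) {
  bins <- purrr::list_rbind(purrr::imap(AUTOSOME_MB, function(mb, i) {
    n <- floor(mb * 1e6 / bin_size)
    tibble(chrom = sprintf("chr%d", i),
           start = (seq_len(n) - 1) * bin_size,
           end = seq_len(n) * bin_size)
  }))
  withr::with_seed(gc_seed, {
    wave <- 0.41 + 0.04 * sin(2 * pi * bins$start / 5e7 +
                                as.integer(factor(bins$chrom)))
    bins$gc <- pmin(0.65, pmax(0.25, wave + stats::rnorm(nrow(bins), 0, 0.02)))
  })
  bins
}

#' A prostate-cancer-like SCNA profile
#'
#' Canonical large events of primary/metastatic prostate cancer on the
#' synthetic genome: 8p loss, 8q gain, and losses on 6q, 10q (PTEN), 13q,
#' 16q, 17p and focal 21q (TMPRSS2-ERG region). All events deviate by a
#' single copy so the single-copy-state tumor-content estimator is exact on
#' them.
#'
#' @return tibble with `chrom`, `start`, `end`, `tumor_cn` (copies in the
#'   tumor compartment; diploid elsewhere).
#' @export
prostate_scna_profile <- function() {
  tibble(
    chrom = c("chr8", "chr8", "chr6", "chr10", "chr13", "chr16", "chr17",
              "chr21"),
    start = c(0, 48e6, 65e6, 85e6, 30e6, 45e6, 0, 36e6),
    end = c(43e6, 146e6, 170e6, 135e6, 114e6, 90e6, 20e6, 44e6),
    tumor_cn = c(1, 3, 1, 1, 1, 1, 1, 1)
  )
}

#' Batch-specific recurrent artifact signature
#'
#' Spurious coverage shifts shared by every sample of a collection batch,
#' emulating collection-tube artifacts concentrated on chromosomes 5, 6, 8
#' and 12.
#'
#' @param shift_log2 magnitude of the injected log2 shift.
#' @return tibble with `chrom`, `start`, `end`, `shift_log2`.
#' @export
edta_artifact_profile <- function(shift_log2 = 0.18) {
  tibble(
    chrom = c("chr5", "chr6", "chr8", "chr12"),
    start = c(40e6, 0, 100e6, 50e6),
    end = c(80e6, 30e6, 130e6, 90e6),
    shift_log2 = c(-1, 1, 1, -1) * shift_log2
  )
}

match_intervals <- function(bins, intervals, value_col, default) {
  out <- rep(default, nrow(bins))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  mid <- (bins$start + bins$end) / 2
  for (i in seq_len(nrow(intervals))) {
    hit <- bins$chrom == intervals$chrom[i] & mid >= intervals$start[i] &
      mid < intervals$end[i]
    out[hit] <- intervals[[value_col]][i]
  }
  out
}

#' Simulate ULP-WGS per-bin read counts at a known tumor fraction
#'
#' Draws overdispersed bin counts whose expectation follows the mixture
#' depth ratio `(2 (1 - f) + c f) / 2` for tumor copy number `c` at tumor
#' fraction `f`, multiplied by a GC-bias factor and any batch-artifact
#' shifts. Artifact shifts are injected identically into every sample
#' simulated with the same `batch_artifacts`, creating the recurrent,
#' cohort-shared signal the artifact filter removes.
#'
#' @param tumor_fraction fraction of cfDNA of tumor origin, in \[0, 1\].
#' @param scna_profile tibble (`chrom`, `start`, `end`, `tumor_cn`) of tumor
#'   copy-number events; `NULL` means copy-neutral. Intervals outside the
#'   genome are an error.
#' @param mean_reads_per_bin expected depth per bin in a diploid region
#'   (2000 reads/1 Mb bin is roughly 0.3x coverage at 165 bp fragments).
#' @param gc_bias_params `NULL` for no bias, or `c(slope, curvature)` of a
#'   log-linear GC effect centred on the genome mean GC.
#' @param batch_artifacts `NULL` or a shift tibble such as
#'   [edta_artifact_profile()].
#' @param seed integer seed.
#' @param genome bin tibble from [ulp_genome()].
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson); the default gives ~5% count CV per 1 Mb bin at 2000
#'   reads/bin, typical of ULP-WGS after GC correction.
#' @return `genome` with `tumor_cn`, `raw_count` columns added.
#' @export
simulate_ulp_bins <- function(tumor_fraction,
                              scna_profile = NULL,
                              mean_reads_per_bin = 2000,
                              gc_bias_params = NULL,
                              batch_artifacts = NULL,
                              seed = 1L,
                              genome = ulp_genome(),
                              dispersion = 500) {
  assert_scalar_number(tumor_fraction, "tumor_fraction", 0, 1)
  if (!is.null(scna_profile)) {
    bad <- !scna_profile$chrom %in% genome$chrom
    lens <- dplyr::summarise(dplyr::group_by(genome, .data$chrom),
                             len = max(.data$end), .groups = "drop")
    over <- scna_profile$end >
      lens$len[match(scna_profile$chrom, lens$chrom)] + 1e6
    if (any(bad) | any(over, na.rm = TRUE)) {
      abort("`scna_profile` has intervals outside the simulated genome")
    }
  }
  cn <- match_intervals(genome, scna_profile, "tumor_cn", 2)
  ratio <- (2 * (1 - tumor_fraction) + cn * tumor_fraction) / 2
  gcfac <- rep(1, nrow(genome))
  if (!is.null(gc_bias_params)) {
    d <- genome$gc - mean(genome$gc)
    gcfac <- exp(gc_bias_params[1] * d +
                   (gc_bias_params[2] %||% 0) * d^2)
    gcfac <- gcfac / mean(gcfac)
  }
  shift <- match_intervals(genome, batch_artifacts, "shift_log2", 0)
  mu <- mean_reads_per_bin * ratio * gcfac * 2^shift
  withr::local_seed(seed)
  dplyr::mutate(genome,
                tumor_cn = cn,
                raw_count = stats::rnbinom(nrow(genome), mu = mu,
                                           size = dispersion))
}
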