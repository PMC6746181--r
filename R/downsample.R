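#' Downsample a read library to a fixed total
#'
#' Uniform sampling without replacement, modelling the discarding of reads
#' before any UMI processing. Asking for at least as many reads as exist
#' returns the library unchanged.
#'
#' @param reads read tibble.
#' @param n_total reads to keep (>= 0).
#' @param seed integer seed; identical seeds give identical subsamples.
#' @return the subsampled read tibble (original order preserved).
#' @examples
#' r <- tibble::tibble(read_id = letters[1:5], seq = strrep("A", 30))
#' downsample_reads(r, 2, seed = 1)
#' @export
downsample_reads <- function(reads, n_total, seed = 1L) {
  if (n_total < 0) abort("`n_total` must be >= 0")
  if (n_total >= nrow(reads)) return(reads)
  withr::local_seed(seed)
  keep <- sort(sample.int(nrow(reads), n_total))
  reads[keep, , drop = FALSE]
}

#' Downsample reads independently within each target locus
#'
#' Reads are assigned to loci (with [assign_locus()] semantics when an
#' assignment is not already present) and sampled uniformly without
#' replacement within each locus, up to `n_per_target` reads per locus.
#' Unassigned reads are dropped.
#'
#' @param reads read tibble; either carries a `locus_id` column or raw reads
#'   plus `amplicons`/`config` so assignment can be computed.
#' @param n_per_target reads to keep per locus (>= 0).
#' @param seed integer seed.
#' @param amplicons,config needed only when `reads` lacks `locus_id`:
#'   amplicon design and [caller_config()] used to extract UMIs and assign
#'   loci (the returned reads are then UMI-trimmed with `umi` and
#'   `locus_id` columns).
#' @return subsampled read tibble with a `locus_id` column.
#' @export
downsample_per_target <- function(reads, n_per_target, seed = 1L,
                                  amplicons = NULL,
                                  config = caller_config()) {
  if (n_per_target < 0) abort("`n_per_target` must be >= 0")
  if (!"locus_id" %in% names(reads)) {
    if (is.null(amplicons)) {
      abort("`reads` lacks `locus_id`; supply `amplicons` to assign loci")
    }
    reads <- extract_umi(reads, config$umi_length, config$min_read_length)
    reads <- assign_locus(reads, amplicons, config$anchor_max_mismatch)
  }
  reads <- reads[!is.na(reads$locus_id), , drop = FALSE]
  withr::local_seed(seed)
  parts <- split(seq_len(nrow(reads)), reads$locus_id)
  keep <- sort(unlist(lapply(parts, function(idx) {
    if (length(idx) <= n_per_target) idx
    else idx[sample.int(length(idx), n_per_target)]
  }), use.names = FALSE))
  reads[keep, , drop = FALSE]
}

#' Re-call detection across a grid of sequencing depths
#'
#' Re-runs the full UMI caller after downsampling a library to each depth in
#' the grid, at whole-library or per-target scope, and reports deduplicated
#' mutant counts, binary detection and the fraction of the full-depth
#' deduplicated count retained.
#'
#' @param reads raw read tibble for one library.
#' @param amplicons amplicon design tibble.
#' @param depths numeric vector of depths (reads per library, or reads per
#'   target when `scope = "per_target"`). The full-depth baseline is always
#'   included as depth `Inf`.
#' @param scope `"library"` or `"per_target"`.
#' @param config a [caller_config()].
#' @param seed integer seed for the subsampling.
#' @return tibble of class `depth_scan`: one row per (depth, locus) with
#'   `dedup_mutant_count`, `detected` and `count_retention`.
#' @export
detection_vs_depth <- function(reads, amplicons, depths,
                               scope = c("per_target", "library"),
                               config = caller_config(), seed = 1L) {
  scope <- match.arg(scope)
  if (length(depths) == 0L) abort("`depths` must be non-empty")
  run_at <- function(depth, i) {
    sub <- if (is.infinite(depth)) {
      reads
    } else if (scope == "library") {
      downsample_reads(reads, depth, seed = seed + i)
    } else {
      down <- downsample_per_target(reads, depth, seed = seed + i,
                                    amplicons = amplicons, config = config)
      # reads are already UMI-trimmed and assigned; restore raw layout by
      # re-prepending the UMI so the caller path is identical
      dplyr::mutate(down, seq = paste0(.data$umi, .data$seq),
                    umi = NULL, locus_id = NULL)
    }
    dplyr::mutate(call_loci(sub, amplicons, config), depth = depth,
                  .before = 1L)
  }
  depths <- sort(unique(c(depths, Inf)), decreasing = TRUE)
  out <- purrr::list_rbind(purrr::imap(depths, run_at))
  base <- dplyr::select(out[is.infinite(out$depth), ],
                        "locus_id", full_count = "dedup_mutant_count")
  out <- dplyr::left_join(out, base, by = "locus_id")
  out <- dplyr::mutate(
    out,
    count_retention = ifelse(.data$full_count > 0,
                             .data$dedup_mutant_count / .data$full_count,
                             NA_real_),
    full_count = NULL
  )
  class(out) <- c("depth_scan", class(out))
  out
}

#' Plot detection against sequencing depth
#'
#' @param object a `depth_scan` from [detection_vs_depth()].
#' @param ... unused.
#' @return a ggplot of per-locus deduplicated-count retention across the
#'   depth grid, with detection status marked.
#' @method autoplot depth_scan
#' @export
autoplot.depth_scan <- function(object, ...) {
  df <- object[is.finite(object$depth), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth,
                                   y = .data$count_retention,
                                   group = .data$locus_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$detected)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reads retained", y = "dedup mutant count retention",
                  colour = "detected",
                  title = "Mutant detection under downsampling") +
    ggplot2::theme_minimal()
}
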