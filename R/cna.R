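#' Bin aligned read positions into fixed-width genomic bins
#'
#' @param positions tibble with `chrom` and `pos` (1-based read start).
#' @param genome bin tibble (e.g. [ulp_genome()]); positions on unknown
#'   chromosomes are an error.
#' @return `genome` with a `raw_count` column; total count conserved for
#'   positions inside the binned territory.
#' @export
bin_counts <- function(positions, genome = ulp_genome()) {
  if (nrow(positions) > 0 && !all(positions$chrom %in% genome$chrom)) {
    abort("read positions on chromosomes absent from the genome")
  }
  counts <- integer(nrow(genome))
  if (nrow(positions) > 0) {
    key_g <- split(seq_len(nrow(genome)), genome$chrom)
    for (ch in names(key_g)) {
      idx <- key_g[[ch]]
      p <- positions$pos[positions$chrom == ch]
      if (length(p) == 0) next
      br <- c(genome$start[idx], genome$end[idx[length(idx)]])
      h <- findInterval(p - 1, br, rightmost.closed = FALSE)
      h <- h[h >= 1 & h <= length(idx)]
      tab <- tabulate(h, nbins = length(idx))
      counts[idx] <- counts[idx] + tab
    }
  }
  dplyr::mutate(genome, raw_count = counts)
}

#' GC-normalise binned counts
#'
#' Counts are divided by the median raw count of their GC decile and
#' expressed as log2 ratios against the autosome-wide median of the
#' corrected values. Bins in deciles with zero median coverage are masked
#' (`norm_log2 = NA`).
#'
#' @param bins tibble with `gc` and `raw_count`.
#' @return `bins` with a `norm_log2` column.
#' @export
gc_normalize <- function(bins) {
  decile <- dplyr::ntile(bins$gc, 10)
  med <- tapply(bins$raw_count, decile, stats::median)
  denom <- as.numeric(med[as.character(decile)])
  corrected <- ifelse(denom > 0, bins$raw_count / denom, NA_real_)
  centre <- stats::median(corrected, na.rm = TRUE)
  dplyr::mutate(bins, norm_log2 = ifelse(
    !is.na(corrected) & corrected > 0,
    log2(corrected / centre),
    NA_real_
  ))
}

# Welch t statistics of all admissible split points of x; returns the best
# split index (last bin of the left part) or NULL.
best_split <- function(x, min_bins) {
  n <- length(x)
  if (n < 2 * min_bins) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  s <- min_bins:(n - min_bins)
  n1 <- s
  n2 <- n - s
  m1 <- cs[s] / n1
  m2 <- (cs[n] - cs[s]) / n2
  v1 <- pmax(0, (cs2[s] - n1 * m1^2) / pmax(1, n1 - 1))
  v2 <- pmax(0, ((cs2[n] - cs2[s]) - n2 * m2^2) / pmax(1, n2 - 1))
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- ifelse(se > 0, abs(m1 - m2) / se, 0)
  best <- which.max(t)
  list(split = s[best], dmean = abs(m1[best] - m2[best]), t = t[best])
}

segment_chrom <- function(x, penalty, min_bins) {
  # returns integer vector of segment ids along x, via recursive binary
  # splitting; deterministic
  seg <- rep(1L, length(x))
  stack <- list(c(1L, length(x)))
  next_id <- 1L
  while (length(stack) > 0) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    bs <- best_split(x[rng[1]:rng[2]], min_bins)
    if (is.null(bs) || bs$dmean < penalty) next
    cut <- rng[1] + bs$split - 1L
    next_id <- next_id + 1L
    seg[(cut + 1L):rng[2]] <- next_id
    stack <- c(stack, list(c(rng[1], cut)), list(c(cut + 1L, rng[2])))
  }
  # renumber in genomic order
  match(seg, unique(seg))
}

#' Segment normalised bins into constant-copy regions
#'
#' Recursive binary segmentation per chromosome: each candidate split
#' maximises the Welch two-sample t statistic and is accepted while the
#' resulting mean difference is at least `penalty` log2 units. Masked bins
#' are excluded; segments never span chromosomes. Deterministic.
#'
#' @param bins tibble with `norm_log2` (from [gc_normalize()]).
#' @param penalty minimum |mean difference| (log2) to accept a split.
#' @param min_bins minimum bins per segment.
#' @return segment tibble: `chrom`, `start`, `end`, `n_bins`, `mean_log2`.
#' @export
segment_bins <- function(bins, penalty = 0.05, min_bins = 8L) {
  use <- bins[!is.na(bins$norm_log2), , drop = FALSE]
  parts <- split(use, factor(use$chrom, levels = unique(use$chrom)))
  purrr::list_rbind(purrr::map(parts, function(df) {
    id <- segment_chrom(df$norm_log2, penalty, min_bins)
    dplyr::summarise(
      dplyr::group_by(dplyr::mutate(df, .seg = id), .data$chrom, .data$.seg),
      start = min(.data$start), end = max(.data$end),
      n_bins = dplyr::n(), mean_log2 = mean(.data$norm_log2),
      .groups = "drop"
    ) |> dplyr::select(!".seg")
  }))
}

#' Call copy-number states from segment means
#'
#' @param segments segment tibble from [segment_bins()].
#' @param gain_cut,loss_cut log2 thresholds (defaults +0.1 / -0.1) with
#'   `loss_cut < 0 < gain_cut`.
#' @return `segments` with a `state` column in `{loss, neutral, gain}`.
#' @export
call_states <- function(segments, gain_cut = 0.1, loss_cut = -0.1) {
  if (!(loss_cut < 0 && 0 < gain_cut)) {
    abort("need loss_cut < 0 < gain_cut")
  }
  dplyr::mutate(segments, state = dplyr::case_when(
    .data$mean_log2 <= loss_cut ~ "loss",
    .data$mean_log2 >= gain_cut ~ "gain",
    TRUE ~ "neutral"
  ))
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

# merge contiguous non-neutral segments of one sample into alteration
# intervals (segmentation sometimes splits one shifted region into several
# adjacent segments; recurrence is a property of the whole altered span)
alteration_intervals <- function(segments) {
  alt <- segments[segments$state != "neutral", , drop = FALSE]
  if (nrow(alt) == 0) return(alt[, c("sample_id", "chrom", "start", "end")])
  alt <- dplyr::arrange(alt, .data$sample_id, .data$chrom, .data$start)
  new_run <- c(TRUE, alt$sample_id[-1] != alt$sample_id[-nrow(alt)] |
                 alt$chrom[-1] != alt$chrom[-nrow(alt)] |
                 alt$start[-1] > alt$end[-nrow(alt)])
  alt$run <- cumsum(new_run)
  dplyr::summarise(dplyr::group_by(alt, .data$sample_id, .data$chrom,
                                   .data$run),
                   start = min(.data$start), end = max(.data$end),
                   .groups = "drop")
}

#' Flag recurrent cohort artifacts in called segments
#'
#' Contiguous non-neutral segments of each sample are merged into
#' alteration intervals; an interval is recurrent when intervals with at
#' least 50% reciprocal overlap are present in at least
#' `recurrence_threshold` of the samples of the same collection batch, and
#' every segment inside a recurrent interval is flagged. Real tumor events
#' are private to a sample and survive; collection-tube artifacts recur
#' across the batch and are removed from downstream tumor-content
#' accounting.
#'
#' @param segments cohort segment tibble with `sample_id`, `batch` and
#'   called `state` columns.
#' @param recurrence_threshold fraction of batch samples (self included)
#'   that must share the alteration (default 0.8).
#' @param min_overlap reciprocal overlap fraction (default 0.5).
#' @return `segments` with an `artifact` logical column. Batches with fewer
#'   than 2 samples are an error.
#' @export
flag_artifacts <- function(segments, recurrence_threshold = 0.8,
                           min_overlap = 0.5) {
  if (!all(c("sample_id", "batch", "state") %in% names(segments))) {
    abort("`segments` needs sample_id, batch and state columns")
  }
  batch_sizes <- tapply(segments$sample_id, segments$batch,
                        function(s) length(unique(s)))
  if (any(batch_sizes < 2)) {
    abort("every batch needs >= 2 samples to assess recurrence")
  }
  iv <- alteration_intervals(segments)
  iv$batch <- segments$batch[match(iv$sample_id, segments$sample_id)]
  segments$artifact <- FALSE
  alt <- which(segments$state != "neutral")
  for (i in alt) {
    b <- segments$batch[i]
    n_batch <- batch_sizes[[b]]
    # the merged interval this segment belongs to
    own <- iv[iv$sample_id == segments$sample_id[i] &
                iv$chrom == segments$chrom[i] &
                iv$start <= segments$start[i] &
                iv$end >= segments$end[i], , drop = FALSE][1, ]
    peers <- iv[iv$batch == b & iv$chrom == own$chrom, , drop = FALSE]
    ov <- reciprocal_overlap(own$start, own$end, peers$start, peers$end)
    sharing <- unique(peers$sample_id[ov >= min_overlap])
    if (length(sharing) / n_batch >= recurrence_threshold) {
      segments$artifact[i] <- TRUE
    }
  }
  segments
}

#' Estimate percent tumor content and percent genome altered
#'
#' Inverts segment log2 ratios under a single-copy-change assumption: for a
#' segment of mean log2 ratio `r`, the implied tumor fraction is
#' `2 (1 - 2^r)` for losses and `2 (2^r - 1)` for gains. Percent tumor
#' content (PTC) is the bin-weighted mean of these per-segment estimates
#' over non-artifact altered autosomal segments, clipped to \[0, 1\]; with
#' no qualifying segment PTC is indeterminate (`NA`), mirroring an
#' all-neutral profile. Percent genome altered (PGA) is the fraction of
#' analysed bins in non-artifact altered segments. Reported ploidy is
#' uncorrected: twice the bin-weighted mean depth ratio.
#'
#' @param segments segment tibble with `state` (and optionally `artifact`)
#'   columns, for one sample.
#' @param exclude_chroms chromosomes excluded from PTC/PGA (sex chromosomes
#'   by default).
#' @return object of class `cna_profile`: list with `segments`, `ptc`
#'   (`NA` when indeterminate), `pga`, `ploidy_uncorrected`, `n_bins`.
#' @export
estimate_ptc <- function(segments,
                         exclude_chroms = c("chrX", "chrY", "X", "Y")) {
  if (!"state" %in% names(segments)) {
    abort("call_states() must be applied before estimate_ptc()")
  }
  if (!"artifact" %in% names(segments)) segments$artifact <- FALSE
  auto <- segments[!segments$chrom %in% exclude_chroms, , drop = FALSE]
  qual <- auto[auto$state != "neutral" & !auto$artifact, , drop = FALSE]
  f_hat <- function(r, state) {
    ifelse(state == "loss", 2 * (1 - 2^r), 2 * (2^r - 1))
  }
  ptc <- if (nrow(qual) == 0) {
    NA_real_
  } else {
    est <- pmin(1, pmax(0, f_hat(qual$mean_log2, qual$state)))
    stats::weighted.mean(est, qual$n_bins)
  }
  total_bins <- sum(auto$n_bins)
  structure(
    list(
      segments = segments,
      ptc = ptc,
      pga = if (total_bins > 0) sum(qual$n_bins) / total_bins else 0,
      ploidy_uncorrected = 2 *
        stats::weighted.mean(2^auto$mean_log2, auto$n_bins),
      n_bins = total_bins
    ),
    class = "cna_profile"
  )
}

#' @export
print.cna_profile <- function(x, ...) {
  ptc <- if (is.na(x$ptc)) "indeterminate" else sprintf("%.1f%%", 100 * x$ptc)
  cat(sprintf("<cna_profile> PTC %s | PGA %.1f%% | ploidy %.2f | %d segments\n",
              ptc, 100 * x$pga, x$ploidy_uncorrected, nrow(x$segments)))
  invisible(x)
}

#' One-call ULP-WGS profiling of a bin-count table
#'
#' Convenience pipeline: [gc_normalize()] then [segment_bins()],
#' [call_states()] and [estimate_ptc()].
#'
#' @param bins bin tibble with `gc` and `raw_count`.
#' @param penalty,min_bins segmentation controls.
#' @param gain_cut,loss_cut state thresholds.
#' @return a `cna_profile`.
#' @export
profile_cna <- function(bins, penalty = 0.05, min_bins = 8L,
                        gain_cut = 0.1, loss_cut = -0.1) {
  bins |>
    gc_normalize() |>
    segment_bins(penalty = penalty, min_bins = min_bins) |>
    call_states(gain_cut = gain_cut, loss_cut = loss_cut) |>
    estimate_ptc()
}

#' @rdname estimate_ptc
#' @param x,object a `cna_profile`.
#' @param ... unused.
#' @method tidy cna_profile
#' @export
tidy.cna_profile <- function(x, ...) as_tibble(x$segments)

#' @rdname estimate_ptc
#' @method glance cna_profile
#' @export
glance.cna_profile <- function(x, ...) {
  tibble(ptc = x$ptc,
         ptc_indeterminate = is.na(x$ptc),
         pga = x$pga,
         ploidy_uncorrected = x$ploidy_uncorrected,
         n_segments = nrow(x$segments),
         n_bins = x$n_bins)
}

#' Plot a copy-number profile across the genome
#'
#' @param object a `cna_profile`.
#' @param bins optional normalised bin tibble to show behind the segments.
#' @param ... unused.
#' @return a ggplot of segment means (coloured by state, artifacts hollow)
#'   along the concatenated genome.
#' @method autoplot cna_profile
#' @export
autoplot.cna_profile <- function(object, bins = NULL, ...) {
  seg <- object$segments
  chroms <- unique(seg$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(seg$end[seg$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  seg$x0 <- seg$start + offs[seg$chrom]
  seg$x1 <- seg$end + offs[seg$chrom]
  p <- ggplot2::ggplot(seg)
  if (!is.null(bins)) {
    b <- bins[!is.na(bins$norm_log2) & bins$chrom %in% chroms, , drop = FALSE]
    b$x <- (b$start + b$end) / 2 + offs[b$chrom]
    p <- p + ggplot2::geom_point(data = b,
                                 ggplot2::aes(x = .data$x,
                                              y = .data$norm_log2),
                                 size = 0.2, colour = "grey70")
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$mean_log2,
                   yend = .data$mean_log2, colour = .data$state,
                   linetype = .data$artifact),
      linewidth = 1.2) +
    ggplot2::geom_vline(xintercept = unname(offs), colour = "grey85",
                        linewidth = 0.2) +
    ggplot2::scale_colour_manual(values = c(loss = "steelblue",
                                            neutral = "grey40",
                                            gain = "firebrick")) +
    ggplot2::labs(x = "genome position", y = "log2 depth ratio",
                  title = sprintf("SCNA profile (PTC %s, PGA %.1f%%)",
                                  ifelse(is.na(object$ptc), "indeterminate",
                                         sprintf("%.1f%%", 100 * object$ptc)),
                                  100 * object$pga)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Write segments in SEG format
#'
#' @param segments segment tibble.
#' @param path output path.
#' @param sample_id sample label for the SEG first column.
#' @export
write_seg <- function(segments, path, sample_id = "sample") {
  seg <- tibble(
    Sample = sample_id,
    Chromosome = segments$chrom,
    Start = segments$start,
    End = segments$end,
    Num_Probes = segments$n_bins,
    Segment_Mean = segments$mean_log2
  )
  readr::write_tsv(seg, path)
  invisible(path)
}

#' Write / read a bin-count table (TSV: chrom, start, end, gc, count)
#'
#' @param bins bin tibble with `gc` and `raw_count`.
#' @param path file path.
#' @export
write_bins_tsv <- function(bins, path) {
  readr::write_tsv(
    dplyr::select(bins, "chrom", "start", "end", "gc", count = "raw_count"),
    path)
  invisible(path)
}

#' @rdname write_bins_tsv
#' @export
read_bins_tsv <- function(path) {
  dplyr::rename(
    readr::read_tsv(path, col_types = "ciidi"),
    raw_count = "count")
}
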