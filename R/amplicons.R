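max_homopolymer_run <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

#' Design short amplicons around selected target alleles
#'
#' Places one amplicon window per target so that ctDNA fragments (~165 bp)
#' can still template it: amplicons are at most `max_amplicon_len` bp
#' (default 139), contain their target base with at least `flank` bp on each
#' side where the locus permits, and start with a unique `anchor_length`-mer
#' used downstream for alignment-free locus assignment. Anchors containing a
#' homopolymer run of 8 or more bases force a window shift; targets too close
#' to a contig end to host any valid window are reported as failures.
#'
#' @param reference a `target_reference` or its `reference` tibble.
#' @param targets allele tibble (`locus_id`, `pos`, `ref`, `alt`, ...).
#' @param max_amplicon_len maximum amplicon length in bp (>= 60).
#' @param flank desired flank on each side of the target base.
#' @param anchor_length anchor k-mer length at the amplicon 5' end.
#' @return tibble with one row per successful design: `locus_id`, `chrom`,
#'   `start` (0-based), `end` (half-open), `length`, `target_offset`
#'   (1-based position of the target inside the amplicon), `ref`, `alt`,
#'   `anchor`, `amplicon_seq`. Failed targets are dropped with a warning and
#'   listed in `attr(, "failures")`.
#' @examples
#' ref <- make_reference(4, 400, seed = 2)
#' design_amplicons(ref, ref$alleles)
#' @export
design_amplicons <- function(reference, targets,
                             max_amplicon_len = 139L,
                             flank = 20L,
                             anchor_length = 15L) {
  if (max_amplicon_len < 60) abort("`max_amplicon_len` must be >= 60")
  if (inherits(reference, "target_reference")) reference <- reference$reference
  seq_of <- stats::setNames(reference$seq, reference$locus_id)
  len_of <- stats::setNames(nchar(reference$seq), reference$locus_id)

  design_one <- function(locus_id, pos, used_anchors) {
    s <- seq_of[[locus_id]]
    L <- min(max_amplicon_len, len_of[[locus_id]])
    # candidate starts (0-based), centred first then shifted outwards
    centre <- max(0L, min(pos - 1L - (L %/% 2L), len_of[[locus_id]] - L))
    shifts <- c(0L, as.vector(rbind(seq_len(L), -seq_len(L))))
    for (d in shifts) {
      start <- centre + d
      end <- start + L
      if (start < 0L || end > len_of[[locus_id]]) next
      left <- pos - 1L - start
      right <- end - pos
      want_left <- min(flank, pos - 1L)
      want_right <- min(flank, len_of[[locus_id]] - pos)
      if (left < max(5L, want_left) || right < max(5L, want_right)) next
      amp <- substr(s, start + 1L, end)
      anchor <- substr(amp, 1L, anchor_length)
      if (max_homopolymer_run(anchor) >= 8L) next
      if (anchor %in% used_anchors) next
      return(list(start = start, end = end, anchor = anchor, amp = amp,
                  target_offset = pos - start))
    }
    NULL
  }

  rows <- vector("list", nrow(targets))
  failures <- character(0)
  used <- character(0)
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    d <- design_one(t$locus_id, t$pos, used)
    if (is.null(d)) {
      failures <- c(failures, t$locus_id)
      next
    }
    used <- c(used, d$anchor)
    rows[[i]] <- tibble(
      locus_id = t$locus_id,
      chrom = t$locus_id,
      start = d$start, end = d$end,
      length = d$end - d$start,
      target_offset = d$target_offset,
      ref = t$ref, alt = t$alt,
      anchor = d$anchor,
      amplicon_seq = d$amp
    )
  }
  out <- dplyr::bind_rows(rows)
  if (length(failures) > 0) {
    warn(sprintf("amplicon design failed for %d target(s): %s",
                 length(failures), paste(failures, collapse = ", ")))
  }
  attr(out, "failures") <- failures
  out
}

#' Write amplicon intervals as BED (0-based half-open)
#'
#' @param amplicons design tibble from [design_amplicons()].
#' @param path output file.
#' @export
write_amplicons_bed <- function(amplicons, path) {
  readr::write_tsv(
    dplyr::transmute(amplicons, chrom = .data$chrom, start = .data$start,
                     end = .data$end, name = .data$locus_id),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_amplicons_bed
#' @export
read_amplicons_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                  col_types = "ciic")
}
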