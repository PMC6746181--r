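#' Extract inline UMIs from read starts
#'
#' The first `umi_length` bases of every read are split off as the UMI and
#' the remainder is kept as the template-derived sequence. Reads shorter
#' than `min_read_length` carry too little template to assign and are
#' discarded (the count is kept in `attr(, "n_discarded")`).
#'
#' @param reads tibble with `read_id` and `seq`.
#' @param umi_length UMI bases at the read start (0 keeps the whole read and
#'   assigns an empty UMI).
#' @param min_read_length minimum usable total read length; default
#'   `umi_length + 20`.
#' @return the read tibble with new `umi` column and `seq` trimmed;
#'   discarded reads removed.
#' @examples
#' extract_umi(tibble::tibble(read_id = "r1",
#'                            seq = "ACGTACGTTTTTTTTTTTTTTTTTTTTTTT"), 7)
#' @export
extract_umi <- function(reads, umi_length = 7L,
                        min_read_length = umi_length + 20L) {
  keep <- nchar(reads$seq) >= min_read_length
  out <- reads[keep, , drop = FALSE]
  out <- dplyr::mutate(
    out,
    umi = substr(.data$seq, 1L, umi_length),
    seq = substr(.data$seq, umi_length + 1L, nchar(.data$seq))
  )
  attr(out, "n_discarded") <- sum(!keep)
  out
}

anchor_mismatches <- function(prefixes, anchor) {
  # vectorised Hamming distance between equal-length prefixes and one anchor
  k <- nchar(anchor)
  a <- strsplit(anchor, "", fixed = TRUE)[[1L]]
  m <- matrix(unlist(strsplit(prefixes, "", fixed = TRUE), use.names = FALSE),
              nrow = k)
  colSums(m != a)
}

#' Assign reads to amplicon loci by anchor k-mer matching
#'
#' Alignment-free locus assignment: a read belongs to the unique amplicon
#' whose primer-proximal anchor (first `anchor_length` bases of the
#' amplicon) matches the read start with at most `max_mismatch`
#' mismatches. Ambiguous or unmatched reads get `NA`. Designs sharing an
#' identical anchor are rejected up front.
#'
#' @param reads tibble of UMI-trimmed reads (from [extract_umi()]).
#' @param amplicons amplicon design tibble with `locus_id` and `anchor`.
#' @param max_mismatch anchor mismatches tolerated (default 1).
#' @return the read tibble with a `locus_id` column (`NA` = unassigned).
#' @export
assign_locus <- function(reads, amplicons, max_mismatch = 1L) {
  if (nrow(amplicons) == 0L) abort("amplicon design is empty")
  if (anyDuplicated(amplicons$anchor)) {
    abort("two amplicon designs share an identical anchor k-mer")
  }
  k <- nchar(amplicons$anchor[1L])
  if (nrow(reads) == 0L) {
    return(dplyr::mutate(reads, locus_id = character(0)))
  }
  prefix <- substr(reads$seq, 1L, k)
  ok_len <- nchar(prefix) == k
  upre <- unique(prefix[ok_len])
  # exact matches dominate; only score the rest against every anchor
  exact <- match(upre, amplicons$anchor)
  assigned <- amplicons$locus_id[exact]
  todo <- which(is.na(exact))
  if (length(todo) > 0L) {
    mm <- vapply(amplicons$anchor,
                 function(a) anchor_mismatches(upre[todo], a),
                 numeric(length(todo)))
    mm <- matrix(mm, nrow = length(todo))
    hits <- mm <= max_mismatch
    n_hits <- rowSums(hits)
    best <- apply(mm, 1L, which.min)
    assigned[todo] <- ifelse(n_hits == 1L, amplicons$locus_id[best],
                             NA_character_)
  }
  locus <- rep(NA_character_, nrow(reads))
  locus[ok_len] <- assigned[match(prefix[ok_len], upre)]
  dplyr::mutate(reads, locus_id = locus)
}

# Union-find over qualifying UMI pairs. Returns, for each unique UMI, the
# representative UMI of its family (the highest-count member, ties broken
# lexicographically).
group_umis <- function(umis, counts, max_dist = 1L) {
  n <- length(umis)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  link <- function(i, j) {
    a <- min(counts[i], counts[j]); b <- max(counts[i], counts[j])
    if (b >= 2 * a - 1) union(i, j)
  }
  if (max_dist == 1L) {
    L <- nchar(umis[1L])
    # all Hamming-1 neighbours, vectorised: 3L variants per UMI
    for (p in seq_len(L)) {
      pre <- substr(umis, 1L, p - 1L)
      suf <- substr(umis, p + 1L, L)
      cur <- substr(umis, p, p)
      for (b in DNA_BASES) {
        hit <- which(cur != b)
        if (length(hit) == 0L) next
        j <- match(paste0(pre[hit], b, suf[hit]), umis)
        found <- which(!is.na(j) & j > hit)
        for (k in found) link(hit[k], j[k])
      }
    }
  } else if (max_dist > 1L) {
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (hamming_dist(umis[i], umis[j]) <= max_dist) link(i, j)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  rep_of <- vapply(split(seq_len(n), root), function(members) {
    m <- members[order(-counts[members], umis[members])]
    umis[m[1L]]
  }, character(1))
  unname(rep_of[as.character(root)])
}

#' Group reads into UMI families with directional merging
#'
#' Reads are first grouped by exact UMI; UMIs within Hamming distance
#' `umi_merge_distance` are then merged when the directional rule holds
#' (a UMI seen `a` times is absorbed by one seen `b` times when
#' `b >= 2a - 1`), which removes families manufactured by sequencing errors
#' inside the UMI itself. Merging is per locus when a `locus_id` column is
#' present.
#'
#' @param reads tibble with `umi` (and optionally `locus_id`) columns.
#' @param umi_merge_distance maximum Hamming distance for merging
#'   (0 disables merging).
#' @return the read tibble with a `family_umi` column naming each read's
#'   family representative.
#' @export
group_families <- function(reads, umi_merge_distance = 1L) {
  if (nrow(reads) == 0L) {
    return(dplyr::mutate(reads, family_umi = character(0)))
  }
  has_locus <- "locus_id" %in% names(reads)
  group_one <- function(df) {
    tab <- dplyr::count(df, .data$umi)
    rep_of <- group_umis(tab$umi, tab$n, max_dist = umi_merge_distance)
    df$family_umi <- rep_of[match(df$umi, tab$umi)]
    df
  }
  if (has_locus) {
    parts <- split(reads, reads$locus_id, drop = TRUE)
    out <- purrr::list_rbind(purrr::map(parts, group_one))
    # reads with NA locus keep NA family
    na_part <- reads[is.na(reads$locus_id), , drop = FALSE]
    if (nrow(na_part) > 0L) {
      na_part$family_umi <- NA_character_
      out <- dplyr::bind_rows(out, na_part)
    }
    out
  } else {
    group_one(reads)
  }
}

#' Per-family consensus at the target base
#'
#' For every UMI family at a locus, takes the majority base among its reads
#' at the target position (ties are ambiguous and never mutant) and applies
#' the mutant filters: consensus equal to the expected alternate allele,
#' family size at least `min_reads`, and agreement at least
#' `min_agreement`.
#'
#' @param reads tibble with `locus_id`, `family_umi`, `seq` (UMI-trimmed,
#'   starting at the amplicon 5' end).
#' @param amplicons amplicon design tibble (`locus_id`, `target_offset`,
#'   `ref`, `alt`).
#' @param min_reads minimum family size for a mutant vote.
#' @param min_agreement minimum consensus agreement fraction, in (0.5, 1].
#' @return tibble with one row per family: `locus_id`, `umi`, `read_count`,
#'   `consensus_base` (`"N"` when tied), `agreement_fraction`, `is_mutant`.
#' @export
consensus_families <- function(reads, amplicons, min_reads = 2L,
                               min_agreement = 0.9) {
  if (min_agreement <= 0.5 || min_agreement > 1) {
    abort("`min_agreement` must lie in (0.5, 1]")
  }
  reads <- reads[!is.na(reads$locus_id) & !is.na(reads$family_umi), ,
                 drop = FALSE]
  if (nrow(reads) == 0L) {
    return(tibble(locus_id = character(0), umi = character(0),
                  read_count = integer(0), consensus_base = character(0),
                  agreement_fraction = numeric(0), is_mutant = logical(0)))
  }
  off <- amplicons$target_offset[match(reads$locus_id, amplicons$locus_id)]
  base <- substr(reads$seq, off, off)
  df <- tibble(locus_id = reads$locus_id, umi = reads$family_umi,
               base = base)
  fam <- dplyr::count(df, .data$locus_id, .data$umi, name = "read_count")
  # per-family base tallies, sorted so each family's top vote comes first
  vc <- dplyr::count(df[df$base %in% DNA_BASES, , drop = FALSE],
                     .data$locus_id, .data$umi, .data$base)
  vc <- dplyr::arrange(vc, .data$locus_id, .data$umi, dplyr::desc(.data$n),
                       .data$base)
  grp <- paste(vc$locus_id, vc$umi, sep = "\r")
  idx_first <- which(!duplicated(grp))
  nxt <- pmin(idx_first + 1L, nrow(vc))
  tied <- grp[nxt] == grp[idx_first] & vc$n[nxt] == vc$n[idx_first] &
    nxt > idx_first
  top <- tibble(locus_id = vc$locus_id[idx_first],
                umi = vc$umi[idx_first],
                consensus_base = ifelse(tied, "N", vc$base[idx_first]),
                support = vc$n[idx_first])
  fam <- dplyr::left_join(fam, top, by = c("locus_id", "umi"))
  fam <- dplyr::mutate(
    fam,
    consensus_base = dplyr::coalesce(.data$consensus_base, "N"),
    agreement_fraction = dplyr::coalesce(.data$support, 0L) /
      .data$read_count,
    support = NULL
  )
  alt <- amplicons$alt[match(fam$locus_id, amplicons$locus_id)]
  dplyr::mutate(
    fam,
    is_mutant = .data$consensus_base == alt &
      .data$read_count >= min_reads &
      .data$agreement_fraction >= min_agreement
  )
}

#' Count deduplicated mutant families and call locus-level detection
#'
#' The deduplicated mutant count of a locus is its number of mutant UMI
#' families; a locus is called detected when that count reaches
#' `min_mutant_families`. Wild-type families are counted but otherwise
#' ignored, mirroring an analysis that tracks only the mutant allele.
#'
#' @param families family tibble from [consensus_families()].
#' @param amplicons amplicon design tibble (defines the loci reported).
#' @param min_mutant_families detection threshold (default 2).
#' @return a locus call report: one row per amplicon locus with
#'   `total_families`, `mutant_families`, `dedup_mutant_count`,
#'   `wildtype_ignored` and `detected`.
#' @export
count_and_detect <- function(families, amplicons, min_mutant_families = 2L) {
  per_locus <- dplyr::summarise(
    dplyr::group_by(families, .data$locus_id),
    total_families = dplyr::n(),
    mutant_families = sum(.data$is_mutant),
    assigned_reads = sum(.data$read_count),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble(locus_id = amplicons$locus_id), per_locus,
                          by = "locus_id")
  out <- tidyr::replace_na(out, list(total_families = 0L,
                                     mutant_families = 0L,
                                     assigned_reads = 0L))
  dplyr::mutate(
    out,
    dedup_mutant_count = .data$mutant_families,
    wildtype_ignored = TRUE,
    detected = .data$mutant_families >= min_mutant_families
  )
}

#' Call mutant ctDNA alleles from raw amplicon reads
#'
#' End-to-end single-molecule caller: UMI extraction, anchor-based locus
#' assignment, directional UMI family grouping, per-family consensus with
#' error filters, and per-locus deduplicated mutant counting with binary
#' detection.
#'
#' @param reads raw read tibble (`read_id`, `seq`) as written to FASTQ.
#' @param amplicons amplicon design tibble from [design_amplicons()].
#' @param config a [caller_config()].
#' @param keep_families return the per-family table in
#'   `attr(, "families")` for debugging.
#' @return locus call report tibble: one row per locus with `total_reads`,
#'   `assigned_reads`, `total_families`, `mutant_families`,
#'   `dedup_mutant_count`, `wildtype_ignored`, `detected`.
#' @examples
#' ref <- make_reference(2, 300, seed = 1)
#' amp <- design_amplicons(ref, ref$alleles)
#' cfg <- sim_config(seed = 1, background_wt_molecules = 50)
#' reads <- simulate_library(amp, molecules = 40, cfg = cfg)
#' call_loci(reads, amp)
#' @export
call_loci <- function(reads, amplicons, config = caller_config(),
                      keep_families = FALSE) {
  total_reads <- nrow(reads)
  reads <- extract_umi(reads, config$umi_length, config$min_read_length)
  reads <- assign_locus(reads, amplicons, config$anchor_max_mismatch)
  reads <- group_families(reads, config$umi_merge_distance)
  fams <- consensus_families(reads, amplicons, config$min_reads,
                             config$min_agreement)
  report <- count_and_detect(fams, amplicons, config$min_mutant_families)
  report <- dplyr::mutate(report, total_reads = total_reads, .before = 2L)
  if (keep_families) attr(report, "families") <- fams
  report
}

#' Run the caller over every library of a multi-library read set
#'
#' @param reads read tibble with a `library_id` column (for example
#'   `simulate_benchmark()$reads`).
#' @inheritParams call_loci
#' @return combined locus call report with a `library_id` column.
#' @export
call_libraries <- function(reads, amplicons, config = caller_config()) {
  parts <- split(reads, reads$library_id)
  purrr::list_rbind(purrr::imap(parts, function(df, lib) {
    dplyr::mutate(call_loci(df, amplicons, config), library_id = lib,
                  .before = 1L)
  }))
}

#' Write / read a locus call report
#'
#' @param report report tibble from [call_loci()].
#' @param path output path; `write_report_json()` serialises with
#'   [jsonlite::write_json()].
#' @export
write_report_tsv <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
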