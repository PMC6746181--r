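# Multivariate hypergeometric thinning of integer family sizes to a fixed
# total: equivalent to sampling `target` reads without replacement from the
# pooled reads of all families.
mhyper_thin <- function(sizes, target) {
  total <- sum(sizes)
  if (total <= target) return(sizes)
  out <- integer(length(sizes))
  remaining <- total
  left <- target
  for (i in seq_along(sizes)) {
    if (left == 0L) break
    k <- stats::rhyper(1L, sizes[i], remaining - sizes[i], left)
    out[i] <- k
    left <- left - k
    remaining <- remaining - sizes[i]
  }
  out
}

#' Simulate one amplicon sequencing library with inline UMIs
#'
#' Generates single-end FASTQ-style reads for one library. Each input
#' template molecule (spiked mutant or wild-type plasma background) is
#' captured with probability `cfg$capture_efficiency`, receives a UMI drawn
#' uniformly from the `4^umi_length` possibilities, and is sequenced into a
#' geometric number of reads (mean `cfg$mean_reads_per_molecule`, total
#' capped at `cfg$reads_per_library`). Library-preparation errors are
#' applied once per molecule and shared by its whole UMI family; sequencing
#' errors are applied independently to every base of every read, UMI
#' included. Reads carry the UMI as their first `umi_length` bases and also
#' record it in the read name after the last colon.
#'
#' @param amplicons amplicon design tibble from [design_amplicons()].
#' @param molecules mutant template molecules: a single total (split evenly
#'   across amplicon loci, remainder to the first loci) or a vector named by
#'   `locus_id`.
#' @param cfg a [sim_config()].
#' @param library_id label used in read names.
#' @param seed seed for this library; defaults to `cfg$seed`.
#' @return tibble with `read_id`, `seq`, plus simulation truth columns
#'   `true_locus` and `true_mutant_template` (ignored by the caller).
#' @examples
#' ref <- make_reference(2, 300, seed = 1)
#' amp <- design_amplicons(ref, ref$alleles)
#' cfg <- sim_config(seed = 1, background_wt_molecules = 20)
#' simulate_library(amp, molecules = 10, cfg = cfg)
#' @export
simulate_library <- function(amplicons, molecules, cfg = sim_config(),
                             library_id = "lib", seed = cfg$seed) {
  if (any(molecules < 0)) abort("`molecules` must be >= 0")
  if (length(molecules) == 1L && is.null(names(molecules))) {
    molecules <- split_molecules(molecules, amplicons$locus_id)
  }
  unknown <- setdiff(names(molecules), amplicons$locus_id)
  if (length(unknown) > 0) {
    abort(paste0("`molecules` names not in amplicon design: ",
                 paste(unknown, collapse = ", ")))
  }
  withr::local_seed(seed)

  per_locus <- lapply(seq_len(nrow(amplicons)), function(i) {
    a <- amplicons[i, ]
    n_mut <- as.integer(molecules[a$locus_id] %||% 0L)
    if (is.na(n_mut)) n_mut <- 0L
    n_wt <- cfg$background_wt_molecules
    tpl_wt <- a$amplicon_seq
    tpl_mut <- tpl_wt
    substr(tpl_mut, a$target_offset, a$target_offset) <- a$alt
    n_cap_mut <- stats::rbinom(1L, n_mut, cfg$capture_efficiency)
    n_cap_wt <- stats::rbinom(1L, n_wt, cfg$capture_efficiency)
    n_cap <- n_cap_mut + n_cap_wt
    if (n_cap == 0L) return(NULL)
    list(
      locus_id = a$locus_id,
      target_offset = a$target_offset,
      amp_len = a$length,
      template = c(rep(tpl_mut, n_cap_mut), rep(tpl_wt, n_cap_wt)),
      is_mutant = rep(c(TRUE, FALSE), c(n_cap_mut, n_cap_wt))
    )
  })
  per_locus <- per_locus[!vapply(per_locus, is.null, logical(1))]
  if (length(per_locus) == 0L) {
    return(tibble(read_id = character(0), seq = character(0),
                  true_locus = character(0),
                  true_mutant_template = logical(0)))
  }

  n_molecules <- sum(vapply(per_locus, function(x) length(x$template),
                            integer(1)))
  # per-molecule attributes, all loci pooled
  template <- unlist(lapply(per_locus, `[[`, "template"), use.names = FALSE)
  is_mut <- unlist(lapply(per_locus, `[[`, "is_mutant"), use.names = FALSE)
  locus <- rep(vapply(per_locus, `[[`, character(1), "locus_id"),
               vapply(per_locus, function(x) length(x$template), integer(1)))
  offset <- rep(vapply(per_locus, `[[`, numeric(1), "target_offset"),
                vapply(per_locus, function(x) length(x$template), integer(1)))
  amp_len <- rep(vapply(per_locus, `[[`, numeric(1), "amp_len"),
                 vapply(per_locus, function(x) length(x$template), integer(1)))

  # library-prep (first-cycle) errors: whole family inherits them
  if (cfg$prep_error_rate > 0) {
    template <- apply_substitution_errors(template, cfg$prep_error_rate)
  }
  umi <- if (cfg$umi_length > 0) {
    random_dna(n_molecules, cfg$umi_length)
  } else {
    rep("", n_molecules)
  }
  sizes <- stats::rgeom(n_molecules, 1 / cfg$mean_reads_per_molecule) + 1L
  sizes <- mhyper_thin(sizes, cfg$reads_per_library)
  keep <- sizes > 0L
  if (!any(keep)) {
    return(tibble(read_id = character(0), seq = character(0),
                  true_locus = character(0),
                  true_mutant_template = logical(0)))
  }

  mol_idx <- rep(which(keep), sizes[keep])
  n_reads <- length(mol_idx)
  frag <- round(stats::rnorm(n_reads, cfg$fragment_len_mean,
                             cfg$fragment_len_sd))
  lo <- pmax(offset[mol_idx], 20)
  frag <- pmin(pmax(frag, lo), amp_len[mol_idx])
  insert <- substr(template[mol_idx], 1L, frag)
  reads <- paste0(umi[mol_idx], insert)
  reads <- apply_substitution_errors(reads, cfg$seq_error_rate)
  read_no <- stats::ave(mol_idx, mol_idx, FUN = seq_along)
  tibble(
    read_id = sprintf("%s:m%06d:r%03d:%s", library_id, mol_idx, read_no,
                      umi[mol_idx]),
    seq = reads,
    true_locus = locus[mol_idx],
    true_mutant_template = is_mut[mol_idx]
  )
}

#' Deterministically split a spike amount across target loci
#'
#' The designed spike level of a library is the total number of mutant
#' template molecules across its loci; the even split (remainder to the
#' first loci) conserves that total exactly.
#'
#' @param total total molecules.
#' @param locus_ids character vector of loci.
#' @return named integer vector summing to `total`.
#' @export
split_molecules <- function(total, locus_ids) {
  n <- length(locus_ids)
  base <- total %/% n
  rem <- total %% n
  stats::setNames(as.integer(base + (seq_len(n) <= rem)), locus_ids)
}
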