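#' Generate a synthetic target reference with defined somatic alleles
#'
#' Builds a set of independent reference loci (each its own contig) of
#' random sequence, and places one patient-specific somatic SNV on each:
#' the target allele the bespoke assay is meant to resequence from plasma.
#' Target positions keep at least 70 bp of flanking sequence so a short
#' amplicon can always be designed around them.
#'
#' @param n_loci number of target loci (>= 1).
#' @param locus_length_bp length of every locus contig; must be at least
#'   200 bp so the locus can host an amplicon with flanks.
#' @param seed integer seed; identical calls are byte-identical.
#' @return a list of class `target_reference` with elements
#'   * `reference`: tibble with `locus_id`, `length`, `seq`;
#'   * `alleles`: tibble with `locus_id`, `chrom`, `pos` (1-based), `ref`,
#'     `alt`, `clonality` (defaults to `"unknown"`).
#' @examples
#' ref <- make_reference(n_loci = 2, locus_length_bp = 300, seed = 1)
#' ref$alleles
#' @export
make_reference <- function(n_loci = 8L, locus_length_bp = 400L, seed = 1L) {
  if (n_loci < 1) abort("`n_loci` must be >= 1")
  if (locus_length_bp < 200) {
    abort("`locus_length_bp` must be >= 200 to host an amplicon with flanks")
  }
  withr::local_seed(seed)
  locus_id <- sprintf("locus_%02d", seq_len(n_loci))
  seqs <- random_dna(n_loci, locus_length_bp)
  flank <- 70L
  pos <- flank + sample.int(locus_length_bp - 2L * flank, n_loci,
                            replace = TRUE)
  ref_base <- substr(seqs, pos, pos)
  alt_base <- vapply(ref_base,
                     function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
  structure(
    list(
      reference = tibble(locus_id = locus_id,
                         length = as.integer(locus_length_bp),
                         seq = seqs),
      alleles = tibble(locus_id = locus_id,
                       chrom = locus_id,
                       pos = as.integer(pos),
                       ref = ref_base,
                       alt = alt_base,
                       clonality = "unknown")
    ),
    class = "target_reference"
  )
}

#' @export
print.target_reference <- function(x, ...) {
  cat(sprintf("<target_reference> %d loci of %d bp\n",
              nrow(x$reference), x$reference$length[1]))
  print(x$alleles, ...)
  invisible(x)
}

#' Write and read reference loci as FASTA
#'
#' @param reference the `reference` tibble of [make_reference()] (or the
#'   `target_reference` object itself).
#' @param path output FASTA path.
#' @return `write_reference_fasta()` returns `path` invisibly;
#'   `read_reference_fasta()` returns a reference tibble.
#' @export
write_reference_fasta <- function(reference, path) {
  if (inherits(reference, "target_reference")) reference <- reference$reference
  set <- Biostrings::DNAStringSet(reference$seq)
  names(set) <- reference$locus_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble(locus_id = names(set),
         length = Biostrings::width(set),
         seq = unname(as.character(set)))
}
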