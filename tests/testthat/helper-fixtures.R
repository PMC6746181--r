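# Shared fixtures: everything is generated in code at test time.

fixture_panel <- function(n_loci = 4, seed = 42) {
  ref <- make_reference(n_loci, 400, seed = seed)
  list(ref = ref, amp = design_amplicons(ref, ref$alleles))
}

# Hand-built reads copied from an amplicon template (no simulator involved),
# so caller unit tests control every base.
reads_from_template <- function(amp_row, umi, n = 1, mutant = FALSE,
                                trim_to = NULL, mutate_pos = NULL,
                                mutate_to = NULL) {
  tpl <- amp_row$amplicon_seq
  if (mutant) {
    substr(tpl, amp_row$target_offset, amp_row$target_offset) <- amp_row$alt
  }
  if (!is.null(mutate_pos)) substr(tpl, mutate_pos, mutate_pos) <- mutate_to
  if (!is.null(trim_to)) tpl <- substr(tpl, 1, trim_to)
  tibble::tibble(
    read_id = sprintf("h:%s:%d:%s", amp_row$locus_id, seq_len(n), umi),
    seq = paste0(umi, tpl)
  )
}

# Brute-force oracle for UMI family grouping: O(n^2) union-find over every
# pair satisfying the directional merge rule.
oracle_umi_partition <- function(umis, counts, max_dist = 1) {
  n <- length(umis)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  hd <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j >= i) next
    if (hd(umis[i], umis[j]) <= max_dist &&
        max(counts[i], counts[j]) >= 2 * min(counts[i], counts[j]) - 1) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(umis, roots)
}

partition_key <- function(groups) {
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = "+"),
                     character(1))))
}
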