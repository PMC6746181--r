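test_that("extract_umi splits tag from template and discards short reads", {
  r <- tibble::tibble(read_id = c("a", "b", "c"),
                      seq = c(paste0("ACGTACG", strrep("T", 25)),
                              "ACGTACGTTT",            # too short
                              paste0("GGGGGGG", strrep("A", 20))))
  out <- extract_umi(r, 7)
  expect_equal(out$read_id, c("a", "c"))
  expect_equal(out$umi, c("ACGTACG", "GGGGGGG"))
  expect_equal(out$seq[1], strrep("T", 25))
  expect_equal(attr(out, "n_discarded"), 1)
  # degenerate config: umi_length 0 keeps whole read, empty umi
  out0 <- extract_umi(r[1, ], 0)
  expect_equal(out0$umi, "")
  expect_equal(nchar(out0$seq), 32)
})

test_that("assign_locus matches anchors with at most one mismatch", {
  p <- fixture_panel(4)
  amp <- p$amp
  exact <- tibble::tibble(read_id = "e", seq = amp$amplicon_seq[3])
  expect_equal(assign_locus(exact, amp)$locus_id, amp$locus_id[3])
  # one error inside the anchor: still assigned
  s <- amp$amplicon_seq[2]
  old <- substr(s, 5, 5)
  substr(s, 5, 5) <- setdiff(c("A", "C", "G", "T"), old)[1]
  expect_equal(assign_locus(tibble::tibble(read_id = "m", seq = s),
                            amp)$locus_id, amp$locus_id[2])
  # random sequence: unassigned (chance of a <=1-mismatch 15-mer hit ~ 1e-4)
  withr::with_seed(8, {
    rand <- tibble::tibble(read_id = sprintf("r%d", 1:500),
                           seq = plasmatrace:::random_dna(500, 60))
  })
  expect_true(all(is.na(assign_locus(rand, amp)$locus_id)))
  # identical anchors are a configuration error
  dup <- amp
  dup$anchor[2] <- dup$anchor[1]
  expect_error(assign_locus(exact, dup), "anchor")
})

test_that("directional UMI grouping follows the stated merge rule", {
  grp <- function(umis, counts, d = 1) {
    r <- tibble::tibble(umi = rep(umis, counts))
    split(r$umi, group_families(r, d)$family_umi)
  }
  # all-same UMI: one family holding all reads
  f <- grp("AAAAAAA", 3)
  expect_equal(lengths(f), c(AAAAAAA = 3))
  # 100 vs 1 at distance 1: absorbed (100 >= 2*1 - 1)
  f <- grp(c("AAAAAAA", "AAAAAAT"), c(100, 1))
  expect_equal(length(f), 1)
  expect_equal(length(f[["AAAAAAA"]]), 101)
  # distance 7: never merged
  f <- grp(c("AAAAAAA", "TTTTTTT"), c(5, 5))
  expect_equal(length(f), 2)
  # 5 vs 5 at distance 1: rule fails (5 < 2*5 - 1), two families
  f <- grp(c("AAAAAAA", "AAAAAAT"), c(5, 5))
  expect_equal(length(f), 2)
})

test_that("grouping equals the brute-force union-find oracle", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      n_umi <- sample(3:25, 1)
      umis <- unique(plasmatrace:::random_dna(n_umi, 4))
      counts <- sample(1:20, length(umis), replace = TRUE)
      counts <- pmin(counts, floor(200 / length(umis))) # <= 200 reads total
    })
    reads <- tibble::tibble(umi = rep(umis, counts))
    got <- split(reads$umi, group_families(reads, 1)$family_umi)
    want <- oracle_umi_partition(umis, counts, 1)
    want_exp <- lapply(want, function(g) rep(g, counts[match(g, umis)]))
    expect_identical(partition_key(got), partition_key(want_exp))
  }
})

test_that("family consensus applies the mutant filters", {
  p <- fixture_panel(1)
  a <- p$amp[1, ]
  run <- function(reads, ...) {
    r <- extract_umi(reads, 7)
    r <- assign_locus(r, p$amp)
    r <- group_families(r, 1)
    consensus_families(r, p$amp, ...)
  }
  # 5 concordant mutant reads: mutant with agreement 1
  f <- run(reads_from_template(a, "ACGTACG", n = 5, mutant = TRUE),
           min_reads = 2, min_agreement = 0.9)
  expect_true(f$is_mutant)
  expect_equal(f$agreement_fraction, 1)
  expect_equal(f$read_count, 5)
  # 5 ref / 5 alt: tie, ambiguous, never mutant
  tie <- dplyr::bind_rows(reads_from_template(a, "ACGTACG", n = 5),
                          reads_from_template(a, "ACGTACG", n = 5,
                                              mutant = TRUE))
  f <- run(tie)
  expect_equal(f$consensus_base, "N")
  expect_false(f$is_mutant)
  # singleton mutant excluded by min_reads = 2
  f <- run(reads_from_template(a, "ACGTACG", n = 1, mutant = TRUE))
  expect_false(f$is_mutant)
  # agreement below threshold: 9 alt + 2 ref = 0.818 < 0.9
  lowagree <- dplyr::bind_rows(
    reads_from_template(a, "ACGTACG", n = 9, mutant = TRUE),
    reads_from_template(a, "ACGTACG", n = 2))
  f <- run(lowagree)
  expect_equal(f$consensus_base, a$alt)
  expect_false(f$is_mutant)
})

test_that("detection requires two independent mutant families", {
  p <- fixture_panel(1)
  a <- p$amp[1, ]
  call <- function(reads) call_loci(reads, p$amp)
  one_fam <- reads_from_template(a, "ACGTACG", n = 5, mutant = TRUE)
  expect_false(call(one_fam)$detected)
  two_fam <- dplyr::bind_rows(
    one_fam, reads_from_template(a, "TTTTCCC", n = 4, mutant = TRUE))
  rep2 <- call(two_fam)
  expect_equal(rep2$dedup_mutant_count, 2)
  expect_true(rep2$detected)
  # wild-type families are counted but never detected
  wt <- reads_from_template(a, "GGGCCCA", n = 6)
  rep0 <- call(wt)
  expect_equal(rep0$total_families, 1)
  expect_equal(rep0$dedup_mutant_count, 0)
  expect_false(rep0$detected)
})

test_that("zero-error libraries count one family per distinct mutant UMI", {
  p <- fixture_panel(2)
  cfg <- sim_config(seed = 13, seq_error_rate = 0, prep_error_rate = 0,
                    capture_efficiency = 1, background_wt_molecules = 0)
  reads <- simulate_library(p$amp, c(locus_01 = 60, locus_02 = 35), cfg)
  config <- caller_config(min_reads = 1, umi_merge_distance = 0)
  report <- call_loci(reads, p$amp, config)
  truth_umis <- tibble::tibble(
    locus = reads$true_locus,
    mol = sub(":r[0-9]+:.*$", "", reads$read_id),
    umi = sub("^.*:", "", reads$read_id)
  )
  expected <- dplyr::summarise(
    dplyr::group_by(truth_umis, locus),
    n = dplyr::n_distinct(umi), .groups = "drop")
  expect_equal(report$dedup_mutant_count,
               expected$n[match(report$locus_id, expected$locus)])
})

test_that("dedup mutant count is monotone in added reads at zero error", {
  p <- fixture_panel(1)
  cfg <- sim_config(seed = 21, seq_error_rate = 0, prep_error_rate = 0,
                    background_wt_molecules = 100)
  reads <- simulate_library(p$amp, c(locus_01 = 80), cfg)
  # pure deduplication semantics (no directional merging, which can flip
  # borderline absorb decisions either way as reads are added)
  config <- caller_config(umi_merge_distance = 0)
  full <- call_loci(reads, p$amp, config)$dedup_mutant_count
  for (frac in c(0.25, 0.5, 0.75)) {
    sub <- downsample_reads(reads, round(nrow(reads) * frac), seed = 2)
    expect_lte(call_loci(sub, p$amp, config)$dedup_mutant_count, full)
  }
})

test_that("negative-control libraries yield no detections at default rates", {
  p <- fixture_panel(4)
  cfg <- sim_config(seed = 31, background_wt_molecules = 500)
  for (s in 1:5) {
    reads <- simulate_library(p$amp, 0, cfg, seed = 100 + s)
    expect_equal(sum(call_loci(reads, p$amp)$detected), 0)
  }
})

test_that("call_libraries splits a benchmark by library", {
  p <- fixture_panel(2)
  d <- benchmark_design(sources = "S", spike_levels = c(20, 60, 200),
                        replicates_per_condition = 1, negative_controls = 1,
                        preps_per_sample = 1, n_alleles = 2)
  cfg <- sim_config(seed = 17, background_wt_molecules = 50)
  sim <- simulate_benchmark(p$amp, d, cfg)
  reports <- call_libraries(sim$reads, p$amp)
  expect_setequal(unique(reports$library_id), sim$manifest$library_id)
  expect_equal(nrow(reports), nrow(sim$manifest) * 2)
})
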