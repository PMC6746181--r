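test_that("make_reference honours construction guarantees", {
  ref <- make_reference(8, 400, seed = 1)
  expect_equal(nrow(ref$reference), 8)
  expect_equal(nrow(ref$alleles), 8)
  expect_true(all(ref$alleles$pos > 70))
  expect_true(all(ref$alleles$pos <= 400 - 70))
  with(ref$alleles, {
    expect_true(all(ref != alt))
    expect_true(all(nchar(ref) == 1 & nchar(alt) == 1))
  })
  # ref base really is the reference base at that position
  base_at <- substr(ref$reference$seq, ref$alleles$pos, ref$alleles$pos)
  expect_identical(base_at, ref$alleles$ref)

  expect_equal(nrow(make_reference(1, 200, seed = 1)$reference), 1)
  expect_error(make_reference(3, 150, seed = 1), "200")
})

test_that("make_reference and simulate_library are seed-deterministic", {
  expect_identical(make_reference(4, 300, seed = 7),
                   make_reference(4, 300, seed = 7))
  p <- fixture_panel(2)
  cfg <- sim_config(seed = 7, background_wt_molecules = 50)
  expect_identical(simulate_library(p$amp, 20, cfg),
                   simulate_library(p$amp, 20, cfg))
  # byte-identical on disk too
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_library(p$amp, 20, cfg), f1)
  write_fastq(simulate_library(p$amp, 20, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulate_library error-free reads match their templates exactly", {
  p <- fixture_panel(2)
  cfg <- sim_config(seed = 3, seq_error_rate = 0, prep_error_rate = 0,
                    capture_efficiency = 1, background_wt_molecules = 0)
  reads <- simulate_library(p$amp, 100, cfg)
  expect_gt(nrow(reads), 0)
  umis <- sub(".*:", "", reads$read_id)
  # inline UMI occupies the first umi_length bases and matches the name tag
  expect_identical(substr(reads$seq, 1, 7), umis)
  for (i in seq_len(nrow(p$amp))) {
    a <- p$amp[i, ]
    tpl <- a$amplicon_seq
    substr(tpl, a$target_offset, a$target_offset) <- a$alt
    sub_reads <- reads$seq[reads$true_locus == a$locus_id]
    body <- substr(sub_reads, 8, nchar(sub_reads))
    expect_true(all(body == substring(tpl, 1, nchar(body))))
  }
  # 100 molecules (50 per locus): never more than 50 distinct UMIs per locus
  per_locus <- table(reads$true_locus[!duplicated(sub("\\:r[0-9]+:.*", "",
                                                      reads$read_id))])
  expect_true(all(per_locus <= 50))
})

test_that("empty library when nothing is captured", {
  p <- fixture_panel(1)
  cfg <- sim_config(seed = 1, background_wt_molecules = 0)
  expect_equal(nrow(simulate_library(p$amp, 0, cfg)), 0)
  expect_error(simulate_library(p$amp, -1, cfg), ">= 0")
})

test_that("distinct UMIs saturate at but never exceed 4^umi_length", {
  # scaled-down tag space: 3-base UMIs give capacity 64
  p <- fixture_panel(1)
  cfg <- sim_config(seed = 2, umi_length = 3, capture_efficiency = 1,
                    mean_reads_per_molecule = 1, background_wt_molecules = 0,
                    reads_per_library = 1e6)
  reads <- simulate_library(p$amp, 2000, cfg)
  n_distinct <- length(unique(substr(reads$seq, 1, 3)))
  expect_lte(n_distinct, 64)
  expect_gte(n_distinct, 60) # essentially saturated at 2000 draws
})

test_that("UMI draws are uniform over the tag space", {
  withr::with_seed(11, {
    umis <- plasmatrace:::random_dna(1e5, 7)
  })
  idx <- vapply(strsplit(umis, ""), function(ch)
    sum((match(ch, c("A", "C", "G", "T")) - 1) * 4^(6:0)) + 1, numeric(1))
  counts <- tabulate(idx, nbins = 16384)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("prep errors propagate to whole families, seq errors do not", {
  p <- fixture_panel(1)
  # sequencing errors only: families are internally discordant somewhere,
  # but no consensus-surviving mutant families arise at a wild-type locus
  cfg <- sim_config(seed = 4, seq_error_rate = 5e-3, prep_error_rate = 0,
                    capture_efficiency = 1, background_wt_molecules = 200,
                    mean_reads_per_molecule = 20)
  reads <- simulate_library(p$amp, 0, cfg)
  rep0 <- call_loci(reads, p$amp, keep_families = TRUE)
  fams <- attr(rep0, "families")
  expect_gt(sum(fams$agreement_fraction < 1), 0) # within-family discordance
  expect_equal(sum(fams$is_mutant), 0)           # none survives consensus
  # prep errors only: any mutant-looking family is perfectly concordant
  cfg2 <- sim_config(seed = 5, seq_error_rate = 0, prep_error_rate = 0.02,
                     capture_efficiency = 1, background_wt_molecules = 300,
                     mean_reads_per_molecule = 8)
  reads2 <- simulate_library(p$amp, 0, cfg2)
  rep2 <- call_loci(reads2, p$amp, caller_config(umi_merge_distance = 0),
                    keep_families = TRUE)
  fams2 <- attr(rep2, "families")
  expect_true(all(fams2$agreement_fraction[fams2$consensus_base ==
                                             p$amp$alt[1]] == 1))
})

test_that("benchmark design arithmetic and manifests", {
  d <- benchmark_design()
  expect_equal(n_spikein_samples(d), 24)
  expect_equal(n_libraries(d), 56)
  expect_equal(nrow(design_manifest(d)), 56)
  d1 <- benchmark_design(sources = "S", spike_levels = 10,
                         replicates_per_condition = 1,
                         negative_controls = 0, preps_per_sample = 1)
  expect_equal(n_libraries(d1), 1)
  expect_error(benchmark_design(spike_levels = c(100, 10)), "increasing")
})

test_that("benchmark truth conserves the designed spike level per library", {
  p <- fixture_panel(3)
  d <- benchmark_design(sources = "S", spike_levels = c(10, 100, 1000),
                        replicates_per_condition = 1, negative_controls = 1,
                        preps_per_sample = 2, n_alleles = 3)
  cfg <- sim_config(seed = 9, background_wt_molecules = 10)
  sim <- simulate_benchmark(p$amp, d, cfg)
  expect_equal(nrow(sim$manifest), n_libraries(d))
  sums <- dplyr::summarise(
    dplyr::group_by(sim$truth, library_id),
    total = sum(true_template_molecules), .groups = "drop")
  joined <- dplyr::left_join(sim$manifest, sums, by = "library_id")
  expect_equal(joined$total, as.integer(joined$spike_level))
  # negative controls carry zero mutant templates
  neg <- sim$truth[grepl("^NC", sim$truth$library_id), ]
  expect_true(all(!neg$true_mutant))
  expect_true(all(neg$true_template_molecules == 0))
})

test_that("ULP bin simulation matches the mixture depth model", {
  # f = 0, no bias: flat expectation across bins
  bins0 <- simulate_ulp_bins(0, seed = 1, mean_reads_per_bin = 2000)
  expect_lt(sd(bins0$raw_count) / mean(bins0$raw_count), 0.2)
  expect_equal(sum(bins0$tumor_cn != 2), 0)
  # one single-copy loss at f = 0.30: depth ratio 0.85 of neutral
  prof <- tibble::tibble(chrom = "chr2", start = 0, end = 100e6,
                         tumor_cn = 1)
  bins <- simulate_ulp_bins(0.30, prof, seed = 2, mean_reads_per_bin = 2000)
  in_loss <- bins$chrom == "chr2" & bins$start < 100e6
  ratio <- mean(bins$raw_count[in_loss]) / mean(bins$raw_count[!in_loss])
  expect_equal(ratio, 0.85, tolerance = 0.01)
  # profile outside the genome is rejected
  bad <- tibble::tibble(chrom = "chr99", start = 0, end = 1e6, tumor_cn = 1)
  expect_error(simulate_ulp_bins(0.1, bad, seed = 1), "outside")
})

test_that("multiregion simulation emits a perfect phylogeny with a trunk", {
  sim <- simulate_multiregion(4, 20, "linear", seed = 1)
  truncal <- sim$truth$mutation[sim$truth$class == "trunk"]
  expect_gte(length(truncal), 1)
  expect_true(all(colSums(sim$matrix[, truncal, drop = FALSE]) == 4))
  expect_true(all(colSums(sim$matrix) >= 1))
  # two foci: only trunk and leaf classes can arise
  sim2 <- simulate_multiregion(2, 12, "linear", seed = 3)
  expect_true(all(sim2$truth$class %in% c("trunk", "leaf")))
  # classification of the emitted matrix matches truth labels exactly
  cl <- classify_clonality(sim$matrix)
  expect_identical(cl$class[match(sim$truth$mutation, cl$mutation)],
                   sim$truth$class)
})
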