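small_genome <- function() {
  tibble::tibble(
    chrom = rep(c("chrA", "chrB"), each = 60),
    start = rep((0:59) * 1e6, 2),
    end = rep((1:60) * 1e6, 2),
    gc = rep(seq(0.35, 0.50, length.out = 60), 2)
  )
}

test_that("bin_counts tiles reads into the right bins", {
  g <- small_genome()
  expect_true(all(bin_counts(tibble::tibble(chrom = character(0),
                                            pos = numeric(0)),
                             g)$raw_count == 0))
  # hand enumeration: 3 bins of chrA get known counts
  pos <- tibble::tibble(
    chrom = "chrA",
    pos = c(rep(5e5, 40), rep(1.5e6, 35), rep(2.5e6, 25)))
  b <- bin_counts(pos, g)
  expect_equal(b$raw_count[b$chrom == "chrA"][1:3], c(40, 35, 25))
  expect_equal(sum(b$raw_count), 100)
  # boundary positions: pos = 1e6 belongs to the second bin (0-based starts)
  b2 <- bin_counts(tibble::tibble(chrom = "chrA", pos = c(1, 1e6, 1e6 + 1)),
                   g)
  expect_equal(b2$raw_count[b2$chrom == "chrA"][1:2], c(2, 1))
  expect_error(bin_counts(tibble::tibble(chrom = "chrZ", pos = 1), g),
               "chromosomes")
})

test_that("gc_normalize removes injected GC bias and centres at zero", {
  bins0 <- simulate_ulp_bins(0, seed = 5, mean_reads_per_bin = 2000)
  n0 <- gc_normalize(bins0)
  expect_lt(abs(mean(n0$norm_log2, na.rm = TRUE)), 0.02)
  biased <- simulate_ulp_bins(0, seed = 5, mean_reads_per_bin = 2000,
                              gc_bias_params = c(2, 0))
  raw_cor <- stats::cor(log2(biased$raw_count + 1), biased$gc)
  nb <- gc_normalize(biased)
  post_cor <- stats::cor(nb$norm_log2, nb$gc, use = "complete.obs")
  expect_gt(abs(raw_cor), 0.3)
  expect_lt(abs(post_cor), 0.05)
})

test_that("a single-copy loss at f = 0.30 normalises to log2(0.85)", {
  prof <- tibble::tibble(chrom = "chr3", start = 0, end = 150e6,
                         tumor_cn = 1)
  bins <- gc_normalize(simulate_ulp_bins(0.30, prof, seed = 11,
                                         mean_reads_per_bin = 2000))
  in_loss <- bins$chrom == "chr3" & bins$start < 150e6
  # decile-median GC correction leaves a small residual shift
  expect_lt(abs(mean(bins$norm_log2[in_loss]) - log2(0.85)), 0.03)
})

test_that("segmentation recovers injected breakpoints and respects chroms", {
  g <- small_genome()
  # perfectly flat signal: one segment per chromosome
  flat <- dplyr::mutate(g, norm_log2 = 0)
  seg <- segment_bins(flat)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$chrom, c("chrA", "chrB"))
  # one 0.5-step on chrA bins 31..60, recovered within +/- 2 bins
  withr::with_seed(4, {
    x <- stats::rnorm(120, 0, 0.03)
  })
  stepped <- dplyr::mutate(g, norm_log2 = x +
                             ifelse(chrom == "chrA" & start >= 30e6, 0.5, 0))
  seg2 <- segment_bins(stepped)
  bk <- seg2[seg2$chrom == "chrA", ]
  expect_equal(nrow(bk), 2)
  expect_lte(abs(bk$start[2] - 30e6), 2e6)
  expect_true(all(seg2$chrom %in% c("chrA", "chrB")))
  # segments partition the analysed bins
  expect_equal(sum(seg2$n_bins), 120)
})

test_that("state calls threshold segment means symmetrically", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1,
                        n_bins = 10, mean_log2 = c(0, -0.234, 0.05, 0.3))
  states <- call_states(seg)$state
  expect_equal(states, c("neutral", "loss", "neutral", "gain"))
  expect_error(call_states(seg, gain_cut = -0.1, loss_cut = 0.1), "loss_cut")
})

test_that("recurrent batch artifacts are flagged, private events are not", {
  art <- edta_artifact_profile(0.3)
  mk <- function(s, batch, f = 0, prof = NULL, artifacts = NULL) {
    bins <- simulate_ulp_bins(f, prof, seed = s, mean_reads_per_bin = 2000,
                              batch_artifacts = artifacts)
    seg <- call_states(segment_bins(gc_normalize(bins)))
    dplyr::mutate(seg, sample_id = paste0("s", s), batch = batch)
  }
  cohort <- dplyr::bind_rows(
    purrr::map(1:5, ~ mk(.x, "EDTA", artifacts = art)),
    mk(6, "EDTA", f = 0.3, prof = prostate_scna_profile(), artifacts = art))
  flagged <- flag_artifacts(cohort)
  # artifact segments flagged in every EDTA sample
  art_hits <- flagged[flagged$chrom == "chr5" & flagged$state != "neutral" &
                        flagged$start < 80e6 & flagged$end > 40e6, ]
  expect_gte(nrow(art_hits), 5)
  expect_true(all(art_hits$artifact))
  # the tumor profile private to sample 6 survives flagging
  tum <- flagged[flagged$sample_id == "s6" & flagged$chrom == "chr13" &
                   flagged$state == "loss", ]
  expect_true(nrow(tum) >= 1 && all(!tum$artifact))
  # private alterations in a large batch are never flagged
  expect_error(flag_artifacts(dplyr::mutate(cohort, batch = sample_id)),
               ">= 2")
})

test_that("PTC inverts the single-copy model and flags indeterminate cases", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 50e6, n_bins = 50,
                        mean_log2 = 0, state = "neutral", artifact = FALSE)
  prof_none <- estimate_ptc(seg)
  expect_true(is.na(prof_none$ptc))
  expect_equal(prof_none$pga, 0)
  expect_equal(glance(prof_none)$ptc_indeterminate, TRUE)
  # single loss at r = -0.234 implies f = 0.30
  seg2 <- dplyr::bind_rows(
    seg, tibble::tibble(chrom = "chr2", start = 0, end = 50e6, n_bins = 50,
                        mean_log2 = -0.234, state = "loss",
                        artifact = FALSE))
  prof <- estimate_ptc(seg2)
  expect_equal(prof$ptc, 2 * (1 - 2^-0.234), tolerance = 1e-6)
  expect_equal(prof$ptc, 0.30, tolerance = 0.01)
  expect_equal(prof$pga, 0.5)
  # artifact segments never contribute
  seg3 <- seg2
  seg3$artifact[2] <- TRUE
  expect_true(is.na(estimate_ptc(seg3)$ptc))
  # sex chromosomes are excluded from the accounting
  seg4 <- dplyr::bind_rows(
    seg, tibble::tibble(chrom = "chrX", start = 0, end = 50e6, n_bins = 50,
                        mean_log2 = -1, state = "loss", artifact = FALSE))
  expect_true(is.na(estimate_ptc(seg4)$ptc))
})

test_that("profile_cna recovers a prostate-like tumor fraction end to end", {
  bins <- simulate_ulp_bins(0.3066, prostate_scna_profile(), seed = 19,
                            mean_reads_per_bin = 2000)
  prof <- profile_cna(bins)
  expect_lt(abs(prof$ptc - 0.3066), 0.05)
  expect_gt(prof$pga, 0.05)
  expect_equal(prof$ploidy_uncorrected, 2 * (1 - 0.3066 * prof$pga / 2),
               tolerance = 0.1)
  expect_s3_class(tidy(prof), "tbl_df")
  expect_s3_class(autoplot(prof, bins = gc_normalize(bins)), "ggplot")
})

test_that("bin tables and SEG files round-trip through disk", {
  bins <- simulate_ulp_bins(0, seed = 2, mean_reads_per_bin = 500)
  f <- tempfile(fileext = ".tsv")
  write_bins_tsv(bins, f)
  back <- read_bins_tsv(f)
  expect_equal(back$raw_count, bins$raw_count)
  seg <- call_states(segment_bins(gc_normalize(bins)))
  sf <- tempfile(fileext = ".seg")
  write_seg(seg, sf, sample_id = "demo")
  lines <- readLines(sf)
  expect_match(lines[1], "Segment_Mean")
  expect_equal(length(lines), nrow(seg) + 1)
})
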