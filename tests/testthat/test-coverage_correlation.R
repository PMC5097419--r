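test_that("binning tiles chromosomes and assigns midpoints half-open", {
  x <- fs("chr1", 1990, 2010, sizes = c(chr1 = 5000))   # midpoint 2000
  bc <- binned_counts(x, bin_width = 2000)
  expect_equal(bc$start, c(0, 2000, 4000))
  expect_equal(bc$end, c(2000, 4000, 5000))             # partial last bin
  expect_equal(bc$count, c(0, 1, 0))                    # second bin
  expect_error(binned_counts(x, bin_width = 0), class = "chipab_error")
})

test_that("binned counts conserve every fragment", {
  set.seed(31)
  x <- random_fragments(1e4, genome = 1e6)
  bc <- binned_counts(x, 2000)
  expect_equal(sum(bc$count), 1e4)
  expect_equal(nrow(bc), 500)
})

test_that("log-log correlation has its closed-form fixed points", {
  set.seed(32)
  x <- random_fragments(5000, genome = 1e5)
  a <- binned_counts(x, 2000)
  expect_equal(loglog_correlation(a, a), 1.0)

  # doubling counts is an affine shift in log space: correlation stays 1
  b <- a
  b$count <- 2 * a$count
  expect_equal(loglog_correlation(a, b, pseudocount = 0), 1.0)

  # symmetry
  set.seed(33)
  y <- random_fragments(5000, genome = 1e5)
  c2 <- binned_counts(y, 2000)
  expect_equal(loglog_correlation(a, c2), loglog_correlation(c2, a))

  mism <- binned_counts(y, 1000)
  expect_error(loglog_correlation(a, mism), class = "chipab_error")
})

test_that("replicates correlate highly; shuffled bins do not", {
  cfg <- sim_config(genome_length = 5e6, n_chromosomes = 2,
                    n_fragments = 2e5, seed = 34)
  ex <- simulate_experiment(cfg, n_replicates = 2)
  b1 <- binned_counts(ex$replicates[[1]], 2000)
  b2 <- binned_counts(ex$replicates[[2]], 2000)
  expect_gt(loglog_correlation(b1, b2), 0.9)
  b2s <- b2
  set.seed(1)
  b2s$count <- sample(b2$count)
  expect_lt(abs(loglog_correlation(b1, b2s)), 0.1)
})

test_that("region allocation tallies midpoints with an unannotated bucket", {
  ann <- genome_annotation(data.frame(
    chrom = "chr1", start = c(0, 1000), end = c(1000, 7000),
    label = c("TSS", "R")))
  start <- c(rep(100, 3), rep(4000, 6), 8000)   # 3 TSS, 6 R, 1 gap
  x <- fs(rep("chr1", 10), start, start + 100, sizes = c(chr1 = 10000))
  prof <- region_allocation(x, ann)
  expect_equal(unname(prof$fractions[["TSS"]]), 0.3)
  expect_equal(unname(prof$fractions[["R"]]), 0.6)
  expect_equal(prof$unannotated, 0.1)
  expect_equal(sum(prof$fractions) + prof$unannotated, 1)

  # restriction to peaks renormalizes over the overlapping subset
  pk <- peak_set(data.frame(chrom = "chr1", start = 0, end = 1000))
  prof_pk <- region_allocation(x, ann, restrict_to_peaks = pk)
  expect_equal(unname(prof_pk$fractions[["TSS"]]), 1.0)
  expect_equal(prof_pk$n, 3)

  gap_pk <- peak_set(data.frame(chrom = "chr1", start = 9500, end = 9900))
  expect_error(region_allocation(x, ann, restrict_to_peaks = gap_pk),
               class = "chipab_analysis_error")
})

test_that("WCE allocation recovers annotation base fractions", {
  cfg <- small_config(n_fragments = 5e4, seed = 36)
  ann <- make_annotation(cfg)
  wce <- simulate_fragments(ann, cfg, mode = "wce", seed = 36)
  prof <- region_allocation(wce, ann)
  expect_true(all(abs(prof$fractions - base_fractions(ann)) < 0.03))
})

test_that("enrichment over WCE is the ratio of read fractions", {
  mk <- function(fracs) {
    counts <- setNames(round(fracs * 10000), canonical_labels)
    structure(list(counts = counts, fractions = counts / sum(counts),
                   unannotated = 0, unannotated_count = 0L,
                   n = sum(counts), sample_id = "x"),
              class = "RegionProfile")
  }
  s <- mk(c(CTCF = .005, PF = .05, TSS = .605, T = .05, E = .05,
            WE = .04, R = .2))
  w <- mk(c(CTCF = .005, PF = .05, TSS = .0398, T = .25, E = .05,
            WE = .04, R = .5653))
  enr <- enrichment_over_wce(s, w)
  # a sample with 60.5% of reads at TSS against a 3.98% background: 15.2x
  expect_equal(round(unname(enr[["TSS"]]), 1), 15.2)
  expect_equal(unname(enrichment_over_wce(w, w)), rep(1, 7))

  # simulated ChIP: enriched label up, repressed background down
  cfg <- small_config(n_fragments = 5e4, enrichment = c(TSS = 10),
                      seed = 37)
  ann <- make_annotation(cfg)
  chip <- simulate_fragments(ann, cfg, mode = "chip", seed = 37)
  wce <- simulate_fragments(ann, cfg, mode = "wce", seed = 38)
  enr2 <- enrichment_over_wce(region_allocation(chip, ann),
                              region_allocation(wce, ann))
  expect_gt(enr2[["TSS"]], 1)
  expect_lt(enr2[["R"]], 1)
})

test_that("region scatter has exact fixed points and subsample slopes", {
  cfg <- small_config(n_fragments = 4e4, seed = 39)
  ann <- make_annotation(cfg)
  chip <- simulate_fragments(ann, cfg, mode = "chip", seed = 39)

  same <- region_scatter_stats(chip, chip, ann, labels = c("TSS", "E"))
  expect_true(all(same$stats$slope == 1.0))
  expect_true(all(same$stats$r_squared == 1.0))

  # counts_b = 3 x counts_a exactly: slope 3, r-squared 1 (closed form)
  trip <- merge_replicates(list(chip, chip, chip))
  three <- region_scatter_stats(chip, trip, ann, labels = "TSS")
  expect_equal(three$stats$slope, rep(3.0, 2))
  expect_equal(three$stats$r_squared, rep(1.0, 2))

  # half-depth subsample: slope ~ 0.5
  half <- downsample_random(chip, 2e4, seed = 40)
  hs <- region_scatter_stats(chip, half, ann, labels = c("TSS", "E"))
  ov <- hs$stats[hs$stats$label == "overall", ]
  expect_lt(abs(ov$slope - 0.5), 0.05)

  expect_warning(region_scatter_stats(chip, chip, ann,
                                      labels = c("TSS", "bogus")),
                 "no annotated intervals")
  expect_error(region_scatter_stats(chip, chip, ann, labels = character()),
               class = "chipab_error")
})
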