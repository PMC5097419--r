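test_that("the windowed caller finds a forced peak and ignores itself", {
  set.seed(2)
  genome <- c(chr1 = 10000)
  start_s <- sample(0:900, 100, replace = TRUE)
  sample_fs <- fs(rep("chr1", 100), start_s, start_s + 100, sizes = genome)
  start_c <- sample(0:9900, 100, replace = TRUE)
  control <- fs(rep("chr1", 100), start_c, start_c + 100, sizes = genome)
  pk <- call_peaks_simple(sample_fs, control, window = 1000,
                          fold_threshold = 2, min_count = 10)
  expect_equal(pk$intervals,
               data.frame(chrom = "chr1", start = 0, end = 1000))

  # a sample identical to its control never clears fold >= 2
  self <- call_peaks_simple(control, control, window = 1000,
                            fold_threshold = 2, min_count = 1)
  expect_equal(nrow(self$intervals), 0)

  # empty sample: empty peaks, not an error; empty control: error
  empty <- fs(character(), numeric(), numeric(), sizes = genome)
  expect_equal(bases_in_peaks(call_peaks_simple(empty, control)), 0)
  expect_error(call_peaks_simple(sample_fs, empty),
               class = "chipab_precondition_error")
})

test_that("the caller agrees with an exhaustive window-scan oracle", {
  set.seed(14)
  for (i in 1:10) {
    genome <- sample(c(2e4, 5e4), 1)
    window <- sample(c(500, 1000), 1)
    chip <- random_fragments(800, genome = genome, min_len = 70,
                             max_len = 300)
    # spike extra fragments into a random region to create enrichment
    hot <- sample(0:(genome - 3000), 1)
    hs <- sample(hot:(hot + 2500), 400, replace = TRUE)
    chip <- merge_replicates(list(chip, fs(rep("chr1", 400), hs, hs + 150,
                                           sizes = chip$chrom_sizes)))
    ctl <- random_fragments(1000, genome = genome, min_len = 70,
                            max_len = 300)
    got <- call_peaks_simple(chip, ctl, window = window,
                             fold_threshold = 2, min_count = 8)
    want <- oracle_call_peaks(chip, ctl, genome, window,
                              fold_threshold = 2, min_count = 8)
    expect_equal(got$intervals, want$intervals)
  }
})

test_that("bases_in_peaks merges then sums, matching a bitmap oracle", {
  p <- peak_set(data.frame(chrom = "chr1", start = c(0, 50),
                           end = c(100, 150)))
  expect_equal(bases_in_peaks(p), 150)
  expect_equal(bases_in_peaks(peak_set(
    data.frame(chrom = character(), start = numeric(),
               end = numeric()))), 0)
  set.seed(21)
  for (i in 1:5) {
    q <- random_peaks(genome = 1e5, n = 100)
    expect_equal(bases_in_peaks(q), oracle_bases(q, 1e5))
  }
})

test_that("sensitivity/specificity match hand counts and the bitmap oracle", {
  ann <- genome_annotation(data.frame(
    chrom = "chr1", start = c(0, 100), end = c(100, 1000),
    label = c("E", "R")))
  pk <- peak_set(data.frame(chrom = "chr1", start = 50, end = 150))
  ss <- sensitivity_specificity(pk, ann, "E")
  expect_equal(unname(ss["sensitivity"]), 0.5)
  expect_equal(unname(ss["specificity"]), 0.5)

  # peaks exactly equal to every E interval: perfect on both axes
  pe <- peak_set(data.frame(chrom = "chr1", start = 0, end = 100))
  expect_equal(unname(sensitivity_specificity(pe, ann, "E")), c(1, 1))

  expect_error(sensitivity_specificity(pk, ann, "TSS"),
               class = "chipab_analysis_error")
  expect_error(sensitivity_specificity(pk, ann, "bogus"),
               class = "chipab_error")

  set.seed(22)
  for (i in 1:5) {
    ann_r <- random_annotation(genome = 1e5, n = 30)
    lab <- sample(unique(ann_r$intervals$label), 1)
    pk_r <- random_peaks(genome = 1e5, n = 20)
    expect_equal(sensitivity_specificity(pk_r, ann_r, lab),
                 oracle_sens_spec(pk_r, ann_r, lab, 1e5),
                 tolerance = 1e-12)
  }
})

test_that("peak bases in unannotated gaps leave the specificity denominator", {
  ann <- genome_annotation(data.frame(chrom = "chr1", start = 0, end = 100,
                                      label = "E"))
  # 100 peak bases: 50 in E, 50 in an unannotated gap
  pk <- peak_set(data.frame(chrom = "chr1", start = 50, end = 150))
  ss <- sensitivity_specificity(pk, ann, "E")
  expect_equal(unname(ss["specificity"]), 1.0)
  expect_equal(unname(ss["sensitivity"]), 0.5)
})

test_that("peak-base overlap partitions the union, matching the oracle", {
  a <- peak_set(data.frame(chrom = "chr1", start = 0, end = 100))
  b <- peak_set(data.frame(chrom = "chr1", start = 50, end = 150))
  ov <- peak_base_overlap(a, b)
  expect_equal(ov$only_a, 50)
  expect_equal(ov$only_b, 50)
  expect_equal(ov$both, 50)
  expect_equal(ov$fraction_both_of_union, 1 / 3)
  expect_equal(peak_base_overlap(a, a)$fraction_both_of_union, 1.0)

  set.seed(23)
  for (i in 1:5) {
    x <- random_peaks(1e5, 30); y <- random_peaks(1e5, 30)
    got <- peak_base_overlap(x, y)
    want <- oracle_overlap(x, y, 1e5)
    expect_equal(got[c("only_a", "only_b", "both")], want)
  }
})

test_that("SPOT scores count any-overlap fragments, matching the oracle", {
  genome <- c(chr1 = 10000)
  pk <- peak_set(data.frame(chrom = "chr1", start = 0, end = 1000))
  start <- c(seq(0, 900, length.out = 4), seq(5000, 8000, length.out = 6))
  x <- fs(rep("chr1", 10), start, start + 50, sizes = genome)
  expect_equal(spot_score(x, pk), 0.4)

  whole <- peak_set(data.frame(chrom = "chr1", start = 0, end = 10000))
  expect_equal(spot_score(x, whole), 1.0)

  empty <- fs(character(), numeric(), numeric(), sizes = genome)
  expect_error(spot_score(empty, pk), class = "chipab_analysis_error")

  set.seed(24)
  for (i in 1:5) {
    fr <- random_fragments(300, genome = 1e5)
    q <- random_peaks(1e5, 15)
    expect_equal(spot_score(fr, q), oracle_spot(fr, q, 1e5))
  }
})

test_that("SPOT is monotone under peak enlargement and senspec is split-invariant", {
  set.seed(25)
  fr <- random_fragments(500, genome = 1e5)
  q <- random_peaks(1e5, 10)
  grown <- peak_set(data.frame(chrom = q$intervals$chrom,
                               start = pmax(0, q$intervals$start - 500),
                               end = pmin(1e5, q$intervals$end + 500)))
  expect_gte(spot_score(fr, grown), spot_score(fr, q))

  ann <- random_annotation(1e5, 30)
  lab <- ann$intervals$label[1]
  # split every peak interval into two adjacent halves
  iv <- q$intervals
  mid <- floor((iv$start + iv$end) / 2)
  split_pk <- peak_set(data.frame(
    chrom = rep(iv$chrom, 2), start = c(iv$start, mid),
    end = c(mid, iv$end)))
  expect_equal(sensitivity_specificity(split_pk, ann, lab),
               sensitivity_specificity(q, ann, lab))
})

test_that("saturation curves are reproducible per depth and plateau by construction", {
  set.seed(26)
  genome <- c(chr1 = 20000)
  hs <- sample(0:1800, 300, replace = TRUE)
  bg <- sample(2000:19800, 100, replace = TRUE)
  chip <- fs(rep("chr1", 400), c(hs, bg), c(hs, bg) + 150, sizes = genome)
  ctl <- random_fragments(400, genome = 20000, min_len = 100, max_len = 200)

  # duplicated full depth gives identical bases (same input regardless of seed)
  sat <- saturation_curve(chip, ctl, depths = c(400, 400), seed = 5,
                          window = 1000, fold_threshold = 2, min_count = 10)
  expect_equal(sat$bases_in_peaks[1], sat$bases_in_peaks[2])

  # the hot region is detectable at quarter depth: plateau from there on
  sat2 <- saturation_curve(chip, ctl, depths = seq(100, 400, 50), seed = 5,
                           window = 2000, fold_threshold = 2, min_count = 5)
  expect_true(all(sat2$bases_in_peaks[sat2$depth >= 200] ==
                    sat2$bases_in_peaks[nrow(sat2)]))
  expect_error(saturation_curve(chip, ctl, depths = c(100, 500), seed = 1),
               class = "chipab_precondition_error")
})
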