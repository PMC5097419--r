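# Fixture builders and independent per-base oracles used across test files.
# Oracles are deliberately naive (logical bitmaps, exhaustive window scans)
# and share no code with the package internals they check.

fs <- function(chrom, start, end, sizes = NULL, id = "test") {
  if (is.null(sizes)) sizes <- tapply(end, chrom, max)
  fragment_set(data.frame(chrom = chrom, start = start, end = end),
               chrom_sizes = sizes, sample_id = id)
}

# uniform random fragments over a single chromosome
random_fragments <- function(n, genome = 1e5, min_len = 70, max_len = 700,
                             chrom = "chr1") {
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, genome - len))
  fs(rep(chrom, n), start, start + len, sizes = setNames(genome, chrom))
}

# random disjoint labelled intervals on one chromosome
random_annotation <- function(genome = 1e5, n = 20,
                              labels = canonical_labels, chrom = "chr1") {
  cuts <- sort(sample(seq(0, genome, by = 10), 2 * n))
  start <- cuts[seq(1, length(cuts), 2)]
  end <- cuts[seq(2, length(cuts), 2)]
  keep <- end > start
  genome_annotation(data.frame(chrom = chrom, start = start[keep],
                               end = end[keep],
                               label = sample(labels, sum(keep),
                                              replace = TRUE)))
}

random_peaks <- function(genome = 1e5, n = 10, chrom = "chr1") {
  start <- sort(sample(seq(0, genome - 200, by = 1), n))
  end <- pmin(start + sample(50:2000, n, replace = TRUE), genome)
  peak_set(data.frame(chrom = chrom, start = start, end = end))
}

# ---- per-base bitmap oracles (single chromosome) ----

bitmap <- function(df, genome) {
  v <- logical(genome)
  for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}

oracle_bases <- function(peaks, genome)
  sum(bitmap(peaks$intervals, genome))

oracle_overlap <- function(a, b, genome) {
  va <- bitmap(a$intervals, genome); vb <- bitmap(b$intervals, genome)
  list(only_a = sum(va & !vb), only_b = sum(!va & vb), both = sum(va & vb))
}

oracle_sens_spec <- function(peaks, annotation, label, genome) {
  vp <- bitmap(peaks$intervals, genome)
  iv <- annotation$intervals
  vann <- bitmap(iv, genome)
  vexp <- bitmap(iv[iv$label == label, , drop = FALSE], genome)
  c(sensitivity = sum(vp & vexp) / sum(vexp),
    specificity = sum(vp & vexp) / sum(vp & vann))
}

oracle_spot <- function(fragments, peaks, genome) {
  vp <- bitmap(peaks$intervals, genome)
  rec <- fragments$records
  hits <- vapply(seq_len(nrow(rec)), function(i)
    any(vp[(rec$start[i] + 1):rec$end[i]]), TRUE)
  mean(hits)
}

# exhaustive window-by-window reimplementation of the simple caller
oracle_call_peaks <- function(sample, control, genome, window,
                              fold_threshold, min_count, chrom = "chr1") {
  nw <- ceiling(genome / window)
  count_in <- function(rec, w0, w1) {
    mid <- (rec$start + rec$end) %/% 2
    sum(mid >= w0 & mid < w1)
  }
  scale <- nrow(sample$records) / nrow(control$records)
  rows <- list()
  for (w in seq_len(nw)) {
    w0 <- (w - 1) * window; w1 <- min(w * window, genome)
    sc <- count_in(sample$records, w0, w1)
    cc <- count_in(control$records, w0, w1)
    if (sc >= min_count && sc / (1 + cc * scale) >= fold_threshold)
      rows[[length(rows) + 1]] <- data.frame(chrom = chrom, start = w0,
                                             end = w1)
  }
  if (!length(rows))
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric())))
  peak_set(do.call(rbind, rows))
}

# tiny config used wherever a fast simulation is enough
small_config <- function(..., genome_length = 1e6, n_chromosomes = 2,
                         n_fragments = 2e4) {
  sim_config(genome_length = genome_length, n_chromosomes = n_chromosomes,
             n_fragments = n_fragments, ...)
}
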