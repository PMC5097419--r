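## Peak-level statistics: a simple windowed caller (test plumbing, not a
## HOMER replacement), saturation curves, base-level sensitivity /
## specificity against the canonical segmentation, base-level overlap
## between two peak sets, and SPOT scoring.

## per-window fragment-midpoint counts over every chromosome
.window_counts <- function(fragments, window) {
  cs <- fragments$chrom_sizes
  rec <- fragments$records
  out <- lapply(names(cs), function(ch) {
    nw <- as.integer(ceiling(cs[[ch]] / window))
    sub <- rec[rec$chrom == ch, , drop = FALSE]
    cnt <- if (nrow(sub)) {
      mid <- (sub$start + sub$end) %/% 2
      tabulate(as.integer(mid %/% window) + 1L, nbins = nw)
    } else integer(nw)
    data.frame(chrom = ch, start = (seq_len(nw) - 1) * window,
               end = pmin(seq_len(nw) * window, cs[[ch]]),
               count = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simple windowed fold-enrichment peak caller
#'
#' Deliberately minimal caller for self-contained pipelines and fixtures:
#' tiles the genome in non-overlapping windows, counts fragment midpoints
#' per window in sample and control, and calls a window peak-positive when
#' `sample count >= min_count` and
#' `sample count / (1 + scaled control count) >= fold_threshold`, where the
#' control count is scaled by the sample/control depth ratio (the +1
#' pseudocount guards empty control windows). Adjacent positive windows are
#' merged. It is not a model-based caller and is no substitute for one on
#' real data.
#'
#' @param sample,control `FragmentSet`s sharing `chrom_sizes`; the control
#'   (typically a WCE) must be non-empty.
#' @param window window size in bp.
#' @param fold_threshold minimum sample/control fold enrichment.
#' @param min_count minimum sample fragment count per window.
#' @return A [peak_set()]; empty if the sample is empty.
#' @export
call_peaks_simple <- function(sample, control, window = 1000,
                              fold_threshold = 2, min_count = 10) {
  stopifnot(inherits(sample, "FragmentSet"),
            inherits(control, "FragmentSet"))
  if (window <= 0) .err("window must be > 0")
  if (n_fragments(control) == 0)
    .err("control FragmentSet is empty", "chipab_precondition_error")
  if (n_fragments(sample) == 0)
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric())))
  sc <- .window_counts(sample, window)
  cc <- .window_counts(control, window)
  scale <- n_fragments(sample) / n_fragments(control)
  positive <- sc$count >= min_count &
    sc$count / (1 + cc$count * scale) >= fold_threshold
  peak_set(sc[positive, c("chrom", "start", "end"), drop = FALSE])
}

#' Total bases covered by a peak set
#'
#' @param peaks a `PeakSet` (intervals are disjoint after construction).
#' @return Total bp in peaks.
#' @export
bases_in_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "PeakSet"))
  sum(peaks$intervals$end - peaks$intervals$start)
}

#' Peak-base saturation curve
#'
#' Randomly downsamples the sample to each requested depth, calls peaks and
#' records the total bases in peaks, emulating the question "would more
#' sequencing find more peak territory?". A plateau indicates saturation.
#' Depth `i` uses seed `seed + i` so depths are reproducible and
#' independent.
#'
#' @param sample,control `FragmentSet`s (control passed to the caller).
#' @param depths increasing read-pair depths; default 20 evenly spaced
#'   depths up to the full sample size.
#' @param seed integer seed.
#' @param caller function `(sample, control) -> PeakSet`; defaults to
#'   [call_peaks_simple()] with the `window`/`fold_threshold`/`min_count`
#'   given here.
#' @inheritParams call_peaks_simple
#' @return Object of class `SaturationCurve`: data.frame with columns
#'   `depth` and `bases_in_peaks`.
#' @export
saturation_curve <- function(sample, control, depths = NULL, seed = 1,
                             caller = NULL, window = 1000,
                             fold_threshold = 2, min_count = 10) {
  stopifnot(inherits(sample, "FragmentSet"))
  N <- n_fragments(sample)
  if (is.null(depths))
    depths <- unique(round(seq(N / 20, N, length.out = 20)))
  if (any(depths > N))
    .err(sprintf("depth %d exceeds sample size %d", max(depths), N),
         "chipab_precondition_error")
  if (is.null(caller))
    caller <- function(s, ctl)
      call_peaks_simple(s, ctl, window = window,
                        fold_threshold = fold_threshold,
                        min_count = min_count)
  bases <- vapply(seq_along(depths), function(i) {
    sub <- downsample_random(sample, depths[i], seed = seed + i)
    bases_in_peaks(caller(sub, control))
  }, 0)
  structure(data.frame(depth = depths, bases_in_peaks = bases),
            class = c("SaturationCurve", "data.frame"))
}

#' @export
print.SaturationCurve <- function(x, ...) {
  cat(sprintf("SaturationCurve: %d depths, %.0f-%.0f bases in peaks\n",
              nrow(x), min(x$bases_in_peaks), max(x$bases_in_peaks)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.SaturationCurve <- function(x, ...) {
  plot(x$depth, x$bases_in_peaks, type = "b", pch = 19,
       xlab = "read pairs", ylab = "bases in peaks", ...)
  invisible(x)
}

#' Base-level sensitivity and specificity of peaks against a label
#'
#' Specificity: fraction of *annotated* peak bases lying in the expected
#' region type. Sensitivity: fraction of expected-region bases covered by
#' peaks. Peak bases falling in unannotated gaps are excluded from the
#' specificity denominator, so both metrics are computed over annotated
#' bases only.
#'
#' @param peaks a `PeakSet`.
#' @param annotation a [genome_annotation()].
#' @param expected_label one of [canonical_labels], present in the
#'   annotation.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(peaks, annotation, expected_label) {
  stopifnot(inherits(peaks, "PeakSet"),
            inherits(annotation, "GenomeAnnotation"))
  if (!(expected_label %in% canonical_labels))
    .err(sprintf("expected_label must be one of %s",
                 paste(canonical_labels, collapse = "/")))
  iv <- annotation$intervals
  if (!any(iv$label == expected_label))
    .err(sprintf("label %s absent from annotation", expected_label),
         "chipab_analysis_error")
  chroms <- unique(c(iv$chrom, peaks$intervals$chrom))
  ann_gr <- .as_gr(iv$chrom, iv$start, iv$end, chroms)
  exp_gr <- ann_gr[iv$label == expected_label]
  pk_gr <- .as_gr(peaks$intervals$chrom, peaks$intervals$start,
                  peaks$intervals$end, chroms)
  w <- function(gr) sum(as.numeric(BiocGenerics::width(gr)))
  tp <- w(GenomicRanges::intersect(pk_gr, exp_gr))
  peak_annot <- w(GenomicRanges::intersect(pk_gr, ann_gr))
  exp_total <- w(exp_gr)
  c(sensitivity = tp / exp_total,
    specificity = if (peak_annot > 0) tp / peak_annot else NA_real_)
}

#' Base-level overlap between two peak sets
#'
#' Partitions the union of two peak sets into bases called only by the
#' first, only by the second, or by both, and reports the both/union
#' fraction (base-level Jaccard).
#'
#' @param a,b `PeakSet`s.
#' @return Object of class `OverlapSummary`: list with `only_a`, `only_b`,
#'   `both` (bp) and `fraction_both_of_union`.
#' @export
peak_base_overlap <- function(a, b) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  chroms <- unique(c(a$intervals$chrom, b$intervals$chrom))
  gra <- .as_gr(a$intervals$chrom, a$intervals$start, a$intervals$end,
                chroms)
  grb <- .as_gr(b$intervals$chrom, b$intervals$start, b$intervals$end,
                chroms)
  w <- function(gr) sum(as.numeric(BiocGenerics::width(gr)))
  both <- w(GenomicRanges::intersect(gra, grb))
  only_a <- w(gra) - both
  only_b <- w(grb) - both
  union <- only_a + only_b + both
  structure(list(only_a = only_a, only_b = only_b, both = both,
                 fraction_both_of_union = if (union > 0) both / union
                 else NA_real_),
            class = "OverlapSummary")
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat(sprintf(
    "OverlapSummary: only A %.0f bp, only B %.0f bp, both %.0f bp (%.1f%% of union)\n",
    x$only_a, x$only_b, x$both, 100 * x$fraction_both_of_union))
  invisible(x)
}

#' SPOT score (signal portion of tags)
#'
#' Fraction of fragments overlapping any peak base by at least 1 bp — the
#' classic signal-to-noise summary for a ChIP library (equivalent to FRiP
#' at the fragment level).
#'
#' @param fragments a non-empty `FragmentSet`.
#' @param peaks a `PeakSet`.
#' @return Fraction in `[0, 1]`.
#' @export
spot_score <- function(fragments, peaks) {
  stopifnot(inherits(fragments, "FragmentSet"), inherits(peaks, "PeakSet"))
  if (n_fragments(fragments) == 0)
    .err("SPOT score undefined for an empty FragmentSet",
         "chipab_analysis_error")
  if (!nrow(peaks$intervals)) return(0)
  chroms <- unique(c(fragments$records$chrom, peaks$intervals$chrom))
  fr_gr <- .as_gr(fragments$records$chrom, fragments$records$start,
                  fragments$records$end, chroms)
  pk_gr <- .as_gr(peaks$intervals$chrom, peaks$intervals$start,
                  peaks$intervals$end, chroms)
  mean(GenomicRanges::countOverlaps(fr_gr, pk_gr) > 0)
}
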