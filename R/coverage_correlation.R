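## Genome-binned coverage, log-log correlation, per-region read allocation,
## WCE-relative enrichment, and region-resolved scatter statistics.
##
## All tallies assign each fragment to exactly one bin/region by its
## midpoint, so counts always form a partition and nothing is double
## counted.

#' Binned fragment counts across the genome
#'
#' Tiles every chromosome in non-overlapping `bin_width` windows (the last
#' bin of a chromosome may be partial and is retained) and counts fragment
#' midpoints per bin.
#'
#' @param fragments a `FragmentSet`.
#' @param bin_width bin size in bp (default 2000).
#' @return Object of class `BinnedCoverage`: data.frame with `chrom`,
#'   `start`, `end`, `count` and attribute `bin_width`.
#' @export
binned_counts <- function(fragments, bin_width = 2000) {
  stopifnot(inherits(fragments, "FragmentSet"))
  if (bin_width <= 0) .err("bin_width must be > 0")
  out <- .window_counts(fragments, bin_width)
  structure(out, bin_width = bin_width,
            class = c("BinnedCoverage", "data.frame"))
}

#' @export
print.BinnedCoverage <- function(x, ...) {
  cat(sprintf("BinnedCoverage: %d bins of %d bp, %.0f fragments\n",
              nrow(x), attr(x, "bin_width"), sum(x$count)))
  invisible(x)
}

#' Log-log Pearson correlation of two binned coverages
#'
#' Pearson correlation of `log(count + pseudocount)` across all bins — the
#' statistic behind genome-wide replicate/antibody scatter plots. Invariant
#' to any positive rescaling of either sample's counts (up to the
#' pseudocount).
#'
#' @param a,b `BinnedCoverage` objects with identical bin structures.
#' @param pseudocount added before the log (default 1, handling zeros).
#' @return Pearson correlation coefficient.
#' @export
loglog_correlation <- function(a, b, pseudocount = 1) {
  stopifnot(inherits(a, "BinnedCoverage"), inherits(b, "BinnedCoverage"))
  if (!identical(a[c("chrom", "start", "end")],
                 b[c("chrom", "start", "end")]))
    .err("bin structures differ between the two coverages")
  stats::cor(log(a$count + pseudocount), log(b$count + pseudocount))
}

#' Regional allocation of fragments
#'
#' Assigns each fragment to one canonical label by midpoint (or to the
#' `unannotated` bucket) and reports per-label counts and fractions. With
#' `restrict_to_peaks`, only fragments overlapping a peak (>= 1 bp) are
#' tallied and fractions renormalize over that subset — the "reads in
#' peaks by region" view.
#'
#' @param fragments a `FragmentSet`.
#' @param annotation a [genome_annotation()].
#' @param restrict_to_peaks optional `PeakSet`.
#' @return Object of class `RegionProfile`: list with `counts` (named over
#'   [canonical_labels]), `fractions` (counts / tallied total, so
#'   `sum(fractions) + unannotated == 1`), `unannotated` (fraction),
#'   `unannotated_count`, `n` (tallied fragments) and `sample_id`.
#' @export
region_allocation <- function(fragments, annotation,
                              restrict_to_peaks = NULL) {
  stopifnot(inherits(fragments, "FragmentSet"),
            inherits(annotation, "GenomeAnnotation"))
  rec <- fragments$records
  iv <- annotation$intervals
  chroms <- unique(c(iv$chrom, rec$chrom))
  if (!is.null(restrict_to_peaks)) {
    stopifnot(inherits(restrict_to_peaks, "PeakSet"))
    pk <- restrict_to_peaks$intervals
    chroms <- unique(c(chroms, pk$chrom))
    fr_gr <- .as_gr(rec$chrom, rec$start, rec$end, chroms)
    pk_gr <- .as_gr(pk$chrom, pk$start, pk$end, chroms)
    rec <- rec[GenomicRanges::countOverlaps(fr_gr, pk_gr) > 0, ,
               drop = FALSE]
  }
  if (!nrow(rec))
    .err("no fragments to tally (empty set or none overlap peaks)",
         "chipab_analysis_error")
  ann_gr <- .as_gr(iv$chrom, iv$start, iv$end, chroms)
  hit <- GenomicRanges::findOverlaps(.midpoint_gr(rec, chroms), ann_gr,
                                     select = "first")
  lab <- ifelse(is.na(hit), "unannotated", iv$label[hit])
  tab <- table(factor(lab, c(canonical_labels, "unannotated")))
  n <- nrow(rec)
  counts <- setNames(as.integer(tab[canonical_labels]), canonical_labels)
  structure(list(counts = counts,
                 fractions = counts / n,
                 unannotated = as.integer(tab[["unannotated"]]) / n,
                 unannotated_count = as.integer(tab[["unannotated"]]),
                 n = n, sample_id = fragments$sample_id),
            class = "RegionProfile")
}

#' @export
print.RegionProfile <- function(x, ...) {
  cat(sprintf("RegionProfile '%s' (%d fragments):\n", x$sample_id, x$n))
  cat(" ", paste(sprintf("%s %.3f", names(x$fractions), x$fractions),
                 collapse = ", "),
      sprintf(", unannotated %.3f\n", x$unannotated))
  invisible(x)
}

#' Region enrichment over the WCE control
#'
#' Elementwise ratio of per-label read fractions, sample over WCE — the
#' standard "enrichment over input" summary (a value of 15 at TSS means 15
#' times the background share of reads lands at TSS).
#'
#' @param sample,wce `RegionProfile`s.
#' @param labels labels to report (default all seven).
#' @return Named numeric vector of ratios; `Inf` where the WCE fraction
#'   is 0.
#' @export
enrichment_over_wce <- function(sample, wce, labels = canonical_labels) {
  stopifnot(inherits(sample, "RegionProfile"),
            inherits(wce, "RegionProfile"))
  s <- sample$fractions[labels]
  w <- wce$fractions[labels]
  out <- ifelse(w > 0, s / w, Inf)
  setNames(out, labels)
}

#' Region-resolved scatter statistics between two samples
#'
#' For every annotated interval of each requested label, counts fragments
#' (midpoint assignment) in samples `a` and `b`, then summarizes each label
#' — and all requested labels pooled (`overall`) — by the least-squares
#' slope of `b` on `a` through the origin and the squared Pearson
#' correlation. Diverging per-label slopes (e.g. enhancer vs TSS) indicate
#' an antibody-specific region preference.
#'
#' @param a,b `FragmentSet`s.
#' @param annotation a [genome_annotation()].
#' @param labels non-empty vector of labels to profile.
#' @return Object of class `RegionScatter`: list with `per_label` (named
#'   list of data.frames `counts_a`/`counts_b` per interval) and `stats`
#'   (data.frame: label, n_intervals, slope, r_squared).
#' @export
region_scatter_stats <- function(a, b, annotation,
                                 labels = c("TSS", "E")) {
  stopifnot(inherits(a, "FragmentSet"), inherits(b, "FragmentSet"),
            inherits(annotation, "GenomeAnnotation"))
  if (!length(labels)) .err("labels must be non-empty")
  iv <- annotation$intervals
  chroms <- unique(c(iv$chrom, a$records$chrom, b$records$chrom))
  ann_gr <- .as_gr(iv$chrom, iv$start, iv$end, chroms)
  count_by_interval <- function(fr) {
    hit <- GenomicRanges::findOverlaps(.midpoint_gr(fr$records, chroms),
                                       ann_gr, select = "first")
    tabulate(hit[!is.na(hit)], nbins = nrow(iv))
  }
  ca <- count_by_interval(a)
  cb <- count_by_interval(b)
  slope_r2 <- function(x, y) {
    sl <- if (sum(x^2) > 0) sum(x * y) / sum(x^2) else NA_real_
    r2 <- if (length(x) > 1 && stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y)^2 else if (all(y == sl * x)) 1 else 0
    c(slope = sl, r_squared = r2)
  }
  per_label <- list()
  rows <- list()
  for (lab in labels) {
    sel <- which(iv$label == lab)
    if (!length(sel)) {
      warning(sprintf("label %s has no annotated intervals; skipped", lab))
      next
    }
    per_label[[lab]] <- data.frame(chrom = iv$chrom[sel],
                                   start = iv$start[sel],
                                   end = iv$end[sel],
                                   counts_a = ca[sel], counts_b = cb[sel])
    st <- slope_r2(ca[sel], cb[sel])
    rows[[lab]] <- data.frame(label = lab, n_intervals = length(sel),
                              slope = st[["slope"]],
                              r_squared = st[["r_squared"]])
  }
  if (!length(per_label))
    .err("none of the requested labels are annotated",
         "chipab_analysis_error")
  pooled <- which(iv$label %in% names(per_label))
  st <- slope_r2(ca[pooled], cb[pooled])
  rows[["overall"]] <- data.frame(label = "overall",
                                  n_intervals = length(pooled),
                                  slope = st[["slope"]],
                                  r_squared = st[["r_squared"]])
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  structure(list(per_label = per_label, stats = stats),
            class = "RegionScatter")
}

#' @export
print.RegionScatter <- function(x, ...) {
  cat("RegionScatter:\n")
  print.data.frame(x$stats, ...)
  invisible(x)
}
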