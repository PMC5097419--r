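## Fragment-length / region bias diagnostic.
##
## Chromatin shears into shorter fragments in open chromatin, so the
## regional allocation of reads depends on insert size: run on a WCE
## control, the fraction of reads at TSS falls with insert size while the
## fraction in repressed regions rises. This module quantifies that trend:
## bin fragments by insert size, compute per-label read fractions per bin
## (midpoint assignment, with an explicit unannotated bucket so fractions
## partition each bin), then fit fraction ~ bin midpoint per label.

#' Bin fragments by insert size
#'
#' Half-open bins `[low, low + width), [low + width, ...)` up to `high`;
#' the final bin may be partial. Records with insert size outside
#' `[low, high)` are excluded.
#'
#' @param fragments a `FragmentSet`.
#' @param low,high insert-size window in bp (default 70-700, the usual
#'   Illumina size-selection window).
#' @param width bin width in bp.
#' @return List of bins, each a list with elements `low`, `high`,
#'   `fragments` (a `FragmentSet`).
#' @export
bin_by_insert <- function(fragments, low = 70, high = 700, width = 50) {
  stopifnot(inherits(fragments, "FragmentSet"))
  if (width <= 0) .err("width must be > 0")
  if (low >= high) .err("low must be < high")
  lows <- seq(low, high - 1, by = width)
  highs <- pmin(lows + width, high)
  sizes <- insert_sizes(fragments)
  idx <- findInterval(sizes, c(lows, high))
  lapply(seq_along(lows), function(i) {
    sub <- fragments
    sub$records <- fragments$records[which(idx == i & sizes >= low &
                                             sizes < high), , drop = FALSE]
    rownames(sub$records) <- NULL
    list(low = lows[i], high = highs[i], fragments = sub)
  })
}

.new_bias_result <- function(bins, fractions, stats = NULL) {
  structure(list(bins = bins, fractions = fractions, stats = stats),
            class = "BiasResult")
}

#' Per-bin regional read fractions
#'
#' Assigns every fragment in every insert-size bin to exactly one label by
#' its midpoint (an `unannotated` bucket catches midpoints in gaps) and
#' returns the per-bin label fractions. Empty bins yield `NA` fractions and
#' are flagged in the `bins` table.
#'
#' @param binned output of [bin_by_insert()].
#' @param annotation a [genome_annotation()].
#' @return A `BiasResult` with `bins` (data.frame: low, high, mid, n,
#'   missing) and `fractions` (matrix, rows = labels + unannotated,
#'   columns = bins); `stats` is unfilled until [bias_statistics()].
#' @export
region_fraction_by_bin <- function(binned, annotation) {
  if (!length(binned)) .err("no insert-size bins supplied")
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  rows <- c(canonical_labels, "unannotated")
  frac <- matrix(NA_real_, nrow = length(rows), ncol = length(binned),
                 dimnames = list(rows, NULL))
  bins <- data.frame(low = vapply(binned, `[[`, 0, "low"),
                     high = vapply(binned, `[[`, 0, "high"),
                     n = vapply(binned, function(b)
                       n_fragments(b$fragments), 0))
  bins$mid <- (bins$low + bins$high) / 2
  bins$missing <- bins$n == 0
  if (all(bins$missing))
    .err("all insert-size bins are empty", "chipab_analysis_error")
  iv <- annotation$intervals
  chroms <- unique(c(iv$chrom,
                     unlist(lapply(binned, function(b)
                       b$fragments$records$chrom), use.names = FALSE)))
  ann_gr <- .as_gr(iv$chrom, iv$start, iv$end, chroms)
  for (j in seq_along(binned)) {
    if (bins$missing[j]) next
    rec <- binned[[j]]$fragments$records
    hit <- GenomicRanges::findOverlaps(.midpoint_gr(rec, chroms), ann_gr,
                                       select = "first")
    lab <- ifelse(is.na(hit), "unannotated", iv$label[hit])
    tab <- table(factor(lab, rows))
    frac[, j] <- as.vector(tab) / nrow(rec)
  }
  .new_bias_result(bins, frac)
}

#' Linear-trend statistics of the fragment-length bias
#'
#' For each focal label, ordinary least squares of the per-bin read
#' fraction on the bin midpoint, plus the fold change between the first and
#' last bins. A negative TSS slope with a positive R slope is the signature
#' of shearing bias in a WCE library.
#'
#' @param result a `BiasResult` from [region_fraction_by_bin()].
#' @param focal_labels labels to fit (default TSS and R, the open/closed
#'   chromatin anchors).
#' @return The `BiasResult` with `stats` filled: data.frame with `label`,
#'   `slope`, `slope_sign`, `r_squared` (0 for a zero-variance response),
#'   `fold_change` (first-bin / last-bin fraction; `Inf` when the last bin
#'   is 0).
#' @export
bias_statistics <- function(result, focal_labels = c("TSS", "R")) {
  stopifnot(inherits(result, "BiasResult"))
  bad <- setdiff(focal_labels, rownames(result$fractions))
  if (length(bad))
    .err(sprintf("unknown focal label(s): %s", paste(bad, collapse = ", ")))
  ok_bins <- !result$bins$missing
  stats <- do.call(rbind, lapply(focal_labels, function(lab) {
    y <- result$fractions[lab, ok_bins]
    x <- result$bins$mid[ok_bins]
    if (sum(!is.na(y)) < 3)
      .err(sprintf("label %s has fewer than 3 non-missing bins", lab),
           "chipab_analysis_error")
    if (max(y, na.rm = TRUE) - min(y, na.rm = TRUE) < .Machine$double.eps) {
      slope <- 0; r2 <- 0                # zero-variance response
    } else {
      fit <- stats::lm(y ~ x)
      slope <- unname(stats::coef(fit)[2])
      r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    }
    first <- y[which(!is.na(y))[1]]
    last <- y[rev(which(!is.na(y)))[1]]
    fold <- if (last == 0) Inf else first / last
    data.frame(label = lab, slope = slope, slope_sign = sign(slope),
               r_squared = r2, fold_change = fold,
               stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  .new_bias_result(result$bins, result$fractions, stats)
}

#' Full fragment-length bias diagnostic
#'
#' Chains [bin_by_insert()], [region_fraction_by_bin()] and
#' [bias_statistics()]. Typically run on a WCE control.
#'
#' @inheritParams bin_by_insert
#' @inheritParams region_fraction_by_bin
#' @inheritParams bias_statistics
#' @param annotation a [genome_annotation()].
#' @return A complete `BiasResult`.
#' @export
fragment_bias <- function(fragments, annotation, low = 70, high = 700,
                          width = 50, focal_labels = c("TSS", "R")) {
  binned <- bin_by_insert(fragments, low = low, high = high, width = width)
  bias_statistics(region_fraction_by_bin(binned, annotation),
                  focal_labels = focal_labels)
}

#' @export
print.BiasResult <- function(x, ...) {
  cat(sprintf("BiasResult: %d insert-size bins [%d, %d)\n",
              nrow(x$bins), min(x$bins$low), max(x$bins$high)))
  if (!is.null(x$stats)) {
    for (i in seq_len(nrow(x$stats)))
      cat(sprintf("  %-4s slope %+.3e  R^2 %.3f  first/last fold %.2f\n",
                  x$stats$label[i], x$stats$slope[i], x$stats$r_squared[i],
                  x$stats$fold_change[i]))
  }
  invisible(x)
}
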