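## Domain value classes and file I/O.
##
## Coordinate convention: 0-based, half-open [start, end) everywhere (the BED
## convention). BAM's 1-based leftmost positions are converted on read.

#' Construct a fragment set
#'
#' A `FragmentSet` holds one deduplicated paired-end alignment set as genomic
#' fragment intervals: one row per read pair, spanning
#' `[leftmost start, leftmost start + |template length|)`. The insert size of
#' a fragment is `end - start`.
#'
#' @param records data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @param sample_id character scalar identifying the sample.
#' @return An object of class `FragmentSet`.
#' @examples
#' fs <- fragment_set(data.frame(chrom = "chr1", start = c(0, 50),
#'                               end = c(100, 250)),
#'                    chrom_sizes = c(chr1 = 1000))
#' insert_sizes(fs)
#' @export
fragment_set <- function(records, chrom_sizes, sample_id = "sample") {
  if (!is.data.frame(records) ||
      !all(c("chrom", "start", "end") %in% names(records)))
    .err("records must be a data.frame with columns chrom, start, end")
  records <- data.frame(chrom = as.character(records$chrom),
                        start = as.numeric(records$start),
                        end = as.numeric(records$end),
                        stringsAsFactors = FALSE)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    .err("chrom_sizes must be a named vector")
  chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  if (nrow(records)) {
    if (any(records$end <= records$start))
      .err("fragment records must satisfy end > start",
           "chipab_validation_error")
    bad <- !(records$chrom %in% names(chrom_sizes))
    if (any(bad))
      .err(sprintf("fragment chromosome(s) not in chrom_sizes: %s",
                   paste(unique(records$chrom[bad]), collapse = ", ")),
           "chipab_validation_error")
    over <- records$end > chrom_sizes[records$chrom]
    if (any(over))
      .err(sprintf("%d fragment(s) extend past their chromosome end",
                   sum(over)), "chipab_validation_error")
  }
  structure(list(records = records, chrom_sizes = chrom_sizes,
                 sample_id = as.character(sample_id)[1]),
            class = "FragmentSet")
}

#' @rdname fragment_set
#' @param x a `FragmentSet`.
#' @export
n_fragments <- function(x) nrow(x$records)

#' @rdname fragment_set
#' @export
insert_sizes <- function(x) x$records$end - x$records$start

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet '%s': %d fragments on %d chromosome(s)\n",
              x$sample_id, n_fragments(x), length(x$chrom_sizes)))
  if (n_fragments(x)) {
    s <- insert_sizes(x)
    cat(sprintf("  insert size: min %d / median %d / max %d bp\n",
                min(s), as.integer(stats::median(s)), max(s)))
  }
  invisible(x)
}

#' Read paired-end fragments from a BAM or fragment-TSV file
#'
#' For BAM input, each proper read pair contributes one fragment taken from
#' its leftmost mate: `[pos - 1, pos - 1 + TLEN)` with `TLEN > 0`. Mates with
#' negative template length are the complementary half of an already-counted
#' pair and are ignored; duplicate-marked and secondary/supplementary records
#' are excluded; remaining primary records that are unpaired, not properly
#' paired, or have template length 0 are skipped and counted (see attribute
#' `n_skipped` on the result). Fragment-TSV input is tab-separated with no
#' header and columns chrom/start/end (0-based half-open).
#'
#' @param path input file.
#' @param format `"bam"`, `"tsv"`, or `"auto"` (by file extension).
#' @param chrom_sizes named vector of chromosome lengths. Required meaning
#'   for TSV input: if omitted, sizes are inferred as the per-chromosome
#'   maximum end. Ignored for BAM (taken from the header).
#' @param sample_id sample identifier; defaults to the file base name.
#' @return A [fragment_set()] with attribute `n_skipped`.
#' @export
read_fragments <- function(path, format = c("auto", "tsv", "bam"),
                           chrom_sizes = NULL, sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    .err(sprintf("cannot read '%s': no such file", path), "chipab_io_error")
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "tsv"
  if (is.null(sample_id))
    sample_id <- sub("\\.(bam|tsv|txt)$", "", basename(path),
                     ignore.case = TRUE)

  if (format == "tsv") {
    if (file.size(path) == 0) {
      df <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
    } else {
      df <- utils::read.table(path, sep = "\t", header = FALSE,
                              col.names = c("chrom", "start", "end"),
                              colClasses = c("character", "numeric",
                                             "numeric"))
    }
    if (is.null(chrom_sizes)) {
      chrom_sizes <- if (nrow(df))
        tapply(df$end, df$chrom, max) else c(unplaced = 1)
      chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
    }
    out <- fragment_set(df, chrom_sizes, sample_id)
    attr(out, "n_skipped") <- 0L
    return(out)
  }

  ## BAM
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!length(hdr))
    .err("BAM header declares no reference sequences", "chipab_format_error")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE),
    what = c("rname", "pos", "isize", "flag"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  rname <- as.character(b$rname)
  isize <- b$isize
  isize[is.na(isize)] <- 0L
  proper <- bitwAnd(b$flag, 2L) > 0L
  keep <- proper & isize > 0L
  mate <- proper & isize < 0L            # other half of a counted pair
  n_skipped <- sum(!keep & !mate)
  if (!all(rname[keep] %in% names(hdr)))
    .err("BAM record on chromosome absent from header",
         "chipab_format_error")
  df <- data.frame(chrom = rname[keep],
                   start = as.numeric(b$pos[keep]) - 1,
                   end = as.numeric(b$pos[keep]) - 1 +
                     as.numeric(isize[keep]),
                   stringsAsFactors = FALSE)
  out <- fragment_set(df, setNames(as.numeric(hdr), names(hdr)), sample_id)
  attr(out, "n_skipped") <- as.integer(n_skipped)
  if (n_skipped)
    message(sprintf("read_fragments: skipped %d record(s) without a usable ",
                    n_skipped), "template length")
  out
}

#' Write fragments as fragment-TSV
#'
#' @param x a `FragmentSet`.
#' @param path output file; tab-separated chrom/start/end, no header.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(x, path) {
  stopifnot(inherits(x, "FragmentSet"))
  utils::write.table(
    data.frame(x$records$chrom, format(x$records$start, scientific = FALSE,
                                       trim = TRUE),
               format(x$records$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path tab-separated file: chromosome name, length in bp.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  setNames(df$size, df$chrom)
}

#' Construct a genome annotation
#'
#' A `GenomeAnnotation` is a set of disjoint labelled intervals over the
#' seven canonical segmentation labels ([canonical_labels]). Intervals on the
#' same chromosome must not overlap; unannotated gaps are allowed.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `label`
#'   (0-based half-open).
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(intervals) {
  if (!is.data.frame(intervals) ||
      !all(c("chrom", "start", "end", "label") %in% names(intervals)))
    .err("intervals must have columns chrom, start, end, label")
  intervals <- data.frame(chrom = as.character(intervals$chrom),
                          start = as.numeric(intervals$start),
                          end = as.numeric(intervals$end),
                          label = as.character(intervals$label),
                          stringsAsFactors = FALSE)
  if (nrow(intervals)) {
    if (any(intervals$end <= intervals$start))
      .err("annotation intervals must satisfy end > start",
           "chipab_validation_error")
    bad <- setdiff(unique(intervals$label), canonical_labels)
    if (length(bad))
      .err(sprintf("unknown annotation label(s): %s (expected %s)",
                   paste(bad, collapse = ", "),
                   paste(canonical_labels, collapse = "/")),
           "chipab_validation_error")
    intervals <- intervals[order(intervals$chrom, intervals$start), ]
    rownames(intervals) <- NULL
    for (ch in unique(intervals$chrom)) {
      sub <- intervals[intervals$chrom == ch, ]
      if (nrow(sub) > 1) {
        i <- which(sub$start[-1] < sub$end[-nrow(sub)])
        if (length(i))
          .err(sprintf(
            "overlapping annotation intervals on %s: [%d,%d) %s and [%d,%d) %s",
            ch, sub$start[i[1]], sub$end[i[1]], sub$label[i[1]],
            sub$start[i[1] + 1], sub$end[i[1] + 1], sub$label[i[1] + 1]),
            "chipab_validation_error")
      }
    }
  }
  structure(list(intervals = intervals), class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  iv <- x$intervals
  cat(sprintf("GenomeAnnotation: %d intervals, %.0f annotated bp\n",
              nrow(iv), sum(iv$end - iv$start)))
  if (nrow(iv)) {
    bp <- tapply(iv$end - iv$start, factor(iv$label, canonical_labels), sum)
    bp[is.na(bp)] <- 0
    f <- bp / sum(bp)
    cat("  base fractions:",
        paste(sprintf("%s %.3f", names(f), f), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-label base fractions of an annotation
#'
#' Fraction of the annotated genome carrying each canonical label.
#'
#' @param annotation a `GenomeAnnotation`.
#' @return Named numeric vector over [canonical_labels], summing to 1.
#' @export
base_fractions <- function(annotation) {
  iv <- annotation$intervals
  bp <- tapply(iv$end - iv$start, factor(iv$label, canonical_labels), sum)
  bp[is.na(bp)] <- 0
  bp / sum(bp)
}

#' Read a BED4 genome segmentation
#'
#' Labels outside the seven canonical types are rejected unless `label_map`
#' translates them (named character vector, raw label -> canonical label).
#'
#' @param path BED file with the label in column 4.
#' @param label_map optional named character vector mapping raw labels to
#'   canonical ones.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, label_map = NULL) {
  if (!file.exists(path))
    .err(sprintf("cannot read '%s': no such file", path), "chipab_io_error")
  gr <- rtracklayer::import(path, format = "BED")
  lab <- as.character(gr$name)
  if (!is.null(label_map)) {
    hit <- lab %in% names(label_map)
    lab[hit] <- unname(label_map[lab[hit]])
  }
  genome_annotation(data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                               start = BiocGenerics::start(gr) - 1,
                               end = BiocGenerics::end(gr),
                               label = lab, stringsAsFactors = FALSE))
}

#' Write an annotation as BED4
#'
#' @param annotation a `GenomeAnnotation`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  iv <- annotation$intervals
  utils::write.table(
    data.frame(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
               format(iv$end, scientific = FALSE, trim = TRUE), iv$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a peak set
#'
#' A `PeakSet` is a set of half-open 0-based genomic intervals called as
#' enriched; overlapping or bookended input intervals are merged on
#' construction so the stored intervals are disjoint.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(intervals) {
  if (!is.data.frame(intervals) ||
      !all(c("chrom", "start", "end") %in% names(intervals)))
    .err("intervals must have columns chrom, start, end")
  intervals <- data.frame(chrom = as.character(intervals$chrom),
                          start = as.numeric(intervals$start),
                          end = as.numeric(intervals$end),
                          stringsAsFactors = FALSE)
  if (nrow(intervals)) {
    if (any(intervals$end <= intervals$start))
      .err("peak intervals must satisfy end > start",
           "chipab_validation_error")
    gr <- GenomicRanges::reduce(.as_gr(intervals$chrom, intervals$start,
                                       intervals$end))
    intervals <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                            start = BiocGenerics::start(gr) - 1,
                            end = BiocGenerics::end(gr),
                            stringsAsFactors = FALSE)
    intervals <- intervals[order(intervals$chrom, intervals$start), ]
    rownames(intervals) <- NULL
  }
  structure(list(intervals = intervals), class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d merged intervals, %.0f bp\n",
              nrow(x$intervals), bases_in_peaks(x)))
  invisible(x)
}

#' Read / write peak intervals as BED3
#'
#' @param path BED file (first three columns used).
#' @return [read_peaks()]: a [peak_set()]. [write_peaks()]: `path`,
#'   invisibly.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path))
    .err(sprintf("cannot read '%s': no such file", path), "chipab_io_error")
  gr <- rtracklayer::import(path, format = "BED")
  peak_set(data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = BiocGenerics::start(gr) - 1,
                      end = BiocGenerics::end(gr), stringsAsFactors = FALSE))
}

#' @rdname read_peaks
#' @param peaks a `PeakSet`.
#' @export
write_peaks <- function(peaks, path) {
  iv <- peaks$intervals
  utils::write.table(
    data.frame(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
               format(iv$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Insert-size histogram of a fragment set
#'
#' Counts of read pairs per insert length, the currency of insert-size-
#' matched normalization.
#'
#' @param x a `FragmentSet`, or an integer vector of insert sizes.
#' @return Object of class `InsertSizeHistogram`: an integer vector of
#'   counts named by insert size, ascending.
#' @export
insert_histogram <- function(x) {
  sizes <- if (inherits(x, "FragmentSet")) insert_sizes(x) else as.numeric(x)
  if (length(sizes) && any(sizes < 1))
    .err("insert sizes must be >= 1", "chipab_validation_error")
  tab <- table(sizes)
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[order(as.numeric(names(counts)))]
  structure(counts, class = "InsertSizeHistogram")
}

#' Build an insert-size histogram from explicit counts
#'
#' @param counts named vector: insert size -> non-negative count. Zero
#'   counts are dropped.
#' @return An `InsertSizeHistogram`.
#' @export
as_insert_histogram <- function(counts) {
  if (length(counts)) {
    if (is.null(names(counts))) .err("counts must be named by insert size")
    keys <- as.numeric(names(counts))
    if (any(is.na(keys)) || any(keys < 1))
      .err("insert sizes must be integers >= 1", "chipab_validation_error")
    if (any(counts < 0))
      .err("counts must be non-negative", "chipab_validation_error")
    counts <- counts[counts > 0]
    counts <- counts[order(as.numeric(names(counts)))]
  }
  structure(setNames(as.integer(counts), names(counts)),
            class = "InsertSizeHistogram")
}

#' @rdname insert_histogram
#' @param hist an `InsertSizeHistogram`.
#' @export
histogram_total <- function(hist) sum(unclass(hist))

#' @export
print.InsertSizeHistogram <- function(x, ...) {
  cat(sprintf("InsertSizeHistogram: %d distinct sizes, %.0f read pairs\n",
              length(x), histogram_total(x)))
  invisible(x)
}

#' @export
as.data.frame.InsertSizeHistogram <- function(x, ...) {
  data.frame(insert_size = as.integer(names(x)), count = as.integer(x))
}
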