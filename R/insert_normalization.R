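## Insert-size-matched downsampling.
##
## Compared libraries should share both read depth and fragment-size
## distribution, otherwise chromatin shearing bias (short fragments enriched
## in open chromatin) masquerades as signal. The groupwise algorithm: count
## read pairs per insert size in every library, take the per-size minimum
## across the group, then sample each library without replacement down to
## that common histogram. Sizes absent from any one library are dropped.

#' Groupwise insert-size target histogram
#'
#' For every insert size present in all input histograms, the target count
#' is the minimum across inputs; sizes missing from any input are dropped
#' (count 0). Downsampling each library to this target yields libraries
#' with identical insert-size distributions of maximal total depth.
#'
#' @param histograms non-empty list of [insert_histogram()] objects.
#' @return An `InsertSizeHistogram`.
#' @examples
#' h <- lapply(list(c("100" = 3, "150" = 5), c("100" = 2, "150" = 7)),
#'             as_insert_histogram)
#' groupwise_insert_target(h)  # 100 -> 2, 150 -> 5
#' @export
groupwise_insert_target <- function(histograms) {
  if (!length(histograms))
    .err("histograms must be a non-empty list")
  if (!all(vapply(histograms, inherits, TRUE, "InsertSizeHistogram")))
    .err("all elements must be InsertSizeHistogram objects")
  shared <- Reduce(intersect, lapply(histograms, names))
  if (!length(shared)) return(as_insert_histogram(integer(0)))
  mins <- do.call(pmin, lapply(histograms, function(h) unclass(h)[shared]))
  as_insert_histogram(setNames(mins, shared))
}

#' Downsample a fragment set to a target insert-size histogram
#'
#' Within each insert-size stratum, exactly `target[k]` records are drawn
#' uniformly without replacement. Strata are processed in ascending size
#' order under a seeded generator, so results are reproducible.
#'
#' @param fragments a `FragmentSet`.
#' @param target an `InsertSizeHistogram`; every target count must not
#'   exceed the count available at that size.
#' @param seed integer seed.
#' @return A `FragmentSet` whose insert histogram equals `target`.
#' @export
downsample_to_histogram <- function(fragments, target, seed = 1) {
  stopifnot(inherits(fragments, "FragmentSet"),
            inherits(target, "InsertSizeHistogram"))
  sizes <- insert_sizes(fragments)
  keys <- as.numeric(names(target))
  keep <- integer(0)
  .with_seed(seed, {
    for (i in order(keys)) {
      k <- keys[i]
      want <- unclass(target)[[i]]
      if (want == 0) next
      idx <- which(sizes == k)
      if (length(idx) < want)
        .err(sprintf(
          "target requires %d record(s) at insert size %d but only %d available",
          want, k, length(idx)), "chipab_precondition_error")
      keep <- c(keep, if (length(idx) == want) idx
                else idx[sample.int(length(idx), want)])
    }
  })
  out <- fragments
  out$records <- fragments$records[sort(keep), , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Random downsampling to a fixed depth
#'
#' @param fragments a `FragmentSet`.
#' @param n number of records to keep, `0 <= n <= n_fragments(fragments)`.
#' @param seed integer seed.
#' @return A `FragmentSet` of exactly `n` records drawn uniformly without
#'   replacement.
#' @export
downsample_random <- function(fragments, n, seed = 1) {
  stopifnot(inherits(fragments, "FragmentSet"))
  N <- n_fragments(fragments)
  if (n < 0 || n > N)
    .err(sprintf("requested depth %d outside [0, %d]", n, N),
         "chipab_precondition_error")
  keep <- .with_seed(seed, sort(sample.int(N, n)))
  out <- fragments
  out$records <- fragments$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Merge technical replicates
#'
#' Concatenates replicate fragment sets. With `balance = b`, only the first
#' `b` replicates (in replicate-number order, i.e. list order) are merged,
#' so that antibody types with unequal replicate counts can be compared on
#' balanced datasets.
#'
#' @param replicates list of `FragmentSet`s sharing `chrom_sizes`.
#' @param balance integer or `NULL` (merge all).
#' @param sample_id identifier for the merged set.
#' @return A `FragmentSet`.
#' @export
merge_replicates <- function(replicates, balance = NULL,
                             sample_id = "merged") {
  if (!length(replicates) ||
      !all(vapply(replicates, inherits, TRUE, "FragmentSet")))
    .err("replicates must be a non-empty list of FragmentSet objects")
  if (!is.null(balance)) {
    if (balance < 1 || balance > length(replicates))
      .err(sprintf("balance = %d but only %d replicate(s) supplied",
                   balance, length(replicates)))
    replicates <- replicates[seq_len(balance)]
  }
  cs <- replicates[[1]]$chrom_sizes
  for (r in replicates[-1])
    if (!identical(r$chrom_sizes, cs))
      .err("replicates do not share chrom_sizes", "chipab_validation_error")
  fragment_set(do.call(rbind, lapply(replicates, function(r) r$records)),
               cs, sample_id)
}

#' Insert-size-matched normalization of a group of fragment sets
#'
#' Convenience driver: computes the [groupwise_insert_target()] of the
#' group and downsamples every member to it (each with a seed derived from
#' `seed` plus its index). WCE controls should not be passed through this
#' normalization; they serve as untouched backgrounds.
#'
#' @param fragsets list of `FragmentSet`s.
#' @param seed integer seed.
#' @return List of normalized `FragmentSet`s with identical insert-size
#'   histograms, plus attribute `target` (the shared histogram).
#' @export
normalize_group <- function(fragsets, seed = 1) {
  target <- groupwise_insert_target(lapply(fragsets, insert_histogram))
  out <- lapply(seq_along(fragsets), function(i)
    downsample_to_histogram(fragsets[[i]], target, seed = seed + i))
  names(out) <- names(fragsets)
  attr(out, "target") <- target
  out
}
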