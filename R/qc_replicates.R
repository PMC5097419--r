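## Replicate-level quality control.
##
## An aberrant technical replicate typically betrays itself through its
## regional read allocation (e.g. systematically more reads at TSS than its
## siblings). With only 3-4 replicates a plain z-score is unstable, so the
## outlier rule combines a leave-one-out z threshold with an absolute
## floor on the deviation.

#' Flag outlier replicates from region profiles
#'
#' For each replicate and label, the mean and standard deviation of the
#' other replicates' fractions are computed (leave-one-out); the value is
#' flagged when `|value - mean| > k * sd` **and** `|value - mean| >
#' min_abs`. A replicate is flagged when any label flags. No
#' multiple-testing correction is applied across labels.
#'
#' @param profiles list of >= 3 [region_allocation()] profiles, or a
#'   numeric matrix (replicates x labels) of fractions.
#' @param k z-score multiplier (default 3).
#' @param min_abs absolute deviation floor on the fraction scale
#'   (default 0.02), preventing flags in trivially tight groups.
#' @return Object of class `ReplicateQC`: list with `flagged` (logical per
#'   replicate), `details` (data.frame: replicate, label, value, loo_mean,
#'   loo_sd, flagged) and the parameters used.
#' @export
flag_outlier_replicates <- function(profiles, k = 3, min_abs = 0.02) {
  if (is.matrix(profiles)) {
    mat <- profiles
    if (is.null(rownames(mat)))
      rownames(mat) <- sprintf("rep%d", seq_len(nrow(mat)))
  } else {
    if (!length(profiles) ||
        !all(vapply(profiles, inherits, TRUE, "RegionProfile")))
      .err("profiles must be RegionProfile objects or a numeric matrix")
    mat <- do.call(rbind, lapply(profiles, function(p) p$fractions))
    rownames(mat) <- make.unique(vapply(seq_along(profiles), function(i) {
      id <- profiles[[i]]$sample_id
      if (is.null(id) || !nzchar(id)) sprintf("rep%d", i) else id
    }, ""))
  }
  if (nrow(mat) < 3)
    .err("need >= 3 replicates (leave-one-out sd undefined for 2)")
  details <- list()
  for (i in seq_len(nrow(mat))) {
    for (lab in colnames(mat)) {
      others <- mat[-i, lab]
      mu <- mean(others)
      sdev <- stats::sd(others)
      dev <- abs(mat[i, lab] - mu)
      details[[length(details) + 1]] <- data.frame(
        replicate = rownames(mat)[i], label = lab, value = mat[i, lab],
        loo_mean = mu, loo_sd = sdev,
        flagged = dev > k * sdev & dev > min_abs,
        stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, details)
  rownames(details) <- NULL
  flagged <- tapply(details$flagged, factor(details$replicate,
                                            rownames(mat)), any)
  structure(list(flagged = setNames(as.logical(flagged), rownames(mat)),
                 details = details, k = k, min_abs = min_abs),
            class = "ReplicateQC")
}

#' @export
print.ReplicateQC <- function(x, ...) {
  n_bad <- sum(x$flagged)
  cat(sprintf("ReplicateQC (k = %g, min_abs = %g): %d of %d replicate(s) flagged\n",
              x$k, x$min_abs, n_bad, length(x$flagged)))
  if (n_bad) {
    bad <- x$details[x$details$flagged, ]
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  %s: %s = %.3f vs leave-one-out %.3f +/- %.4f\n",
                  bad$replicate[i], bad$label[i], bad$value[i],
                  bad$loo_mean[i], bad$loo_sd[i]))
  }
  invisible(x)
}

#' Compare per-replicate scores between two groups
#'
#' Welch (unequal-variance) two-sample t test, two-sided — the default
#' choice for comparing, e.g., SPOT scores between monoclonal and
#' polyclonal replicate groups. Degenerate inputs (zero variance in both
#' groups) are handled by convention: equal means give `t = 0, p = 1`;
#' unequal means give `t = +/-Inf, p = 0` (perfectly separated constant
#' groups).
#'
#' @param scores_a,scores_b numeric vectors, each of length >= 2.
#' @return List with `t`, `p_value`, `df`, `mean_a`, `mean_b`, `method`.
#' @export
group_compare <- function(scores_a, scores_b) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    .err("each group needs >= 2 values")
  va <- stats::var(scores_a); vb <- stats::var(scores_b)
  ma <- mean(scores_a); mb <- mean(scores_b)
  if (va == 0 && vb == 0) {
    t <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
    return(list(t = t, p_value = p, df = NA_real_, mean_a = ma,
                mean_b = mb, method = "Welch t test (degenerate inputs)"))
  }
  ht <- stats::t.test(scores_a, scores_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_a = ma, mean_b = mb,
       method = "Welch two-sample t test, two-sided")
}
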