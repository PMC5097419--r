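## Synthetic fragment generator.
##
## Emulates the statistical structure the antibody-comparison analyses
## assume: a region-labelled genome dominated by repressed chromatin,
## region-dependent fragment-length distributions (shorter fragments in open
## chromatin, i.e. at TSS), mark-specific enrichment over a uniform WCE
## background, replicate-level overdispersion, and an antibody-specific
## region preference ("immunogen effect") expressed as per-label multipliers.

.default_proportions <- c(R = 0.84, T = 0.08, E = 0.03, WE = 0.02,
                          PF = 0.015, TSS = 0.01, CTCF = 0.005)
.default_seg_mean <- c(R = 20000, T = 8000, E = 1500, WE = 1500,
                       PF = 1000, TSS = 500, CTCF = 800)
## log-normal location per label; open chromatin shears shorter, so the TSS
## location sits ~0.5 log-units below repressed regions
.default_frag_meanlog <- c(R = 5.6, T = 5.5, E = 5.3, WE = 5.3,
                           PF = 5.3, TSS = 5.1, CTCF = 5.4)
.default_frag_sdlog <- c(R = 0.5, T = 0.5, E = 0.5, WE = 0.5,
                         PF = 0.5, TSS = 0.5, CTCF = 0.5)
## H3K4me3-like default mark: strong TSS enrichment, some promoter-flanking
## and enhancer signal
.default_enrichment <- c(R = 1, T = 1, E = 2, WE = 1, PF = 4,
                         TSS = 20, CTCF = 1)

## merge a partial user vector over defaults; always returned in
## canonical_labels order so label-keyed vectors can be combined elementwise
.fill_labels <- function(x, default) {
  out <- default
  if (!is.null(x)) {
    bad <- setdiff(names(x), canonical_labels)
    if (length(bad))
      .err(sprintf("unknown label(s) in config: %s",
                   paste(bad, collapse = ", ")), "chipab_config_error")
    out[names(x)] <- x
  }
  out[canonical_labels]
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic genome/fragment generator.
#' Defaults emulate the study conditions the analyses target: 84% of the
#' annotated genome repressed (R) and ~1% at transcription start sites
#' (TSS), fragment lengths log-normal within the 70-700 bp sequencing
#' window with the TSS location shifted short (the shearing bias of open
#' chromatin), and an H3K4me3-like enrichment profile for ChIP mode.
#'
#' @param genome_length total genome size in bp.
#' @param n_chromosomes number of equally sized chromosomes.
#' @param region_proportions named vector, label -> fraction of the
#'   annotated genome; may sum to < 1 (remainder unannotated). Labels not
#'   named keep their defaults only when the argument is `NULL`; a supplied
#'   vector is used as-is (missing labels get 0).
#' @param mean_segment_length named vector, label -> mean segment length bp.
#' @param fragment_meanlog,fragment_sdlog named vectors giving the
#'   log-normal location/scale of fragment length per label (truncated to
#'   `[min_insert, max_insert]`). Partial vectors override defaults.
#' @param min_insert,max_insert insert-size truncation window in bp.
#' @param enrichment named vector of relative sampling weights for ChIP mode
#'   (WCE mode uses weight 1 everywhere). Partial vectors override defaults.
#' @param n_fragments number of fragments to draw per sample.
#' @param replicate_noise overdispersion factor >= 1; per-replicate,
#'   per-label weights are jittered by a gamma variate with mean 1 and
#'   variance `(replicate_noise - 1) / 10` (1 = no jitter).
#' @param seed integer seed; every simulation derived from the config is
#'   reproducible given it.
#' @return Object of class `SimulationConfig` (a list of the above).
#' @export
sim_config <- function(genome_length = 1e7, n_chromosomes = 4,
                       region_proportions = NULL,
                       mean_segment_length = NULL,
                       fragment_meanlog = NULL, fragment_sdlog = NULL,
                       min_insert = 70, max_insert = 700,
                       enrichment = NULL, n_fragments = 1e6,
                       replicate_noise = 1, seed = 1) {
  props <- if (is.null(region_proportions))
    .default_proportions[canonical_labels] else {
    bad <- setdiff(names(region_proportions), canonical_labels)
    if (length(bad) || is.null(names(region_proportions)))
      .err(sprintf("region_proportions must be named with canonical labels"),
           "chipab_config_error")
    p <- setNames(numeric(length(canonical_labels)), canonical_labels)
    p[names(region_proportions)] <- region_proportions
    p
  }
  if (any(props < 0) || sum(props) > 1 + 1e-9)
    .err("region_proportions must be non-negative and sum to <= 1",
         "chipab_config_error")
  if (min_insert >= max_insert)
    .err("min_insert must be < max_insert", "chipab_config_error")
  enr <- .fill_labels(enrichment, .default_enrichment)
  if (any(enr <= 0))
    .err("enrichment weights must be > 0", "chipab_config_error")
  if (replicate_noise < 1)
    .err("replicate_noise must be >= 1", "chipab_config_error")
  structure(list(
    genome_length = genome_length,
    n_chromosomes = as.integer(n_chromosomes),
    region_proportions = props,
    mean_segment_length = .fill_labels(mean_segment_length,
                                       .default_seg_mean),
    fragment_meanlog = .fill_labels(fragment_meanlog,
                                    .default_frag_meanlog),
    fragment_sdlog = .fill_labels(fragment_sdlog, .default_frag_sdlog),
    min_insert = min_insert, max_insert = max_insert,
    enrichment = enr, n_fragments = as.numeric(n_fragments),
    replicate_noise = replicate_noise, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf("SimulationConfig: %.0f bp genome on %d chromosome(s), %g fragments, seed %d\n",
              x$genome_length, x$n_chromosomes, x$n_fragments, x$seed))
  cat("  proportions:",
      paste(sprintf("%s %.3f", names(x$region_proportions),
                    x$region_proportions), collapse = ", "), "\n")
  invisible(x)
}

.chrom_lengths <- function(config) {
  n <- config$n_chromosomes
  len <- rep(floor(config$genome_length / n), n)
  len[n] <- config$genome_length - sum(len[-n])
  setNames(len, paste0("chr", seq_len(n)))
}

#' Simulate a labelled genome segmentation
#'
#' Lays alternating segments along each chromosome. Segment types are drawn
#' with probability proportional to `proportion / mean_segment_length` (so
#' realized base fractions converge to `region_proportions`) and segment
#' lengths are exponential with the configured per-label mean; the remainder
#' `1 - sum(proportions)` is emitted as unannotated gaps.
#'
#' @param config a [sim_config()].
#' @return A [genome_annotation()].
#' @export
make_annotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  props <- config$region_proportions
  gap_p <- max(0, 1 - sum(props))
  labs <- names(props)[props > 0]
  p <- props[labs]
  m <- config$mean_segment_length[labs]
  if (gap_p > 1e-12) {
    labs <- c(labs, NA_character_)
    p <- c(p, gap_p)
    m <- c(m, 5000)                      # gap mean segment length
  }
  q <- (p / m) / sum(p / m)              # segment-type frequency
  lens <- .chrom_lengths(config)
  .with_seed(config$seed, {
    out <- vector("list", length(lens))
    for (ci in seq_along(lens)) {
      L <- lens[ci]
      pos <- 0
      starts <- ends <- numeric(0)
      seg_lab <- character(0)
      while (pos < L) {
        k <- max(64, ceiling((L - pos) / sum(q * m) * 1.4))
        li <- sample.int(length(labs), k, replace = TRUE, prob = q)
        sl <- pmax(1, ceiling(stats::rexp(k, rate = 1 / m[li])))
        cs <- pos + cumsum(sl)
        take <- which(cs - sl < L)
        starts <- c(starts, (cs - sl)[take])
        ends <- c(ends, pmin(cs[take], L))
        seg_lab <- c(seg_lab, labs[li][take])
        pos <- cs[length(cs)]
      }
      keep <- !is.na(seg_lab) & ends > starts
      out[[ci]] <- data.frame(chrom = names(lens)[ci], start = starts[keep],
                              end = ends[keep], label = seg_lab[keep],
                              stringsAsFactors = FALSE)
    }
    genome_annotation(do.call(rbind, out))
  })
}

## integer fragment lengths from a label's truncated log-normal
.draw_lengths <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  x <- stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
  pmin(hi, pmax(lo, round(x)))
}

#' Simulate a ChIP or WCE fragment set over an annotation
#'
#' Each fragment is generated by (1) drawing a label with probability
#' proportional to its annotated base fraction times its enrichment weight
#' (all weights 1 in WCE mode), (2) picking an interval of that label with
#' probability proportional to its length and a start uniform within it,
#' and (3) drawing the fragment length from the label's truncated
#' log-normal. Fragments that would overhang the chromosome end are shifted
#' left, never shortened, so insert sizes always lie in
#' `[min_insert, max_insert]`.
#'
#' @param annotation a [genome_annotation()] consistent with `config`.
#' @param config a [sim_config()].
#' @param mode `"chip"` (use enrichment weights) or `"wce"` (uniform).
#' @param seed integer seed; defaults to `config$seed`.
#' @param enrichment optional named weight vector overriding
#'   `config$enrichment` (used for replicate jitter and antibody shifts).
#' @param sample_id sample identifier for the output.
#' @return A [fragment_set()] with exactly `config$n_fragments` records.
#' @export
simulate_fragments <- function(annotation, config,
                               mode = c("chip", "wce"),
                               seed = config$seed, enrichment = NULL,
                               sample_id = NULL) {
  stopifnot(inherits(annotation, "GenomeAnnotation"),
            inherits(config, "SimulationConfig"))
  mode <- match.arg(mode)
  n <- config$n_fragments
  if (n <= 0) .err("n_fragments must be > 0", "chipab_config_error")
  if (is.null(sample_id)) sample_id <- mode
  iv <- annotation$intervals
  if (!nrow(iv)) .err("annotation has no intervals", "chipab_config_error")
  chrom_sizes <- .chrom_lengths(config)
  if (!all(iv$chrom %in% names(chrom_sizes)))
    .err("annotation chromosomes inconsistent with config",
         "chipab_config_error")
  w <- if (mode == "wce") setNames(rep(1, length(canonical_labels)),
                                   canonical_labels)
       else .fill_labels(enrichment, config$enrichment)
  widths <- iv$end - iv$start
  bp <- tapply(widths, factor(iv$label, canonical_labels), sum)
  bp[is.na(bp)] <- 0
  prob <- bp / sum(bp) * w[canonical_labels]
  lo <- config$min_insert; hi <- config$max_insert

  .with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, prob))
    recs <- vector("list", length(canonical_labels))
    for (k in seq_along(canonical_labels)) {
      ck <- counts[k]
      if (ck == 0) next
      lab <- canonical_labels[k]
      idx_lab <- which(iv$label == lab)
      pick <- idx_lab[sample.int(length(idx_lab), ck, replace = TRUE,
                                 prob = widths[idx_lab])]
      start <- iv$start[pick] +
        floor(stats::runif(ck) * (iv$end[pick] - iv$start[pick]))
      len <- .draw_lengths(ck, config$fragment_meanlog[lab],
                           config$fragment_sdlog[lab], lo, hi)
      clen <- chrom_sizes[iv$chrom[pick]]
      start <- pmax(0, pmin(start, clen - len))
      recs[[k]] <- data.frame(chrom = iv$chrom[pick], start = start,
                              end = start + len, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs)
    df <- df[order(df$chrom, df$start, df$end), ]
    rownames(df) <- NULL
    fragment_set(df, chrom_sizes, sample_id)
  })
}

#' Simulate a replicated ChIP experiment with a WCE control
#'
#' Draws `n_replicates` ChIP fragment sets over a shared simulated
#' annotation, each with per-label weights
#' `enrichment * antibody_shift * jitter`, where the jitter is a gamma
#' variate with mean 1 and variance `(replicate_noise - 1) / 10`, plus one
#' un-enriched WCE control. `antibody_shift` expresses an immunogen effect:
#' e.g. `c(E = 2)` doubles the relative pull-down of enhancer fragments.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of ChIP replicates (>= 1).
#' @param antibody_shift named per-label multipliers (default: all 1).
#' @return List with elements `replicates` (list of `FragmentSet`), `wce`
#'   (a `FragmentSet`) and `truth` (the shared [genome_annotation()]).
#' @export
simulate_experiment <- function(config, n_replicates = 2,
                                antibody_shift = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (n_replicates < 1)
    .err("n_replicates must be >= 1", "chipab_config_error")
  shift <- .fill_labels(antibody_shift,
                        setNames(rep(1, 7), canonical_labels))
  truth <- make_annotation(config)
  v <- (config$replicate_noise - 1) / 10
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    seed_i <- config$seed + i
    jit <- if (v > 0)
      .with_seed(seed_i * 2 + 1,
                 stats::rgamma(7, shape = 1 / v, rate = 1 / v))
      else rep(1, 7)
    w <- config$enrichment[canonical_labels] * shift[canonical_labels] *
      setNames(jit, canonical_labels)
    reps[[i]] <- simulate_fragments(truth, config, mode = "chip",
                                    seed = seed_i, enrichment = w,
                                    sample_id = sprintf("rep%d", i))
  }
  wce <- simulate_fragments(truth, config, mode = "wce",
                            seed = config$seed + n_replicates + 1,
                            sample_id = "wce")
  list(replicates = reps, wce = wce, truth = truth)
}
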