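# Divergence-interval scan: threshold, seed runs, merge short interruptions,
# measure. This is the core interval-identification algorithm.

#' Parameters of the divergence-interval scan
#'
#' A variant qualifies when its |delta p| exceeds `high_threshold` (strictly,
#' "greater than"). Maximal runs of consecutively indexed qualifying variants
#' seed intervals; two neighbouring intervals are merged, together with the
#' interruption between them, when the interruption holds at most
#' `max_interruption` variants ("fewer than three" at the default of 2) and
#' every one of them exceeds `interruption_threshold`.
#'
#' Adjacency is counted in variant-table index, not bp: interruptions are
#' measured in numbers of variants, which is only meaningful on the index
#' scale.
#'
#' @param high_threshold |delta p| cutoff for qualifying variants.
#' @param interruption_threshold minimum |delta p| (strict) inside a
#'   mergeable interruption.
#' @param max_interruption largest number of variants a mergeable
#'   interruption may contain.
#' @return object of class `scan_params`.
#' @export
scan_params <- function(high_threshold = 0.8, interruption_threshold = 0.5,
                        max_interruption = 2L) {
  assert_that(interruption_threshold > 0 &&
                interruption_threshold < high_threshold &&
                high_threshold <= 1,
              "need 0 < interruption_threshold < high_threshold <= 1")
  assert_that(max_interruption >= 0, "max_interruption must be >= 0")
  structure(list(high_threshold = high_threshold,
                 interruption_threshold = interruption_threshold,
                 max_interruption = as.integer(max_interruption)),
            class = "scan_params")
}

# merge decision for the gap (index run) between two seed runs; the rule
# depends only on the gap itself, never on the extent of the flanking
# intervals, which is what makes the merge order-independent
gap_mergeable <- function(delta_p_gap, params) {
  length(delta_p_gap) <= params$max_interruption &&
    all(delta_p_gap > params$interruption_threshold)
}

#' Identify intervals of near-fixed allele-frequency divergence
#'
#' Per arm: (1) mark variants with `delta_p > high_threshold`; (2) take
#' maximal runs of consecutively indexed marked variants as seed intervals
#' (single qualifying variants form length-0, one-variant intervals);
#' (3) repeatedly merge neighbouring intervals whose intervening
#' interruption has at most `max_interruption` variants, all with
#' `delta_p > interruption_threshold`, until no merge applies (the rule
#' qualifies a gap independently of interval extent, so the fixpoint does
#' not depend on merge order); (4) report each interval with its bp span
#' (distance between its first and last member variant) and summary
#' statistics over all member variants, merged interruptions included.
#'
#' @param variants variant table sorted by (arm, pos) with a `delta_p`
#'   column (see [read_variants()]).
#' @param params a [scan_params()].
#' @return data.frame with one row per interval: `interval_id`, `arm`,
#'   `start_pos`, `end_pos`, `span_bp`, `n_variants`, `min_delta_p`,
#'   `mean_delta_p`, `genes` (empty until [assign_genes()]).
#' @export
scan_intervals <- function(variants, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  empty <- data.frame(interval_id = character(), arm = character(),
                      start_pos = numeric(), end_pos = numeric(),
                      span_bp = numeric(), n_variants = integer(),
                      min_delta_p = numeric(), mean_delta_p = numeric(),
                      genes = character(), stringsAsFactors = FALSE)
  if (is.null(variants) || nrow(variants) == 0) return(empty)
  assert_that(!is.null(variants$delta_p), "variants lack delta_p")
  ord <- order(factor(variants$arm, levels = unique(variants$arm)),
               variants$pos)
  assert_that(identical(ord, seq_len(nrow(variants))),
              "variants must be sorted by (arm, pos)")

  out <- list()
  for (arm in unique(variants$arm)) {
    v <- variants[variants$arm == arm, , drop = FALSE]
    runs <- scan_arm_runs(v$delta_p, params)
    if (is.null(runs)) next
    out[[arm]] <- data.frame(
      arm = arm,
      start_pos = v$pos[runs[, 1]],
      end_pos = v$pos[runs[, 2]],
      n_variants = runs[, 2] - runs[, 1] + 1L,
      min_delta_p = vapply(seq_len(nrow(runs)), function(i)
        min(v$delta_p[runs[i, 1]:runs[i, 2]]), numeric(1)),
      mean_delta_p = vapply(seq_len(nrow(runs)), function(i)
        mean(v$delta_p[runs[i, 1]:runs[i, 2]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$span_bp <- res$end_pos - res$start_pos
  res$interval_id <- paste0(res$arm, ":", res$start_pos, "-", res$end_pos)
  res$genes <- ""
  res[, names(empty)]
}

# seed + merge on one arm; returns matrix of [start_index, end_index] runs
scan_arm_runs <- function(delta_p, params) {
  marked <- delta_p > params$high_threshold
  if (!any(marked)) return(NULL)
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seeds <- cbind(starts[r$values], ends[r$values])
  # left-to-right merge to fixpoint: absorb the gap to the previous interval
  # whenever it qualifies
  merged <- seeds[1, , drop = FALSE]
  for (i in seq_len(nrow(seeds))[-1]) {
    k <- nrow(merged)
    gap <- (merged[k, 2] + 1L):(seeds[i, 1] - 1L)
    if (gap_mergeable(delta_p[gap], params)) {
      merged[k, 2] <- seeds[i, 2]
    } else {
      merged <- rbind(merged, seeds[i, , drop = FALSE])
    }
  }
  merged
}

#' Attach overlapping genes to divergence intervals
#'
#' A gene is listed for an interval when `[start - flank_bp, end + flank_bp]`
#' overlaps `[start_pos, end_pos]` by at least 1 bp (coordinates 1-based
#' inclusive on both sides). Genes on arms absent from the interval table
#' are simply never matched; annotations on arms absent from the scan input
#' produce a warning and are skipped.
#'
#' @param intervals output of [scan_intervals()].
#' @param annotations gene-annotation table (see [read_annotations()]).
#' @param flank_bp symmetric flank added to each gene before testing
#'   overlap. The assignment rule behind published gene-in-interval counts
#'   is not standardised; the flank is exposed rather than guessed.
#' @param known_arms optional character vector of valid arm names (defaults
#'   to the arms seen in `intervals`); annotations outside it are skipped
#'   with a warning.
#' @return `intervals` with the `genes` column filled (comma-separated
#'   gene ids).
#' @export
assign_genes <- function(intervals, annotations, flank_bp = 0,
                         known_arms = NULL) {
  if (nrow(intervals) == 0) return(intervals)
  known_arms <- known_arms %||% unique(intervals$arm)
  unknown <- !(annotations$arm %in% known_arms)
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) on arms unknown to the scan skipped: ",
            paste(utils::head(unique(annotations$arm[unknown]), 3),
                  collapse = ", "), call. = FALSE)
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  intervals$genes <- vapply(seq_len(nrow(intervals)), function(i) {
    hit <- annotations$arm == intervals$arm[i] &
      annotations$start - flank_bp <= intervals$end_pos[i] &
      annotations$end + flank_bp >= intervals$start_pos[i]
    paste(annotations$gene_id[hit], collapse = ",")
  }, character(1))
  intervals
}

#' Genes contained in any divergence interval
#' @param intervals interval table after [assign_genes()].
#' @return character vector of unique gene ids.
#' @export
interval_gene_ids <- function(intervals) {
  unique(unlist(strsplit(intervals$genes[nzchar(intervals$genes)], ",")))
}

#' Score recovery of planted sweeps by the interval scan
#'
#' A planted sweep counts as recovered when a reported interval on the same
#' arm overlaps it and the interval's first/last member variants are within
#' `boundary_tol` variant indices of the sweep's first/last in-sweep
#' variants.
#'
#' @param variants table from [simulate_frequencies()] (needs the `sweep`
#'   truth column).
#' @param intervals table from [scan_intervals()].
#' @param boundary_tol allowed boundary error in variant indices.
#' @return data.frame with one row per planted sweep: `sweep`, `arm`,
#'   `n_variants`, `recovered`, `start_err`, `end_err` (variant indices).
#' @export
sweep_recovery <- function(variants, intervals, boundary_tol = 2L) {
  assert_that(!is.null(variants$sweep), "variants lack the sweep truth column")
  sweeps <- unique(stats::na.omit(variants$sweep))
  res <- lapply(sweeps, function(s) {
    vi <- which(variants$sweep == s)
    arm <- variants$arm[vi[1]]
    v_arm <- which(variants$arm == arm)
    first <- match(vi[1], v_arm)
    last <- match(vi[length(vi)], v_arm)
    cand <- intervals[intervals$arm == arm, , drop = FALSE]
    start_err <- end_err <- NA_integer_
    recovered <- FALSE
    if (nrow(cand)) {
      ci_first <- match(cand$start_pos, variants$pos[v_arm])
      ci_last <- match(cand$end_pos, variants$pos[v_arm])
      ov <- which(ci_first <= last & ci_last >= first)
      if (length(ov)) {
        j <- ov[which.max(ci_last[ov] - ci_first[ov])]
        start_err <- abs(ci_first[j] - first)
        end_err <- abs(ci_last[j] - last)
        recovered <- start_err <= boundary_tol && end_err <= boundary_tol
      }
    }
    data.frame(sweep = s, arm = arm, n_variants = length(vi),
               recovered = recovered, start_err = start_err,
               end_err = end_err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
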