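# Genome-side synthetic data: replicate-line allele frequencies with drift
# noise, binomial sequencing noise, and planted sweep intervals.

# Beta draw around a center with concentration c; exact at the boundaries.
rbeta_center <- function(n, center, c) {
  out <- numeric(n)
  fixed <- center <= 0 | center >= 1
  out[fixed] <- center[fixed]
  if (any(!fixed)) {
    out[!fixed] <- stats::rbeta(sum(!fixed),
                                center[!fixed] * c, (1 - center[!fixed]) * c)
  }
  out
}

#' Simulate replicate-line allele-frequency tables with planted sweeps
#'
#' For each variant an ancestral frequency `p0` is drawn uniformly on
#' (0.05, 0.95). Each control-line true frequency is drawn from
#' Beta(p0*c, (1-p0)*c) with `c` the drift concentration; selected-line
#' frequencies are drawn the same way outside sweeps. Inside a planted sweep
#' the selected lines are centred on the boundary opposite the control mean,
#' displaced by the sweep's target divergence `d` (the ancestral frequency is
#' drawn from the region where a displacement of `d` is feasible), so the
#' expected |delta p| of in-sweep variants equals `d` up to noise. Observed
#' frequencies add binomial read-sampling noise at the configured coverage.
#'
#' Simulated per-variant divergence P-values (`p_divergence`) emulate a prior
#' single-variant divergence test: log10 P uniform on (-12, -6) inside
#' sweeps and (-4, 0) outside. They are carried as an opaque input column,
#' exactly as the downstream filter treats them.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `arm`, `pos`, `sel_1..n`, `ctl_1..m`,
#'   `delta_p`, `p_divergence`, and `sweep` (planted sweep id, NA outside
#'   sweeps); rows sorted by (arm, pos), positions unique within arm.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  ns <- config$n_sel_lines
  nc <- config$n_ctl_lines
  cdrift <- config$drift_concentration
  cov <- config$coverage

  pieces <- vector("list", nrow(config$arms))
  for (i in seq_len(nrow(config$arms))) {
    arm <- config$arms$arm[i]
    n <- config$arms$n_variants[i]
    pos <- sort(sample.int(config$arms$length_bp[i], n))
    p0 <- stats::runif(n, 0.05, 0.95)
    p_sel_center <- p0
    sweep_id <- rep(NA_character_, n)
    log10p <- -stats::runif(n, 0, 4)

    if (!is.null(config$sweeps)) {
      sw <- config$sweeps[config$sweeps$arm == arm, , drop = FALSE]
      for (j in seq_len(nrow(sw))) {
        idx <- which(pos >= sw$start[j] & pos <= sw$end[j])
        if (!length(idx)) next
        d <- sw$divergence[j]
        k <- length(idx)
        # ancestral frequency where a displacement of d stays inside [0,1]
        hi <- min(0.45, 1 - d)
        lo <- min(0.02, hi)
        base <- if (hi > lo) stats::runif(k, lo, hi) else rep(1 - d, k)
        flip <- stats::runif(k) < 0.5
        p0[idx] <- ifelse(flip, 1 - base, base)
        p_sel_center[idx] <- ifelse(flip, 1 - (base + d), base + d)
        sweep_id[idx] <- paste0(arm, ":", sw$start[j], "-", sw$end[j])
        log10p[idx] <- -stats::runif(k, 6, 12)
      }
    }

    true_sel <- matrix(rbeta_center(n * ns, rep(p_sel_center, ns), cdrift),
                       n, ns)
    true_ctl <- matrix(rbeta_center(n * nc, rep(p0, nc), cdrift), n, nc)
    obs_sel <- matrix(stats::rbinom(n * ns, cov, true_sel) / cov, n, ns)
    obs_ctl <- matrix(stats::rbinom(n * nc, cov, true_ctl) / cov, n, nc)
    colnames(obs_sel) <- paste0("sel_", seq_len(ns))
    colnames(obs_ctl) <- paste0("ctl_", seq_len(nc))

    pieces[[i]] <- data.frame(
      arm = arm, pos = pos, obs_sel, obs_ctl,
      delta_p = abs(rowMeans(obs_sel) - rowMeans(obs_ctl)),
      p_divergence = 10^log10p,
      sweep = sweep_id,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulate a synthetic gene-annotation table
#'
#' Places non-overlapping genes uniformly along each arm and assigns
#' expression and RNAi-stock availability flags at realistic marginal rates
#' (about 60% of genes expressed in each reproductive tissue, 70% with a
#' usable RNAi stock). The table is entirely synthetic; in a real analysis
#' these flags would come from expression atlases and stock-centre catalogs.
#'
#' @param config a [sim_config()].
#' @param variants optional variant table from [simulate_frequencies()]; when
#'   supplied, `min_snp_p` (smallest `p_divergence` among a gene's variants)
#'   is filled via [gene_min_snp_p()].
#' @return data.frame of gene annotations (see [read_annotations()] schema).
#' @export
simulate_annotations <- function(config, variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  pieces <- vector("list", nrow(config$arms))
  idx0 <- 0L
  for (i in seq_len(nrow(config$arms))) {
    arm <- config$arms$arm[i]
    len <- config$arms$length_bp[i]
    ng <- config$genes_per_arm
    width <- round(stats::runif(ng, 2e3, 2e4))
    gap <- len / ng
    start <- round((seq_len(ng) - 1) * gap +
                     stats::runif(ng, 1, pmax(2, gap - width)))
    end <- pmin(start + width - 1, len)
    pieces[[i]] <- data.frame(
      gene_id = sprintf("SYNG%05d", idx0 + seq_len(ng)),
      symbol = sprintf("sg%d.%s", idx0 + seq_len(ng), arm),
      arm = arm, start = start, end = end,
      expressed_ovary = stats::runif(ng) < 0.6,
      expressed_accessory_gland = stats::runif(ng) < 0.6,
      rnai_available = stats::runif(ng) < 0.7,
      stringsAsFactors = FALSE
    )
    idx0 <- idx0 + ng
  }
  ann <- do.call(rbind, pieces)
  rownames(ann) <- NULL
  ann$min_snp_p <- NA_real_
  if (!is.null(variants)) ann$min_snp_p <- gene_min_snp_p(variants, ann)
  ann
}

#' Smallest per-variant divergence P-value within each gene
#'
#' @param variants variant table with `arm`, `pos`, `p_divergence`.
#' @param annotations gene annotation table.
#' @param flank_bp extend each gene this many bp on both sides.
#' @return numeric vector aligned with `annotations` rows (NA when the gene
#'   spans no variant with a P-value).
#' @export
gene_min_snp_p <- function(variants, annotations, flank_bp = 0) {
  if (is.null(variants$p_divergence)) {
    return(rep(NA_real_, nrow(annotations)))
  }
  vapply(seq_len(nrow(annotations)), function(i) {
    sel <- variants$arm == annotations$arm[i] &
      variants$pos >= annotations$start[i] - flank_bp &
      variants$pos <= annotations$end[i] + flank_bp
    p <- variants$p_divergence[sel]
    p <- p[!is.na(p)]
    if (length(p)) min(p) else NA_real_
  }, numeric(1))
}
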