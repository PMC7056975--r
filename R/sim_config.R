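#' Baseline phenotype parameters for the synthetic screen
#'
#' Means and variance components used by [simulate_screen()] and
#' [simulate_ob_productivity()]. Units: lifespan in days, productivity in
#' adult offspring per female per vial per week, qPCR in Ct cycles.
#'
#' Defaults emulate unselected control-population flies at 25 degrees C:
#' mean lifespan near eight weeks with females outliving males, weekly
#' productivity declining with age, and a reference gene near Ct 16.
#'
#' @param lifespan_f,lifespan_m mean lifespan (days) by sex.
#' @param vial_sd between-vial standard deviation of lifespan (days); the
#'   vial effect is shared by all six flies in a vial.
#' @param lifespan_sd residual (fly-to-fly) lifespan standard deviation.
#' @param prod_week_means mean weekly offspring/female; length sets the
#'   number of assay weeks.
#' @param prod_sd residual standard deviation of weekly offspring/female.
#' @param ob_week_means weekly means for the selected-vs-control (O/B)
#'   productivity assay (four weekly lays).
#' @param ct_ref mean Ct of the internal-control (housekeeping) gene.
#' @param dct_base mean Ct separation of a target gene above the reference.
#' @param dct_gene_sd between-gene spread of baseline target expression.
#' @param qpcr_bio_sd between-biological-replicate standard deviation (Ct).
#' @param qpcr_tech_sd technical (well-to-well) standard deviation (Ct).
#' @param qpcr_input_sd between-biological-replicate RNA-input shift (Ct),
#'   shared by target and reference so normalization cancels it.
#' @return a named list.
#' @export
sim_baseline <- function(lifespan_f = 55, lifespan_m = 50,
                         vial_sd = 3, lifespan_sd = 12,
                         prod_week_means = c(45, 38, 30, 22, 14, 7),
                         prod_sd = 8,
                         ob_week_means = c(40, 34, 25, 15),
                         ct_ref = 16, dct_base = 5, dct_gene_sd = 1,
                         qpcr_bio_sd = 0.3, qpcr_tech_sd = 0.2,
                         qpcr_input_sd = 0.5) {
  out <- as.list(environment())
  assert_that(all(out$prod_week_means >= 0) && out$prod_sd > 0,
              "productivity baselines must be non-negative with positive sd")
  assert_that(out$vial_sd >= 0 && out$lifespan_sd > 0,
              "lifespan variance components invalid")
  out
}

#' Replication structure of the synthetic study
#'
#' Design constants of the screen and the selected-vs-control productivity
#' assay: 48 lifespan vials per genotype with 3 flies of each sex, weekly
#' productivity recorded for 13 of those vials, 15 vials per cross in the
#' O/B assay, qPCR with 2 biological x 3 technical replicates, and the
#' screen run in 6 blocks.
#'
#' @param n_vials lifespan vials per genotype.
#' @param flies_per_sex flies of each sex per vial.
#' @param prod_vials vials (per genotype) followed for weekly productivity.
#' @param ob_vials vials per cross in the O/B productivity assay.
#' @param qpcr_bio,qpcr_tech biological / technical qPCR replicates.
#' @param n_blocks number of experimental blocks the screen is split into.
#' @return a named list.
#' @export
sim_design <- function(n_vials = 48, flies_per_sex = 3, prod_vials = 13,
                       ob_vials = 15, qpcr_bio = 2, qpcr_tech = 3,
                       n_blocks = 6) {
  out <- as.list(environment())
  assert_that(all(unlist(out) >= 1), "design counts must be >= 1")
  assert_that(out$prod_vials <= out$n_vials,
              "prod_vials cannot exceed n_vials")
  out
}

#' Configuration of the synthetic evolve-and-resequence study
#'
#' Bundles every parameter of the synthetic data generator: the genome
#' (chromosome arms, variant counts, planted sweep intervals, drift and
#' sequencing noise) and the RNAi screen (per-gene planted effects,
#' phenotype baselines, replication design).
#'
#' @param seed master integer seed; all stages derive substreams from it via
#'   [derive_seed()].
#' @param n_sel_lines,n_ctl_lines replicate selected (O) / control (B)
#'   population counts.
#' @param arms data.frame with columns `arm`, `length_bp`, `n_variants`.
#' @param sweeps `NULL` or data.frame with columns `arm`, `start`, `end`,
#'   `divergence` (target mean |delta p| in (0, 1] for variants inside).
#'   Sweeps on one arm must not overlap.
#' @param drift_concentration Beta concentration `c` for line-to-line drift:
#'   each line's true frequency is Beta(p0*c, (1-p0)*c) around the ancestral
#'   frequency p0. Larger is tighter.
#' @param coverage mean read depth; observed frequency is
#'   Binomial(coverage, p)/coverage.
#' @param screen_genes `NULL` (use [default_screen_panel()]) or a data.frame
#'   with columns `gene`, `construct` ("KK"/"GD"), `lifespan_f`,
#'   `lifespan_m` (shift in days), `qpcr_knockdown` (fraction of expression
#'   retained in (0,1], or NA for genes not assayed by qPCR).
#' @param productivity_effects `NULL` or numeric matrix (genes x weeks) of
#'   planted shifts in offspring/female/week; rownames must match
#'   `screen_genes$gene`.
#' @param baseline see [sim_baseline()].
#' @param design see [sim_design()].
#' @param genes_per_arm number of synthetic annotated genes placed per arm.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sel_lines = 5L, n_ctl_lines = 5L,
                       arms = data.frame(
                         arm = c("X", "2L", "2R", "3L", "3R"),
                         length_bp = c(22e6, 23e6, 21e6, 24e6, 27e6),
                         n_variants = c(2000, 2000, 2000, 2000, 2000)
                       ),
                       sweeps = NULL,
                       drift_concentration = 50,
                       coverage = 50,
                       screen_genes = NULL,
                       productivity_effects = NULL,
                       baseline = sim_baseline(),
                       design = sim_design(),
                       genes_per_arm = 25L) {
  assert_that(is.numeric(seed) && length(seed) == 1L, "seed must be scalar")
  assert_that(n_sel_lines >= 1 && n_ctl_lines >= 1, "line counts must be > 0")
  assert_that(is.data.frame(arms) &&
                all(c("arm", "length_bp", "n_variants") %in% names(arms)),
              "arms must have columns arm, length_bp, n_variants")
  assert_that(all(arms$n_variants > 0) && all(arms$length_bp > 0),
              "arm sizes and variant counts must be positive")
  assert_that(!anyDuplicated(arms$arm), "duplicate arm names")
  assert_that(drift_concentration > 0, "drift_concentration must be > 0")
  assert_that(coverage >= 1, "coverage must be >= 1")

  if (!is.null(sweeps)) {
    assert_that(all(c("arm", "start", "end", "divergence") %in% names(sweeps)),
                "sweeps must have columns arm, start, end, divergence")
    assert_that(all(sweeps$start < sweeps$end), "sweep start must be < end")
    assert_that(all(sweeps$divergence > 0 & sweeps$divergence <= 1),
                "sweep divergence must lie in (0, 1]")
    assert_that(all(sweeps$arm %in% arms$arm), "sweep on unknown arm")
    len <- stats::setNames(arms$length_bp, arms$arm)
    assert_that(all(sweeps$end <= len[sweeps$arm]),
                "sweep extends beyond arm length")
    for (a in unique(sweeps$arm)) {
      s <- sweeps[sweeps$arm == a, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping sweeps on arm ", a, call. = FALSE)
    }
  }

  if (is.null(screen_genes)) {
    panel <- default_screen_panel()
    screen_genes <- panel$genes
    if (is.null(productivity_effects)) productivity_effects <- panel$productivity
  }
  assert_that(all(c("gene", "construct", "lifespan_f", "lifespan_m",
                    "qpcr_knockdown") %in% names(screen_genes)),
              "screen_genes missing required columns")
  assert_that(!anyDuplicated(screen_genes$gene), "duplicate screen gene")
  assert_that(all(screen_genes$construct %in% c("KK", "GD")),
              "construct must be KK or GD")
  kd <- screen_genes$qpcr_knockdown
  assert_that(all(is.na(kd) | (kd > 0 & kd <= 1)),
              "qpcr_knockdown must lie in (0, 1] or be NA")
  n_weeks <- length(baseline$prod_week_means)
  if (is.null(productivity_effects)) {
    productivity_effects <- matrix(
      0, nrow(screen_genes), n_weeks,
      dimnames = list(screen_genes$gene, NULL))
  }
  assert_that(is.matrix(productivity_effects) &&
                ncol(productivity_effects) == n_weeks &&
                setequal(rownames(productivity_effects), screen_genes$gene),
              "productivity_effects must be a genes x weeks matrix")
  productivity_effects <- productivity_effects[screen_genes$gene, , drop = FALSE]

  structure(list(seed = as.integer(seed),
                 n_sel_lines = as.integer(n_sel_lines),
                 n_ctl_lines = as.integer(n_ctl_lines),
                 arms = arms, sweeps = sweeps,
                 drift_concentration = drift_concentration,
                 coverage = coverage,
                 screen_genes = screen_genes,
                 productivity_effects = productivity_effects,
                 baseline = baseline, design = design,
                 genes_per_arm = as.integer(genes_per_arm)),
            class = "sim_config")
}

#' Default synthetic screen panel
#'
#' Twelve genes spanning the effect archetypes the screen is meant to
#' resolve: a null gene, sex-specific and sexually antagonistic lifespan
#' shifts, concordant lifespan+productivity effects in both directions, and
#' early/late productivity trade-offs. Lifespan shifts of 8-10 days and
#' weekly productivity shifts of 10 offspring/female are of the order the
#' screen design can detect; knockdowns retain 25% of expression.
#'
#' @return list with elements `genes` (data.frame) and `productivity`
#'   (genes x 6 weeks effect matrix).
#' @export
default_screen_panel <- function() {
  genes <- data.frame(
    gene = c("null1", "fem_up", "male_down", "sexantag1", "sexantag2",
             "conc_up", "conc_down", "early_up_late_down",
             "early_down_late_up", "prod_down", "prod_up", "life_only_up"),
    construct = rep(c("KK", "GD"), length.out = 12),
    lifespan_f = c(0, 10, 0, 8, -8, 8, -8, -8, 8, 0, 0, 9),
    lifespan_m = c(0, 0, -8, -8, 8, 8, -8, 8, -8, 0, 0, 0),
    qpcr_knockdown = c(NA, 0.25, 0.25, NA, NA, 0.25, NA, NA, NA, 0.5, NA, NA),
    stringsAsFactors = FALSE
  )
  prod <- matrix(0, nrow(genes), 6, dimnames = list(genes$gene, NULL))
  prod["conc_up", ] <- 8
  prod["conc_down", ] <- -8
  prod["early_up_late_down", ] <- c(10, 10, 0, -10, -10, -10)
  prod["early_down_late_up", ] <- c(-10, -10, 0, 10, 10, 10)
  prod["prod_down", ] <- -10
  prod["prod_up", ] <- 10
  list(genes = genes, productivity = prod)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", nrow(x$arms), " arms, ",
      sum(x$arms$n_variants), " variants, ",
      if (is.null(x$sweeps)) 0 else nrow(x$sweeps), " planted sweeps\n",
      sep = "")
  cat("  lines: ", x$n_sel_lines, " selected vs ", x$n_ctl_lines,
      " control; drift concentration ", x$drift_concentration,
      ", coverage ", x$coverage, "x\n", sep = "")
  cat("  screen: ", nrow(x$screen_genes), " genes, ",
      x$design$n_vials, " vials/genotype, ",
      x$design$prod_vials, " productivity vials, ",
      length(x$baseline$prod_week_means), " weeks\n", sep = "")
  invisible(x)
}
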