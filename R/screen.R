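# Apply the ANOVA battery to screen tables, producing per-gene effect calls
# for lifespan (by sex), lifetime productivity, weekly productivity and
# qPCR knockdown, plus the selected-vs-control (O/B) maternal-effect
# analysis. All estimates are RNAi minus control on the trait's scale;
# direction is "ns" unless p < alpha.

effect_call_row <- function(gene, trait, week, estimate, se, p_value, alpha,
                            extra = NULL) {
  out <- data.frame(gene = gene, trait = trait, week = week,
                    estimate = estimate, se = se, p_value = p_value,
                    direction = call_direction(estimate, p_value, alpha),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

screen_genes_of <- function(tab) {
  g <- unique(tab$genotype[!is.na(tab$control)])
  g[order(match(g, tab$genotype))]
}

# rows of one gene plus its block-matched control; G coded with the control
# as the first level so estimates read RNAi minus control
gene_with_control <- function(tab, gene) {
  gi <- tab[tab$genotype == gene & !is.na(tab$control), , drop = FALSE]
  assert_that(nrow(gi) > 0, paste("no data for gene", gene))
  ctl <- unique(gi$control)
  assert_that(length(ctl) == 1 && !is.na(ctl),
              paste("missing control pairing for gene", gene))
  blocks <- unique(gi$block)
  ci <- tab[tab$genotype == ctl & tab$block %in% blocks, , drop = FALSE]
  assert_that(nrow(ci) > 0,
              paste("control", ctl, "absent from block(s) of gene", gene))
  d <- rbind(ci, gi)
  d$genotype <- factor(d$genotype, levels = c(ctl, gene))
  d
}

#' Call RNAi effects on lifespan, by sex
#'
#' For each gene (paired with its construct-matched control within its
#' block): the full mixed model
#' `lifespan = S + G + S*G + vial(G) + S*vial(G)` supplies the sex-by-
#' genotype interaction test, and per-sex reduced models
#' `lifespan = G + vial(G)` (genotype tested against the vial-within-
#' genotype mean square) supply the sex-specific estimate and P-value that
#' the calls are based on.
#'
#' @param lifespan lifespan table (see [read_phenotypes()]).
#' @param alpha per-test significance level (no multiple-testing
#'   correction, matching how the screen is read out).
#' @return effect-call data.frame: one row per gene x sex with `trait`
#'   `"lifespan_F"`/`"lifespan_M"`, plus `p_sex_by_genotype` from the full
#'   model.
#' @export
call_lifespan_effects <- function(lifespan, alpha = 0.05) {
  calls <- lapply(screen_genes_of(lifespan), function(gene) {
    d <- gene_with_control(lifespan, gene)
    full <- fit_anova(d, "lifespan",
                      "sex + genotype + sex*genotype + vial(genotype) + sex*vial(genotype)")
    p_int <- full$table$p.value[full$table$term == "sex*genotype"]
    per_sex <- lapply(c(F_ = "F", M_ = "M"), function(sx) {
      ds <- d[d$sex == sx, , drop = FALSE]
      fit <- fit_anova(ds, "lifespan", "genotype + vial(genotype)")
      mns <- marginal_means(fit, "genotype")
      est <- mns$mean[2] - mns$mean[1]
      se <- sqrt(sum(mns$se^2))
      p <- fit$table$p.value[fit$table$term == "genotype"]
      effect_call_row(gene, paste0("lifespan_", sx), NA_integer_,
                      est, se, p, alpha,
                      extra = data.frame(p_sex_by_genotype = p_int))
    })
    do.call(rbind, per_sex)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Call RNAi effects on lifetime and weekly productivity
#'
#' Lifetime productivity per vial is the sum of its observed weekly
#' offspring/female values: weeks after a vial's females have died are
#' genuinely zero further reproduction, so they contribute 0 to the sum
#' (whereas the weekly models treat those cells as missing). The lifetime
#' model is the one-way `Y = G`; the weekly analysis fits the full
#' `Y = W + G + W*G` on the weeks where both genotypes have data, then
#' per-week reduced one-way models `Y = G` give the week-specific calls.
#'
#' @param productivity weekly productivity table.
#' @inheritParams call_lifespan_effects
#' @return effect-call data.frame with traits `"lifetime_productivity"`
#'   (week NA) and `"weekly_productivity"` (one row per common week), plus
#'   `p_week_by_genotype` from the full weekly model.
#' @export
call_productivity_effects <- function(productivity, alpha = 0.05) {
  calls <- lapply(screen_genes_of(productivity), function(gene) {
    d <- gene_with_control(productivity, gene)

    lifetime <- stats::aggregate(
      offspring_per_female ~ vial + genotype, data = d, FUN = sum)
    names(lifetime)[3] <- "lifetime"
    fit_l <- fit_anova(lifetime, "lifetime", "genotype")
    mns <- marginal_means(fit_l, "genotype")
    out <- effect_call_row(
      gene, "lifetime_productivity", NA_integer_,
      mns$mean[2] - mns$mean[1], sqrt(sum(mns$se^2)),
      fit_l$table$p.value[fit_l$table$term == "genotype"], alpha,
      extra = data.frame(p_week_by_genotype = NA_real_))

    weeks_by_geno <- tapply(d$week, d$genotype, unique)
    common <- sort(Reduce(intersect, weeks_by_geno))
    assert_that(length(common) > 0,
                paste("no overlapping weeks between", gene, "and its control"))
    dw <- d[d$week %in% common, , drop = FALSE]
    p_wg <- NA_real_
    if (length(common) > 1) {
      full <- fit_anova(dw, "offspring_per_female",
                        "week + genotype + week*genotype")
      p_wg <- full$table$p.value[full$table$term == "week*genotype"]
    }
    weekly <- lapply(common, function(w) {
      fit <- fit_anova(dw[dw$week == w, , drop = FALSE],
                       "offspring_per_female", "genotype")
      m <- marginal_means(fit, "genotype")
      effect_call_row(gene, "weekly_productivity", as.integer(w),
                      m$mean[2] - m$mean[1], sqrt(sum(m$se^2)),
                      fit$table$p.value[fit$table$term == "genotype"], alpha,
                      extra = data.frame(p_week_by_genotype = p_wg))
    })
    rbind(out, do.call(rbind, weekly))
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Maternal/paternal decomposition of selected-vs-control productivity
#'
#' Fits the full factorial
#' `Y = Gm + Gf + W + Gm*W + Gf*W + Gm*Gf + Gm*Gf*W` on the reciprocal
#' O/B crosses, then per-week reduced models `Y = Gm + Gf + Gm*Gf` with
#' Tukey-Kramer letters over the four crosses. Weeks where one regime is
#' entirely missing are skipped with a warning.
#'
#' @param ob data.frame from [simulate_ob_productivity()] or
#'   [read_phenotypes()] with columns `gm`, `gf`, `vial`, `week`,
#'   `offspring_per_female`.
#' @param alpha significance level for the Tukey letters.
#' @return list with `full` (the full-model [fit_anova()] result) and
#'   `weekly`, a named list per week of `fit` and `tukey`.
#' @export
analyze_ob_productivity <- function(ob, alpha = 0.05) {
  full <- fit_anova(ob, "offspring_per_female",
                    "gm + gf + week + gm*week + gf*week + gm*gf + gm*gf*week")
  weekly <- list()
  for (w in sort(unique(ob$week))) {
    dw <- ob[ob$week == w, , drop = FALSE]
    if (length(unique(dw$gm)) < 2 || length(unique(dw$gf)) < 2) {
      warning("week ", w, ": a parental regime is missing; reduced model skipped",
              call. = FALSE)
      next
    }
    fit <- fit_anova(dw, "offspring_per_female", "gm + gf + gm*gf")
    weekly[[as.character(w)]] <-
      list(fit = fit, tukey = tukey_pairwise(fit, c("gm", "gf"), alpha = alpha))
  }
  list(full = full, weekly = weekly)
}

#' Call RNAi knockdown from qPCR tables
#'
#' Expression is normalized per technical replicate as
#' `2^-(Ct_target - Ct_reference)` against the housekeeping control and
#' analysed on the log2 scale. Per tissue: a combined model
#' `Y = L + G + L*G + rep(L*G)` across genes (biological replicate as the
#' random stratum), then per-gene reduced models `Y = L + rep(L)` give the
#' knockdown estimate (log2 fold change, RNAi minus control) and P-value,
#' with the line effect tested against the biological-replicate mean
#' square. Technical replicates missing a reference Ct are dropped with a
#' warning.
#'
#' @param qpcr qPCR table (see [read_phenotypes()]).
#' @inheritParams call_lifespan_effects
#' @return effect-call data.frame, traits `"expression_ovary"` /
#'   `"expression_AG"`, estimates on the log2 scale, plus `p_combined_line`
#'   (combined-model L term) per tissue.
#' @export
call_knockdown <- function(qpcr, alpha = 0.05) {
  miss <- is.na(qpcr$ct_reference)
  if (any(miss)) {
    warning(sum(miss), " qPCR replicate(s) without reference Ct dropped",
            call. = FALSE)
    qpcr <- qpcr[!miss, , drop = FALSE]
  }
  qpcr$log2_expr <- -(qpcr$ct_target - qpcr$ct_reference)
  qpcr$line_type <- ifelse(qpcr$line == qpcr$gene, "RNAi", "control")
  out <- list()
  for (tis in unique(qpcr$tissue)) {
    dt <- qpcr[qpcr$tissue == tis, , drop = FALSE]
    trait <- if (tis == "ovary") "expression_ovary" else "expression_AG"
    p_comb <- NA_real_
    if (length(unique(dt$gene)) > 1) {
      comb <- fit_anova(dt, "log2_expr",
                        "line_type + gene + line_type*gene + biological_rep(line_type*gene)")
      p_comb <- comb$table$p.value[comb$table$term == "line_type"]
    }
    for (g in unique(dt$gene)) {
      dg <- dt[dt$gene == g, , drop = FALSE]
      dg$line_type <- factor(dg$line_type, levels = c("control", "RNAi"))
      fit <- fit_anova(dg, "log2_expr", "line_type + biological_rep(line_type)")
      mns <- marginal_means(fit, "line_type")
      out[[length(out) + 1L]] <- effect_call_row(
        g, trait, NA_integer_, mns$mean[2] - mns$mean[1],
        sqrt(sum(mns$se^2)),
        fit$table$p.value[fit$table$term == "line_type"], alpha,
        extra = data.frame(p_combined_line = p_comb))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run all effect callers on a simulated (or loaded) screen
#'
#' @param screen list with `lifespan`, `productivity` and `qpcr` tables, as
#'   returned by [simulate_screen()].
#' @inheritParams call_lifespan_effects
#' @return one effect-call data.frame combining lifespan, productivity and
#'   (when qPCR data is present) knockdown calls.
#' @export
call_screen_effects <- function(screen, alpha = 0.05) {
  life <- call_lifespan_effects(screen$lifespan, alpha = alpha)
  prod <- call_productivity_effects(screen$productivity, alpha = alpha)
  common <- c("gene", "trait", "week", "estimate", "se", "p_value", "direction")
  out <- rbind(life[common], prod[common])
  if (!is.null(screen$qpcr) && nrow(screen$qpcr) > 0) {
    kd <- call_knockdown(screen$qpcr, alpha = alpha)
    out <- rbind(out, kd[common])
  }
  rownames(out) <- NULL
  out
}

#' Headline tallies over a set of effect calls
#'
#' Counts, over genes: affected lifespan in at least one sex, increased /
#' decreased lifespan in at least one sex, sexually antagonistic lifespan
#' effects, affected lifetime productivity, affected productivity in at
#' least one week.
#'
#' @param calls effect-call data.frame.
#' @return named integer vector of tallies.
#' @export
summarize_calls <- function(calls) {
  life <- calls[calls$trait %in% c("lifespan_F", "lifespan_M"), ]
  by_gene <- split(life$direction, life$gene)
  n_aff <- sum(vapply(by_gene, function(d) any(d != "ns"), logical(1)))
  n_up <- sum(vapply(by_gene, function(d) any(d == "increase"), logical(1)))
  n_dn <- sum(vapply(by_gene, function(d) any(d == "decrease"), logical(1)))
  n_antag <- sum(vapply(by_gene, function(d)
    any(d == "increase") && any(d == "decrease"), logical(1)))
  lt <- calls[calls$trait == "lifetime_productivity", ]
  wk <- calls[calls$trait == "weekly_productivity", ]
  c(lifespan_affected = n_aff,
    lifespan_increased = n_up,
    lifespan_decreased = n_dn,
    lifespan_sex_antagonistic = n_antag,
    lifetime_productivity_affected =
      length(unique(lt$gene[lt$direction != "ns"])),
    weekly_productivity_affected =
      length(unique(wk$gene[wk$direction != "ns"])))
}
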