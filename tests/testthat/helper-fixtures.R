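# Shared fixtures and independent oracles.

# minimal variant table realising a given |delta p| sequence exactly
# (one selected line at dp, one control line at 0)
make_variants <- function(delta_p, pos = seq_along(delta_p) * 100,
                          arm = "X") {
  data.frame(arm = arm, pos = pos, sel_1 = delta_p, ctl_1 = 0,
             delta_p = delta_p, stringsAsFactors = FALSE)
}

random_variant_table <- function(n_max = 30) {
  n <- sample.int(n_max, 1)
  arms <- sample(c("X", "2L"), n, replace = TRUE,
                 prob = c(0.7, 0.3))
  kind <- sample.int(3, n, replace = TRUE, prob = c(0.45, 0.3, 0.25))
  dp <- numeric(n)
  dp[kind == 1] <- runif(sum(kind == 1), 0.801, 1)
  dp[kind == 2] <- runif(sum(kind == 2), 0.501, 0.8)
  dp[kind == 3] <- runif(sum(kind == 3), 0, 0.5)
  out <- do.call(rbind, lapply(unique(arms), function(a) {
    k <- sum(arms == a)
    make_variants(dp[arms == a], pos = sort(sample.int(10000, k)), arm = a)
  }))
  rownames(out) <- NULL
  out
}

# brute-force oracle: enumerate merges to a fixpoint in random order, per arm
oracle_scan_arm <- function(dp, pos, params) {
  idx <- which(dp > params$high_threshold)
  if (!length(idx)) return(NULL)
  runs <- unname(split(idx, cumsum(c(1, diff(idx) != 1))))
  ints <- lapply(runs, range)
  repeat {
    if (length(ints) < 2) break
    mergeable <- which(vapply(seq_len(length(ints) - 1), function(i) {
      gap <- (ints[[i]][2] + 1):(ints[[i + 1]][1] - 1)
      length(gap) <= params$max_interruption &&
        all(dp[gap] > params$interruption_threshold)
    }, logical(1)))
    if (!length(mergeable)) break
    i <- if (length(mergeable) == 1) mergeable else sample(mergeable, 1)
    ints[[i]] <- c(ints[[i]][1], ints[[i + 1]][2])
    ints[[i + 1]] <- NULL
  }
  data.frame(start_pos = vapply(ints, function(r) pos[r[1]], numeric(1)),
             end_pos = vapply(ints, function(r) pos[r[2]], numeric(1)),
             n_variants = vapply(ints, function(r) r[2] - r[1] + 1, numeric(1)))
}

oracle_scan <- function(variants, params) {
  out <- lapply(unique(variants$arm), function(a) {
    v <- variants[variants$arm == a, ]
    res <- oracle_scan_arm(v$delta_p, v$pos, params)
    if (!is.null(res)) cbind(arm = a, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(arm = character(), start_pos = numeric(),
                      end_pos = numeric(), n_variants = numeric())
  }
  out
}

# effect-call rows for the classifier: directions given per trait,
# p = 0.01 when called, 0.5 otherwise
make_calls <- function(gene, lifespan_f = "ns", lifespan_m = "ns",
                       weeks = list(), lifetime = "ns") {
  row <- function(trait, week, dir) {
    est <- switch(dir, increase = 1, decrease = -1, ns = 0.1)
    data.frame(gene = gene, trait = trait, week = week, estimate = est,
               se = 0.5, p_value = if (dir == "ns") 0.5 else 0.01,
               direction = dir, stringsAsFactors = FALSE)
  }
  out <- rbind(row("lifespan_F", NA, lifespan_f),
               row("lifespan_M", NA, lifespan_m),
               row("lifetime_productivity", NA, lifetime))
  for (w in names(weeks)) {
    out <- rbind(out, row("weekly_productivity", as.integer(w), weeks[[w]]))
  }
  out
}

# the published gene-category sentences encoded as direction vectors
# (weeks: 1-2 early, 4-5 late), with the expected category and axes
golden_gene_fixture <- function() {
  g <- function(gene, f = "ns", m = "ns", w1 = "ns", w2 = "ns", w4 = "ns",
                w5 = "ns", lt = "ns", category, axes = "") {
    list(calls = make_calls(gene, f, m,
                            weeks = list(`1` = w1, `2` = w2,
                                         `4` = w4, `5` = w5),
                            lifetime = lt),
         gene = gene, category = category, axes = axes)
  }
  up <- "increase"; dn <- "decrease"
  c(
    # lifespan only
    lapply(c("Lztr1", "Nmd3", "pcx", "Pgant1"), function(x)
      g(x, f = up, category = "lifespan_only_benefit")),
    lapply(c("CG18273", "TRAM"), function(x)
      g(x, m = dn, category = "lifespan_only_cost")),
    # productivity only
    lapply(c("CG7970", "CG13933", "Hsp22", "Hsl", "l(1)G0004", "Fdx1"),
           function(x) g(x, w2 = dn, lt = dn, category = "productivity_only")),
    list(g("piwi", w1 = up, category = "productivity_only")),
    lapply(c("babos", "sov"), function(x)
      g(x, w1 = up, w5 = dn, category = "antagonistic_pleiotropy",
        axes = "early_vs_late_reproduction")),
    # concordant deleterious / beneficial
    lapply(c("blw", "boi", "CG12018", "CG14969", "CG16868", "CG17777",
             "CG4452", "CG5254", "crn", "CycE", "Cyp4g1", "dx", "ND-ACP",
             "pn", "RpL22"), function(x)
      g(x, f = dn, w2 = dn, lt = dn, category = "concordant_deleterious")),
    lapply(c("CG3071", "sgg", "zf30c"), function(x)
      g(x, f = up, w1 = up, lt = up, category = "concordant_beneficial")),
    list(g("dnc", category = "no_effect")),
    # antagonistic pleiotropy
    lapply(c("abo", "CG13760", "CG7971", "fs(1)N", "G9a", "Klp67A"),
           function(x) g(x, f = up, w1 = dn,
                         category = "antagonistic_pleiotropy",
                         axes = "lifespan_vs_reproduction")),
    lapply(c("CG3704", "msn", "sra"), function(x)
      g(x, f = dn, w1 = up, category = "antagonistic_pleiotropy",
        axes = "lifespan_vs_reproduction")),
    lapply(c("Cdc7", "CG3326", "Dredd", "egh", "lama"), function(x)
      g(x, f = up, m = dn, w2 = dn, category = "antagonistic_pleiotropy",
        axes = "sex,lifespan_vs_reproduction")),
    lapply(c("CG32809", "CG4281", "CG4554", "DAAM", "wds"), function(x)
      g(x, f = up, w1 = dn, w5 = up,
        category = "antagonistic_pleiotropy",
        axes = "early_vs_late_reproduction,lifespan_vs_reproduction")),
    list(g("Eip75B", f = dn, w1 = up, w5 = dn,
           category = "antagonistic_pleiotropy",
           axes = "early_vs_late_reproduction,lifespan_vs_reproduction")),
    lapply(c("capu", "MED22"), function(x)
      g(x, f = dn, m = up, w1 = up, w5 = dn,
        category = "antagonistic_pleiotropy",
        axes = "sex,early_vs_late_reproduction,lifespan_vs_reproduction")),
    list(g("CG13369", f = up, m = dn, w1 = dn, w5 = up,
           category = "antagonistic_pleiotropy",
           axes = "sex,early_vs_late_reproduction,lifespan_vs_reproduction"))
  )
}

# small screen config used across tests: one gene vs its control
one_gene_config <- function(seed, lifespan_f = 0, lifespan_m = 0,
                            prod = rep(0, 6), knockdown = NA) {
  genes <- data.frame(gene = "g1", construct = "KK",
                      lifespan_f = lifespan_f, lifespan_m = lifespan_m,
                      qpcr_knockdown = knockdown, stringsAsFactors = FALSE)
  sim_config(seed = seed,
             arms = data.frame(arm = "X", length_bp = 1e6, n_variants = 50),
             screen_genes = genes,
             productivity_effects = matrix(prod, 1, 6,
                                           dimnames = list("g1", NULL)))
}

# relabel a gene/control pair so RNAi and control swap roles
swap_labels <- function(tab, gene) {
  ctl <- unique(tab$control[tab$genotype == gene])
  ctl <- ctl[!is.na(ctl)]
  out <- tab[tab$genotype %in% c(gene, ctl), ]
  is_gene <- out$genotype == gene
  out$genotype[is_gene] <- ctl
  out$genotype[!is_gene] <- gene
  out$control[is_gene] <- NA
  out$control[!is_gene] <- ctl
  out
}
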