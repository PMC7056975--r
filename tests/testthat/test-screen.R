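test_that("planted sex-antagonistic lifespan effects are called with correct signs", {
  cfg <- one_gene_config(seed = 101, lifespan_f = 8, lifespan_m = -8)
  calls <- call_lifespan_effects(simulate_screen(cfg)$lifespan)
  expect_equal(calls$direction[calls$trait == "lifespan_F"], "increase")
  expect_equal(calls$direction[calls$trait == "lifespan_M"], "decrease")
  expect_equal(calls$estimate[calls$trait == "lifespan_F"], 8, tolerance = 0.5)
  expect_lt(calls$p_sex_by_genotype[1], 0.05)
})

test_that("a control compared against itself gives estimate 0 and ns", {
  s <- simulate_screen(one_gene_config(seed = 102))
  ctl <- s$lifespan[is.na(s$lifespan$control), ]
  self <- ctl
  self$genotype <- "selfcheck"
  self$control <- unique(ctl$genotype)
  calls <- call_lifespan_effects(rbind(ctl, self))
  expect_equal(calls$estimate, c(0, 0), tolerance = 1e-12)
  expect_true(all(calls$direction == "ns"))
  expect_true(all(calls$p_value == 1))
})

test_that("missing control pairing is an error", {
  s <- simulate_screen(one_gene_config(seed = 103))
  orphan <- s$lifespan[!is.na(s$lifespan$control), ]
  orphan$control <- "control_absent"
  expect_error(call_lifespan_effects(orphan), "control")
})

test_that("planted early/late productivity trade-off is resolved per week", {
  cfg <- one_gene_config(seed = 104, prod = c(10, 10, 0, -10, -10, -10))
  calls <- call_productivity_effects(simulate_screen(cfg)$productivity)
  wk <- calls[calls$trait == "weekly_productivity", ]
  expect_true(any(wk$direction[wk$week %in% 1:2] == "increase"))
  expect_false(any(wk$direction[wk$week %in% 1:2] == "decrease"))
  expect_true(any(wk$direction[wk$week >= 4] == "decrease"))
  expect_false(any(wk$direction[wk$week >= 4] == "increase"))
})

test_that("a uniform productivity increase is called on the lifetime scale", {
  cfg <- one_gene_config(seed = 105, prod = rep(5, 6))
  calls <- call_productivity_effects(simulate_screen(cfg)$productivity)
  lt <- calls[calls$trait == "lifetime_productivity", ]
  expect_equal(lt$direction, "increase")
  expect_equal(lt$estimate, 30, tolerance = 12)
})

test_that("swapping RNAi and control labels negates estimates and keeps P-values", {
  cfg <- one_gene_config(seed = 106, lifespan_f = 6, lifespan_m = -3,
                         prod = c(5, 5, 0, -5, -5, -5))
  s <- simulate_screen(cfg)
  life1 <- call_lifespan_effects(s$lifespan)
  life2 <- call_lifespan_effects(swap_labels(s$lifespan, "g1"))
  expect_equal(life2$estimate, -life1$estimate, tolerance = 1e-10)
  expect_equal(life2$p_value, life1$p_value, tolerance = 1e-10)
  prod1 <- call_productivity_effects(s$productivity)
  prod2 <- call_productivity_effects(swap_labels(s$productivity, "g1"))
  expect_equal(prod2$estimate, -prod1$estimate, tolerance = 1e-10)
  expect_equal(prod2$p_value, prod1$p_value, tolerance = 1e-10)
})

test_that("maternal late-week effects are attributed to the maternal regime", {
  cfg <- sim_config(seed = 107)
  ob <- simulate_ob_productivity(cfg, maternal_effect = c(0, 0, 8, 12))
  res <- analyze_ob_productivity(ob)
  w4 <- res$weekly[["4"]]$fit$table
  expect_lt(w4$p.value[w4$term == "gm"], 0.05)
  expect_gt(w4$p.value[w4$term == "gf"], 0.05)
  full <- res$full$table
  expect_lt(full$p.value[full$term == "gm*week"], 0.05)
})

test_that("identical cross data give ns terms and one Tukey letter", {
  # literally identical values in every cross: all cross SS are exactly zero
  base <- data.frame(vial = rep(sprintf("v%02d", 1:8), 2),
                     week = rep(1:2, each = 8),
                     offspring_per_female = c(seq(20, 34, by = 2),
                                              seq(10, 24, by = 2)))
  ob <- do.call(rbind, lapply(c("O", "B"), function(gm)
    do.call(rbind, lapply(c("O", "B"), function(gf)
      cbind(gm = gm, gf = gf, base)))))
  res <- analyze_ob_productivity(ob)
  w1 <- res$weekly[["1"]]
  cross_terms <- w1$fit$table
  expect_true(all(cross_terms$p.value[cross_terms$term != "week"] > 0.05))
  expect_true(all(w1$tukey$letters$letters == "a"))
})

test_that("a planted maternal x paternal interaction is detected", {
  cfg <- sim_config(seed = 109)
  ob <- simulate_ob_productivity(cfg, interaction_effect = c(12, 12, 12, 12))
  full <- analyze_ob_productivity(ob)$full$table
  expect_lt(full$p.value[full$term == "gm*gf"], 0.05)
})

test_that("a 4x knockdown is estimated near -2 on the log2 scale and called", {
  cfg <- one_gene_config(seed = 110, knockdown = 0.25)
  kd <- call_knockdown(simulate_screen(cfg)$qpcr)
  expect_equal(nrow(kd), 2) # ovary + accessory gland
  expect_equal(kd$estimate, c(-2, -2), tolerance = 0.6)
  expect_true(all(kd$direction == "decrease"))
})

test_that("large biological-replicate variance makes knockdown calls ns", {
  bl <- sim_baseline(qpcr_bio_sd = 2.5)
  genes <- data.frame(gene = "g1", construct = "KK", lifespan_f = 0,
                      lifespan_m = 0, qpcr_knockdown = 0.25)
  cfg <- sim_config(seed = 111,
                    arms = data.frame(arm = "X", length_bp = 1e6,
                                      n_variants = 50),
                    screen_genes = genes, baseline = bl)
  kd <- call_knockdown(simulate_screen(cfg)$qpcr)
  # point estimates still go down, but the test is underpowered
  expect_true(all(kd$estimate < 0))
  expect_true(any(kd$direction == "ns"))
})

test_that("replicates without a reference Ct are dropped with a warning", {
  q <- simulate_screen(one_gene_config(seed = 112, knockdown = 0.25))$qpcr
  q$ct_reference[1] <- NA
  expect_warning(kd <- call_knockdown(q), "dropped")
  expect_equal(nrow(kd), 2)
})
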