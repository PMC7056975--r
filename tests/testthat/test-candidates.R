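make_ann <- function(gene_id, min_snp_p, ovary = TRUE, ag = TRUE,
                     rnai = TRUE, start = 150, end = 250) {
  data.frame(gene_id = gene_id, symbol = gene_id, arm = "X",
             start = start, end = end, expressed_ovary = ovary,
             expressed_accessory_gland = ag, rnai_available = rnai,
             min_snp_p = min_snp_p, stringsAsFactors = FALSE)
}

fixture_intervals <- function() {
  scan_intervals(make_variants(c(0.9, 0.85, 0.9), pos = c(100, 200, 300)))
}

test_that("the three selection criteria combine as specified", {
  iv <- fixture_intervals()
  ann <- rbind(
    make_ann("in_iv_good", 1e-6),                      # interval route
    make_ann("in_iv_weak_p", 1e-4),                    # fails p < 1e-5
    make_ann("no_ovary", 1e-6, ovary = FALSE),         # expression fail
    make_ann("no_rnai", 1e-6, rnai = FALSE),           # stock fail
    make_ann("nominal_route", 5e-4, start = 5000, end = 6000), # outside, p<1e-3
    make_ann("outside_weak", 5e-3, start = 5000, end = 6000),
    make_ann("unknown_expr", 1e-6, ovary = NA)
  )
  iv <- assign_genes(iv, ann)
  out <- select_candidates(ann, iv)

  expect_true(out$selected[out$gene_id == "in_iv_good"])
  expect_equal(out$route[out$gene_id == "in_iv_good"], "interval")
  expect_true(out$selected[out$gene_id == "nominal_route"])
  expect_equal(out$route[out$gene_id == "nominal_route"], "nominal")

  expect_false(out$selected[out$gene_id == "in_iv_weak_p"])
  expect_equal(out$audit[out$gene_id == "in_iv_weak_p"], "divergence")
  expect_equal(out$audit[out$gene_id == "no_ovary"], "expression")
  expect_equal(out$audit[out$gene_id == "no_rnai"], "rnai_availability")
  expect_equal(out$audit[out$gene_id == "outside_weak"], "divergence")
  expect_equal(out$audit[out$gene_id == "unknown_expr"], "unknown-expression")
})

test_that("audit flags exhaustively explain every rejection", {
  set.seed(55)
  cfg <- sim_config(seed = 55,
                    arms = data.frame(arm = "X", length_bp = 2e6,
                                      n_variants = 600),
                    sweeps = data.frame(arm = "X", start = 5e5, end = 1e6,
                                        divergence = 0.95))
  v <- simulate_frequencies(cfg)
  ann <- simulate_annotations(cfg, v)
  iv <- assign_genes(scan_intervals(v), ann)
  out <- select_candidates(ann, iv)
  expect_true(all(nzchar(out$audit[!out$selected])))
  expect_true(all(out$audit[out$selected] == ""))
})

test_that("relaxing cutoffs never removes a selected gene (monotonicity)", {
  cfg <- sim_config(seed = 56,
                    arms = data.frame(arm = "X", length_bp = 2e6,
                                      n_variants = 600),
                    sweeps = data.frame(arm = "X", start = 5e5, end = 1e6,
                                        divergence = 0.95))
  v <- simulate_frequencies(cfg)
  ann <- simulate_annotations(cfg, v)
  iv <- assign_genes(scan_intervals(v), ann)
  strict <- select_candidates(ann, iv, filter_params(1e-5, 1e-3))
  relaxed <- select_candidates(ann, iv, filter_params(1e-3, 1e-2))
  expect_true(all(relaxed$selected[strict$selected]))
})
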