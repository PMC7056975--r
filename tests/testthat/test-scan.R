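test_that("hand-traced merge examples produce the stated intervals", {
  # interruption of 2 variants, both > 0.5: merged into one interval
  iv <- scan_intervals(make_variants(c(0.9, 0.85, 0.6, 0.55, 0.95),
                                     pos = c(100, 200, 300, 400, 500)))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_pos, 100)
  expect_equal(iv$end_pos, 500)
  expect_equal(iv$n_variants, 5L)
  expect_equal(iv$span_bp, 400)

  # 3-variant interruption: not merged ("fewer than three" fails)
  iv <- scan_intervals(make_variants(c(0.9, 0.6, 0.6, 0.6, 0.9)))
  expect_equal(nrow(iv), 2)
  expect_equal(iv$n_variants, c(1L, 1L))
  expect_equal(iv$span_bp, c(0, 0))

  # interruption violating the 0.5 minimum: not merged
  iv <- scan_intervals(make_variants(c(0.9, 0.4, 0.9)))
  expect_equal(nrow(iv), 2)
  expect_equal(iv$n_variants, c(1L, 1L))

  # nothing above the high threshold
  expect_equal(nrow(scan_intervals(make_variants(c(0.5, 0.79, 0.3)))), 0)
})

test_that("thresholds are strict inequalities", {
  # delta_p exactly 0.8 does not qualify; exactly 0.5 does not merge
  iv <- scan_intervals(make_variants(c(0.8, 0.9, 0.5, 0.9)))
  expect_equal(nrow(iv), 2)
  expect_equal(iv$n_variants, c(1L, 1L))
})

test_that("scan agrees with the brute-force merge-to-fixpoint oracle", {
  set.seed(7001)
  params <- scan_params()
  for (i in 1:300) {
    v <- random_variant_table()
    got <- scan_intervals(v, params)
    want <- oracle_scan(v, params)
    expect_equal(got$arm, want$arm)
    expect_equal(got$start_pos, want$start_pos)
    expect_equal(got$end_pos, want$end_pos)
    expect_equal(got$n_variants, as.integer(want$n_variants))
  }
})

test_that("scan output satisfies its structural invariants", {
  set.seed(7002)
  for (i in 1:50) {
    v <- random_variant_table()
    iv <- scan_intervals(v)
    # disjoint and sorted within arm; never spanning arms
    for (a in unique(iv$arm)) {
      ia <- iv[iv$arm == a, ]
      expect_true(all(ia$start_pos <= ia$end_pos))
      if (nrow(ia) > 1) {
        expect_true(all(ia$start_pos[-1] > ia$end_pos[-nrow(ia)]))
      }
      expect_true(all(ia$end_pos <= max(v$pos[v$arm == a])))
    }
    expect_equal(iv$span_bp, iv$end_pos - iv$start_pos)
    expect_true(all(iv$span_bp[iv$n_variants == 1] == 0))
    # every qualifying variant lies in exactly one interval
    hot <- v[v$delta_p > 0.8, ]
    n_cover <- vapply(seq_len(nrow(hot)), function(j) {
      sum(iv$arm == hot$arm[j] & iv$start_pos <= hot$pos[j] &
            iv$end_pos >= hot$pos[j])
    }, numeric(1))
    expect_true(all(n_cover == 1))
    # monotonicity: a stricter high threshold never covers more variants
    iv9 <- scan_intervals(v, scan_params(high_threshold = 0.9))
    expect_lte(sum(iv9$n_variants), sum(iv$n_variants))
  }
})

test_that("unsorted input is rejected", {
  v <- make_variants(c(0.9, 0.9), pos = c(200, 100))
  expect_error(scan_intervals(v), "sorted")
})

test_that("gene assignment follows closed-interval overlap with optional flank", {
  iv <- scan_intervals(make_variants(c(0.9, 0.85, 0.6, 0.55, 0.95),
                                     pos = c(100, 200, 300, 400, 500)))
  ann <- data.frame(gene_id = c("inside", "beyond", "tail"),
                    symbol = c("a", "b", "c"), arm = "X",
                    start = c(150, 501, 495), end = c(250, 600, 600),
                    expressed_ovary = TRUE, expressed_accessory_gland = TRUE,
                    rnai_available = TRUE, min_snp_p = NA_real_)
  g0 <- assign_genes(iv, ann, flank_bp = 0)
  expect_setequal(strsplit(g0$genes, ",")[[1]], c("inside", "tail"))
  g100 <- assign_genes(iv, ann, flank_bp = 100)
  expect_setequal(strsplit(g100$genes, ",")[[1]],
                  c("inside", "tail", "beyond"))

  # zero-span single-variant interval still overlaps a containing gene
  iv1 <- scan_intervals(make_variants(0.9, pos = 50))
  ann1 <- ann[1, ]
  ann1$start <- 10; ann1$end <- 60
  expect_equal(assign_genes(iv1, ann1)$genes, "inside")

  ann_bad <- rbind(ann, transform(ann[1, ], arm = "Y", gene_id = "offarm"))
  expect_warning(g <- assign_genes(iv, ann_bad), "unknown")
  expect_false(grepl("offarm", g$genes[1]))
})

test_that("planted sweeps are recovered on synthetic data", {
  cfg <- sim_config(seed = 42,
                    arms = data.frame(arm = "X", length_bp = 5e6,
                                      n_variants = 1500),
                    sweeps = data.frame(arm = "X",
                                        start = c(5e5, 3e6),
                                        end = c(1e6, 3.6e6),
                                        divergence = c(0.95, 0.9)))
  v <- simulate_frequencies(cfg)
  rec <- sweep_recovery(v, scan_intervals(v))
  expect_true(all(rec$recovered))
})
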