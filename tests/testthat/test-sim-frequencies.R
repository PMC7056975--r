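test_that("genome simulation is deterministic and gene-panel independent", {
  cfg <- sim_config(seed = 11,
                    arms = data.frame(arm = "X", length_bp = 1e6,
                                      n_variants = 300),
                    sweeps = data.frame(arm = "X", start = 2e5, end = 4e5,
                                        divergence = 0.9))
  v1 <- simulate_frequencies(cfg)
  v2 <- simulate_frequencies(cfg)
  expect_identical(v1, v2)

  # adding screen genes must not perturb the genome substream
  panel <- default_screen_panel()
  cfg2 <- sim_config(seed = 11, arms = cfg$arms, sweeps = cfg$sweeps,
                     screen_genes = panel$genes[1:3, ],
                     productivity_effects = panel$productivity[1:3, ])
  expect_identical(simulate_frequencies(cfg2), v1)
})

test_that("noise-free limit gives exactly the target divergence", {
  cfg <- sim_config(seed = 2,
                    arms = data.frame(arm = "X", length_bp = 1e5,
                                      n_variants = 100),
                    sweeps = data.frame(arm = "X", start = 1, end = 1e5,
                                        divergence = 1.0),
                    drift_concentration = 1e9, coverage = 1e7)
  v <- simulate_frequencies(cfg)
  expect_true(all(!is.na(v$sweep)))
  expect_equal(v$delta_p, rep(1, nrow(v)), tolerance = 1e-6)
})

test_that("without sweeps the |delta p| > 0.8 tail is essentially empty", {
  # independent Monte-Carlo oracle for the beta-binomial difference tail at
  # drift concentration 50, coverage 50, 5-vs-5 lines
  set.seed(401)
  n <- 20000
  p0 <- runif(n, 0.05, 0.95)
  grp <- function() {
    tr <- matrix(rbeta(n * 5, rep(p0, 5) * 50, rep(1 - p0, 5) * 50), n, 5)
    rowMeans(matrix(rbinom(n * 5, 50, tr) / 50, n, 5))
  }
  oracle_tail <- mean(abs(grp() - grp()) > 0.8)
  expect_lt(oracle_tail, 0.001)

  for (seed in 1:3) {
    cfg <- sim_config(seed = seed,
                      arms = data.frame(arm = "X", length_bp = 2e7,
                                        n_variants = 10000))
    v <- simulate_frequencies(cfg)
    expect_lt(mean(v$delta_p > 0.8), 0.001)
  }
})

test_that("planted-sweep |delta p| matches the target over many seeds", {
  means <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed,
                      arms = data.frame(arm = "2L", length_bp = 1e6,
                                        n_variants = 400),
                      sweeps = data.frame(arm = "2L", start = 1e5, end = 9e5,
                                          divergence = 0.85))
    v <- simulate_frequencies(cfg)
    mean(v$delta_p[!is.na(v$sweep)])
  }, numeric(1))
  expect_equal(mean(means), 0.85, tolerance = 0.02)
})

test_that("variant tables satisfy their invariants", {
  cfg <- sim_config(seed = 5,
                    arms = data.frame(arm = c("X", "3R"),
                                      length_bp = c(1e6, 1e6),
                                      n_variants = c(200, 200)),
                    sweeps = data.frame(arm = "X", start = 1e5, end = 3e5,
                                        divergence = 0.95))
  v <- simulate_frequencies(cfg)
  fr <- as.matrix(v[, grep("^(sel|ctl)_", names(v))])
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(v$p_divergence > 0 & v$p_divergence <= 1))
  for (a in unique(v$arm)) {
    pos <- v$pos[v$arm == a]
    expect_false(is.unsorted(pos, strictly = TRUE))
  }
  # delta_p recomputable from the frequency columns
  dp <- abs(rowMeans(v[, paste0("sel_", 1:5)]) -
              rowMeans(v[, paste0("ctl_", 1:5)]))
  expect_equal(v$delta_p, dp)
})

test_that("overlapping sweeps on one arm are rejected", {
  expect_error(
    sim_config(seed = 1,
               arms = data.frame(arm = "X", length_bp = 1e6, n_variants = 10),
               sweeps = data.frame(arm = c("X", "X"),
                                   start = c(100, 5000),
                                   end = c(6000, 9000),
                                   divergence = c(0.9, 0.9))),
    "overlapping sweeps")
})
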