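test_that("identical genotype patterns give zero genotype SS, F = 0, P = 1", {
  d <- data.frame(
    genotype = rep(c("a", "b"), each = 4),
    vial = rep(c("a1", "a2", "b1", "b2"), each = 2),
    y = rep(c(10, 12), 4)
  )
  fit <- fit_anova(d, "y", "genotype + vial(genotype)")
  row <- fit$table[fit$table$term == "genotype", ]
  expect_equal(row$sumsq, 0)
  expect_equal(row$statistic, 0)
  expect_equal(row$p.value, 1)
})

test_that("balanced 2x2 SS match the closed-form cell-mean decomposition", {
  # small integer table, 3 replicates per cell
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), r = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  d$y <- c(3, 7, 5, 11, 4, 8, 6, 12, 5, 9, 7, 13)
  fit <- fit_anova(d, "y", "A + B + A*B")

  # independent closed-form computation from cell and marginal means
  n_cell <- 3; n_lev <- 2
  mu <- mean(d$y)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  ss_A <- n_cell * n_lev * sum((mA - mu)^2)
  ss_B <- n_cell * n_lev * sum((mB - mu)^2)
  ss_AB <- n_cell * sum((sweep(sweep(mAB, 1, mA), 2, mB) + mu)^2)
  expect_equal(fit$table$sumsq, c(ss_A, ss_B, ss_AB), tolerance = 1e-10)

  # orthogonality on balanced data
  expect_equal(sum(fit$table$sumsq) + fit$residual_ss, fit$total_ss,
               tolerance = 1e-8)
})

test_that("2-level fixed factor F equals the squared pooled-variance t", {
  set.seed(77)
  d <- data.frame(g = rep(c("x", "y"), each = 8), y = rnorm(16, 5, 2))
  d$y[d$g == "y"] <- d$y[d$g == "y"] + 1.3
  fit <- fit_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(fit$table$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$table$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("mixed-model F ratios match the aov error-strata oracle", {
  set.seed(42)
  d <- expand.grid(sex = c("F", "M"), genotype = c("ctl", "rnai"),
                   vial_i = 1:6, fly = 1:3, stringsAsFactors = FALSE)
  d$vial <- paste0(d$genotype, d$vial_i)
  d$y <- rnorm(nrow(d), 10 + (d$sex == "M") * 2 + (d$genotype == "rnai") * 1.5)
  fit <- fit_anova(d, "y",
                   "sex + genotype + sex*genotype + vial(genotype) + sex*vial(genotype)")
  a <- summary(aov(y ~ sex * genotype + Error(vial / sex), data = d))
  vial_stratum <- a[["Error: vial"]][[1]]
  sex_stratum <- a[["Error: vial:sex"]][[1]]
  rownames(vial_stratum) <- trimws(rownames(vial_stratum))
  rownames(sex_stratum) <- trimws(rownames(sex_stratum))
  tab <- fit$table
  expect_equal(tab$statistic[tab$term == "genotype"],
               vial_stratum["genotype", "F value"], tolerance = 1e-8)
  expect_equal(tab$p.value[tab$term == "genotype"],
               vial_stratum["genotype", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "sex"],
               sex_stratum["sex", "F value"], tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "sex*genotype"],
               sex_stratum["sex:genotype", "F value"], tolerance = 1e-8)
  # EMS denominators chosen as stated
  expect_equal(tab$denom[tab$term == "genotype"], "vial(genotype)")
  expect_equal(tab$denom[tab$term == "sex"], "sex*vial(genotype)")
  expect_equal(tab$denom[tab$term == "sex*genotype"], "sex*vial(genotype)")
})

test_that("partial SS on unbalanced fixed designs match the Type III oracle", {
  set.seed(99)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"), r = 1:4,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[-c(1, 5, 10), ] # unbalance the cells
  d$y <- rnorm(nrow(d), 3 + (d$A == "a2") * 1 + (d$B == "b3") * 2)
  fit <- fit_anova(d, "y", "A + B + A*B")
  m <- lm(y ~ A * B, data = d,
          contrasts = list(A = contr.sum, B = contr.sum))
  oracle <- car::Anova(m, type = 3)
  expect_equal(fit$table$sumsq,
               oracle[c("A", "B", "A:B"), "Sum Sq"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("row order never changes any statistic", {
  set.seed(31)
  d <- expand.grid(g = c("a", "b"), v = 1:4, r = 1:3,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$vial <- paste0(d$g, d$v)
  d$y <- rnorm(nrow(d))
  f1 <- fit_anova(d, "y", "g + vial(g)")
  f2 <- fit_anova(d[sample(nrow(d)), ], "y", "g + vial(g)")
  expect_equal(f1$table, f2$table, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(g = c("a", "a", "b", "b"), y = 1:4,
                  h = c("x", "x", "y", "y"))
  # aliased: h is confounded with g
  expect_error(fit_anova(d, "y", "g + h"), "aliased")
  # single level
  expect_error(fit_anova(data.frame(g = "a", y = 1), "y", "g"),
               "fewer than 2 levels")
  # zero residual df
  expect_error(fit_anova(data.frame(g = c("a", "b"), y = 1:2), "y", "g"),
               "residual degrees of freedom")
  # interaction without its main effects
  d2 <- expand.grid(A = c("a", "b"), B = c("c", "d"), r = 1:2)
  d2$y <- rnorm(8)
  expect_error(fit_anova(d2, "y", "A + A*B"), "main effects")
  # empty fixed-effect cell
  d3 <- d2[!(d2$A == "a" & d2$B == "c"), ]
  expect_error(fit_anova(d3, "y", "A + B + A*B"), "empty cell")
})
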