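# Classical fixed/mixed factorial ANOVA on (near-)balanced designs.
#
# Model terms are written in the field's notation, e.g.
#   "S + G + S*G + Rep(G) + S*Rep(G)"
# where Name(Inner) marks a random grouping factor (Name) nested within the
# Inner factors; any term containing a nested grouping factor is random.
# Sums of squares are partial (Type III-style, full-vs-reduced on
# sum-to-zero contrast blocks), which reduce to the sequential decomposition
# when the design is balanced. Each term's F denominator is chosen by
# expected mean squares: the lowest random term whose factor set contains
# the tested term's factors, falling back to the residual.

split_outside_parens <- function(s, seps) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  parts <- character()
  cur <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth == 0L && ch %in% seps) {
      parts <- c(parts, paste(cur, collapse = ""))
      cur <- character()
    } else cur <- c(cur, ch)
  }
  trimws(c(parts, paste(cur, collapse = "")))
}

cross_seps <- c("*", ":", "×")

parse_model_terms <- function(model) {
  term_strs <- split_outside_parens(model, "+")
  term_strs <- term_strs[nzchar(term_strs)]
  assert_that(length(term_strs) > 0, "empty model")
  lapply(term_strs, function(ts) {
    comps <- split_outside_parens(ts, cross_seps)
    plain <- character(); nested <- list()
    for (cp in comps) {
      m <- regmatches(cp, regexec("^([A-Za-z_.][A-Za-z0-9_.]*)\\((.+)\\)$", cp))[[1]]
      if (length(m)) {
        inner <- split_outside_parens(m[3], cross_seps)
        nested[[length(nested) + 1L]] <- list(name = m[2], within = inner)
      } else {
        assert_that(grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", cp),
                    paste("cannot parse model component:", cp))
        plain <- c(plain, cp)
      }
    }
    factors <- unique(c(plain, vapply(nested, `[[`, "", "name"),
                        unlist(lapply(nested, `[[`, "within"))))
    list(label = ts, plain = plain, nested = nested,
         factors = factors, random = length(nested) > 0)
  })
}

factor_contrast <- function(f) {
  f <- droplevels(factor(f))
  C <- stats::contr.sum(nlevels(f))
  C[as.integer(f), , drop = FALSE]
}

row_kron <- function(A, B) {
  if (ncol(A) == 0L || ncol(B) == 0L) return(matrix(0, nrow(A), 0L))
  out <- matrix(NA_real_, nrow(A), ncol(A) * ncol(B))
  k <- 0L
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    k <- k + 1L
    out[, k] <- A[, i] * B[, j]
  }
  out
}

# sum-to-zero contrasts among replicates within each nesting cell
nested_block <- function(data, rep_name, cell_factors) {
  n <- nrow(data)
  cell <- interaction(data[cell_factors], drop = TRUE)
  repv <- as.character(data[[rep_name]])
  blocks <- list()
  for (cl in levels(cell)) {
    rows <- which(cell == cl)
    reps <- sort(unique(repv[rows]))
    k <- length(reps)
    if (k < 2L) next
    C <- stats::contr.sum(k)
    Mi <- matrix(0, n, k - 1L)
    Mi[rows, ] <- C[match(repv[rows], reps), , drop = FALSE]
    blocks[[cl]] <- Mi
  }
  if (!length(blocks)) matrix(0, n, 0L) else do.call(cbind, blocks)
}

term_block <- function(term, data) {
  M <- matrix(1, nrow(data), 1L)
  for (p in term$plain) M <- row_kron(M, factor_contrast(data[[p]]))
  for (nst in term$nested) M <- row_kron(M, nested_block(data, nst$name, nst$within))
  M
}

rss_of <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a fixed or mixed factorial ANOVA with EMS F-tests
#'
#' See the file-level notes for the model grammar. Designs must have at
#' least two levels per factor and no empty fixed-effect cell; aliased
#' (rank-deficient) terms and zero residual degrees of freedom are errors.
#'
#' @param data data.frame holding the response and every model factor.
#' @param response name of the (numeric) response column.
#' @param model model string, e.g. `"sex + genotype + sex*genotype +
#'   vial(genotype) + sex*vial(genotype)"`.
#' @return object of class `ems_anova`: a list with `table` (term, df,
#'   sumsq, meansq, denom, statistic, p.value), `residual_df`,
#'   `residual_ss`, `cell_means` (marginal means per fixed term), and the
#'   ingredients needed by [tukey_pairwise()].
#' @export
fit_anova <- function(data, response, model) {
  assert_that(response %in% names(data),
              paste("no response column", response))
  y <- data[[response]]
  assert_that(is.numeric(y) && all(is.finite(y)), "response must be numeric")
  terms <- parse_model_terms(model)
  labels <- vapply(terms, `[[`, "", "label")

  all_factors <- unique(unlist(lapply(terms, `[[`, "factors")))
  miss <- setdiff(all_factors, names(data))
  assert_that(length(miss) == 0,
              paste("model factors absent from data:",
                    paste(miss, collapse = ", ")))
  for (f in all_factors) {
    data[[f]] <- droplevels(factor(data[[f]]))
    assert_that(nlevels(data[[f]]) >= 2,
                paste("factor", f, "has fewer than 2 levels"))
  }
  # hierarchy: every fixed interaction's main effects must be in the model
  fixed_single <- unlist(lapply(terms, function(t)
    if (!t$random && length(t$plain) == 1L) t$plain))
  for (t in terms) {
    if (!t$random && length(t$plain) > 1L) {
      assert_that(all(t$plain %in% fixed_single),
                  paste("interaction", t$label, "lacks its main effects"))
    }
    if (!t$random) {
      tb <- table(data[t$plain])
      assert_that(all(tb > 0),
                  paste("empty cell in fixed term", t$label))
    }
  }

  blocks <- lapply(terms, term_block, data = data)
  ncols <- vapply(blocks, ncol, 0L)
  X <- cbind(`(Intercept)` = rep(1, nrow(data)), do.call(cbind, blocks))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep_cols <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    col_term <- rep(c("(Intercept)", labels), times = c(1L, ncols))
    stop("aliased model terms: ",
         paste(unique(col_term[dep_cols]), collapse = ", "), call. = FALSE)
  }
  resid_df <- nrow(data) - ncol(X)
  assert_that(resid_df > 0, "zero residual degrees of freedom")
  rss_full <- rss_of(X, y)

  ss <- df <- numeric(length(terms))
  col_start <- 1L + c(0L, cumsum(ncols))[seq_along(terms)]
  for (i in seq_along(terms)) {
    keep <- setdiff(seq_len(ncol(X)), col_start[i] + seq_len(ncols[i]) - 1L + 1L)
    ss[i] <- max(0, rss_of(X[, keep, drop = FALSE], y) - rss_full)
    df[i] <- ncols[i]
  }
  ms <- ss / df
  ms_resid <- rss_full / resid_df

  # EMS denominator: lowest random term whose factor set contains the term's
  denom <- character(length(terms))
  f_val <- p_val <- denom_df <- denom_ms <- numeric(length(terms))
  fsets <- lapply(terms, `[[`, "factors")
  for (i in seq_along(terms)) {
    cands <- which(vapply(seq_along(terms), function(j) {
      j != i && terms[[j]]$random && all(fsets[[i]] %in% fsets[[j]])
    }, logical(1)))
    if (length(cands)) {
      j <- cands[which.min(lengths(fsets[cands]))]
      denom[i] <- labels[j]
      denom_ms[i] <- ms[j]
      denom_df[i] <- df[j]
    } else {
      denom[i] <- "Residual"
      denom_ms[i] <- ms_resid
      denom_df[i] <- resid_df
    }
    # a term with zero SS is a zero effect (F = 0, P = 1) even when its
    # denominator MS is also zero, e.g. perfectly symmetric fixtures
    f_val[i] <- if (ms[i] == 0) 0
    else if (denom_ms[i] > 0) ms[i] / denom_ms[i] else Inf
    p_val[i] <- stats::pf(f_val[i], df[i], denom_df[i], lower.tail = FALSE)
  }

  tab <- data.frame(term = labels, df = df, sumsq = ss, meansq = ms,
                    denom = denom, statistic = f_val, p.value = p_val,
                    stringsAsFactors = FALSE)
  fit <- structure(list(
    table = tab, residual_df = resid_df, residual_ss = rss_full,
    total_ss = sum((y - mean(y))^2), n = nrow(data),
    response = response, model = model, terms = terms,
    ms = c(stats::setNames(ms, labels), Residual = ms_resid),
    denom_df_all = c(stats::setNames(denom_df, labels), Residual = resid_df),
    data = data
  ), class = "ems_anova")
  fit$cell_means <- stats::setNames(
    lapply(terms[!vapply(terms, `[[`, TRUE, "random")], function(t)
      marginal_means(fit, t$plain)),
    labels[!vapply(terms, `[[`, TRUE, "random")])
  fit
}

#' @export
print.ems_anova <- function(x, ...) {
  cat("EMS ANOVA of", x$response, "~", x$model, "\n")
  tab <- x$table
  tab$sumsq <- signif(tab$sumsq, 5)
  tab$meansq <- signif(tab$meansq, 5)
  tab$statistic <- signif(tab$statistic, 4)
  tab$p.value <- signif(tab$p.value, 3)
  print(tab, row.names = FALSE)
  cat("Residual: df", x$residual_df, " SS", signif(x$residual_ss, 5), "\n")
  invisible(x)
}

# error stratum (denominator MS and df) appropriate for a set of factors
error_stratum <- function(fit, factors) {
  labels <- vapply(fit$terms, `[[`, "", "label")
  match_i <- which(vapply(fit$terms, function(t)
    setequal(t$factors, factors) && !t$random, logical(1)))
  if (length(match_i)) {
    i <- match_i[1]
    list(ms = fit$ms[[fit$table$denom[i]]] %||% unname(fit$ms["Residual"]),
         df = unname(fit$denom_df_all[labels[i]]),
         label = fit$table$denom[i])
  } else {
    list(ms = unname(fit$ms["Residual"]), df = fit$residual_df,
         label = "Residual")
  }
}

#' Marginal means, replication and standard errors for a factor combination
#'
#' Standard errors use the factor's EMS error stratum: for a genotype mean
#' over `n` flies in randomly varying vials, `sqrt(MS_vial(genotype) / n)`
#' estimates the standard error of the genotype mean; purely fixed factors
#' use the residual mean square.
#'
#' @param fit an [fit_anova()] result.
#' @param factors character vector of factor names.
#' @return data.frame with the factor levels, `mean`, `n`, `se`.
#' @export
marginal_means <- function(fit, factors) {
  d <- fit$data
  y <- d[[fit$response]]
  g <- interaction(d[factors], drop = TRUE, sep = ":")
  mn <- tapply(y, g, mean)
  n <- tapply(y, g, length)
  strat <- error_stratum(fit, factors)
  lv <- do.call(rbind, strsplit(names(mn), ":", fixed = TRUE))
  out <- data.frame(lv, stringsAsFactors = FALSE)
  names(out) <- factors
  out$level <- names(mn)
  out$mean <- as.numeric(mn)
  out$n <- as.integer(n)
  out$se <- sqrt(strat$ms / out$n)
  rownames(out) <- NULL
  out
}

# maximal cliques of an undirected graph given as logical adjacency matrix
# (Bron-Kerbosch, no pivoting; used on small group counts)
max_cliques <- function(adj) {
  n <- nrow(adj)
  res <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      res[[length(res) + 1L]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  res
}

#' Tukey-Kramer pairwise comparisons with a compact letter display
#'
#' All pairwise comparisons of the marginal means of `factor` (a factor name
#' or a vector naming a factor combination, e.g. the four O/B crosses)
#' against the model's EMS error stratum for that factor, using the
#' studentized-range distribution. Groups sharing a letter are not
#' significantly different at `alpha`. Letters are derived from the maximal
#' cliques of the non-significance graph.
#'
#' @param fit an [fit_anova()] result.
#' @param factor character (scalar or vector) naming the grouping factor(s).
#' @param alpha family-wise significance level.
#' @return list with `comparisons` (level pair, diff, se, q, p.value,
#'   significant) and `letters` (level, mean, n, letters), class
#'   `tukey_letters`.
#' @export
tukey_pairwise <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "ems_anova"))
  mns <- marginal_means(fit, factor)
  k <- nrow(mns)
  assert_that(k >= 2, paste("factor", paste(factor, collapse = ":"),
                            "has a single level"))
  strat <- error_stratum(fit, factor)
  pairs <- utils::combn(k, 2)
  diff <- mns$mean[pairs[1, ]] - mns$mean[pairs[2, ]]
  se_q <- sqrt(strat$ms / 2 * (1 / mns$n[pairs[1, ]] + 1 / mns$n[pairs[2, ]]))
  q <- abs(diff) / se_q
  p <- stats::ptukey(q, nmeans = k, df = strat$df, lower.tail = FALSE)
  comparisons <- data.frame(
    level1 = mns$level[pairs[1, ]], level2 = mns$level[pairs[2, ]],
    diff = diff, se = se_q * sqrt(2), q = q, p.value = p,
    significant = p < alpha, stringsAsFactors = FALSE)

  adj <- matrix(FALSE, k, k)
  adj[t(pairs)[!comparisons$significant, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj) # no self-loops: Bron-Kerbosch needs a simple graph
  cl <- max_cliques(adj)
  # order cliques by the largest member mean so 'a' tags the top group
  cl <- cl[order(vapply(cl, function(m) -max(mns$mean[m]), numeric(1)))]
  lett <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cl, function(m) i %in% m, logical(1)))],
          collapse = "")
  }, character(1))
  letters_tab <- data.frame(level = mns$level, mean = mns$mean, n = mns$n,
                            letters = lett, stringsAsFactors = FALSE)
  structure(list(comparisons = comparisons, letters = letters_tab,
                 ms = strat$ms, df = strat$df, alpha = alpha),
            class = "tukey_letters")
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat("Tukey-Kramer comparisons (error MS ", signif(x$ms, 5), ", df ",
      x$df, ", alpha ", x$alpha, ")\n", sep = "")
  print(x$letters, row.names = FALSE)
  invisible(x)
}
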