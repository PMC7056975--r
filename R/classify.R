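# Map each gene's effect calls onto the antagonistic-pleiotropy taxonomy.
#
# Axes of antagonism:
#   sex                      - significant lifespan calls oppose across sexes
#   early_vs_late_reproduction - significant weekly calls oppose between the
#                              early-week and late-week sets
#   lifespan_vs_reproduction - a significant lifespan call opposes a
#                              significant productivity call in fitness sign
#                              (a decrease in either trait is a cost)
# A gene with any axis is antagonistic_pleiotropy; with no significant call
# at all it is no_effect; otherwise it falls into the lifespan-only,
# productivity-only or concordant categories.

pleiotropy_categories <- c("no_effect", "lifespan_only_benefit",
                           "lifespan_only_cost", "productivity_only",
                           "concordant_beneficial", "concordant_deleterious",
                           "antagonistic_pleiotropy")

sig_dirs <- function(d) d[d != "ns"]

lifespan_pattern_of <- function(dF, dM) {
  if (dF == "increase" && dM == "increase") return("both_up")
  if (dF == "decrease" && dM == "decrease") return("both_down")
  if (dF != "ns" && dM != "ns") return("sex_antagonistic")
  if (dF == "increase" || dM == "increase") return("one_sex_up")
  if (dF == "decrease" || dM == "decrease") return("one_sex_down")
  "none"
}

productivity_pattern_of <- function(early, late, lifetime, all_weeks) {
  if (any(early == "increase") && any(late == "decrease"))
    return("early_up_late_down")
  if (any(early == "decrease") && any(late == "increase"))
    return("early_down_late_up")
  if (lifetime == "increase") return("lifetime_up")
  if (lifetime == "decrease") return("lifetime_down")
  if (any(all_weeks == "decrease")) return("some_week_down")
  if (any(all_weeks == "increase")) return("some_week_up")
  "none"
}

#' Classify one gene's effect calls into a pleiotropy profile
#'
#' Deterministic rule cascade over the directions of the gene's significant
#' calls; see the file-level notes for the axis definitions. The early/late
#' boundary is a parameter because the underlying vocabulary ("early age",
#' "later ages") has no canonical cutoff; weeks in neither set contribute to
#' the lifespan-vs-reproduction axis and the week-level patterns but never
#' to the early/late axis.
#'
#' @param calls effect-call data.frame for a single gene, covering
#'   `lifespan_F`, `lifespan_M` and at least one productivity trait.
#' @param early_weeks integer weeks counted as "early" (default 1-2).
#' @param late_weeks integer weeks counted as "late"; `NULL` means every
#'   assayed week >= 4.
#' @return one-row data.frame: `gene`, `lifespan_pattern`,
#'   `productivity_pattern`, `category`, `antagonism_axes`
#'   (comma-separated, "" when none).
#' @export
classify_pleiotropy <- function(calls, early_weeks = c(1L, 2L),
                                late_weeks = NULL) {
  gene <- unique(calls$gene)
  assert_that(length(gene) == 1, "calls must belong to a single gene")
  dir_of <- function(trait) {
    d <- calls$direction[calls$trait == trait]
    if (length(d)) d[1] else "ns"
  }
  dF <- dir_of("lifespan_F")
  dM <- dir_of("lifespan_M")
  assert_that(any(calls$trait == "lifespan_F") &&
                any(calls$trait == "lifespan_M"),
              "calls must cover both sexes' lifespan")
  wk <- calls[calls$trait == "weekly_productivity", , drop = FALSE]
  lt <- dir_of("lifetime_productivity")
  assert_that(nrow(wk) > 0 || any(calls$trait == "lifetime_productivity"),
              "calls must cover at least one productivity trait")
  if (is.null(late_weeks)) late_weeks <- unique(wk$week[wk$week >= 4])
  early <- sig_dirs(wk$direction[wk$week %in% early_weeks])
  late <- sig_dirs(wk$direction[wk$week %in% late_weeks])
  all_weeks <- sig_dirs(wk$direction)

  life_sig <- sig_dirs(c(dF, dM))
  prod_sig <- sig_dirs(c(all_weeks, lt))

  axes <- character()
  if (all(c("increase", "decrease") %in% life_sig)) axes <- c(axes, "sex")
  if ((any(early == "increase") && any(late == "decrease")) ||
      (any(early == "decrease") && any(late == "increase")))
    axes <- c(axes, "early_vs_late_reproduction")
  if (length(life_sig) && length(prod_sig) &&
      ((any(life_sig == "increase") && any(prod_sig == "decrease")) ||
       (any(life_sig == "decrease") && any(prod_sig == "increase"))))
    axes <- c(axes, "lifespan_vs_reproduction")

  category <-
    if (!length(life_sig) && !length(prod_sig)) "no_effect"
    else if (length(axes)) "antagonistic_pleiotropy"
    else if (!length(prod_sig))
      if (all(life_sig == "increase")) "lifespan_only_benefit"
      else "lifespan_only_cost"
    else if (!length(life_sig)) "productivity_only"
    else if (all(c(life_sig, prod_sig) == "increase")) "concordant_beneficial"
    else "concordant_deleterious"

  data.frame(
    gene = gene,
    lifespan_pattern = lifespan_pattern_of(dF, dM),
    productivity_pattern =
      productivity_pattern_of(early, late, lt, all_weeks),
    category = category,
    antagonism_axes = paste(axes, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Classify every gene in an effect-call table
#'
#' @param calls effect-call data.frame covering multiple genes.
#' @inheritParams classify_pleiotropy
#' @return data.frame with one [classify_pleiotropy()] row per gene.
#' @export
classify_screen <- function(calls, early_weeks = c(1L, 2L),
                            late_weeks = NULL) {
  genes <- unique(calls$gene)
  out <- do.call(rbind, lapply(genes, function(g)
    classify_pleiotropy(calls[calls$gene == g, , drop = FALSE],
                        early_weeks = early_weeks, late_weeks = late_weeks)))
  rownames(out) <- NULL
  out
}

#' Category tallies over a set of pleiotropy profiles
#' @param profiles output of [classify_screen()].
#' @return named integer vector over every category (zeros included).
#' @export
tally_categories <- function(profiles) {
  tab <- table(factor(profiles$category, levels = pleiotropy_categories))
  stats::setNames(as.integer(tab), names(tab))
}
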