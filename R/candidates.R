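# Three-criterion candidate-gene selection with per-criterion audit flags.

#' Parameters of the candidate-gene filter
#'
#' Two selection routes feed the screen: genes inside a divergence interval
#' whose best single-variant divergence P-value beats `p_cutoff`, and genes
#' outside any interval (divergence below the interval threshold) whose
#' best P-value is still nominally significant (`nominal_p_cutoff`). Either
#' route additionally requires expression in both ovary and accessory gland
#' and an available RNAi stock.
#'
#' @param p_cutoff per-variant divergence P-value cutoff on the interval
#'   route (default 1e-5).
#' @param nominal_p_cutoff cutoff on the non-interval (nominal) route
#'   (default 1e-3).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(p_cutoff = 1e-5, nominal_p_cutoff = 1e-3) {
  assert_that(p_cutoff > 0 && p_cutoff < 1, "p_cutoff must lie in (0,1)")
  assert_that(nominal_p_cutoff > 0 && nominal_p_cutoff < 1,
              "nominal_p_cutoff must lie in (0,1)")
  structure(list(p_cutoff = p_cutoff, nominal_p_cutoff = nominal_p_cutoff),
            class = "filter_params")
}

#' Select candidate genes for the RNAi screen
#'
#' A gene is selected iff it clears the divergence criterion on either
#' route — (interval membership AND `min_snp_p < p_cutoff`) OR (no interval
#' membership AND `min_snp_p < nominal_p_cutoff`) — AND is expressed in both
#' ovary and accessory gland AND has an RNAi stock available. Rejected genes
#' carry audit flags naming every failed criterion, so alternative
#' reconstructions of the published list are possible from the output.
#'
#' @param annotations gene-annotation table with `min_snp_p` filled (see
#'   [gene_min_snp_p()]).
#' @param intervals interval table from [scan_intervals()] +
#'   [assign_genes()].
#' @param params a [filter_params()].
#' @return `annotations` plus columns `in_interval`, `crit_divergence`,
#'   `crit_expression`, `crit_rnai`, `selected`, `route`
#'   ("interval"/"nominal"/NA) and `audit` (semicolon-joined failed
#'   criteria, "" when selected).
#' @export
select_candidates <- function(annotations, intervals,
                              params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  in_iv <- annotations$gene_id %in% interval_gene_ids(intervals)
  p <- annotations$min_snp_p
  route_interval <- in_iv & !is.na(p) & p < params$p_cutoff
  route_nominal <- !in_iv & !is.na(p) & p < params$nominal_p_cutoff
  crit_divergence <- route_interval | route_nominal

  expr_known <- !is.na(annotations$expressed_ovary) &
    !is.na(annotations$expressed_accessory_gland)
  crit_expression <- expr_known & annotations$expressed_ovary &
    annotations$expressed_accessory_gland
  crit_rnai <- !is.na(annotations$rnai_available) & annotations$rnai_available

  selected <- crit_divergence & crit_expression & crit_rnai
  audit <- vapply(seq_along(selected), function(i) {
    if (selected[i]) return("")
    flags <- c(
      if (!crit_divergence[i]) "divergence",
      if (!expr_known[i]) "unknown-expression"
      else if (!crit_expression[i]) "expression",
      if (!crit_rnai[i]) "rnai_availability"
    )
    paste(flags, collapse = ";")
  }, character(1))

  out <- annotations
  out$in_interval <- in_iv
  out$crit_divergence <- crit_divergence
  out$crit_expression <- crit_expression
  out$crit_rnai <- crit_rnai
  out$selected <- selected
  out$route <- ifelse(selected & route_interval, "interval",
                      ifelse(selected & route_nominal, "nominal", NA))
  out$audit <- audit
  out
}
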