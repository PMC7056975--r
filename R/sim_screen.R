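# Phenotype-side synthetic data: the RNAi screen (lifespan, weekly
# productivity, qPCR) and the selected-vs-control (O/B) productivity assay.

control_label <- function(construct) paste0("control_", construct)

# one genotype x block cell of the lifespan assay
sim_lifespan_cell <- function(genotype, construct, control, block,
                              eff_f, eff_m, bl, ds) {
  nv <- ds$n_vials
  fps <- ds$flies_per_sex
  vial_eff <- stats::rnorm(nv, 0, bl$vial_sd)
  vial_id <- sprintf("%s.b%d.v%02d", genotype, block, seq_len(nv))
  per_sex <- function(sex, base, eff) {
    data.frame(
      genotype = genotype, control = control, construct = construct,
      block = block, sex = sex,
      vial = rep(vial_id, each = fps),
      lifespan = pmax(0, base + eff + rep(vial_eff, each = fps) +
                        stats::rnorm(nv * fps, 0, bl$lifespan_sd)),
      stringsAsFactors = FALSE
    )
  }
  rbind(per_sex("F", bl$lifespan_f, eff_f),
        per_sex("M", bl$lifespan_m, eff_m))
}

# weekly productivity for the first prod_vials vials of a cell; a vial stops
# contributing the week after its last female has died
sim_productivity_cell <- function(lifespan_cell, prod_eff, bl, ds) {
  weeks <- seq_along(bl$prod_week_means)
  vials <- unique(lifespan_cell$vial)[seq_len(ds$prod_vials)]
  fem <- lifespan_cell[lifespan_cell$sex == "F" &
                         lifespan_cell$vial %in% vials, ]
  last_female <- tapply(fem$lifespan, fem$vial, max)[vials]
  rows <- expand.grid(vial = vials, week = weeks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lay_day <- (rows$week - 1) * 7 + 3 # first lay at 3-5 d old, then weekly
  rows <- rows[lay_day <= last_female[rows$vial], , drop = FALSE]
  val <- bl$prod_week_means[rows$week] + prod_eff[rows$week] +
    stats::rnorm(nrow(rows), 0, bl$prod_sd)
  one <- lifespan_cell[1, c("genotype", "control", "construct", "block")]
  data.frame(one, vial = rows$vial, week = rows$week,
             offspring_per_female = pmax(0, val),
             row.names = NULL, stringsAsFactors = FALSE)
}

# qPCR for one gene vs its control, both tissues
sim_qpcr_gene <- function(gene, control, knockdown, dct_gene, bl, ds) {
  pieces <- list()
  for (tissue in c("ovary", "accessory_gland")) {
    for (line in c(gene, control)) {
      dct_line <- bl$dct_base + dct_gene +
        if (line == gene) -log2(knockdown) else 0
      for (b in seq_len(ds$qpcr_bio)) {
        input <- stats::rnorm(1, 0, bl$qpcr_input_sd)
        dct_bio <- dct_line + stats::rnorm(1, 0, bl$qpcr_bio_sd)
        ct_ref <- bl$ct_ref + input + stats::rnorm(ds$qpcr_tech, 0, bl$qpcr_tech_sd)
        ct_tgt <- bl$ct_ref + input + dct_bio +
          stats::rnorm(ds$qpcr_tech, 0, bl$qpcr_tech_sd)
        pieces[[length(pieces) + 1L]] <- data.frame(
          line = line, gene = gene, tissue = tissue,
          biological_rep = b, technical_rep = seq_len(ds$qpcr_tech),
          ct_target = ct_tgt, ct_reference = ct_ref,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, pieces)
}

#' Simulate the RNAi screen: lifespan, weekly productivity and qPCR tables
#'
#' Emulates the screen design: per genotype, 48 vials of 3 males + 3 females
#' with a shared random vial effect on lifespan; weekly offspring/female for
#' 13 of those vials, declining with age and ending once all of a vial's
#' females have died; and qPCR (2 biological x 3 technical replicates,
#' normalized against a constant housekeeping gene) for the genes with a
#' planted knockdown. Genes are assigned round-robin to blocks and each
#' block gets its own independently simulated control genotypes (one per
#' construct background present in the block).
#'
#' Each gene, and each control x block cell, draws from its own RNG
#' substream derived from the master seed, so extending the panel never
#' changes the other genes' data.
#'
#' @param config a [sim_config()].
#' @return list with data.frames `lifespan`, `productivity`, `qpcr`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- config$screen_genes
  bl <- config$baseline
  ds <- config$design
  genes$block <- ((seq_len(nrow(genes)) - 1L) %% ds$n_blocks) + 1L

  life <- list(); prod <- list(); qpcr <- list()
  # controls: one per construct per block that needs it
  need <- unique(genes[, c("construct", "block")])
  for (i in seq_len(nrow(need))) {
    cs <- need$construct[i]; b <- need$block[i]
    set.seed(derive_seed(config$seed, sprintf("control:%s:%d", cs, b)))
    cell <- sim_lifespan_cell(control_label(cs), cs, NA_character_, b,
                              0, 0, bl, ds)
    life[[length(life) + 1L]] <- cell
    prod[[length(prod) + 1L]] <-
      sim_productivity_cell(cell, numeric(length(bl$prod_week_means)), bl, ds)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    set.seed(derive_seed(config$seed, paste0("gene:", g$gene)))
    cell <- sim_lifespan_cell(g$gene, g$construct, control_label(g$construct),
                              g$block, g$lifespan_f, g$lifespan_m, bl, ds)
    life[[length(life) + 1L]] <- cell
    prod[[length(prod) + 1L]] <- sim_productivity_cell(
      cell, config$productivity_effects[g$gene, ], bl, ds)
    if (!is.na(g$qpcr_knockdown)) {
      set.seed(derive_seed(config$seed, paste0("qpcr:", g$gene)))
      dct_gene <- stats::rnorm(1, 0, bl$dct_gene_sd)
      qpcr[[length(qpcr) + 1L]] <- sim_qpcr_gene(
        g$gene, control_label(g$construct), g$qpcr_knockdown, dct_gene, bl, ds)
    }
  }
  list(
    lifespan = do.call(rbind, life),
    productivity = do.call(rbind, prod),
    qpcr = if (length(qpcr)) do.call(rbind, qpcr) else
      data.frame(line = character(), gene = character(), tissue = character(),
                 biological_rep = integer(), technical_rep = integer(),
                 ct_target = numeric(), ct_reference = numeric())
  )
}

#' Simulate the selected-vs-control (O/B) reciprocal-cross productivity assay
#'
#' Four crosses (maternal regime x paternal regime, O/B each), 15 vials per
#' cross, four weekly lays. The default planted effects emulate maternally
#' controlled postponed reproductive senescence: selected-line (O) mothers
#' sustain late-week productivity while control-line (B) mothers decline.
#'
#' @param config a [sim_config()].
#' @param maternal_effect per-week offspring/female added when the mother is
#'   from the O regime.
#' @param paternal_effect per-week shift added when the father is from O.
#' @param interaction_effect per-week shift added only to the O x O cross.
#' @return data.frame with columns `gm`, `gf` (maternal/paternal regime),
#'   `vial`, `week`, `offspring_per_female`.
#' @export
simulate_ob_productivity <- function(config,
                                     maternal_effect = c(0, 2, 8, 12),
                                     paternal_effect = c(0, 0, 0, 0),
                                     interaction_effect = c(0, 0, 0, 0)) {
  stopifnot(inherits(config, "sim_config"))
  bl <- config$baseline
  ds <- config$design
  weeks <- seq_along(bl$ob_week_means)
  stopifnot(length(maternal_effect) == length(weeks),
            length(paternal_effect) == length(weeks),
            length(interaction_effect) == length(weeks))
  set.seed(derive_seed(config$seed, "ob_productivity"))
  out <- list()
  for (gm in c("O", "B")) for (gf in c("O", "B")) {
    for (w in weeks) {
      mu <- bl$ob_week_means[w] +
        (gm == "O") * maternal_effect[w] +
        (gf == "O") * paternal_effect[w] +
        (gm == "O" && gf == "O") * interaction_effect[w]
      out[[length(out) + 1L]] <- data.frame(
        gm = gm, gf = gf,
        vial = sprintf("%s%s.v%02d", gm, gf, seq_len(ds$ob_vials)),
        week = w,
        offspring_per_female = pmax(0, mu + stats::rnorm(ds$ob_vials, 0, bl$prod_sd)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
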