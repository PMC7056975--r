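# Readers/writers for the pipeline's plain-text tables.
#
# Coordinate convention: all internal coordinates are 1-based inclusive
# (FlyBase convention). Only the BED export converts to 0-based half-open.
# Allele-frequency polarity is whatever allele the input reports; the scan
# uses only |delta p|, so polarity never matters.

freq_cols <- function(nms) {
  list(sel = grep("^sel_[0-9]+$", nms, value = TRUE),
       ctl = grep("^ctl_[0-9]+$", nms, value = TRUE))
}

#' Read a per-variant allele-frequency table
#'
#' Expected TSV schema: columns `arm`, `pos`, one `sel_<i>` column per
#' selected replicate line and one `ctl_<j>` per control line (reference
#' allele frequency in \[0, 1\]), plus optional `delta_p`, `p_divergence`
#' and any extra columns (preserved). `delta_p` is (re)computed as
#' |mean(sel) - mean(ctl)| when absent. Rows are returned sorted by
#' (arm, pos) with arm order as first encountered.
#'
#' @param path TSV file path.
#' @param min_lines `NULL` (default): any variant with a missing line
#'   frequency is dropped with a warning. Otherwise, keep variants with at
#'   least `min_lines` non-missing frequencies in each of the two groups
#'   (delta_p then uses the available lines).
#' @return data.frame of variants.
#' @export
read_variants <- function(path, min_lines = NULL) {
  assert_that(file.exists(path), paste("no such file:", path))
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_variants(x, min_lines = min_lines, source = path)
}

#' Validate (and complete) an in-memory variant table
#'
#' Applies the same checks as [read_variants()]: required columns, frequency
#' bounds, unique sorted coordinates, missing-line policy, and recomputation
#' of `delta_p`.
#'
#' @param x data.frame in the variant schema.
#' @inheritParams read_variants
#' @param source label used in error messages.
#' @return validated data.frame.
#' @export
validate_variants <- function(x, min_lines = NULL, source = "variants") {
  assert_that(all(c("arm", "pos") %in% names(x)),
              paste(source, "lacks arm/pos columns"))
  fc <- freq_cols(names(x))
  assert_that(length(fc$sel) >= 1 && length(fc$ctl) >= 1,
              paste(source, "needs sel_<i> and ctl_<j> frequency columns"))
  assert_that(is.numeric(x$pos) && all(is.finite(x$pos)) && all(x$pos >= 1),
              paste(source, ": pos must be >= 1"))

  fr <- as.matrix(x[, c(fc$sel, fc$ctl), drop = FALSE])
  bad <- which(rowSums(!is.na(fr) & (fr < 0 | fr > 1)) > 0)
  if (length(bad)) {
    stop(source, ": frequency outside [0,1] at row ", bad[1],
         " (", x$arm[bad[1]], ":", x$pos[bad[1]], ")", call. = FALSE)
  }
  n_na_sel <- rowSums(is.na(fr[, fc$sel, drop = FALSE]))
  n_na_ctl <- rowSums(is.na(fr[, fc$ctl, drop = FALSE]))
  if (is.null(min_lines)) {
    drop <- n_na_sel + n_na_ctl > 0
  } else {
    drop <- (length(fc$sel) - n_na_sel) < min_lines |
      (length(fc$ctl) - n_na_ctl) < min_lines
  }
  if (any(drop)) {
    warning(sum(drop), " variant(s) dropped for missing line frequencies",
            call. = FALSE)
    x <- x[!drop, , drop = FALSE]
  }
  x$delta_p <- abs(
    rowMeans(as.matrix(x[, fc$sel, drop = FALSE]), na.rm = TRUE) -
      rowMeans(as.matrix(x[, fc$ctl, drop = FALSE]), na.rm = TRUE))
  if (!is.null(x$p_divergence)) {
    assert_that(all(is.na(x$p_divergence) |
                      (x$p_divergence > 0 & x$p_divergence <= 1)),
                paste(source, ": p_divergence must lie in (0,1]"))
  }
  x$arm <- factor(x$arm, levels = unique(x$arm))
  x <- x[order(x$arm, x$pos), , drop = FALSE]
  x$arm <- as.character(x$arm)
  if (anyDuplicated(x[, c("arm", "pos")])) {
    d <- x[duplicated(x[, c("arm", "pos")]), c("arm", "pos")][1, ]
    stop(source, ": duplicate variant at ", d$arm, ":", d$pos, call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Write a variant table as TSV
#' @param x variant data.frame.
#' @param path output path.
#' @export
write_variants <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variants from a VCF with a per-sample AF FORMAT field
#'
#' Thin adapter over \pkg{vcfR}: extracts the numeric `AF` value per sample
#' and assembles the same table [read_variants()] produces from TSV.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sel_samples,ctl_samples sample names of the selected / control
#'   replicate lines.
#' @inheritParams read_variants
#' @return data.frame of variants.
#' @export
read_variants_vcf <- function(path, sel_samples, ctl_samples,
                              min_lines = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  af <- vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)
  miss <- setdiff(c(sel_samples, ctl_samples), colnames(af))
  assert_that(length(miss) == 0,
              paste("samples absent from VCF:", paste(miss, collapse = ", ")))
  fix <- vcfR::getFIX(v)
  x <- data.frame(arm = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                  stringsAsFactors = FALSE)
  for (i in seq_along(sel_samples)) x[[paste0("sel_", i)]] <- af[, sel_samples[i]]
  for (i in seq_along(ctl_samples)) x[[paste0("ctl_", i)]] <- af[, ctl_samples[i]]
  validate_variants(x, min_lines = min_lines, source = path)
}

annotation_cols <- c("gene_id", "symbol", "arm", "start", "end",
                     "expressed_ovary", "expressed_accessory_gland",
                     "rnai_available")

#' Read a gene-annotation table (TSV)
#'
#' Columns: `gene_id`, `symbol`, `arm`, `start`, `end` (1-based inclusive),
#' logical `expressed_ovary`, `expressed_accessory_gland`,
#' `rnai_available`, optional `min_snp_p`.
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(annotation_cols %in% names(x)),
              paste("annotation table lacks columns:",
                    paste(setdiff(annotation_cols, names(x)), collapse = ", ")))
  assert_that(all(x$start <= x$end), "gene start must be <= end")
  for (col in c("expressed_ovary", "expressed_accessory_gland",
                "rnai_available")) {
    x[[col]] <- as.logical(x[[col]])
  }
  if (is.null(x$min_snp_p)) x$min_snp_p <- NA_real_
  x
}

#' Write a gene-annotation table (TSV)
#' @param x annotation data.frame.
#' @param path output path.
#' @export
write_annotations <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write divergence intervals as BED
#'
#' BED is 0-based half-open, so `chromStart = start_pos - 1` and
#' `chromEnd = end_pos`; a single-variant interval at position p becomes
#' the 1-bp feature `[p-1, p)`. The name column carries the interval id and
#' the score column the member-variant count capped at 1000.
#'
#' @param intervals interval table from [scan_intervals()].
#' @param path output path.
#' @export
write_intervals_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = intervals$arm,
                    chromStart = intervals$start_pos - 1,
                    chromEnd = intervals$end_pos,
                    name = intervals$interval_id,
                    score = pmin(intervals$n_variants, 1000))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write the three phenotype tables (CSV)
#'
#' `kind` selects the schema: `"lifespan"` (genotype, control, construct,
#' block, sex, vial, lifespan), `"productivity"` (genotype or gm/gf cross,
#' vial, week, offspring_per_female), or `"qpcr"` (line, gene, tissue,
#' biological_rep, technical_rep, ct_target, ct_reference).
#'
#' @param path CSV path.
#' @param kind one of `"lifespan"`, `"productivity"`, `"qpcr"`.
#' @return data.frame.
#' @export
read_phenotypes <- function(path, kind = c("lifespan", "productivity", "qpcr")) {
  kind <- match.arg(kind)
  assert_that(file.exists(path), paste("no such file:", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- switch(kind,
    lifespan = c("genotype", "sex", "vial", "lifespan"),
    productivity = c("vial", "week", "offspring_per_female"),
    qpcr = c("line", "gene", "tissue", "biological_rep", "technical_rep",
             "ct_target", "ct_reference"))
  assert_that(all(required %in% names(x)),
              paste(kind, "table lacks columns:",
                    paste(setdiff(required, names(x)), collapse = ", ")))
  if (kind == "lifespan") {
    assert_that(all(x$sex %in% c("F", "M")), "sex must be F or M")
    assert_that(all(is.finite(x$lifespan) & x$lifespan >= 0),
                "lifespan must be finite and >= 0")
  }
  if (kind == "productivity") {
    assert_that(all(x$week == round(x$week) & x$week >= 1),
                "week must be a positive integer")
    assert_that(all(is.na(x$offspring_per_female) |
                      x$offspring_per_female >= 0),
                "offspring_per_female must be non-negative or missing")
  }
  if (kind == "qpcr") {
    assert_that(all(is.na(x$ct_reference) |
                      (is.finite(x$ct_reference) & x$ct_reference > 0)) &&
                  all(is.finite(x$ct_target) & x$ct_target > 0),
                "Ct values must be finite and positive")
  }
  x
}

#' @rdname read_phenotypes
#' @param x phenotype data.frame.
#' @export
write_phenotypes <- function(x, path, kind = c("lifespan", "productivity", "qpcr")) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
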