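#' Classification thresholds for rare deleterious variants
#'
#' Defaults follow the standard exome filtering rules: rare means gnomAD
#' global AF below 1%; a missense variant is predicted deleterious when
#' Phred-scaled CADD >= 20, or REVEL >= 0.7, or PREDICT >= 0.6; a
#' loss-of-function variant when CADD >= 20 or LOFTEE is high-confidence.
#'
#' @param rare_af_max Rarity cut-off on gnomAD global AF.
#' @param cadd_min,revel_min,predict_min Missense score thresholds.
#' @param loftee_required LOFTEE flag counting as supporting ("HC").
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function(rare_af_max = 0.01, cadd_min = 20,
                                      revel_min = 0.7, predict_min = 0.6,
                                      loftee_required = "HC") {
  stopifnot(rare_af_max > 0, cadd_min > 0, revel_min > 0, predict_min > 0)
  list(rare_af_max = rare_af_max, cadd_min = cadd_min, revel_min = revel_min,
       predict_min = predict_min, loftee_required = loftee_required)
}

LOF_CONSEQUENCES <- c("lof_frameshift", "lof_stopgain", "lof_startloss",
                      "lof_splice")

#' Classify annotated variants as rare and predicted deleterious
#'
#' Total, deterministic classification of an annotation table. A variant is
#' rare when its gnomAD AF is below the cut-off or missing (variants absent
#' from gnomAD are treated as rare -- required for novel variants to be
#' countable). Deleteriousness is an OR over the available evidence for the
#' consequence group: missense uses CADD/REVEL/PREDICT, loss-of-function
#' (including canonical splice sites) uses CADD/LOFTEE; other consequences
#' are never deleterious. A missing score is non-supporting. A variant is
#' novel when absent from gnomAD, dbSNP, and ClinVar.
#'
#' @param annotations Data frame with columns `variant_id`, `gene`,
#'   `consequence` (one of `missense`, `lof_frameshift`, `lof_stopgain`,
#'   `lof_startloss`, `lof_splice`, `other`), `gnomad_af`, `cadd_phred`,
#'   `revel`, `predict_score`, `loftee`, `in_gnomad`, `in_dbsnp`,
#'   `in_clinvar`. Missing values are allowed in the score columns.
#' @param thresholds See [classification_thresholds()].
#' @return The input with added columns `is_rare`, `is_deleterious`,
#'   `tools_supporting` (semicolon-joined), `is_novel`, `is_lof`.
#' @export
classify_variants <- function(annotations, thresholds = classification_thresholds()) {
  a <- annotations
  ok <- function(x, cut) !is.na(x) & x >= cut
  is_lof <- a$consequence %in% LOF_CONSEQUENCES
  is_mis <- a$consequence == "missense"
  cadd <- ok(a$cadd_phred, thresholds$cadd_min)
  revel <- ok(a$revel, thresholds$revel_min) & is_mis
  pred <- ok(a$predict_score, thresholds$predict_min) & is_mis
  loftee <- !is.na(a$loftee) & a$loftee == thresholds$loftee_required & is_lof
  support <- cbind(CADD = cadd & (is_mis | is_lof), REVEL = revel,
                   PREDICT = pred, LOFTEE = loftee)
  a$is_lof <- is_lof
  a$is_rare <- is.na(a$gnomad_af) | a$gnomad_af < thresholds$rare_af_max
  a$is_deleterious <- rowSums(support) > 0
  a$tools_supporting <- apply(support, 1, function(r)
    paste(colnames(support)[r], collapse = ";"))
  a$is_novel <- !(a$in_gnomad | a$in_dbsnp | a$in_clinvar)
  a
}

#' Disease-cohort exclusions for gene-level analyses
#'
#' Removes samples whose disease cohort would inflate variant counts in the
#' matching gene: respiratory-disease samples for CFTR, neuromuscular
#' samples for RYR1. Other genes pass through unchanged.
#'
#' @param samples Sample data frame with a `cohort_label` column.
#' @param gene Gene under analysis.
#' @param exclusions Named character vector mapping gene to the excluded
#'   cohort label.
#' @return Filtered sample data frame.
#' @export
apply_cohort_exclusions <- function(samples, gene,
                                    exclusions = c(CFTR = "respiratory",
                                                   RYR1 = "neuromuscular")) {
  if (!gene %in% names(exclusions)) {
    message("no cohort exclusion defined for ", gene, "; samples unchanged")
    return(samples)
  }
  keep <- is.na(samples$cohort_label) |
    samples$cohort_label != exclusions[[gene]]
  out <- samples[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("all samples excluded for ", gene, " analysis", call. = FALSE)
  }
  out
}

#' Per-sample burden of rare deleterious variants
#'
#' Counts, per sample, the distinct rare predicted-deleterious variants
#' carried (>= 1 copy counts once; homozygotes contribute one). Optionally
#' restricted to a gene list (e.g. the CYP genes).
#'
#' @param geno A `pgx_geno`.
#' @param classifications Output of [classify_variants()] with `variant_id`
#'   values matching the matrix's `chrom:pos:ref:alt` keys or rsIDs.
#' @param genes Optional gene subset.
#' @return A `pgx_burden` (see [actionable_burden()]).
#' @export
rare_deleterious_burden <- function(geno, classifications, genes = NULL) {
  q <- classifications[classifications$is_rare & classifications$is_deleterious, ]
  if (!is.null(genes)) q <- q[q$gene %in% genes, ]
  keys <- colnames(geno$calls)
  idx <- match(q$variant_id, keys)
  miss <- is.na(idx)
  idx[miss] <- match(q$variant_id[miss], geno$variants$rsid)
  idx <- idx[!is.na(idx)]
  carried <- geno$calls[, idx, drop = FALSE] >= 1
  carried[is.na(carried)] <- FALSE
  burden_summary(rowSums(carried), geno$samples$sample)
}

#' Tool-agreement summary of deleterious predictions
#'
#' Tabulates, separately for missense and loss-of-function variants (among
#' the rare ones), how many variants each non-empty tool subset supports,
#' with "at least one tool" and "all applicable tools" (consensus)
#' marginals.
#'
#' @param classifications Output of [classify_variants()].
#' @param rare_only Restrict to rare variants (default TRUE, matching the
#'   usual reporting).
#' @return List with per-group pattern tables and marginals.
#' @export
consensus_summary <- function(classifications, rare_only = TRUE) {
  cl <- classifications
  if (rare_only) cl <- cl[cl$is_rare, , drop = FALSE]
  summarize <- function(d, all_tools) {
    pat <- table(d$tools_supporting[d$tools_supporting != ""])
    n_tools <- lengths(strsplit(d$tools_supporting, ";", fixed = TRUE))
    list(patterns = pat,
         n = nrow(d),
         at_least_one = sum(d$is_deleterious),
         consensus = sum(n_tools == length(all_tools)))
  }
  list(missense = summarize(cl[cl$consequence == "missense", , drop = FALSE],
                            c("CADD", "REVEL", "PREDICT")),
       lof = summarize(cl[cl$is_lof, , drop = FALSE], c("CADD", "LOFTEE")))
}

#' Regression of per-gene variant count on transcript length and constraint
#'
#' Ordinary least squares of the total variant count per gene on transcript
#' length (in kilobases) and the gnomAD-style o/e constraint score. The
#' length coefficient is the expected increase in variants per kilobase of
#' transcript.
#'
#' @param per_gene_counts Data frame with columns `gene` and `n_variants`.
#' @param registry A `pgx_registry` supplying `transcript_length` and
#'   `oe_constraint`.
#' @return List of class `pgx_regression`: `slope_per_kb`, `intercept`,
#'   `oe_coefficient`, `p_values`, and the underlying `lm` fit.
#' @export
variant_count_regression <- function(per_gene_counts, registry) {
  d <- merge(per_gene_counts, as.data.frame(registry), by = "gene")
  if (nrow(d) < 3) {
    stop("degenerate design: need at least 3 genes with counts, lengths, ",
         "and constraint scores", call. = FALSE)
  }
  d$length_kb <- d$transcript_length / 1000
  fit <- stats::lm(n_variants ~ length_kb + oe_constraint, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear design: regression coefficients not estimable", call. = FALSE)
  }
  s <- summary(fit)
  out <- list(slope_per_kb = unname(stats::coef(fit)["length_kb"]),
              intercept = unname(stats::coef(fit)["(Intercept)"]),
              oe_coefficient = unname(stats::coef(fit)["oe_constraint"]),
              p_values = s$coefficients[, "Pr(>|t|)"],
              fit = fit)
  class(out) <- "pgx_regression"
  out
}

#' @export
print.pgx_regression <- function(x, ...) {
  cat(sprintf("Variant-count regression: %+.3f variants per kb (p = %.2g), o/e coefficient %+.3f (p = %.2g)\n",
              x$slope_per_kb, x$p_values["length_kb"],
              x$oe_coefficient, x$p_values["oe_constraint"]))
  invisible(x)
}
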