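#' Percentage summary with report-layer rounding
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @param digits Decimal places (default 1).
#' @return `100 * num / den` rounded; `NA` where the denominator is zero.
#' @export
#' @examples
#' summarize_percentages(3586, 13165)  # 27.2
summarize_percentages <- function(num, den, digits = 1) {
  if (any(num > den, na.rm = TRUE)) {
    stop("numerator exceeds denominator", call. = FALSE)
  }
  out <- ifelse(den == 0, NA_real_, round(100 * num / den, digits))
  out
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end demonstration pipeline: cohort
#' size and seed, QC and classification thresholds, currency rate,
#' population size, annotation-table size, and the prescription extract
#' specification (set `drug_specs = NULL` to skip the impact stage).
#'
#' @param seed Root seed for all randomness.
#' @param n_samples Cohort size.
#' @param population Population the prescriptions are drawn from.
#' @param hkd_per_usd Currency conversion rate.
#' @param qc QC thresholds ([qc_thresholds()]).
#' @param thresholds Classification thresholds
#'   ([classification_thresholds()]).
#' @param n_annotation_variants Size of the simulated annotation table.
#' @param drug_specs Prescription simulation table (see
#'   [simulate_prescriptions()]); default [demo_drug_specs()].
#' @param out_dir Optional directory for the report files.
#' @return List of class `pgx_config`.
#' @export
pipeline_config <- function(seed = 1, n_samples = 1116, population = 7.5e6,
                            hkd_per_usd = 7.8, qc = qc_thresholds(),
                            thresholds = classification_thresholds(),
                            n_annotation_variants = 2000,
                            drug_specs = demo_drug_specs(),
                            out_dir = NULL) {
  out <- list(seed = as.integer(seed), n_samples = n_samples,
              population = population, hkd_per_usd = hkd_per_usd, qc = qc,
              thresholds = thresholds,
              n_annotation_variants = n_annotation_variants,
              drug_specs = drug_specs, out_dir = out_dir)
  class(out) <- "pgx_config"
  out
}

#' Demonstration prescription extract specification
#'
#' Drug-level unique patient counts at roughly 1/100 of a city-scale public
#' healthcare system, with 1.5x row duplication so deduplication is
#' exercised.
#'
#' @return Data frame for [simulate_prescriptions()].
#' @export
demo_drug_specs <- function() {
  data.frame(
    drug = c("simvastatin", "clopidogrel", "ibuprofen", "warfarin",
             "tacrolimus", "escitalopram", "azathioprine", "allopurinol",
             "carbamazepine", "rasburicase"),
    unique_patients = c(5663, 460, 2226, 310, 42, 640, 77, 520, 150, 12),
    duplication_rate = 1.5,
    unit_cost_hkd = c(120, 900, 40, 260, 9200, 410, 350, 60, 180, 8000),
    year = 2019L, stringsAsFactors = FALSE)
}

# estimate allele-class frequencies from called diplotypes:
# class frequency = alleles of that class / called alleles
cohort_class_frequencies <- function(diplotype_calls, defs, hla = NULL,
                                     class_freqs_template = read_class_frequencies()) {
  rows <- list()
  for (g in names(diplotype_calls)) {
    calls <- diplotype_calls[[g]]
    ok <- !calls$ambiguous & !calls$no_call
    classes <- attr(calls, "classes")
    als <- c(calls$allele1[ok], calls$allele2[ok & !calls$hemizygous])
    als <- als[!is.na(als)]
    if (length(als) == 0) next
    cl <- classes[als]
    tab <- table(cl) / length(als)
    ref <- unique(class_freqs_template$reference_class[
      class_freqs_template$gene == g])
    ref <- if (length(ref)) ref[1] else "normal"
    for (nm in names(tab)) {
      if (identical(nm, ref)) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, class = nm, freq = as.numeric(tab[[nm]]),
        reference_class = ref, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(hla)) {
    for (loc in unique(hla$locus)) {
      h <- hla[hla$locus == loc, ]
      als <- c(h$allele1, h$allele2)
      tab <- table(als) / length(als)
      for (nm in names(tab)) {
        if (grepl("XX", nm, fixed = TRUE)) next
        rows[[length(rows) + 1]] <- data.frame(
          gene = loc, class = nm, freq = as.numeric(tab[[nm]]),
          reference_class = "other", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pgx_class_freqs", "data.frame")
  out
}

#' Run the full demonstration pipeline
#'
#' Orchestrates catalog validation, cohort simulation, QC, allele
#' frequencies, star-allele and phenotype calling, actionable burden,
#' phenotype-frequency projection, rare-deleterious classification and
#' burden, the variant-count regression, and the prescription-impact
#' projection, from a single seeded configuration. Rerunning with the same
#' configuration reproduces every report exactly.
#'
#' @param config A `pgx_config` (see [pipeline_config()]).
#' @return List of class `pgx_reports`: `actionable_variants` (per-variant
#'   table with observed AF and carrier counts), `phenotype_frequencies`
#'   (frequency-table shape), `burden` (actionable and rare histograms plus
#'   headline fractions/medians), `rare_deleterious` (per-variant
#'   classification list), `impact` (per-drug projection, NULL when no
#'   prescription data), plus `regression`, `consensus`, `validation`, and
#'   `summary`. When `config$out_dir` is set the tables are also written as
#'   TSV and the summary as JSON.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pgx_config"))
  catalog <- load_actionable_catalog()
  registry <- load_pharmacogene_registry()
  validation <- validate_catalog(catalog, registry)
  defs <- read_star_allele_definitions()
  rules <- read_genotype_rules()

  # cohort
  spec <- hk_cohort_spec(config$n_samples, seed = config$seed)
  cohort <- simulate_cohort(spec)
  qc <- apply_qc(cohort$geno, thresholds = config$qc)
  geno <- qc$geno

  # observed allele frequencies / actionable variant table
  af <- compute_allele_frequency(geno)
  carriage <- catalog_carriage(geno, catalog, defs, cohort$hla)
  marker_af <- stats::setNames(af, geno$variants$rsid)
  first_marker <- vapply(seq_len(nrow(catalog)), function(i) {
    id <- catalog$identifier[i]
    if (startsWith(id, "rs")) return(id)
    m <- defs$markers[defs$gene == catalog$gene[i] & defs$allele == id]
    if (length(m) && length(m[[1]])) m[[1]][1] else NA_character_
  }, "")
  actionable_tab <- data.frame(
    gene = catalog$gene, identifier = catalog$identifier,
    functional_class = catalog$functional_class,
    af_observed = unname(marker_af[first_marker]),
    n_carriers = NA_integer_, stringsAsFactors = FALSE)
  lbl <- paste(catalog$gene, catalog$identifier)
  hit <- match(lbl, colnames(carriage))
  actionable_tab$n_carriers[!is.na(hit)] <- colSums(carriage)[hit[!is.na(hit)]]

  # diplotypes and phenotypes
  call_genes <- setdiff(unique(defs$gene), "CYP2D6")
  dcalls <- lapply(call_genes, function(g) call_star_alleles(geno, defs, g))
  names(dcalls) <- call_genes
  sex <- geno$samples$sex
  phenotypes <- do.call(rbind, lapply(dcalls, assign_phenotype, rules = rules,
                                      sex = sex))

  # burden of actionable variants
  burden_act <- actionable_burden(geno, catalog, defs, cohort$hla)

  # phenotype frequency projection from the cohort's allele-class estimates
  cf_cohort <- cohort_class_frequencies(dcalls, defs, cohort$hla)
  ptab <- phenotype_frequency_table(rules, cf_cohort)

  # rare deleterious variants
  aspec <- annotation_spec(config$n_annotation_variants,
                           genes = registry$gene, seed = config$seed)
  ann <- simulate_annotations(aspec)
  classified <- classify_variants(ann, config$thresholds)
  rare_geno <- simulate_genotypes_for_annotations(classified, geno$samples,
                                                  seed = config$seed)
  burden_rare <- rare_deleterious_burden(rare_geno, classified)
  consensus <- consensus_summary(classified)
  counts <- stats::aggregate(list(n_variants = classified$variant_id),
                             by = list(gene = classified$gene), FUN = length)
  regression <- variant_count_regression(counts, registry)

  # prescription impact
  impact <- NULL
  if (is.null(config$drug_specs)) {
    warning("no prescription table configured; impact stage skipped",
            call. = FALSE)
  } else {
    raw <- simulate_prescriptions(config$drug_specs, seed = config$seed)
    rx <- dedupe_headcount(raw)
    bygene <- unique(ptab[, c("gene", "by_gene", "sex_mode")])
    gene_freqs <- stats::setNames(bygene$by_gene, bygene$gene)
    # X-linked genes enter drug-level frequencies as a population rate
    xg <- unique(ptab$gene[ptab$sex_mode == "x_linked_male"])
    for (g in xg) {
      qv <- cf_cohort$freq[cf_cohort$gene == g]
      gene_freqs[g] <- population_carrier_rate_x_linked(sum(qv),
                                                        spec$male_fraction)
    }
    gene_freqs <- gene_freqs[!duplicated(names(gene_freqs))]
    impact <- impact_report(rx, gene_freqs = gene_freqs,
                            rate = config$hkd_per_usd)
  }

  summary <- list(
    n_samples = nrow(geno$samples),
    n_catalog_entries = nrow(catalog),
    n_catalog_genes = length(unique(catalog$gene)),
    qc = qc$report,
    fraction_ge1_actionable = burden_act$fraction_ge1,
    median_actionable_burden = burden_act$median,
    fraction_ge1_rare_deleterious = burden_rare$fraction_ge1,
    median_rare_deleterious_burden = burden_rare$median,
    n_rare = sum(classified$is_rare),
    n_rare_deleterious = sum(classified$is_rare & classified$is_deleterious),
    pct_rare = summarize_percentages(sum(classified$is_rare), nrow(classified)),
    regression_slope_per_kb = regression$slope_per_kb)
  if (!is.null(impact)) {
    summary$total_patients <- attr(impact, "total_patients")
    summary$population_share_pct <-
      population_share(attr(impact, "total_patients"), config$population)
    summary$projected_expenditure_usd <- attr(impact, "total_projected_usd")
  }

  reports <- list(actionable_variants = actionable_tab,
                  phenotype_frequencies = format_phenotype_table(ptab),
                  burden = list(actionable = burden_act, rare = burden_rare),
                  rare_deleterious = classified[classified$is_rare &
                                                  classified$is_deleterious, ],
                  impact = impact, regression = regression,
                  consensus = consensus, phenotypes = phenotypes,
                  validation = validation, summary = summary)
  class(reports) <- "pgx_reports"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) write_tsv(as.data.frame(df),
                                   file.path(config$out_dir, f))
    w(actionable_tab, "actionable_variants.tsv")
    w(reports$phenotype_frequencies, "phenotype_frequencies.tsv")
    w(data.frame(burden = names(burden_act$histogram),
                 n_actionable = as.integer(burden_act$histogram)),
      "burden_actionable.tsv")
    w(data.frame(burden = names(burden_rare$histogram),
                 n_rare_deleterious = as.integer(burden_rare$histogram)),
      "burden_rare.tsv")
    w(reports$rare_deleterious, "rare_deleterious_variants.tsv")
    if (!is.null(impact)) w(impact, "impact.tsv")
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  reports
}

#' @export
print.pgx_reports <- function(x, ...) {
  s <- x$summary
  cat("Pipeline reports (", s$n_samples, " samples)\n", sep = "")
  cat(sprintf("  actionable burden: %.1f%% carry >=1, median %d\n",
              100 * s$fraction_ge1_actionable, s$median_actionable_burden))
  cat(sprintf("  rare deleterious burden: %.1f%% carry >=1, median %d\n",
              100 * s$fraction_ge1_rare_deleterious,
              s$median_rare_deleterious_burden))
  if (!is.null(s$population_share_pct)) {
    cat(sprintf("  impact: %s unique patients (%.1f%% of population)\n",
                format(s$total_patients, big.mark = ","),
                s$population_share_pct))
  }
  invisible(x)
}
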