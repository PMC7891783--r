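#' Deduplicate prescription rows to unique patient headcounts
#'
#' A patient prescribed the same drug several times in a year, by different
#' routes or at different doses, counts once toward that drug-year's unique
#' headcount; expenditure is summed over all rows.
#'
#' @param raw Data frame of raw prescription rows with columns `patient_id`,
#'   `drug`, and either `year` or a `date` (from which the year is taken);
#'   optional `cost_hkd`, `route`, `dose`, `age_band`.
#' @return Data frame of class `pgx_prescriptions`: one row per (drug, year)
#'   with `unique_patients` and `expenditure_hkd`.
#' @export
dedupe_headcount <- function(raw) {
  if (nrow(raw) == 0) {
    out <- data.frame(drug = character(0), year = integer(0),
                      unique_patients = integer(0), expenditure_hkd = numeric(0))
    class(out) <- c("pgx_prescriptions", "data.frame")
    return(out)
  }
  if (!"patient_id" %in% names(raw) || anyNA(raw$patient_id)) {
    stop("prescription rows must all carry a patient_id", call. = FALSE)
  }
  if (!"year" %in% names(raw)) {
    if (!"date" %in% names(raw)) stop("need a year or date column", call. = FALSE)
    raw$year <- as.integer(format(as.Date(raw$date), "%Y"))
  }
  if (!"cost_hkd" %in% names(raw)) raw$cost_hkd <- 0
  key <- interaction(raw$drug, raw$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(raw, key), function(d) {
    data.frame(drug = d$drug[1], year = d$year[1],
               unique_patients = length(unique(d$patient_id)),
               expenditure_hkd = sum(d$cost_hkd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("pgx_prescriptions", "data.frame")
  out
}

#' Combine gene-level actionable frequencies to a drug-level frequency
#'
#' Probability that a patient has an actionable phenotype in at least one of
#' the genes implicated for the drug, assuming independence across genes:
#' `f_drug = 1 - prod(1 - f_gene)`.
#'
#' @param f_genes Numeric vector of by-gene actionable frequencies
#'   (fractions), one per implicated gene.
#' @return Drug-level actionable frequency fraction.
#' @export
#' @examples
#' combine_gene_frequencies(c(CYP4F2 = 0.3989, CYP2C9 = 0.0539))  # 0.4313
combine_gene_frequencies <- function(f_genes) {
  if (length(f_genes) == 0) {
    stop("empty gene set: a drug must map to at least one gene", call. = FALSE)
  }
  stopifnot_prob(f_genes, "gene-level frequency")
  1 - prod(1 - f_genes)
}

#' Projected actionable patient headcount for a drug
#'
#' @param unique_patients Unique patients prescribed the drug.
#' @param f_drug Drug-level actionable phenotype frequency.
#' @return `round(unique_patients * f_drug)` to the nearest integer.
#' @export
project_headcount <- function(unique_patients, f_drug) {
  stopifnot_prob(f_drug, "f_drug")
  round(unique_patients * f_drug)
}

#' Projected actionable drug expenditure in USD
#'
#' @param expenditure_hkd Annual expenditure on the drug in HKD.
#' @param f_drug Drug-level actionable phenotype frequency.
#' @param rate HKD per USD (default 7.8).
#' @return Projected expenditure in USD (full precision; round at report
#'   time).
#' @export
project_expenditure <- function(expenditure_hkd, f_drug, rate = 7.8) {
  stopifnot(rate > 0)
  stopifnot_prob(f_drug, "f_drug")
  expenditure_hkd * f_drug / rate
}

#' Share of the population prescribed the implicated drugs
#'
#' @param total_unique_patients Unique patients across the implicated drugs.
#' @param population Population size.
#' @param digits Decimal places on the percent scale (default 1).
#' @return Percentage.
#' @export
population_share <- function(total_unique_patients, population, digits = 1) {
  stopifnot(population > 0)
  round(100 * total_unique_patients / population, digits)
}

#' Genotype split of an actionable headcount under Hardy-Weinberg
#'
#' Given the printed heterozygote and homozygote phenotype frequencies of a
#' biallelic actionable genotype, derives the underlying allele frequency
#' from the heterozygote class (`h = 2q(1-q)`, so `q = (1 - sqrt(1-2h))/2`),
#' re-projects both genotype frequencies at full precision, and returns the
#' proportional split of an actionable headcount between them.
#'
#' @param het_freq Heterozygote phenotype frequency (fraction).
#' @param hom_freq Homozygote phenotype frequency (fraction, for
#'   cross-checking; the split is computed from the re-projected values).
#' @return Named vector `c(hom = , het = )` of shares summing to 1, with the
#'   derived allele frequency as attribute `q`.
#' @export
hwe_genotype_split <- function(het_freq, hom_freq) {
  stopifnot_prob(c(het_freq, hom_freq), "genotype frequency")
  if (het_freq > 0.5) stop("heterozygote frequency cannot exceed 0.5 under HWE",
                           call. = FALSE)
  q <- (1 - sqrt(1 - 2 * het_freq)) / 2
  het <- 2 * q * (1 - q)
  hom <- q^2
  out <- c(hom = hom, het = het) / (hom + het)
  attr(out, "q") <- q
  out
}

#' Expected adverse events prevented by genotype-guided prescribing
#'
#' Splits an actionable headcount across its genotype/phenotype groups and
#' applies each group's cumulative adverse-event risk, assuming the
#' intervention removes the excess risk entirely:
#' `sum_g n * split(g) * risk(g)`, rounded to the nearest case.
#'
#' @param n_actionable Patients with an actionable phenotype.
#' @param phenotype_split Named fractions summing to 1 over the groups.
#' @param risk_model Named per-group cumulative event probabilities.
#' @return Expected prevented cases (integer).
#' @export
#' @examples
#' prevented_events(1000, c(CC = 0.1, TC = 0.9), c(CC = 0.18, TC = 0.03))  # 45
prevented_events <- function(n_actionable, phenotype_split, risk_model) {
  if (abs(sum(phenotype_split) - 1) > 1e-6) {
    stop("phenotype_split fractions must sum to 1", call. = FALSE)
  }
  if (any(risk_model < 0 | risk_model > 1)) {
    stop("risks must lie in [0, 1]", call. = FALSE)
  }
  groups <- names(phenotype_split)
  if (!all(groups %in% names(risk_model))) {
    stop("risk_model missing group(s): ",
         paste(setdiff(groups, names(risk_model)), collapse = ", "),
         call. = FALSE)
  }
  round(sum(n_actionable * phenotype_split * risk_model[groups]))
}

#' Drug-level prescription impact report
#'
#' Joins deduplicated prescription headcounts with the drug-gene map and the
#' by-gene actionable phenotype frequencies, computing each drug's
#' actionable frequency (independence across implicated genes), projected
#' patient headcount, and projected expenditure in USD.
#'
#' @param prescriptions A `pgx_prescriptions` table.
#' @param drug_gene_map Data frame with columns `drug` and `genes`
#'   (semicolon-joined); default the packaged map.
#' @param gene_freqs Named vector of by-gene actionable frequencies
#'   (fractions).
#' @param rate HKD per USD (default 7.8).
#' @return Data frame of class `pgx_impact`, one row per drug, plus totals
#'   in attributes `total_patients`, `total_expenditure_usd`,
#'   `total_projected_usd`.
#' @export
impact_report <- function(prescriptions, drug_gene_map = NULL, gene_freqs,
                          rate = 7.8) {
  if (is.null(drug_gene_map)) {
    drug_gene_map <- read_tsv(pgx_example("drug_gene_map.tsv"))
  }
  m <- merge(as.data.frame(prescriptions), drug_gene_map, by = "drug")
  if (nrow(m) == 0) stop("no prescribed drug matches the drug-gene map", call. = FALSE)
  m$f_actionable <- vapply(strsplit(m$genes, ";", fixed = TRUE), function(gs) {
    known <- gs[gs %in% names(gene_freqs)]
    if (length(known) == 0) return(NA_real_)
    combine_gene_frequencies(gene_freqs[known])
  }, numeric(1))
  m <- m[!is.na(m$f_actionable), , drop = FALSE]
  m$projected_patients <- project_headcount(m$unique_patients, m$f_actionable)
  m$projected_expenditure_usd <-
    project_expenditure(m$expenditure_hkd, m$f_actionable, rate)
  m$expenditure_usd <- m$expenditure_hkd / rate
  if ("indication_caveat" %in% names(m)) {
    m$caveat_flag <- !is.na(m$indication_caveat) & m$indication_caveat != ""
  }
  m <- m[order(-m$projected_patients), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "total_patients") <- sum(m$unique_patients)
  attr(m, "total_expenditure_usd") <- sum(m$expenditure_usd)
  attr(m, "total_projected_usd") <- sum(m$projected_expenditure_usd)
  class(m) <- c("pgx_impact", "data.frame")
  m
}

#' @export
print.pgx_impact <- function(x, ...) {
  cat("Prescription impact:", nrow(x), "drugs;",
      attr(x, "total_patients"), "unique patients;",
      sprintf("projected actionable expenditure %.0f USD (%.1f%% of total)\n",
              attr(x, "total_projected_usd"),
              100 * attr(x, "total_projected_usd") / attr(x, "total_expenditure_usd")))
  invisible(x)
}
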