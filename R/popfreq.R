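#' Load allele-class frequencies
#'
#' One row per (gene, functional class or named allele) with its summed
#' allele frequency; the gene's reference class takes the remaining
#' frequency, `1 - sum(others)`. The packaged set carries the Hong Kong
#' Chinese frequencies back-derived in closed form from a published
#' phenotype-frequency table.
#'
#' @param path TSV path; default the packaged Hong Kong set.
#' @return Data frame of class `pgx_class_freqs` with columns `gene`,
#'   `class`, `freq`, `reference_class`.
#' @export
read_class_frequencies <- function(path = pgx_example("allele_class_frequencies_hk.tsv")) {
  df <- read_tsv(path)
  stopifnot_prob(df$freq, "allele-class frequency")
  agg <- tapply(df$freq, df$gene, sum)
  if (any(agg > 1 + 1e-9)) {
    stop("allele-class frequencies for ",
         paste(names(agg)[agg > 1 + 1e-9], collapse = ", "),
         " sum to more than 1", call. = FALSE)
  }
  class(df) <- c("pgx_class_freqs", "data.frame")
  df
}

# named q-vector for one gene, with the implicit reference class filled in;
# a gene with no listed classes yields an empty map (all classes at zero)
gene_class_freqs <- function(class_freqs, gene) {
  d <- class_freqs[class_freqs$gene == gene, , drop = FALSE]
  if (nrow(d) == 0) return(stats::setNames(numeric(0), character(0)))
  q <- stats::setNames(d$freq, d$class)
  ref <- unique(d$reference_class)
  if (length(ref) == 1 && !is.na(ref) && !ref %in% names(q)) {
    q <- c(q, stats::setNames(max(0, 1 - sum(q)), ref))
  }
  q
}

#' Phenotype frequency under Hardy-Weinberg equilibrium
#'
#' Projects a genotype-definition pattern onto a frequency using HWE:
#' an unordered pair `"A/B"` gives `2*qA*qB` for distinct classes and `qA^2`
#' for a homozygous pair; a single class under `sex_mode = "x_linked_male"`
#' gives `qA` (hemizygous); `"A/A"` under `"x_linked_female"` gives `qA^2`;
#' `"carrier:A"` gives `1 - (1-qA)^2`. A class absent from the frequency map
#' contributes frequency zero. Patterns over more than two classes are not
#' supported.
#'
#' @param pattern Rule pattern string.
#' @param q Named vector of summed allele-class frequencies for the gene
#'   (see [gene_class_freqs()] / [read_class_frequencies()]).
#' @param sex_mode `"autosomal"`, `"x_linked_male"`, or `"x_linked_female"`.
#' @return Frequency fraction in \[0, 1\].
#' @export
#' @examples
#' hwe_phenotype_frequency("normal/no_function",
#'                         c(normal = 0.7, no_function = 0.3))  # 0.42
hwe_phenotype_frequency <- function(pattern, q, sex_mode = "autosomal") {
  getq <- function(cl) if (cl %in% names(q)) unname(q[cl]) else 0
  if (startsWith(pattern, "carrier:")) {
    return(carrier_frequency(getq(sub("^carrier:", "", pattern))))
  }
  parts <- strsplit(pattern, "/", fixed = TRUE)[[1]]
  if (length(parts) > 2) {
    stop("unsupported rule pattern (arity > 2): ", pattern, call. = FALSE)
  }
  if (length(parts) == 1) {
    if (!identical(sex_mode, "x_linked_male")) {
      stop("single-class pattern '", pattern,
           "' only supported for x_linked_male rules", call. = FALSE)
    }
    return(getq(parts))
  }
  qa <- getq(parts[1]); qb <- getq(parts[2])
  if (parts[1] == parts[2]) qa * qb else 2 * qa * qb
}

#' Carrier frequency from allele frequency
#'
#' Probability of carrying at least one copy of an allele with frequency `q`
#' under Hardy-Weinberg: `1 - (1-q)^2`.
#'
#' @param q Allele frequency (vectorized).
#' @return Carrier frequency.
#' @export
carrier_frequency <- function(q) {
  stopifnot_prob(q, "allele frequency")
  1 - (1 - q)^2
}

#' Allele frequency from carrier frequency
#'
#' Inverse of [carrier_frequency()]: `q = 1 - sqrt(1 - c)`.
#'
#' @param c Carrier frequency (vectorized).
#' @return Allele frequency.
#' @export
allele_freq_from_carrier <- function(c) {
  stopifnot_prob(c, "carrier frequency")
  1 - sqrt(1 - c)
}

#' Aggregate phenotype frequencies to a by-gene figure
#'
#' Metabolizer-style phenotype classes partition diplotype space, so their
#' frequencies add (`mode = "disjoint"`). Multiple risk alleles at one locus
#' do not: a compound heterozygote is a carrier of both, so per-allele
#' carrier frequencies are converted back to allele frequencies, summed, and
#' re-projected (`mode = "carrier_union"`), giving
#' `1 - (1 - sum(q_i))^2 <= sum(c_i)`.
#'
#' @param freqs Numeric vector of actionable phenotype frequencies
#'   (fractions).
#' @param mode `"disjoint"` or `"carrier_union"`.
#' @return By-gene actionable frequency fraction.
#' @export
#' @examples
#' aggregate_gene_actionable(c(0.4525, 0.1196), "disjoint")
#' aggregate_gene_actionable(c(0.1842, 0.0018, 0.1704), "carrier_union")
aggregate_gene_actionable <- function(freqs, mode = c("disjoint", "carrier_union")) {
  mode <- match.arg(mode)
  stopifnot_prob(freqs, "phenotype frequency")
  if (mode == "disjoint") {
    s <- sum(freqs)
    if (s > 1 + 1e-9) {
      stop("disjoint phenotype frequencies sum to more than 1 ",
           "(overlapping rules?)", call. = FALSE)
    }
    min(s, 1)
  } else {
    carrier_frequency(min(1, sum(allele_freq_from_carrier(freqs))))
  }
}

#' Override a gene's phenotype frequency with an external estimate
#'
#' Used for genes whose diplotypes cannot be called reliably from exome data
#' (copy-number and haplotype structure, e.g. CYP2D6), where a published
#' population frequency substitutes for the HWE projection.
#'
#' @param gene Gene symbol.
#' @param frequency Fraction in \[0, 1\].
#' @param source Free-text provenance of the estimate.
#' @param rules Optional rules table; a warning is issued if the gene has no
#'   rules.
#' @return One-row data frame: `gene`, `phenotype`, `frequency`, `source`.
#' @export
external_frequency_override <- function(gene, frequency, source = "external",
                                        rules = NULL) {
  if (!is.finite(frequency) || frequency < 0 || frequency > 1) {
    stop("external frequency for ", gene, " must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(rules) && !gene %in% rules$gene) {
    warning("external override for ", gene,
            ", which has no genotype rules", call. = FALSE)
  }
  data.frame(gene = gene, phenotype = "by_gene", frequency = frequency,
             source = source, stringsAsFactors = FALSE)
}

#' Population carrier rate of an X-linked allele
#'
#' Mixes the male (hemizygous, rate `q`) and female (homozygous, rate `q^2`)
#' affected rates by the population's male fraction:
#' `male_fraction*q + (1-male_fraction)*q^2`.
#'
#' @param q Allele frequency.
#' @param male_fraction Fraction of males in the population (default 0.456,
#'   the Hong Kong male:female ratio 45.6:54.4).
#' @return Population rate fraction.
#' @export
population_carrier_rate_x_linked <- function(q, male_fraction = 0.456) {
  stopifnot_prob(q, "allele frequency")
  stopifnot_prob(male_fraction, "male_fraction")
  male_fraction * q + (1 - male_fraction) * q^2
}

#' Phenotype frequency table
#'
#' Computes, for every rule, the phenotype frequency (HWE projection from the
#' allele-class frequencies, or the rule's external published estimate) and
#' the by-gene actionable aggregate under the gene's declared aggregation
#' mode. Frequencies are carried at full precision; use
#' [format_phenotype_table()] for display rounding.
#'
#' @param rules A `pgx_rules` table (default packaged).
#' @param class_freqs A `pgx_class_freqs` table (default packaged Hong Kong
#'   set).
#' @return Data frame of class `pgx_phenofreq`: `gene`, `phenotype`,
#'   `definition`, `frequency` (fraction), `by_gene` (fraction), `source`,
#'   `sex_mode`.
#' @export
phenotype_frequency_table <- function(rules = read_genotype_rules(),
                                      class_freqs = read_class_frequencies()) {
  rules$frequency <- NA_real_
  for (i in seq_len(nrow(rules))) {
    if (rules$source[i] == "external") {
      rules$frequency[i] <- rules$external_freq_pct[i] / 100
    } else {
      q <- gene_class_freqs(class_freqs, rules$gene[i])
      rules$frequency[i] <- hwe_phenotype_frequency(rules$pattern[i], q,
                                                    rules$sex_mode[i])
    }
  }
  rules$by_gene <- NA_real_
  for (g in unique(rules$gene)) {
    rr <- rules$gene == g & rules$actionable
    mode <- unique(rules$aggregate_mode[rules$gene == g])[1]
    if (mode == "x_linked") {
      # per-sex rows reported separately, as in the source table
      rules$by_gene[rules$gene == g] <- rules$frequency[rules$gene == g]
    } else {
      rules$by_gene[rules$gene == g] <-
        aggregate_gene_actionable(rules$frequency[rr], mode)
    }
  }
  out <- rules[, c("gene", "phenotype", "definition", "frequency", "by_gene",
                   "source", "sex_mode", "actionable")]
  class(out) <- c("pgx_phenofreq", "data.frame")
  out
}

#' Round a phenotype frequency table for display
#'
#' @param tab A `pgx_phenofreq` table.
#' @param digits Decimal places on the percent scale (default 2).
#' @return Data frame with `frequency_pct` and `by_gene_pct` columns.
#' @export
format_phenotype_table <- function(tab, digits = 2) {
  out <- as.data.frame(tab)
  out$frequency_pct <- round(100 * out$frequency, digits)
  out$by_gene_pct <- round(100 * out$by_gene, digits)
  out$frequency <- out$by_gene <- NULL
  out
}
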