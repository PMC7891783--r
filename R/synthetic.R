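#' Cohort simulation specification
#'
#' Describes the generating model of a synthetic exome cohort: sample size,
#' sex ratio, per-gene star-allele frequencies (haplotypes drawn
#' independently under Hardy-Weinberg; one haplotype for males at X-linked
#' genes), HLA allele frequencies per locus (two independent draws), and a
#' disease-cohort label mixture.
#'
#' @param n_samples Number of samples.
#' @param male_fraction Fraction of males (default 0.456, the Hong Kong
#'   male:female ratio).
#' @param alleles Data frame with columns `gene`, `allele`,
#'   `functional_class`, `freq` and a list column `markers` (rsIDs); only
#'   non-reference alleles are listed, the reference takes the remainder.
#' @param x_linked_genes Genes simulated as X-linked.
#' @param hla Data frame with columns `locus`, `allele`, `freq`; per-locus
#'   frequencies must sum to at most 1, the remainder going to a background
#'   allele.
#' @param labels Named probability vector of cohort labels.
#' @param seed Root seed; per-component sub-seeds are derived as
#'   `seed + 1..4` (sex/labels, gene haplotypes, HLA, extras).
#' @return List of class `pgx_cohort_spec`.
#' @export
cohort_spec <- function(n_samples, male_fraction = 0.456, alleles,
                        x_linked_genes = "G6PD", hla = NULL,
                        labels = c(rare_disease = 0.55, complex_disease = 0.25,
                                   respiratory = 0.1, neuromuscular = 0.1),
                        seed = 1) {
  stopifnot(n_samples > 0)
  stopifnot_prob(male_fraction, "male_fraction")
  stopifnot_prob(alleles$freq, "allele frequency")
  per_gene <- tapply(alleles$freq, alleles$gene, sum)
  if (any(per_gene > 1 + 1e-9)) {
    stop("allele frequencies for ",
         paste(names(per_gene)[per_gene > 1 + 1e-9], collapse = ", "),
         " sum to more than 1", call. = FALSE)
  }
  if (!is.null(hla)) {
    per_locus <- tapply(hla$freq, hla$locus, sum)
    if (any(per_locus > 1 + 1e-9)) {
      stop("HLA allele frequencies exceed 1 for a locus", call. = FALSE)
    }
  }
  out <- list(n_samples = as.integer(n_samples), male_fraction = male_fraction,
              alleles = alleles, x_linked_genes = x_linked_genes, hla = hla,
              labels = labels / sum(labels), seed = as.integer(seed))
  class(out) <- "pgx_cohort_spec"
  out
}

# deterministic split of a class frequency across its alleles:
# weights 2^-(i-1) in definition order, normalized
split_class_freq <- function(q, k) {
  w <- 2^-(seq_len(k) - 1)
  q * w / sum(w)
}

#' Hong Kong-like cohort specification
#'
#' The packaged demonstration spec: per-gene allele frequencies chosen so
#' that the class sums equal the packaged Hong Kong allele-class frequencies
#' (class mass split across a gene's defined alleles by fixed halving
#' weights), HLA frequencies matching the published risk-allele frequencies
#' with named background alleles filling each locus, and the Hong Kong sex
#' ratio. A cohort simulated from this spec reproduces the published
#' phenotype frequencies up to sampling error.
#'
#' @param n_samples Cohort size (default 1116).
#' @param seed Root seed.
#' @return A `pgx_cohort_spec`.
#' @export
hk_cohort_spec <- function(n_samples = 1116, seed = 1) {
  defs <- read_star_allele_definitions()
  cf <- read_class_frequencies()
  rows <- list()
  for (g in unique(defs$gene)) {
    d <- defs[defs$gene == g, , drop = FALSE]
    nonref <- d[lengths(d$markers) > 0, , drop = FALSE]
    qmap <- gene_class_freqs(cf, g)
    for (cl in unique(nonref$functional_class)) {
      a <- nonref[nonref$functional_class == cl, , drop = FALSE]
      q <- if (cl %in% names(qmap)) unname(qmap[cl]) else 0
      a$freq <- split_class_freq(q, nrow(a))
      rows[[length(rows) + 1]] <- a
    }
  }
  alleles <- do.call(rbind, rows)
  hla <- data.frame(
    locus = c("HLA-B", "HLA-B", "HLA-B", "HLA-B", "HLA-B",
              "HLA-A", "HLA-A", "HLA-A"),
    allele = c("B*15:02", "B*57:01", "B*58:01", "B*40:01", "B*46:01",
               "A*31:01", "A*02:01", "A*11:01"),
    freq = c(cf$freq[cf$class == "B*15:02"], cf$freq[cf$class == "B*57:01"],
             cf$freq[cf$class == "B*58:01"], 0.15, 0.12,
             cf$freq[cf$class == "A*31:01"], 0.28, 0.22),
    stringsAsFactors = FALSE)
  cohort_spec(n_samples, alleles = alleles, hla = hla, seed = seed)
}

#' Simulate a synthetic exome cohort
#'
#' Draws gene haplotypes independently per sample from the spec's allele
#' frequencies (two per autosomal gene; one for males at X-linked genes),
#' derives unphased marker genotypes from the haplotypes' marker content,
#' and draws HLA typings as two independent alleles per locus. Fully
#' reproducible given the spec's seed.
#'
#' @param spec A `pgx_cohort_spec`.
#' @return List of class `pgx_cohort`: `geno` (a `pgx_geno`), `hla`
#'   (a `pgx_hla` or NULL), `metadata`, `haplotypes` (the generating truth),
#'   and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "pgx_cohort_spec"))
  n <- spec$n_samples
  ids <- sprintf("S%05d", seq_len(n))

  set.seed(spec$seed + 1L)
  n_male <- round(n * spec$male_fraction)
  sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
  metadata <- data.frame(
    sample = ids, sex = sex,
    cohort_label = sample(names(spec$labels), n, replace = TRUE,
                          prob = spec$labels),
    stringsAsFactors = FALSE)

  set.seed(spec$seed + 2L)
  marker_tab <- read_tsv(pgx_example("marker_variants.tsv"))
  all_markers <- unique(unlist(spec$alleles$markers))
  geno_mat <- matrix(0L, n, length(all_markers),
                     dimnames = list(ids, all_markers))
  haplos <- list()
  for (g in unique(spec$alleles$gene)) {
    a <- spec$alleles[spec$alleles$gene == g, , drop = FALSE]
    probs <- c(a$freq, 1 - sum(a$freq))       # last index = reference
    names(probs) <- c(a$allele, "<ref>")
    x_linked <- g %in% spec$x_linked_genes
    h1 <- sample(seq_along(probs), n, replace = TRUE, prob = probs)
    h2 <- sample(seq_along(probs), n, replace = TRUE, prob = probs)
    if (x_linked) h2[sex == "male"] <- NA
    haplos[[g]] <- data.frame(sample = ids, allele1 = names(probs)[h1],
                              allele2 = names(probs)[h2],
                              stringsAsFactors = FALSE)
    for (j in seq_len(nrow(a))) {
      m <- a$markers[[j]]
      carry <- (h1 == j) + ifelse(is.na(h2), 0L, h2 == j)
      geno_mat[, m] <- geno_mat[, m] + carry
    }
  }
  idx <- match(all_markers, marker_tab$rsid)
  variants <- data.frame(
    chrom = ifelse(is.na(idx), "1", marker_tab$chrom[idx]),
    pos = ifelse(is.na(idx), seq_along(all_markers) * 1000L, marker_tab$pos[idx]),
    ref = ifelse(is.na(idx), "A", marker_tab$ref[idx]),
    alt = ifelse(is.na(idx), "G", marker_tab$alt[idx]),
    rsid = all_markers, stringsAsFactors = FALSE)
  geno <- new_geno(variants, metadata, geno_mat)

  hla <- NULL
  if (!is.null(spec$hla)) {
    set.seed(spec$seed + 3L)
    out <- list()
    for (loc in unique(spec$hla$locus)) {
      h <- spec$hla[spec$hla$locus == loc, , drop = FALSE]
      probs <- c(h$freq, 1 - sum(h$freq))
      als <- c(h$allele, paste0(sub("^HLA-", "", loc), "*XX:XX"))
      out[[loc]] <- data.frame(
        sample = ids, locus = loc,
        allele1 = sample(als, n, replace = TRUE, prob = probs),
        allele2 = sample(als, n, replace = TRUE, prob = probs),
        stringsAsFactors = FALSE)
    }
    hla <- do.call(rbind, out)
    rownames(hla) <- NULL
    class(hla) <- c("pgx_hla", "data.frame")
  }

  out <- list(geno = geno, hla = hla, metadata = metadata,
              haplotypes = haplos, spec = spec)
  class(out) <- "pgx_cohort"
  out
}

#' Write a simulated cohort in pipeline input formats
#'
#' Emits `cohort.vcf` (VCF 4.2 with GT genotypes; male X genotypes written
#' hemizygous), `metadata.tsv`, and `hla.tsv` so the ingest path
#' ([read_vcf()], [read_hla_table()]) can be exercised end to end.
#'
#' @param cohort A `pgx_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- cohort$geno
  male <- g$samples$sex == "male"
  x_site <- is_x_chrom(g$variants$chrom)
  gt_str <- matrix("", nrow(g$calls), ncol(g$calls))
  code <- g$calls
  gt_str[] <- c("0/0", "0/1", "1/1")[code + 1L]
  gt_str[is.na(code)] <- "./."
  if (any(x_site)) {
    for (j in which(x_site)) {
      gt_str[male, j] <- as.character(code[male, j])
      gt_str[male & is.na(code[, j]), j] <- "."
    }
  }
  ord <- order(g$variants$chrom, g$variants$pos)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample), collapse = "\t"))
  body <- vapply(ord, function(j) {
    paste(c(g$variants$chrom[j], g$variants$pos[j],
            ifelse(is.na(g$variants$rsid[j]), ".", g$variants$rsid[j]),
            g$variants$ref[j], g$variants$alt[j], ".", "PASS", ".", "GT",
            gt_str[, j]), collapse = "\t")
  }, "")
  writeLines(c(lines, body), file.path(dir, "cohort.vcf"))
  write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(cohort$hla)) {
    write_tsv(as.data.frame(cohort$hla), file.path(dir, "hla.tsv"))
  }
  invisible(dir)
}

#' Annotation-table simulation specification
#'
#' Describes a synthetic variant annotation table: consequence mixture and,
#' per tool, the probability that a variant crosses the tool's deleterious
#' threshold (drawn independently, so planted deleterious fractions have the
#' closed form `1 - prod(1 - p_tool)` within each consequence group).
#'
#' @param n_variants Number of variants.
#' @param p_missense,p_lof Consequence mixture (remainder is `other`).
#' @param p_cadd_mis,p_revel,p_predict Per-tool exceedance probabilities for
#'   missense variants.
#' @param p_cadd_lof,p_loftee_hc Exceedance probabilities for LoF variants.
#' @param frac_rare Fraction with gnomAD AF below 1%.
#' @param frac_novel Fraction absent from gnomAD/dbSNP/ClinVar (a subset of
#'   the rare fraction).
#' @param genes Gene pool to assign variants to.
#' @param seed Seed.
#' @return List of class `pgx_annotation_spec`.
#' @export
annotation_spec <- function(n_variants, p_missense = 0.6, p_lof = 0.1,
                            p_cadd_mis = 0.3, p_revel = 0.2, p_predict = 0.15,
                            p_cadd_lof = 0.7, p_loftee_hc = 0.6,
                            frac_rare = 0.3, frac_novel = 0.05,
                            genes = NULL, seed = 1) {
  stopifnot(p_missense + p_lof <= 1, frac_novel <= frac_rare)
  stopifnot_prob(c(p_missense, p_lof, p_cadd_mis, p_revel, p_predict,
                   p_cadd_lof, p_loftee_hc, frac_rare, frac_novel),
                 "annotation spec probability")
  out <- list(n_variants = as.integer(n_variants), p_missense = p_missense,
              p_lof = p_lof, p_cadd_mis = p_cadd_mis, p_revel = p_revel,
              p_predict = p_predict, p_cadd_lof = p_cadd_lof,
              p_loftee_hc = p_loftee_hc, frac_rare = frac_rare,
              frac_novel = frac_novel, genes = genes, seed = as.integer(seed))
  class(out) <- "pgx_annotation_spec"
  out
}

#' Simulate a variant annotation table
#'
#' @param spec A `pgx_annotation_spec`.
#' @return Data frame in the shape [classify_variants()] consumes, with the
#'   generating truth columns `planted_cadd`, `planted_revel`, etc. omitted
#'   (the planted fractions are recoverable from the spec's closed form).
#' @export
simulate_annotations <- function(spec) {
  stopifnot(inherits(spec, "pgx_annotation_spec"))
  set.seed(spec$seed + 4L)
  n <- spec$n_variants
  lof_types <- LOF_CONSEQUENCES
  consequence <- sample(
    c("missense", "lof", "other"), n, replace = TRUE,
    prob = c(spec$p_missense, spec$p_lof, 1 - spec$p_missense - spec$p_lof))
  consequence[consequence == "lof"] <-
    sample(lof_types, sum(consequence == "lof"), replace = TRUE)
  is_mis <- consequence == "missense"
  is_lof <- consequence %in% lof_types

  draw_score <- function(cross, lo, hi, cut) {
    ifelse(cross, stats::runif(length(cross), cut, hi),
           stats::runif(length(cross), lo, cut * 0.999))
  }
  p_cadd <- ifelse(is_mis, spec$p_cadd_mis, ifelse(is_lof, spec$p_cadd_lof, 0.05))
  cadd <- draw_score(stats::runif(n) < p_cadd, 0, 45, 20)
  revel <- ifelse(is_mis, draw_score(stats::runif(n) < spec$p_revel, 0, 1, 0.7),
                  NA_real_)
  predict_score <- ifelse(is_mis,
                          draw_score(stats::runif(n) < spec$p_predict, 0, 1, 0.6),
                          NA_real_)
  loftee <- ifelse(is_lof,
                   ifelse(stats::runif(n) < spec$p_loftee_hc, "HC", "LC"),
                   NA_character_)

  rare <- stats::runif(n) < spec$frac_rare
  novel <- rare & (stats::runif(n) < spec$frac_novel / max(spec$frac_rare, 1e-12))
  af <- ifelse(rare, stats::runif(n, 1e-5, 0.0099), stats::runif(n, 0.011, 0.5))
  af[novel] <- NA_real_

  genes <- spec$genes %||% sprintf("GENE%03d", 1:20)
  data.frame(
    variant_id = sprintf("V%06d", seq_len(n)),
    gene = sample(genes, n, replace = TRUE),
    consequence = consequence,
    gnomad_af = af, cadd_phred = cadd, revel = revel,
    predict_score = predict_score, loftee = loftee,
    in_gnomad = !novel, in_dbsnp = !novel & stats::runif(n) < 0.9,
    in_clinvar = !novel & stats::runif(n) < 0.2,
    stringsAsFactors = FALSE)
}

#' Simulate cohort genotypes for an annotation table
#'
#' Draws Hardy-Weinberg genotypes for each annotated variant at its
#' (cohort) allele frequency -- gnomAD AF where available, a small random
#' frequency for novel variants -- so rare-variant burden summaries can be
#' computed on a synthetic cohort.
#'
#' @param annotations Annotation table (see [simulate_annotations()]).
#' @param metadata Sample metadata (samples, sex).
#' @param seed Seed.
#' @param af Optional explicit allele frequencies (recycled).
#' @return A `pgx_geno` over the annotated variants (all autosomal).
#' @export
simulate_genotypes_for_annotations <- function(annotations, metadata, seed = 1,
                                               af = NULL) {
  set.seed(seed + 5L)
  n <- nrow(metadata); m <- nrow(annotations)
  if (is.null(af)) {
    af <- annotations$gnomad_af
    af[is.na(af)] <- stats::runif(sum(is.na(af)), 1e-4, 0.002)
  } else {
    af <- rep_len(af, m)
  }
  calls <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, af[j]),
                  integer(n))
  variants <- data.frame(chrom = "1", pos = seq_len(m) * 100L, ref = "A",
                         alt = "G", rsid = annotations$variant_id,
                         stringsAsFactors = FALSE)
  g <- new_geno(variants, metadata, calls)
  # burden lookups key on variant_id
  colnames(g$calls) <- annotations$variant_id
  g
}

#' Simulate a raw prescription extract
#'
#' Generates prescription rows with planted unique patient headcounts: each
#' drug's patients appear once, and `round(unique_patients *
#' (duplication_rate - 1))` extra rows duplicate random patients with a
#' different route or dose, so deduplication recovers the planted counts
#' exactly.
#'
#' @param drug_specs Data frame with columns `drug`, `unique_patients`,
#'   `duplication_rate` (>= 1), `unit_cost_hkd`, and optional `year`
#'   (default 2019).
#' @param seed Seed.
#' @return Data frame of raw rows: `patient_id`, `drug`, `route`, `dose`,
#'   `date`, `year`, `cost_hkd`, `age_band`.
#' @export
simulate_prescriptions <- function(drug_specs, seed = 1) {
  set.seed(seed + 6L)
  stopifnot(all(drug_specs$duplication_rate >= 1))
  if (!"year" %in% names(drug_specs)) drug_specs$year <- 2019L
  rows <- list()
  for (i in seq_len(nrow(drug_specs))) {
    d <- drug_specs[i, ]
    u <- d$unique_patients
    if (u == 0) next
    n_rows <- round(u * d$duplication_rate)
    pid <- sprintf("%s_P%05d", toupper(substr(d$drug, 1, 3)), seq_len(u))
    extra <- if (n_rows > u) sample(pid, n_rows - u, replace = TRUE) else character(0)
    all_pid <- c(pid, extra)
    rows[[i]] <- data.frame(
      patient_id = all_pid, drug = d$drug,
      route = sample(c("oral", "iv"), length(all_pid), replace = TRUE),
      dose = sample(c("low", "standard", "high"), length(all_pid), replace = TRUE),
      date = sprintf("%d-%02d-01", d$year, sample(1:12, length(all_pid), replace = TRUE)),
      year = d$year, cost_hkd = d$unit_cost_hkd,
      age_band = sample(c("0-18", "19-60", ">60"), length(all_pid),
                        replace = TRUE, prob = c(0.15, 0.5, 0.35)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), drug = character(0),
                      route = character(0), dose = character(0),
                      date = character(0), year = integer(0),
                      cost_hkd = numeric(0), age_band = character(0))
  }
  rownames(out) <- NULL
  out
}
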