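#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `sex` (`male`/`female`) and
#'   `cohort_label`.
#' @return Data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(c("sample", "sex"), names(df))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female' for every sample", call. = FALSE)
  }
  if (!"cohort_label" %in% names(df)) df$cohort_label <- NA_character_
  df
}

# Construct a pgx_geno object from parts. calls: samples x variants integer
# matrix of alt-allele counts (NA = missing); male X entries are hemizygous
# codes in {0, 1}.
new_geno <- function(variants, samples, calls, depth = NULL) {
  stopifnot(nrow(calls) == nrow(samples), ncol(calls) == nrow(variants))
  rownames(calls) <- samples$sample
  colnames(calls) <- variant_key(variants$chrom, variants$pos,
                                 variants$ref, variants$alt)
  obj <- list(variants = variants, samples = samples, calls = calls,
              depth = depth)
  class(obj) <- "pgx_geno"
  obj
}

#' @export
print.pgx_geno <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$samples), " samples x ",
      nrow(x$variants), " variants (",
      sum(x$samples$sex == "male"), " males, ",
      sum(x$samples$sex == "female"), " females)\n", sep = "")
  invisible(x)
}

# parse one GT string into allele indices; returns integer vector, NA for "."
parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")[[1]]
  suppressWarnings(as.integer(ifelse(alleles == ".", NA, alleles)))
}

#' Read cohort genotypes from a VCF
#'
#' Parses a VCF 4.x file into a genotype matrix of alt-allele counts.
#' Multi-allelic records are split into one biallelic row per alternate
#' allele. Genotypes of male samples at X-chromosome sites are collapsed to
#' hemizygous codes (0/1); a heterozygous male X call is treated as missing.
#' Missing genotypes (`./.` or `.`) are preserved as `NA`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param metadata Sample metadata data frame (see [read_sample_metadata()]);
#'   every sample in the VCF must be listed.
#' @return A `pgx_geno` object: list with `variants` (chrom, pos, ref, alt,
#'   rsid), `samples`, and `calls` (samples x variants integer matrix).
#' @export
read_vcf <- function(path, metadata) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix),
                     dimnames = list(NULL, colnames(v@gt)[-1]))
  }
  vcf_samples <- colnames(gt_raw)
  absent <- setdiff(vcf_samples, metadata$sample)
  if (length(absent)) {
    stop("VCF sample(s) absent from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  samples <- metadata[match(vcf_samples, metadata$sample), , drop = FALSE]
  rownames(samples) <- NULL
  male <- samples$sex == "male"

  out_var <- list(); out_calls <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    x_site <- is_x_chrom(fix$CHROM[i])
    parsed <- lapply(gt_raw[i, ], parse_gt)
    for (k in seq_along(alts)) {
      codes <- vapply(seq_along(parsed), function(s) {
        al <- parsed[[s]]
        if (all(is.na(al))) return(NA_integer_)
        if (anyNA(al)) return(NA_integer_)  # partial calls treated as missing
        cnt <- sum(al == k)
        if (x_site && male[s]) {
          if (length(al) == 1L) return(cnt)
          # diploid-coded male X: collapse homozygous, drop heterozygous
          if (al[1] == al[2]) return(as.integer(al[1] == k))
          return(NA_integer_)
        }
        as.integer(cnt)
      }, integer(1))
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        rsid = ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".", NA_character_, fix$ID[i]),
        stringsAsFactors = FALSE)
      out_calls[[length(out_calls) + 1L]] <- codes
    }
  }
  variants <- do.call(rbind, out_var)
  calls <- do.call(cbind, out_calls)
  new_geno(variants, samples, calls)
}

#' Read an HLA typing table
#'
#' @param path TSV with columns `sample`, `locus`, `allele1`, `allele2`.
#'   Homozygous typings must repeat the allele; a missing second allele is an
#'   error.
#' @return Data frame of class `pgx_hla`.
#' @export
read_hla_table <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(c("sample", "locus", "allele1", "allele2"), names(df))
  if (length(missing)) {
    stop("HLA table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- is.na(df$allele2) | df$allele2 == ""
  if (any(bad)) {
    stop("HLA typing rows with missing second allele (homozygotes must be ",
         "explicit): sample ", paste(df$sample[bad], collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$sample, df$locus)
  if (anyDuplicated(key)) {
    stop("duplicated (sample, locus) HLA typing: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  class(df) <- c("pgx_hla", "data.frame")
  df
}

#' Default quality-control thresholds
#'
#' Genotypes with depth below `genotype_depth` are set missing, variants with
#' call rate below `variant_call_rate` are dropped, then samples with
#' missingness above `sample_missingness` are dropped. These defaults (8X,
#' 0.90, 0.10) are documented stand-ins for cohort-specific cut-offs and can
#' be overridden.
#'
#' @param genotype_depth Minimum read depth for an individual genotype.
#' @param variant_call_rate Minimum fraction of non-missing calls per variant.
#' @param sample_missingness Maximum fraction of missing calls per sample.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(genotype_depth = 8, variant_call_rate = 0.9,
                          sample_missingness = 0.1) {
  stopifnot(genotype_depth > 0, variant_call_rate >= 0, variant_call_rate <= 1,
            sample_missingness >= 0, sample_missingness <= 1)
  list(genotype_depth = genotype_depth,
       variant_call_rate = variant_call_rate,
       sample_missingness = sample_missingness)
}

#' Apply sample/variant/genotype-level quality control
#'
#' Filtering is iterated to a fixed point (dropping samples can lower a
#' variant's call rate and vice versa), which makes the operation idempotent.
#'
#' @param geno A `pgx_geno` object.
#' @param depth Optional samples x variants read-depth matrix; genotypes below
#'   the depth threshold are set missing before filtering.
#' @param thresholds See [qc_thresholds()].
#' @return List with elements `geno` (filtered matrix) and `report` (counts of
#'   genotypes masked, variants dropped, samples dropped).
#' @export
apply_qc <- function(geno, depth = NULL, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "pgx_geno"))
  calls <- geno$calls
  n_masked <- 0L
  depth <- depth %||% geno$depth
  if (!is.null(depth)) {
    stopifnot(all(dim(depth) == dim(calls)))
    mask <- depth < thresholds$genotype_depth & !is.na(calls)
    n_masked <- sum(mask)
    calls[mask] <- NA_integer_
  }
  keep_v <- rep(TRUE, ncol(calls)); keep_s <- rep(TRUE, nrow(calls))
  repeat {
    cr <- colMeans(!is.na(calls[keep_s, keep_v, drop = FALSE]))
    drop_v <- cr < thresholds$variant_call_rate
    keep_v[keep_v] <- !drop_v
    sm <- rowMeans(is.na(calls[keep_s, keep_v, drop = FALSE]))
    if (ncol(calls[keep_s, keep_v, drop = FALSE]) == 0) sm <- rep(0, sum(keep_s))
    drop_s <- sm > thresholds$sample_missingness
    keep_s[keep_s] <- !drop_s
    if (!any(drop_v) && !any(drop_s)) break
    if (!any(keep_s)) stop("all samples removed by QC", call. = FALSE)
  }
  if (!any(keep_s)) stop("all samples removed by QC", call. = FALSE)
  out <- new_geno(geno$variants[keep_v, , drop = FALSE],
                  geno$samples[keep_s, , drop = FALSE],
                  calls[keep_s, keep_v, drop = FALSE])
  report <- list(genotypes_masked = n_masked,
                 variants_dropped = sum(!keep_v),
                 samples_dropped = sum(!keep_s),
                 variants_retained = sum(keep_v),
                 samples_retained = sum(keep_s))
  list(geno = out, report = report)
}

#' Allele frequencies from a genotype matrix
#'
#' AF = (sum of alt-allele counts) / (number of called allele slots). On the
#' X chromosome a called male contributes one allele slot and a called female
#' two; missing calls are excluded from the denominator. A variant with no
#' called slots gets `NA` (undefined), which is distinct from an observed
#' frequency of zero.
#'
#' @param geno A `pgx_geno` object.
#' @param variant Optional variant key(s) (`chrom:pos:ref:alt`) or rsID(s) to
#'   restrict to; default all variants.
#' @return Named numeric vector of allele frequencies.
#' @export
compute_allele_frequency <- function(geno, variant = NULL) {
  stopifnot(inherits(geno, "pgx_geno"))
  calls <- geno$calls
  male <- geno$samples$sex == "male"
  x_site <- is_x_chrom(geno$variants$chrom)
  slots <- matrix(2, nrow(calls), ncol(calls))
  slots[male, x_site] <- 1
  slots[is.na(calls)] <- 0
  af <- colSums(calls, na.rm = TRUE) / colSums(slots)
  af[colSums(slots) == 0] <- NA_real_
  if (!is.null(variant)) {
    idx <- match(variant, colnames(calls))
    miss <- is.na(idx)
    idx[miss] <- match(variant[miss], geno$variants$rsid)
    if (anyNA(idx)) {
      stop("variant(s) not in matrix: ",
           paste(variant[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    af <- stats::setNames(af[idx], variant)
  }
  af
}
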