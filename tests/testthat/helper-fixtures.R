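# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing binary is stored.

# build a pgx_geno directly from a calls matrix (samples x variants)
make_geno <- function(calls, sex = rep("female", nrow(calls)),
                      chrom = rep("1", ncol(calls)),
                      rsid = paste0("rs", seq_len(ncol(calls))),
                      cohort_label = rep("rare_disease", nrow(calls))) {
  n <- nrow(calls)
  variants <- data.frame(chrom = chrom, pos = seq_len(ncol(calls)) * 100L,
                         ref = "A", alt = "G", rsid = rsid,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample = sprintf("S%03d", seq_len(n)), sex = sex,
                        cohort_label = cohort_label, stringsAsFactors = FALSE)
  pgximpact:::new_geno(variants, samples, calls)
}

# write a star-allele definition data frame (markers as ";"-joined string)
# to a temp TSV and load it through the package reader
load_defs <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  read_star_allele_definitions(f)
}

# Independent oracle: exhaustively enumerate all diplotypes (or single
# alleles for a hemizygous male) of a gene's definitions, keep those whose
# combined marker content equals the observed genotype vector, and pick the
# ones with the fewest non-reference alleles. Returns a list of candidate
# calls as sorted allele-name pairs (or single names).
enumerate_diplotypes <- function(defs_gene, gvec, markers, x_male = FALSE) {
  sets <- lapply(defs_gene$markers, function(m) as.integer(markers %in% m))
  nonref <- lengths(defs_gene$markers) > 0
  k <- nrow(defs_gene)
  cands <- list(); costs <- integer(0)
  if (x_male) {
    for (i in seq_len(k)) {
      if (all(sets[[i]] == gvec)) {
        cands[[length(cands) + 1]] <- defs_gene$allele[i]
        costs <- c(costs, nonref[i])
      }
    }
  } else {
    for (i in seq_len(k)) for (j in i:k) {
      if (all(sets[[i]] + sets[[j]] == gvec)) {
        cands[[length(cands) + 1]] <- sort(c(defs_gene$allele[i],
                                             defs_gene$allele[j]))
        costs <- c(costs, nonref[i] + nonref[j])
      }
    }
  }
  if (!length(cands)) return(list())
  cands[costs == min(costs)]
}

# three-sigma binomial check helper
within_3se <- function(observed, expected, n) {
  se <- sqrt(expected * (1 - expected) / n)
  abs(observed - expected) <= 3 * se + 1e-12
}
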