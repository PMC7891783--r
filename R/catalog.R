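#' Load an actionable pharmacogenetic variant catalog
#'
#' Reads a tab-separated catalog of actionable pharmacogenetic variants and
#' alleles (one record per gene/identifier with a functional class and a
#' semicolon-joined drug list). The packaged default mirrors the structure of
#' a PharmGKB level 1A/1B + CPIC curation: 133 entries across 19 genes, four
#' of which are non-coding and therefore not ascertainable by exome
#' sequencing. Entries whose defining information is not printed in the source
#' frequency table are synthetic stand-ins, marked in the `provenance` column;
#' users can supply their own curated file with the same columns.
#'
#' @param path Path to a catalog TSV. Default: the packaged catalog.
#' @return A data frame of class `pgx_catalog` with columns `gene`,
#'   `identifier`, `entry_class`, `functional_class`, `drugs`, `evidence`,
#'   `exome_ascertainable`, `provenance`.
#' @export
#' @examples
#' cat <- load_actionable_catalog()
#' nrow(cat)                     # 133
#' length(unique(cat$gene))      # 19
load_actionable_catalog <- function(path = pgx_example("actionable_catalog_synthetic.tsv")) {
  df <- read_tsv(path)
  required <- c("gene", "identifier", "entry_class", "functional_class",
                "drugs", "exome_ascertainable")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"evidence" %in% names(df)) df$evidence <- rep(NA_character_, nrow(df))
  if (!"provenance" %in% names(df)) df$provenance <- rep(NA_character_, nrow(df))
  if (nrow(df) == 0) {
    df$exome_ascertainable <- logical(0)
    class(df) <- c("pgx_catalog", "data.frame")
    return(df)
  }
  bad <- which(!df$functional_class %in% FUNCTIONAL_CLASSES)
  if (length(bad)) {
    stop("unknown functional_class '", df$functional_class[bad[1]],
         "' in catalog row ", bad[1], " (", df$gene[bad[1]], " ",
         df$identifier[bad[1]], ")", call. = FALSE)
  }
  key <- paste(df$gene, df$identifier)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate catalog entry: ", d, call. = FALSE)
  }
  df$exome_ascertainable <- as.logical(df$exome_ascertainable)
  nc <- df$entry_class == "noncoding" & df$exome_ascertainable
  if (any(nc)) {
    stop("non-coding catalog entries cannot be exome-ascertainable: ",
         paste(df$identifier[nc], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("pgx_catalog", "data.frame")
  df
}

#' @export
print.pgx_catalog <- function(x, ...) {
  cat("Actionable variant catalog: ", nrow(x), " entries in ",
      length(unique(x$gene)), " genes (",
      sum(!x$exome_ascertainable), " not exome-ascertainable)\n", sep = "")
  invisible(x)
}

#' Write a catalog back to TSV
#'
#' Inverse of [load_actionable_catalog()]; a written catalog re-loads to an
#' identical record set.
#'
#' @param catalog A `pgx_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path)
  invisible(path)
}

#' Load the high-confidence pharmacogene registry
#'
#' Reads the registry of high-confidence pharmacogenes (genes with at least
#' one strong clinical annotation), one row per gene with its transcript
#' length and a gnomAD-style loss-of-function constraint (o/e) score. The
#' packaged default has 108 genes; its lengths and constraint scores are
#' synthetic stand-ins of realistic magnitude.
#'
#' @param path Path to a registry TSV. Default: the packaged registry.
#' @return A data frame of class `pgx_registry` with columns `gene`,
#'   `transcript_length`, `oe_constraint`, `tier`.
#' @export
load_pharmacogene_registry <- function(path = pgx_example("pharmacogene_registry_synthetic.tsv")) {
  df <- read_tsv(path)
  required <- c("gene", "transcript_length")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene symbol in registry: ",
         df$gene[duplicated(df$gene)][1], call. = FALSE)
  }
  if (nrow(df) && any(!is.finite(df$transcript_length) | df$transcript_length <= 0)) {
    stop("transcript_length must be positive for all registry genes",
         call. = FALSE)
  }
  if (!"oe_constraint" %in% names(df)) df$oe_constraint <- NA_real_
  if (!"tier" %in% names(df)) df$tier <- NA_character_
  class(df) <- c("pgx_registry", "data.frame")
  df
}

#' Cross-validate a catalog against the pharmacogene registry
#'
#' Report-only consistency check: catalog genes absent from the registry are
#' flagged unless they are HLA loci (HLA genes are analyzed through typing
#' tables, not variant calls, and are deliberately outside the registry);
#' non-coding entries are listed as not ascertainable by exome sequencing;
#' per-gene entry counts are tabulated.
#'
#' @param catalog A `pgx_catalog`.
#' @param registry A `pgx_registry`.
#' @param hla_loci Gene symbols exempt from the registry requirement.
#' @return A list of class `pgx_validation` with elements
#'   `genes_missing_from_registry`, `non_ascertainable` (data frame of
#'   flagged entries), and `per_gene_counts`.
#' @export
validate_catalog <- function(catalog, registry,
                             hla_loci = c("HLA-A", "HLA-B")) {
  stopifnot(inherits(catalog, "pgx_catalog"), inherits(registry, "pgx_registry"))
  if (nrow(catalog) == 0) {
    out <- list(genes_missing_from_registry = character(0),
                non_ascertainable = catalog[0, c("gene", "identifier")],
                per_gene_counts = integer(0))
    class(out) <- "pgx_validation"
    return(out)
  }
  genes <- unique(catalog$gene)
  missing <- setdiff(genes, c(registry$gene, hla_loci))
  if (length(missing)) {
    warning("catalog gene(s) absent from registry: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list(
    genes_missing_from_registry = missing,
    non_ascertainable = as.data.frame(
      catalog[!catalog$exome_ascertainable, c("gene", "identifier", "entry_class")]),
    per_gene_counts = table(catalog$gene))
  class(out) <- "pgx_validation"
  out
}

#' @export
print.pgx_validation <- function(x, ...) {
  cat("Catalog validation report\n")
  cat("  entries not exome-ascertainable:", nrow(x$non_ascertainable), "\n")
  if (length(x$genes_missing_from_registry)) {
    cat("  genes missing from registry:",
        paste(x$genes_missing_from_registry, collapse = ", "), "\n")
  }
  invisible(x)
}
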