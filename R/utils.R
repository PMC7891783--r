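#' Path to a packaged example/reference file
#'
#' Convenience accessor for the tab-separated reference tables shipped with
#' the package (actionable-variant catalog, pharmacogene registry, star-allele
#' definitions, genotype rules, allele-class frequencies, drug-gene map).
#'
#' @param file File name under `extdata/`. With no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
#' @examples
#' pgx_example()
#' pgx_example("genotype_rules.tsv")
pgx_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "pgximpact")))
  }
  path <- system.file("extdata", file, package = "pgximpact")
  if (identical(path, "")) {
    stop("no packaged file '", file, "'; see pgx_example() for the list",
         call. = FALSE)
  }
  path
}

# closed vocabulary for allele functional classes
FUNCTIONAL_CLASSES <- c("no_function", "decreased", "normal", "increased",
                        "risk", "favorable")

# read a UTF-8 TSV with a header row
read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8", check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# X chromosome spellings accepted in variant tables
is_x_chrom <- function(chrom) chrom %in% c("X", "chrX", "x", "23")

# canonical variant identity key: chrom:pos:ref:alt
variant_key <- function(chrom, pos, ref, alt) {
  paste(sub("^chr", "", chrom), pos, ref, alt, sep = ":")
}
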