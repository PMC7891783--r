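#' Load star-allele definitions
#'
#' Each row names one allele of a gene, its functional class, and the
#' semicolon-joined rsIDs of its defining marker variants. The allele with an
#' empty marker set is the gene's reference allele. Within a gene, two
#' alleles may not share an identical marker set (the caller could never
#' distinguish them).
#'
#' @param path TSV path; default the packaged definitions.
#' @return Data frame of class `pgx_star_defs` with a list column `markers`.
#' @export
read_star_allele_definitions <- function(path = pgx_example("star_allele_definitions.tsv")) {
  df <- read_tsv(path, na.strings = c("NA"))
  missing <- setdiff(c("gene", "allele", "functional_class", "markers"), names(df))
  if (length(missing)) {
    stop("definitions missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$functional_class %in% FUNCTIONAL_CLASSES)) {
    stop("unknown functional_class in star-allele definitions", call. = FALSE)
  }
  df$markers <- lapply(df$markers, function(m) {
    if (is.na(m) || m == "") character(0) else strsplit(m, ";", fixed = TRUE)[[1]]
  })
  for (g in unique(df$gene)) {
    sets <- df$markers[df$gene == g]
    keys <- vapply(sets, function(s) paste(sort(s), collapse = ";"), "")
    if (anyDuplicated(keys)) {
      stop("gene ", g, ": two alleles share an identical marker set",
           call. = FALSE)
    }
  }
  class(df) <- c("pgx_star_defs", "data.frame")
  df
}

#' Call star-allele diplotypes from unphased genotypes
#'
#' For each sample, enumerates the allele pairs (single alleles for males at
#' an X-linked gene) whose combined marker content reproduces the observed
#' unphased genotypes at the gene's marker variants exactly. Marker variants
#' absent from the matrix are taken as homozygous reference (explicitly
#' absent from the cohort). Ambiguity among exact solutions is resolved by
#' maximum parsimony (fewest non-reference alleles), then by definition-file
#' order; when more than one minimal solution remains the call is flagged
#' ambiguous and the candidate set reported. A sample with any missing marker
#' genotype is a no-call.
#'
#' @param geno A `pgx_geno` object.
#' @param defs Star-allele definitions (see
#'   [read_star_allele_definitions()]).
#' @param gene Gene symbol to call.
#' @param x_linked Is the gene X-linked? Default: any marker on chromosome X.
#' @return Data frame of class `pgx_diplotypes`: one row per sample with
#'   `allele1`, `allele2` (`NA` for hemizygous males), `hemizygous`,
#'   `ambiguous`, `no_call`, and semicolon-joined `candidates`.
#' @export
call_star_alleles <- function(geno, defs, gene, x_linked = NULL) {
  stopifnot(inherits(geno, "pgx_geno"))
  d <- defs[defs$gene == gene, , drop = FALSE]
  if (nrow(d) == 0) stop("no star-allele definitions for gene ", gene, call. = FALSE)
  markers <- unique(unlist(d$markers))
  idx <- match(markers, geno$variants$rsid)
  if (is.null(x_linked)) {
    x_linked <- any(is_x_chrom(geno$variants$chrom[idx[!is.na(idx)]]))
  }
  # marker indicator matrix: alleles x markers
  ind <- do.call(rbind, lapply(d$markers, function(m)
    as.integer(markers %in% m)))
  nonref <- vapply(d$markers, length, 1L) > 0

  # observed genotype matrix over markers (absent marker -> 0)
  obs <- matrix(0L, nrow(geno$samples), length(markers))
  present <- !is.na(idx)
  obs[, present] <- geno$calls[, idx[present], drop = FALSE]

  male <- geno$samples$sex == "male"
  n_all <- nrow(d)
  pair_idx <- which(upper.tri(matrix(0, n_all, n_all), diag = TRUE), arr.ind = TRUE)
  # order pairs by parsimony then definition order
  pair_nonref <- nonref[pair_idx[, 1]] + nonref[pair_idx[, 2]]
  ord <- order(pair_nonref, pair_idx[, 1], pair_idx[, 2])
  pair_idx <- pair_idx[ord, , drop = FALSE]
  pair_nonref <- pair_nonref[ord]
  pair_geno <- ind[pair_idx[, 1], , drop = FALSE] + ind[pair_idx[, 2], , drop = FALSE]

  res <- data.frame(sample = geno$samples$sample, gene = gene,
                    allele1 = NA_character_, allele2 = NA_character_,
                    hemizygous = FALSE, ambiguous = FALSE, no_call = FALSE,
                    candidates = NA_character_, stringsAsFactors = FALSE)
  single_ord <- order(nonref, seq_len(n_all))
  for (s in seq_len(nrow(res))) {
    g <- obs[s, ]
    if (anyNA(g)) { res$no_call[s] <- TRUE; next }
    if (x_linked && male[s]) {
      hit <- single_ord[colSums(t(ind[single_ord, , drop = FALSE]) != g) == 0]
      if (length(hit) == 0) { res$no_call[s] <- TRUE; next }
      minimal <- hit[nonref[hit] == min(nonref[hit])]
      res$allele1[s] <- d$allele[minimal[1]]
      res$hemizygous[s] <- TRUE
      if (length(minimal) > 1) {
        res$ambiguous[s] <- TRUE
        res$candidates[s] <- paste(d$allele[minimal], collapse = ";")
      }
    } else {
      exact <- which(colSums(t(pair_geno) != g) == 0)
      if (length(exact) == 0) { res$no_call[s] <- TRUE; next }
      minimal <- exact[pair_nonref[exact] == min(pair_nonref[exact])]
      best <- pair_idx[minimal[1], ]
      res$allele1[s] <- d$allele[best[1]]
      res$allele2[s] <- d$allele[best[2]]
      if (length(minimal) > 1) {
        res$ambiguous[s] <- TRUE
        res$candidates[s] <- paste(
          vapply(minimal, function(m) paste(d$allele[pair_idx[m, ]], collapse = "/"), ""),
          collapse = ";")
      }
    }
  }
  attr(res, "classes") <- stats::setNames(d$functional_class, d$allele)
  class(res) <- c("pgx_diplotypes", "data.frame")
  res
}

# pattern matchers ------------------------------------------------------------

# does the (multi)set of functional classes satisfy a rule pattern?
match_pattern <- function(pattern, classes) {
  if (startsWith(pattern, "carrier:")) {
    return(sub("^carrier:", "", pattern) %in% classes)
  }
  want <- sort(strsplit(pattern, "/", fixed = TRUE)[[1]])
  identical(sort(classes), want)
}

#' Load genotype-definition rules
#'
#' Declarative mapping from diplotype functional-class patterns to phenotype
#' labels, mirroring a CPIC-style frequency table. Pattern syntax:
#' `"classA/classB"` (unordered diplotype multiset), a single class for
#' hemizygous male X rules, or `"carrier:class"` (at least one allele of the
#' class). `aggregate_mode` declares how the gene's actionable phenotype
#' frequencies combine to a by-gene figure (`disjoint`, `carrier_union`, or
#' `x_linked`), and `source` whether the frequency comes from Hardy-Weinberg
#' projection (`hwe`) or an external published estimate (`external`, with
#' `external_freq_pct`).
#'
#' @param path TSV path; default the packaged rules.
#' @return Data frame of class `pgx_rules`.
#' @export
read_genotype_rules <- function(path = pgx_example("genotype_rules.tsv")) {
  df <- read_tsv(path, na.strings = "NA")
  need <- c("gene", "phenotype", "pattern", "sex_mode", "actionable",
            "aggregate_mode", "source")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("rules missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$actionable <- as.logical(df$actionable)
  df$rule_id <- paste0(df$gene, ":", df$phenotype)
  # exclusivity within (gene, sex_mode) is checked by enumeration
  for (g in unique(df$gene)) check_rule_exclusivity(df[df$gene == g, ])
  class(df) <- c("pgx_rules", "data.frame")
  df
}

# enumerate all diplotype class multisets and verify no two rules of the same
# gene and sex mode both match
check_rule_exclusivity <- function(rules, classes = FUNCTIONAL_CLASSES) {
  for (sm in unique(rules$sex_mode)) {
    r <- rules[rules$sex_mode == sm, , drop = FALSE]
    if (nrow(r) < 2) next
    combos <- if (sm == "x_linked_male") {
      as.list(classes)
    } else {
      unlist(lapply(seq_along(classes), function(i)
        lapply(seq(i, length(classes)), function(j) c(classes[i], classes[j]))),
        recursive = FALSE)
    }
    for (cc in combos) {
      hits <- vapply(r$pattern, match_pattern, logical(1), classes = cc)
      if (sum(hits) > 1) {
        stop("rules for ", r$gene[1], " are not mutually exclusive: ",
             paste(r$phenotype[hits], collapse = " / "),
             " both match {", paste(cc, collapse = ", "), "}", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Translate diplotype calls to phenotypes
#'
#' Matches each unambiguous diplotype's functional-class multiset against the
#' gene's rules for the appropriate sex mode. Diplotypes matching no rule are
#' labelled with `unmatched_label` and are not actionable. Ambiguous and
#' no-call diplotypes are excluded (phenotype `NA`), which keeps frequency
#' tallies conservative.
#'
#' @param calls A `pgx_diplotypes` from [call_star_alleles()].
#' @param rules A `pgx_rules` table.
#' @param sex Character vector of sample sexes aligned with `calls` (only
#'   consulted for X-linked rules); default taken from the calls when the
#'   gene is autosomal.
#' @param unmatched_label Label for diplotypes matching no rule.
#' @return Data frame: `sample`, `gene`, `phenotype`, `actionable`,
#'   `rule_id`, `excluded`.
#' @export
assign_phenotype <- function(calls, rules, sex = NULL,
                             unmatched_label = "Normal/indeterminate") {
  gene <- calls$gene[1]
  classes <- attr(calls, "classes")
  r <- rules[rules$gene == gene, , drop = FALSE]
  out <- data.frame(sample = calls$sample, gene = gene,
                    phenotype = NA_character_, actionable = FALSE,
                    rule_id = NA_character_,
                    excluded = calls$ambiguous | calls$no_call,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (out$excluded[i]) next
    hemi <- calls$hemizygous[i]
    cl <- classes[c(calls$allele1[i], if (!hemi) calls$allele2[i])]
    sm <- if (!any(grepl("x_linked", r$sex_mode))) "autosomal"
          else if (hemi || (!is.null(sex) && sex[i] == "male")) "x_linked_male"
          else "x_linked_female"
    rr <- r[r$sex_mode == sm, , drop = FALSE]
    hits <- which(vapply(rr$pattern, match_pattern, logical(1),
                         classes = unname(cl)))
    if (length(hits) > 1) {
      stop("rules for ", gene, " are not mutually exclusive (sample ",
           out$sample[i], ")", call. = FALSE)
    }
    if (length(hits) == 1) {
      out$phenotype[i] <- rr$phenotype[hits]
      out$actionable[i] <- rr$actionable[hits]
      out$rule_id[i] <- rr$rule_id[hits]
    } else {
      out$phenotype[i] <- unmatched_label
    }
  }
  out
}

#' HLA risk-allele carrier status
#'
#' A sample is positive for a risk allele if the allele appears at least once
#' in its typed pair at the locus. Samples without typing at the locus are
#' no-calls and are omitted (excluded from denominators).
#'
#' @param typing A `pgx_hla` table.
#' @param risk_alleles Data frame with columns `locus` and `allele` (one row
#'   per risk allele), or a character vector of alleles if `typing` carries a
#'   single locus.
#' @return Data frame: `sample`, `locus`, `allele`, `positive`.
#' @export
hla_carrier_status <- function(typing, risk_alleles) {
  if (is.character(risk_alleles)) {
    risk_alleles <- data.frame(locus = unique(typing$locus),
                               allele = risk_alleles,
                               stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(risk_alleles))) {
    loc <- risk_alleles$locus[i]; al <- risk_alleles$allele[i]
    t <- typing[typing$locus == loc, , drop = FALSE]
    if (nrow(t) == 0) next
    out[[i]] <- data.frame(sample = t$sample, locus = loc, allele = al,
                           positive = t$allele1 == al | t$allele2 == al,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# which catalog entries does each sample carry (>=1 copy)?
# Resolves each entry to marker rsIDs: rs-identifiers map to themselves,
# star alleles through the definitions, HLA alleles through the typing table.
# Entries with no resolvable markers are skipped and listed in the
# "unascertained" attribute.
catalog_carriage <- function(geno, catalog, defs = NULL, hla = NULL) {
  n <- nrow(geno$samples)
  carried <- matrix(FALSE, n, 0)
  skipped <- character(0)
  rsids <- geno$variants$rsid
  for (i in seq_len(nrow(catalog))) {
    id <- catalog$identifier[i]; gene <- catalog$gene[i]
    if (catalog$entry_class[i] == "hla_allele") {
      if (is.null(hla)) { skipped <- c(skipped, id); next }
      st <- hla_carrier_status(hla, data.frame(locus = gene, allele = id))
      v <- rep(FALSE, n)
      if (!is.null(st)) {
        v[match(st$sample, geno$samples$sample)] <- st$positive
      }
      carried <- cbind(carried, v); colnames(carried)[ncol(carried)] <- paste(gene, id)
      next
    }
    markers <- if (startsWith(id, "rs")) id
               else if (!is.null(defs)) {
                 m <- defs$markers[defs$gene == gene & defs$allele == id]
                 if (length(m)) m[[1]] else character(0)
               } else character(0)
    idx <- match(markers, rsids)
    if (length(markers) == 0 || anyNA(idx)) { skipped <- c(skipped, paste(gene, id)); next }
    g <- geno$calls[, idx, drop = FALSE]
    v <- rowSums(g >= 1) == length(idx)   # all defining markers carried
    v[is.na(v)] <- FALSE
    carried <- cbind(carried, v); colnames(carried)[ncol(carried)] <- paste(gene, id)
  }
  attr(carried, "unascertained") <- skipped
  carried
}

#' Per-sample actionable-variant burden
#'
#' Counts, for each sample, the distinct actionable catalog variants/alleles
#' carried (one or more copies counts once; a homozygote contributes one).
#' Catalog entries that cannot be resolved to markers in the matrix or to an
#' HLA typing (e.g., non-coding entries) are skipped and reported.
#'
#' @param geno A `pgx_geno`.
#' @param catalog A `pgx_catalog`.
#' @param defs Star-allele definitions used to resolve star-allele entries.
#' @param hla Optional `pgx_hla` typing table for HLA entries.
#' @return List of class `pgx_burden`: `per_sample` counts, `histogram`,
#'   `median`, `fraction_ge1`, and `unascertained` entry labels.
#' @export
actionable_burden <- function(geno, catalog, defs = NULL, hla = NULL) {
  carried <- catalog_carriage(geno, catalog, defs, hla)
  burden_summary(rowSums(carried), geno$samples$sample,
                 unascertained = attr(carried, "unascertained"))
}

burden_summary <- function(counts, samples, unascertained = character(0)) {
  counts <- as.integer(counts)
  out <- list(per_sample = stats::setNames(counts, samples),
              histogram = table(factor(counts, levels = 0:max(counts, 0))),
              median = stats::median(counts),
              fraction_ge1 = mean(counts >= 1),
              unascertained = unascertained)
  class(out) <- "pgx_burden"
  out
}

#' @export
print.pgx_burden <- function(x, ...) {
  cat("Per-sample variant burden: n =", length(x$per_sample),
      "| median =", x$median,
      sprintf("| %.1f%% carry >=1\n", 100 * x$fraction_ge1))
  invisible(x)
}
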