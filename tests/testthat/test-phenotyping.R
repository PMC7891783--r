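# a small gene with nested marker sets (classic *3A/*3C-style structure)
toy_defs_df <- data.frame(
  gene = "TOY",
  allele = c("*1", "*2", "*3", "*4"),
  functional_class = c("normal", "no_function", "no_function", "decreased"),
  markers = c("", "rsA;rsB", "rsB", "rsC"),
  stringsAsFactors = FALSE)

test_that("definition loader parses markers and rejects duplicate marker sets", {
  defs <- load_defs(toy_defs_df)
  expect_equal(defs$markers[[2]], c("rsA", "rsB"))
  expect_length(defs$markers[[1]], 0)

  bad <- toy_defs_df
  bad$markers[3] <- "rsA;rsB"   # same set as *2
  expect_error(load_defs(bad), "identical marker set")
})

test_that("star-allele calls match hand-derived diplotypes", {
  defs <- load_defs(toy_defs_df)
  # samples: ref/ref; *1/*3 (rsB het); *2/*2 (both hom); *1/*4; *3/*3
  calls_mat <- rbind(c(0L, 0L, 0L),
                     c(0L, 1L, 0L),
                     c(2L, 2L, 0L),
                     c(0L, 0L, 1L),
                     c(0L, 2L, 0L))
  g <- make_geno(calls_mat, rsid = c("rsA", "rsB", "rsC"))
  out <- call_star_alleles(g, defs, "TOY")
  expect_equal(out$allele1, c("*1", "*1", "*2", "*1", "*3"))
  expect_equal(out$allele2, c("*1", "*3", "*2", "*4", "*3"))
  expect_false(any(out$ambiguous))
  expect_false(any(out$no_call))
})

test_that("missing marker genotypes give a no-call and parsimony breaks ties", {
  defs <- load_defs(toy_defs_df)
  g <- make_geno(rbind(c(NA, 1L, 0L)), rsid = c("rsA", "rsB", "rsC"))
  out <- call_star_alleles(g, defs, "TOY")
  expect_true(out$no_call[1])

  # rsA het + rsB hom: exact solutions are *2/*3 (two non-ref).
  g2 <- make_geno(rbind(c(1L, 2L, 0L)), rsid = c("rsA", "rsB", "rsC"))
  out2 <- call_star_alleles(g2, defs, "TOY")
  expect_equal(sort(c(out2$allele1, out2$allele2)), c("*2", "*3"))
})

test_that("caller agrees with exhaustive enumeration on all genotype inputs", {
  defs <- load_defs(toy_defs_df)
  d <- defs[defs$gene == "TOY", ]
  markers <- c("rsA", "rsB", "rsC")
  grid <- expand.grid(0:2, 0:2, 0:2)
  for (i in seq_len(nrow(grid))) {
    gvec <- as.integer(grid[i, ])
    oracle <- enumerate_diplotypes(d, gvec, markers)
    g <- make_geno(matrix(gvec, 1), rsid = markers)
    out <- call_star_alleles(g, defs, "TOY")
    if (length(oracle) == 0) {
      expect_true(out$no_call[1], info = paste(gvec, collapse = ","))
    } else {
      expect_false(out$no_call[1], info = paste(gvec, collapse = ","))
      got <- sort(c(out$allele1[1], out$allele2[1]))
      expect_true(any(vapply(oracle, identical, TRUE, x = got)),
                  info = paste(gvec, collapse = ","))
      expect_equal(out$ambiguous[1], length(oracle) > 1,
                   info = paste(gvec, collapse = ","))
    }
  }
})

test_that("caller agrees with enumeration for hemizygous males at an X gene", {
  defs_x <- load_defs(data.frame(
    gene = "XG", allele = c("B", "Canton", "Kaiping"),
    functional_class = c("normal", "decreased", "decreased"),
    markers = c("", "rsA", "rsB"), stringsAsFactors = FALSE))
  d <- defs_x[defs_x$gene == "XG", ]
  markers <- c("rsA", "rsB")
  for (a in 0:1) for (b in 0:1) {
    gvec <- c(a, b)
    oracle <- enumerate_diplotypes(d, gvec, markers, x_male = TRUE)
    g <- make_geno(matrix(as.integer(gvec), 1), sex = "male",
                   chrom = c("X", "X"), rsid = markers)
    out <- call_star_alleles(g, defs_x, "XG")
    if (length(oracle) == 0) {
      expect_true(out$no_call[1])
    } else {
      expect_true(out$hemizygous[1])
      expect_equal(out$allele1[1], oracle[[1]])
    }
  }
})

test_that("phenotype rules translate diplotype class multisets", {
  rules <- read_genotype_rules()
  defs <- read_star_allele_definitions()
  # CYP2C19 *1/*2 -> intermediate metabolizer (actionable)
  g <- make_geno(matrix(c(1L, 0L, 0L), 1),
                 rsid = c("rs4244285", "rs4986893", "rs72552267"))
  calls <- call_star_alleles(g, defs, "CYP2C19")
  ph <- assign_phenotype(calls, rules)
  expect_equal(ph$phenotype, "Intermediate metabolizer")
  expect_true(ph$actionable)

  # homozygous reference -> unmatched label, not actionable
  g0 <- make_geno(matrix(c(0L, 0L, 0L), 1),
                  rsid = c("rs4244285", "rs4986893", "rs72552267"))
  ph0 <- assign_phenotype(call_star_alleles(g0, defs, "CYP2C19"), rules)
  expect_equal(ph0$phenotype, "Normal/indeterminate")
  expect_false(ph0$actionable)
})

test_that("G6PD phenotype assignment is sex-consistent", {
  rules <- read_genotype_rules()
  defs <- read_star_allele_definitions()
  rs <- c("rs72554665", "rs72554664", "rs72554663")
  # male hemizygous carrier -> Deficient (male)
  gm <- make_geno(matrix(c(1L, 0L, 0L), 1), sex = "male",
                  chrom = rep("X", 3), rsid = rs)
  phm <- assign_phenotype(call_star_alleles(gm, defs, "G6PD"), rules,
                          sex = "male")
  expect_equal(phm$phenotype, "Deficient (male)")

  # female heterozygote matches no rule (two deficient alleles required)
  gf <- make_geno(matrix(c(1L, 0L, 0L), 1), sex = "female",
                  chrom = rep("X", 3), rsid = rs)
  phf <- assign_phenotype(call_star_alleles(gf, defs, "G6PD"), rules,
                          sex = "female")
  expect_equal(phf$phenotype, "Normal/indeterminate")

  # female compound deficient homozygote -> Deficient (female)
  gf2 <- make_geno(matrix(c(1L, 1L, 0L), 1), sex = "female",
                   chrom = rep("X", 3), rsid = rs)
  phf2 <- assign_phenotype(call_star_alleles(gf2, defs, "G6PD"), rules,
                           sex = "female")
  expect_equal(phf2$phenotype, "Deficient (female)")
})

test_that("rules within a gene are mutually exclusive; overlap is an error", {
  rules <- read_genotype_rules()
  for (g in unique(rules$gene)) {
    expect_true(pgximpact:::check_rule_exclusivity(rules[rules$gene == g, ]))
  }
  overlap <- data.frame(
    gene = "BAD", phenotype = c("P1", "P2"),
    pattern = c("carrier:no_function", "normal/no_function"),
    sex_mode = "autosomal", actionable = TRUE, stringsAsFactors = FALSE)
  expect_error(pgximpact:::check_rule_exclusivity(overlap), "not mutually exclusive")
})

test_that("HLA carrier status is per risk allele; one sample can carry two", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tlocus\tallele1\tallele2",
               "S1\tHLA-B\tB*15:02\tB*40:01",
               "S2\tHLA-B\tB*58:01\tB*58:01",
               "S3\tHLA-B\tB*15:02\tB*58:01"), f)
  h <- read_hla_table(f)
  st <- hla_carrier_status(h, data.frame(locus = c("HLA-B", "HLA-B"),
                                         allele = c("B*15:02", "B*58:01")))
  pos <- st[st$positive, c("sample", "allele")]
  expect_equal(sort(paste(pos$sample, pos$allele)),
               c("S1 B*15:02", "S2 B*58:01", "S3 B*15:02", "S3 B*58:01"))
  # untyped locus gives no rows (excluded, not negative)
  expect_null(hla_carrier_status(h, data.frame(locus = "HLA-A",
                                               allele = "A*31:01")))
})

test_that("actionable burden counts distinct variants once each", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tidentifier\tentry_class\tfunctional_class\tdrugs\texome_ascertainable",
               "G1\trs1\tsnv_marker\trisk\tdrugA\tTRUE",
               "G2\trs2\tsnv_marker\trisk\tdrugB\tTRUE",
               "G3\trs3\tsnv_marker\trisk\tdrugC\tTRUE",
               "G4\trs4\tsnv_marker\trisk\tdrugD\tTRUE"), f)
  cat <- load_actionable_catalog(f)
  # sample 1: het at 3 variants + hom at 1 -> burden 4; sample 2: none
  calls <- rbind(c(1L, 1L, 1L, 2L), c(0L, 0L, 0L, 0L))
  b <- actionable_burden(make_geno(calls), cat)
  expect_equal(unname(b$per_sample), c(4L, 0L))
  expect_equal(b$fraction_ge1, 0.5)
})

test_that("fraction with >=1 actionable variant matches the independence closed form", {
  set.seed(5)
  n <- 6000
  afs <- c(0.05, 0.1, 0.2, 0.02, 0.15)
  calls <- vapply(afs, function(q) rbinom(n, 2, q), integer(n))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tidentifier\tentry_class\tfunctional_class\tdrugs\texome_ascertainable",
               sprintf("G%d\trs%d\tsnv_marker\trisk\tdrug\tTRUE", 1:5, 1:5)), f)
  b <- actionable_burden(make_geno(calls), load_actionable_catalog(f))
  expected <- 1 - prod((1 - afs)^2)
  expect_true(within_3se(b$fraction_ge1, expected, n))
})
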