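ann_row <- function(consequence = "missense", gnomad_af = 0.001,
                    cadd = NA, revel = NA, predict = NA, loftee = NA,
                    in_gnomad = TRUE, in_dbsnp = TRUE, in_clinvar = FALSE,
                    gene = "CYP2C9", id = "v1") {
  data.frame(variant_id = id, gene = gene, consequence = consequence,
             gnomad_af = gnomad_af, cadd_phred = cadd, revel = revel,
             predict_score = predict, loftee = loftee, in_gnomad = in_gnomad,
             in_dbsnp = in_dbsnp, in_clinvar = in_clinvar,
             stringsAsFactors = FALSE)
}

test_that("threshold rules classify missense and LoF variants", {
  # missense: one tool over threshold suffices
  r <- classify_variants(ann_row(cadd = 25, revel = 0.2, predict = 0.1))
  expect_true(r$is_rare); expect_true(r$is_deleterious)
  expect_equal(r$tools_supporting, "CADD")

  r2 <- classify_variants(ann_row(cadd = 10, revel = 0.5, predict = 0.3))
  expect_false(r2$is_deleterious)
  expect_equal(r2$tools_supporting, "")

  # LoF: LOFTEE high-confidence alone suffices even with low CADD
  r3 <- classify_variants(ann_row("lof_stopgain", cadd = 15, loftee = "HC"))
  expect_true(r3$is_deleterious)
  expect_equal(r3$tools_supporting, "LOFTEE")

  # REVEL/PREDICT never support a LoF variant; LOFTEE never a missense one
  r4 <- classify_variants(ann_row("lof_splice", cadd = 10, revel = 0.99,
                                  predict = 0.99, loftee = "LC"))
  expect_false(r4$is_deleterious)
  r5 <- classify_variants(ann_row("missense", loftee = "HC"))
  expect_false(r5$is_deleterious)

  # other consequences are never deleterious
  r6 <- classify_variants(ann_row("other", cadd = 35))
  expect_false(r6$is_deleterious)
})

test_that("rarity uses gnomAD AF with absent-from-gnomAD treated as rare", {
  expect_false(classify_variants(ann_row(gnomad_af = 0.02))$is_rare)
  expect_true(classify_variants(ann_row(gnomad_af = 0.0099))$is_rare)
  miss <- classify_variants(ann_row(gnomad_af = NA, in_gnomad = FALSE,
                                    in_dbsnp = FALSE, in_clinvar = FALSE))
  expect_true(miss$is_rare)
  expect_true(miss$is_novel)
  known <- classify_variants(ann_row(gnomad_af = NA, in_gnomad = FALSE,
                                     in_dbsnp = TRUE))
  expect_false(known$is_novel)
})

test_that("classification is total, order-invariant, and monotone in thresholds", {
  spec <- annotation_spec(500, seed = 77, genes = c("A", "B"))
  ann <- simulate_annotations(spec)
  cl <- classify_variants(ann)
  expect_equal(nrow(cl), 500)
  expect_true(all(cl$tools_supporting[cl$is_deleterious] != ""))

  set.seed(1)
  perm <- sample(nrow(ann))
  cl_perm <- classify_variants(ann[perm, ])
  expect_equal(sum(cl_perm$is_deleterious), sum(cl$is_deleterious))
  expect_equal(sum(cl_perm$is_rare), sum(cl$is_rare))

  n_del <- sum(cl$is_deleterious)
  for (t in list(classification_thresholds(cadd_min = 30),
                 classification_thresholds(revel_min = 0.9),
                 classification_thresholds(predict_min = 0.9))) {
    expect_lte(sum(classify_variants(ann, t)$is_deleterious), n_del)
  }
})

test_that("planted deleterious fractions are recovered", {
  # 30% of missense cross CADD only: recovered fraction ~ 0.30
  spec <- annotation_spec(4000, p_missense = 1, p_lof = 0,
                          p_cadd_mis = 0.3, p_revel = 0, p_predict = 0,
                          seed = 99)
  cl <- classify_variants(simulate_annotations(spec))
  expect_true(within_3se(mean(cl$is_deleterious), 0.3, 4000))

  # everything below threshold -> zero deleterious
  spec0 <- annotation_spec(500, p_cadd_mis = 0, p_revel = 0, p_predict = 0,
                           p_cadd_lof = 0, p_loftee_hc = 0, seed = 3)
  expect_equal(sum(classify_variants(simulate_annotations(spec0))$is_deleterious), 0)
})

test_that("cohort exclusions remove the implicated disease groups only", {
  samples <- data.frame(sample = sprintf("S%d", 1:10),
                        cohort_label = c(rep("respiratory", 2),
                                         rep("rare_disease", 8)),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(apply_cohort_exclusions(samples, "CFTR")), 8)
  expect_equal(nrow(suppressMessages(apply_cohort_exclusions(samples, "CYP2C19"))), 10)
  allnm <- data.frame(sample = "S1", cohort_label = "neuromuscular",
                      stringsAsFactors = FALSE)
  expect_warning(out <- apply_cohort_exclusions(allnm, "RYR1"), "all samples")
  expect_equal(nrow(out), 0)
})

test_that("rare-deleterious burden counts variants once and supports gene subsets", {
  ann <- rbind(ann_row(cadd = 30, id = "V1", gene = "CYP2C9"),
               ann_row(cadd = 30, id = "V2", gene = "LPA"),
               ann_row(cadd = 5, id = "V3", gene = "CYP2C9"))
  cl <- classify_variants(ann)
  calls <- rbind(c(1L, 2L, 1L),   # carries both qualifying variants
                 c(0L, 0L, 2L))   # only the non-qualifying one
  g <- make_geno(calls, rsid = c("V1", "V2", "V3"))
  colnames(g$calls) <- c("V1", "V2", "V3")
  b <- rare_deleterious_burden(g, cl)
  expect_equal(unname(b$per_sample), c(2L, 0L))
  b_cyp <- rare_deleterious_burden(g, cl, genes = "CYP2C9")
  expect_equal(unname(b_cyp$per_sample), c(1L, 0L))
})

test_that("burden fraction matches the closed form under independence", {
  set.seed(21)
  n <- 5000; a <- 0.03; k <- 6
  calls <- vapply(1:k, function(j) rbinom(n, 2, a), integer(n))
  ann <- do.call(rbind, lapply(1:k, function(j)
    ann_row(cadd = 30, id = paste0("V", j))))
  g <- make_geno(calls, rsid = paste0("V", 1:k))
  colnames(g$calls) <- paste0("V", 1:k)
  b <- rare_deleterious_burden(g, classify_variants(ann))
  carrier <- 1 - (1 - a)^2
  expected <- 1 - (1 - carrier)^k
  expect_true(within_3se(b$fraction_ge1, expected, n))
})

test_that("consensus summary splits tool-agreement patterns", {
  ann <- rbind(ann_row(cadd = 30, id = "V1"),
               ann_row(cadd = 30, revel = 0.9, predict = 0.8, id = "V2"),
               ann_row(cadd = 5, id = "V3"))
  cs <- consensus_summary(classify_variants(ann))
  expect_equal(cs$missense$at_least_one, 2)
  expect_equal(cs$missense$consensus, 1)

  none <- consensus_summary(classify_variants(ann_row(cadd = 1)))
  expect_equal(none$missense$at_least_one, 0)
  expect_equal(none$lof$n, 0)
})

test_that("deleterious split percentages come out on the published scale", {
  # a 531-variant classification with 475 missense and 56 LoF deleterious
  expect_equal(summarize_percentages(475, 531), 89.5)
  expect_equal(summarize_percentages(56, 531), 10.5)
})

test_that("variant-count regression recovers noiseless coefficients exactly", {
  reg <- load_pharmacogene_registry()
  d <- as.data.frame(reg)[1:40, ]
  counts <- data.frame(gene = d$gene,
                       n_variants = 5 + 0.3 * d$transcript_length / 1000)
  fit <- suppressWarnings(variant_count_regression(counts, reg))
  expect_lt(abs(fit$slope_per_kb - 0.3), 1e-8)
  expect_lt(abs(fit$intercept - 5), 1e-8)
  expect_lt(abs(fit$oe_coefficient), 1e-8)

  expect_error(variant_count_regression(counts[1:2, ], reg), "degenerate")
})

test_that("under the null the slope CI covers zero in most replicates", {
  reg <- load_pharmacogene_registry()
  d <- as.data.frame(reg)[1:50, ]
  covered <- 0L
  for (s in 1:100) {
    set.seed(s)
    counts <- data.frame(gene = d$gene, n_variants = rnorm(50, 20, 4))
    fit <- variant_count_regression(counts, reg)
    ci <- stats::confint(fit$fit, "length_kb", level = 0.95)
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1L
  }
  expect_gte(covered, 90)
})
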