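test_that("up/down flags are strict on both the fold-change and FDR axes", {
  de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   logFC = c(1.0, 1.5, 2.0, -1.5, 0.2),
                   fdr = c(0.01, 0.2, 0.01, 0.01, 0.001))
  fl <- flag_upregulated(de)
  expect_identical(fl$status, c("intermediate", "intermediate", "up",
                                "down", "intermediate"))
})

test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeom_upper(10, 5, 5, 5), 1 / 252)
  expect_equal(hypergeom_upper(100, 30, 10, 0), 1)
  set.seed(51)
  for (i in 1:40) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper(N, K, n, k),
                 hyper_upper_oracle(N, K, n, k), tolerance = 1e-12)
    # complement identity and monotone decrease in k
    if (k >= 1)
      expect_equal(hypergeom_upper(N, K, n, k) +
                     phyper(k - 1, K, N - K, n), 1, tolerance = 1e-12)
    if (k < min(n, K))
      expect_gte(hypergeom_upper(N, K, n, k),
                 hypergeom_upper(N, K, n, k + 1))
  }
  expect_equal(hypergeom_upper(20, 20, 7, 5), 1)  # K = N
  expect_error(hypergeom_upper(10, 12, 5, 1))
  expect_error(hypergeom_upper(10, 5, 5, 6))
})

fake_assessment <- function(subtype, n = 40, cand = 1:20, up = 1:8,
                            hypo = c(1:4, 9:10), poor = c(1:3, 11:12),
                            cs = NULL) {
  gene <- sprintf("G%02d", 1:n)
  if (is.null(cs)) {
    cs <- rep(-0.2, n); cs[cand] <- seq(-0.99, -0.71, length.out = length(cand))
  }
  conn <- data.frame(knocked_gene = gene, es_up = 0, es_down = 0,
                     es = cs, cs = cs)
  de <- data.frame(gene = gene, logFC = ifelse(seq_len(n) %in% up, 2, 0),
                   fdr = ifelse(seq_len(n) %in% up, 1e-5, 0.9))
  meth <- data.frame(gene = gene, hypo = seq_len(n) %in% hypo,
                     hyper = FALSE)
  assess_genes(conn, flag_upregulated(de),
               survival_genes = gene[poor], meth_flags = meth,
               subtype = subtype)
}

test_that("the final-target verdict is the four-filter conjunction", {
  a <- fake_assessment("LumA")
  want <- sprintf("G%02d", 1:3)  # candidate & up & hypo & poor-survival
  expect_setequal(a$gene[a$final_target], want)
  # failing any one filter drops the gene
  expect_false(a$final_target[a$gene == "G04"])  # not poor-survival
  expect_false(a$final_target[a$gene == "G09"])  # not candidate-up?: hypo+poor
  expect_false(any(a$final_target[!a$is_candidate]))
})

test_that("missing filters are reported as not-evaluated, never false", {
  gene <- sprintf("G%02d", 1:10)
  conn <- data.frame(knocked_gene = gene, es_up = 0, es_down = 0,
                     es = -0.8, cs = rep(-0.8, 10))
  de <- data.frame(gene = gene, logFC = 2, fdr = 1e-6)
  a <- assess_genes(conn, flag_upregulated(de), survival_genes = NULL,
                    meth_flags = NULL, subtype = "LumA")
  expect_true(all(is.na(a$poor_survival)))
  expect_true(all(is.na(a$hypo)))
  expect_true(all(is.na(a$final_target)))
  expect_true(all(is.na(a$n_drugs)))
})

test_that("enrichment report reproduces oracle counts and probabilities", {
  a1 <- fake_assessment("LumA")
  a2 <- fake_assessment("LumB", up = 3:9)
  rep_ <- enrichment_report(list(LumA = a1, LumB = a2), high_cs_cut = 0.8)
  # population = candidates; high-CS genes are those with cs < -0.8 here
  cand <- a1$gene[a1$is_candidate]
  high <- a1$gene[a1$is_candidate & abs(a1$cs) > 0.8]
  poor <- intersect(sprintf("G%02d", c(1:3, 11:12)), cand)
  r1 <- rep_[rep_$test == "poor_survival_vs_high_cs", ]
  expect_equal(r1$N, length(cand))
  expect_equal(r1$K, length(poor))
  expect_equal(r1$n, length(high))
  expect_equal(r1$k, length(intersect(poor, high)))
  expect_equal(r1$p, hyper_upper_oracle(r1$N, r1$K, r1$n, r1$k),
               tolerance = 1e-12)
  hu <- a2$gene[a2$is_candidate & a2$hypo & a2$is_up]
  r2 <- rep_[rep_$test == "hypo_up_vs_poor_survival" & rep_$subtype == "LumB", ]
  expect_equal(r2$K, length(hu))
  expect_equal(r2$k, length(intersect(hu, poor)))
})

test_that("census annotation flags membership and breast specificity", {
  tb <- data.frame(gene = c("G01", "G03", "G99"),
                   breast = c(TRUE, FALSE, TRUE))
  res <- suppressMessages(annotate_census(sprintf("G%02d", 1:5), tb))
  expect_equal(res$census, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$census_breast, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  empty <- suppressMessages(annotate_census(
    c("A", "B"), data.frame(gene = character(0), breast = logical(0))))
  expect_false(any(empty$census))
})

test_that("drug annotation counts approved drugs per target gene", {
  tb <- read.delim(system.file("extdata", "synthetic_drug_targets.tsv",
                               package = "kdscreen"))
  res <- annotate_drugs(c("GENE00004", "GENE00005", "GENE00018",
                          "GENE00099"), tb)
  # GABRP-like pattern: 41 approved drugs on one receptor gene
  expect_equal(res$n_drugs[res$gene == "GENE00004"], 41)
  expect_equal(res$n_antineoplastic[res$gene == "GENE00004"], 1)
  # unapproved drugs are not counted
  expect_equal(res$n_drugs[res$gene == "GENE00005"], 1)
  expect_true(res$novel[res$gene == "GENE00099"])
  # one drug hitting two genes counts once per gene
  tb2 <- data.frame(drug_id = "D1", drug_name = "x",
                    target_gene = c("A", "B"), approved_flag = TRUE,
                    atc_code = "L01AA")
  res2 <- annotate_drugs(c("A", "B"), tb2)
  expect_equal(res2$n_drugs, c(1, 1))
})

test_that("the final table prints per-subtype cells with dashes elsewhere", {
  mk <- function(st, finals) {
    a <- fake_assessment(st)
    a$final_target <- a$gene %in% finals
    a
  }
  all4 <- sprintf("G%02d", 1)
  asm <- list(LumA = mk("LumA", c("G01", "G02")), LumB = mk("LumB", all4),
              HER2 = mk("HER2", all4), TNBC = mk("TNBC", all4))
  ft <- final_table(asm)
  r1 <- ft[ft$gene == "G01", ]
  cells <- unlist(r1[grep("^(CS|logFC)_", names(ft))])
  expect_true(all(cells != "-"))           # 8 numeric cells
  expect_equal(r1$specificity, "common")
  r2 <- ft[ft$gene == "G02", ]
  cells2 <- unlist(r2[grep("^(CS|logFC)_", names(ft))])
  expect_equal(sum(cells2 == "-"), 6)      # one subtype: 6 dashes
  expect_equal(r2$specificity, "specific")
  expect_equal(nrow(final_table(list(LumA = mk("LumA", character(0))))), 0)
})
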