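test_that("most-variable gene selection matches a brute-force variance sort", {
  set.seed(11)
  m <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:20)))
  got <- select_most_variable(m, 10)
  v <- apply(m, 1, var)
  want <- names(sort(v, decreasing = TRUE))[1:10]
  expect_identical(got, want)
  # ties broken lexicographically: constant matrix
  k <- matrix(1, 10, 5, dimnames = list(sprintf("g%02d", 10:1), paste0("s", 1:5)))
  expect_identical(select_most_variable(k, 5), sort(rownames(k))[1:5])
  # single dominant gene
  m2 <- matrix(rnorm(5 * 10, sd = 1), 5, 10,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m2["g3", ] <- rnorm(10, sd = 10)
  expect_identical(select_most_variable(m2, 1), "g3")
  expect_error(select_most_variable(m, 0), "positive")
})

test_that("outlier removal drops an anti-correlated sample and only that", {
  set.seed(12)
  va <- rnorm(60); vb <- rnorm(60)
  mk <- function(v, n, pre) {
    sapply(seq_len(n), function(i) v + rnorm(60, sd = 0.05)) |>
      (\(m) {colnames(m) <- paste0(pre, seq_len(n)); m})()
  }
  expr <- cbind(mk(va, 5, "A"), mk(vb, 5, "B"))
  expr <- cbind(expr, Aout = -va + rnorm(60, sd = 0.05))
  rownames(expr) <- sprintf("g%03d", 1:60)
  annot <- data.frame(sample_id = colnames(expr),
                      subtype = c(rep("A", 5), rep("B", 5), "A"))
  out <- suppressMessages(remove_outliers(expr, annot, n_var = 60,
                                          cut_height = 0.5))
  expect_identical(out$removed, "Aout")
  # identical samples: nothing removed
  same <- matrix(rep(va, 8), 60, 8,
                 dimnames = list(rownames(expr), paste0("s", 1:8)))
  annot2 <- data.frame(sample_id = colnames(same),
                       subtype = rep(c("A", "B"), each = 4))
  expect_length(remove_outliers(same, annot2, n_var = 60,
                                cut_height = 0.5)$removed, 0)
  # cut height zero: every sample is a singleton majority cluster
  out0 <- remove_outliers(expr, annot, n_var = 60, cut_height = 0)
  expect_length(out0$removed, 0)
  # constant samples give a degenerate distance
  cst <- matrix(1, 60, 6, dimnames = list(rownames(expr), paste0("s", 1:6)))
  annot3 <- data.frame(sample_id = colnames(cst),
                       subtype = rep(c("A", "B"), each = 3))
  expect_error(remove_outliers(cst, annot3, n_var = 60), "degenerate")
})

test_that("moderated t agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(13)
  sds <- sqrt(rchisq(400, 4) / 4)
  m <- matrix(rnorm(400 * 16, sd = rep(sds, 16)), 400, 16,
              dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:16)))
  m[1:20, 1:8] <- m[1:20, 1:8] + 1.5
  de <- moderated_t_de(m, paste0("s", 1:8), paste0("s", 9:16))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(1, 0), each = 8))))
  expect_equal(de$fit$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(de$fit$s0_sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(de$table$t_mod, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(de$table$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
  # posterior variances sit between the prior and the sample variance
  s2 <- de$fit$s_tilde_sq
  lo <- pmin(fit$sigma^2, fit$s2.prior); hi <- pmax(fit$sigma^2, fit$s2.prior)
  expect_true(all(s2 >= lo - 1e-12 & s2 <= hi + 1e-12))
})

test_that("moderated t handles degenerate rows and identical means", {
  m <- sim_two_group(50, 10, 10, seed = 14)
  m["g0001", ] <- 5  # constant row
  de <- moderated_t_de(m, colnames(m)[1:10], colnames(m)[11:20])
  row <- de$table[de$table$gene == "g0001", ]
  expect_equal(row$t_mod, 0)
  expect_equal(row$p, 1)
  # matched group means at large n: small t, large p
  big <- sim_two_group(200, 50, 50, seed = 15)
  de2 <- moderated_t_de(big, colnames(big)[1:50], colnames(big)[51:100])
  expect_lt(median(abs(de2$table$t_mod)), 1)
  expect_gt(median(de2$table$p), 0.3)
})

test_that("prior variance recovery on homoscedastic data is within 20%", {
  true_var <- 0.64
  m <- sim_two_group(5000, 10, 10, sd = sqrt(true_var), seed = 16)
  de <- moderated_t_de(m, colnames(m)[1:10], colnames(m)[11:20])
  expect_lt(abs(de$fit$s0_sq - true_var) / true_var, 0.2)
})

test_that("BH adjustment follows the step-up rule and rejects bad input", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NaN)), "finite")
  expect_error(bh_fdr(c(0.1, NA)), "finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  # monotone non-decreasing in sorted-p order; permutation invariant
  set.seed(17)
  p <- runif(200)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample.int(200)
  expect_equal(bh_fdr(p[perm]), adj[perm])
})

test_that("DE gene sets use strict thresholds on both axes", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(2.0, 2.5, -2.5, 3.0),
                   fdr = c(0.01, 0.04, 0.04, 0.05))
  expect_identical(de_gene_set(de), c("b", "c"))
})

test_that("subtype overlap curves and Venn regions match enumeration", {
  s <- sprintf("g%03d", 1:40)
  same <- list(A = s[1:20], B = s[1:20], C = s[1:20], D = s[1:20])
  ov <- subtype_overlap(same)
  expect_equal(ov$pairwise$overlap, rep(1:20, 6))
  expect_equal(unname(ov$venn[["A&B&C&D"]]), 20)
  disj <- list(A = s[1:10], B = s[11:20], C = s[21:30], D = s[31:40])
  expect_true(all(subtype_overlap(disj)$pairwise$overlap == 0))
  # random sets vs a brute-force region count
  set.seed(18)
  u <- sprintf("u%04d", 1:1000)
  sets <- lapply(1:4, function(i) sample(u, 100))
  names(sets) <- c("A", "B", "C", "D")
  venn <- subtype_overlap(sets)$venn
  for (reg in names(venn)) {
    inn <- strsplit(reg, "&", fixed = TRUE)[[1]]
    outt <- setdiff(names(sets), inn)
    want <- sum(vapply(unique(unlist(sets)), function(g)
      all(vapply(inn, function(s2) g %in% sets[[s2]], logical(1))) &&
        !any(vapply(outt, function(s2) g %in% sets[[s2]], logical(1))),
      logical(1)))
    expect_equal(unname(venn[[reg]]), want, info = reg)
    # brute-force top-k overlap for one pair
  }
  ab <- subtype_overlap(sets)$pairwise
  ab <- ab[ab$set_a == "A" & ab$set_b == "B", ]
  for (k in c(1, 7, 50, 100))
    expect_equal(ab$overlap[ab$k == k],
                 length(intersect(sets$A[1:k], sets$B[1:k])))
})

test_that("signatures take the extreme moderated-t tails, disjointly", {
  set.seed(19)
  de <- data.frame(gene = sprintf("g%03d", 1:600),
                   t_mod = c(rnorm(300, 4), rnorm(300, -4)))
  sig <- build_signature(de, 250)
  expect_length(sig$up, 250)
  expect_length(intersect(sig$up, sig$down), 0)
  expect_true(min(de$t_mod[match(sig$up, de$gene)]) >=
                max(de$t_mod[match(setdiff(de$gene[de$t_mod > 0], sig$up),
                                   de$gene)]) - 1e-12)
  sig1 <- build_signature(de, 1)
  expect_identical(sig1$up, de$gene[which.max(de$t_mod)])
  expect_identical(sig1$down, de$gene[which.min(de$t_mod)])
  # exactly 250 positive / 250 negative: the full split
  de2 <- data.frame(gene = sprintf("h%03d", 1:500),
                    t_mod = c(seq(0.1, 25, length.out = 250),
                              -seq(0.1, 25, length.out = 250)))
  sig2 <- build_signature(de2, 250)
  expect_setequal(sig2$up, de2$gene[de2$t_mod > 0])
  expect_setequal(sig2$down, de2$gene[de2$t_mod < 0])
  expect_error(build_signature(de2, 251), "not enough")
  # planted extremes always make the signature
  de$t_mod[1:5] <- 50; de$t_mod[6:10] <- -50
  sig3 <- build_signature(de, 20)
  expect_true(all(de$gene[1:5] %in% sig3$up))
  expect_true(all(de$gene[6:10] %in% sig3$down))
})
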