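#' Most-variable genes
#'
#' Genes with the largest variance across samples, in descending order of
#' variance; ties broken lexicographically by gene id for determinism.
#'
#' @param expr gene x sample numeric matrix (log2 scale).
#' @param n number of genes to return.
#' @return character vector of length \code{n}.
#' @export
select_most_variable <- function(expr, n) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(expr)) stop("n exceeds the number of genes")
  v <- row_vars(expr)
  rownames(expr)[order(-v, rownames(expr))][seq_len(n)]
}

row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Drop samples falling outside their group's majority cluster
#'
#' Average-linkage hierarchical clustering on 1 - Pearson correlation over
#' the most-variable genes. The tree is cut either at \code{cut_height} or
#' (default) into as many clusters as there are annotated groups. Within each
#' group, samples outside the cluster(s) holding the group's plurality are
#' removed; plurality ties keep all tied clusters, so a cut into singletons
#' removes nothing.
#'
#' @param expr gene x sample matrix.
#' @param annot data frame with \code{sample_id} and \code{subtype} covering
#'   every column of \code{expr}.
#' @param n_var number of most-variable genes for the distance (capped at the
#'   gene count).
#' @param cut_height optional dendrogram cut height; when \code{NULL} the tree
#'   is cut into \code{length(unique(annot$subtype))} clusters.
#' @return list with \code{retained} and \code{removed} sample id vectors and
#'   the \code{cluster} assignment.
#' @export
remove_outliers <- function(expr, annot, n_var = 1000, cut_height = NULL) {
  stopifnot(all(colnames(expr) %in% annot$sample_id))
  tab <- table(annot$subtype[annot$sample_id %in% colnames(expr)])
  if (any(tab < 3)) stop("need at least 3 samples per group")
  genes <- select_most_variable(expr, min(n_var, nrow(expr)))
  cm <- suppressWarnings(stats::cor(expr[genes, , drop = FALSE]))
  if (any(!is.finite(cm)))
    stop("degenerate distance: constant sample(s) over the selected genes")
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  cl <- if (is.null(cut_height)) {
    stats::cutree(hc, k = length(unique(annot$subtype)))
  } else {
    stats::cutree(hc, h = cut_height)
  }
  keep <- character(0)
  for (st in unique(annot$subtype)) {
    ids <- intersect(annot$sample_id[annot$subtype == st], colnames(expr))
    counts <- table(cl[ids])
    majority <- names(counts)[counts == max(counts)]
    keep <- c(keep, ids[as.character(cl[ids]) %in% majority])
  }
  removed <- setdiff(colnames(expr), keep)
  if (length(removed))
    message(sprintf("remove_outliers: dropped %d sample(s)", length(removed)))
  list(retained = intersect(colnames(expr), keep), removed = removed,
       cluster = cl)
}

# Newton iteration for the inverse of the trigamma function, used by the
# empirical-Bayes moment estimator of the prior degrees of freedom.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Two-group differential expression with empirical-Bayes variance shrinkage
#'
#' Fits, per gene, the two-group model logFC = mean(tumor) - mean(normal)
#' with pooled residual variance s^2 on d = n1 + n2 - 2 degrees of freedom,
#' then shrinks the variances toward a prior s0^2 estimated together with the
#' prior degrees of freedom d0 by moment matching on the log sample
#' variances (the marginal of log s^2 under the scaled-F model). The
#' moderated t is logFC / (s_tilde * sqrt(1/n1 + 1/n2)) on d + d0 degrees of
#' freedom; FDR by Benjamini-Hochberg.
#'
#' Genes that are constant across all samples get t = 0 and p = 1.
#'
#' @param expr gene x sample matrix.
#' @param tumor_ids,normal_ids column ids of the two groups (>= 2 each).
#' @return list with \code{table} (data frame: gene, logFC, t_mod, p, fdr)
#'   and \code{fit} (d0, s0_sq, df_residual, s_tilde_sq).
#' @export
moderated_t_de <- function(expr, tumor_ids, normal_ids) {
  stopifnot(length(tumor_ids) >= 2, length(normal_ids) >= 2,
            all(c(tumor_ids, normal_ids) %in% colnames(expr)))
  n1 <- length(tumor_ids); n2 <- length(normal_ids)
  d <- n1 + n2 - 2
  if (d <= 0) stop("zero residual degrees of freedom")
  x1 <- expr[, tumor_ids, drop = FALSE]
  x2 <- expr[, normal_ids, drop = FALSE]
  logfc <- rowMeans(x1) - rowMeans(x2)
  s2 <- (rowSums((x1 - rowMeans(x1))^2) +
           rowSums((x2 - rowMeans(x2))^2)) / d

  ok <- s2 > 0
  if (!any(ok)) {
    d0 <- Inf; s0_sq <- NA_real_
  } else {
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  }
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  if (is.na(s0_sq)) s_tilde_sq <- rep(0, length(s2))

  se <- sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, logfc / se, 0)
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[se == 0 & logfc == 0] <- 1
  tab <- data.frame(gene = rownames(expr), logFC = logfc, t_mod = t_mod,
                    p = p, fdr = bh_fdr(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  list(table = tab,
       fit = list(d0 = d0, s0_sq = s0_sq, df_residual = d,
                  s_tilde_sq = s_tilde_sq))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param pvalues numeric vector in [0, 1]; NA/NaN rejected.
#' @return adjusted values in [0, 1].
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)))
    stop("p-values must be finite (no NA/NaN)")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differentially expressed gene set at strict thresholds
#'
#' @param de DE table from [moderated_t_de()] (\code{$table}).
#' @param logfc_cut,fdr_cut positive thresholds; a gene is selected when
#'   |logFC| > \code{logfc_cut} (strict) and fdr < \code{fdr_cut} (strict).
#' @return character vector of selected genes.
#' @export
de_gene_set <- function(de, logfc_cut = 2, fdr_cut = 0.05) {
  stopifnot(logfc_cut > 0, fdr_cut > 0)
  de$gene[abs(de$logFC) > logfc_cut & de$fdr < fdr_cut]
}

#' Pairwise top-k overlap curves and four-way Venn counts for DE sets
#'
#' @param ranked_sets named list of gene vectors, each ranked by |moderated t|
#'   descending.
#' @return list with \code{pairwise} (data frame: set_a, set_b, k, overlap)
#'   and, when four sets are given, \code{venn} (named counts for all 15
#'   non-empty membership regions, names like "LumA&TNBC").
#' @export
subtype_overlap <- function(ranked_sets) {
  stopifnot(is.list(ranked_sets), length(ranked_sets) >= 2,
            !is.null(names(ranked_sets)))
  nm <- names(ranked_sets)
  pairs <- utils::combn(nm, 2)
  out <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- ranked_sets[[pairs[1, i]]]; b <- ranked_sets[[pairs[2, i]]]
    kmax <- min(length(a), length(b))
    pos_a <- match(b[seq_len(kmax)], a)   # rank in a of b's top-k genes
    pos_b <- match(a[seq_len(kmax)], b)
    # a gene in both lists at ranks (i, j) counts toward every k >= max(i, j)
    joint <- pmax(seq_len(kmax), pos_b[seq_len(kmax)])
    joint <- joint[!is.na(joint) & joint <= kmax]
    counts <- cumsum(tabulate(joint, nbins = kmax))
    out[[i]] <- data.frame(set_a = pairs[1, i], set_b = pairs[2, i],
                           k = seq_len(kmax), overlap = counts,
                           stringsAsFactors = FALSE)
  }
  res <- list(pairwise = do.call(rbind, out))
  if (length(ranked_sets) == 4) {
    all_genes <- unique(unlist(ranked_sets))
    member <- sapply(ranked_sets, function(s) all_genes %in% s)
    code <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
    regions <- unlist(lapply(1:4, function(k)
      apply(utils::combn(nm, k), 2, paste, collapse = "&")))
    venn <- stats::setNames(integer(length(regions)), regions)
    tab <- table(code)
    venn[names(tab)] <- as.integer(tab)
    res$venn <- venn
  }
  res
}

#' Build a two-sided query signature from a DE result
#'
#' The up set is the top \code{n_per_side} genes by moderated t descending,
#' the down set the top \code{n_per_side} ascending; ties broken by gene id.
#'
#' @param de DE table from [moderated_t_de()] (\code{$table}).
#' @param n_per_side genes per direction (default 250).
#' @return object of class \code{kd_signature}: list with ordered \code{up}
#'   and \code{down} gene vectors.
#' @export
build_signature <- function(de, n_per_side = 250) {
  stopifnot(n_per_side >= 1)
  if (sum(de$t_mod > 0) < n_per_side || sum(de$t_mod < 0) < n_per_side)
    stop("not enough genes with positive and negative moderated t")
  up <- de$gene[order(-de$t_mod, de$gene)][seq_len(n_per_side)]
  down <- de$gene[order(de$t_mod, de$gene)][seq_len(n_per_side)]
  structure(list(up = up, down = down), class = "kd_signature")
}

#' @export
print.kd_signature <- function(x, ...) {
  cat(sprintf("query signature: %d up / %d down genes\n",
              length(x$up), length(x$down)))
  invisible(x)
}
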