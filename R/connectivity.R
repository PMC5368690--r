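#' Collapse raw knockdown profiles into one log-fold-change profile per gene
#'
#' Replicate profiles are averaged per reagent, the mean untreated control
#' profile is subtracted to give a log fold change, and for each knocked-down
#' gene the reagent with the lowest post-knockdown expression of its own
#' target (the best-silencing reagent) is retained.
#'
#' @param profiles gene x column raw profile matrix (e.g. from
#'   [gen_reference_db()] or [read_gct()]).
#' @param reagent_map data frame with columns \code{column_id},
#'   \code{reagent_id}, \code{knocked_gene}, \code{is_control} covering every
#'   column of \code{profiles}.
#' @return list with \code{lfc} (gene x knocked-gene log-fold-change matrix)
#'   and \code{selected} (data frame: knocked_gene, reagent_id, self_expr).
#' @export
process_reference <- function(profiles, reagent_map) {
  stopifnot(all(c("column_id", "reagent_id", "knocked_gene", "is_control")
                %in% names(reagent_map)),
            all(colnames(profiles) %in% reagent_map$column_id))
  rm_ <- reagent_map[match(colnames(profiles), reagent_map$column_id), ]
  ctrl_cols <- rm_$column_id[rm_$is_control]
  if (!length(ctrl_cols)) stop("at least one control profile is required")
  ctrl_mean <- rowMeans(profiles[, ctrl_cols, drop = FALSE])

  kd <- rm_[!rm_$is_control, ]
  missing <- setdiff(unique(kd$knocked_gene), rownames(profiles))
  if (length(missing)) {
    warning(sprintf(
      "%d knocked gene(s) absent from the measured universe; skipped: %s",
      length(missing), paste(utils::head(missing, 5), collapse = ", ")))
    kd <- kd[!kd$knocked_gene %in% missing, ]
  }
  reagents <- unique(kd[, c("reagent_id", "knocked_gene")])
  merged <- vapply(reagents$reagent_id, function(rid) {
    rowMeans(profiles[, kd$column_id[kd$reagent_id == rid], drop = FALSE])
  }, numeric(nrow(profiles)))
  self_expr <- merged[cbind(match(reagents$knocked_gene, rownames(profiles)),
                            seq_len(nrow(reagents)))]

  genes <- unique(reagents$knocked_gene)
  sel_idx <- vapply(genes, function(g) {
    i <- which(reagents$knocked_gene == g)
    # argmin self-expression, ties broken by reagent id
    i[order(self_expr[i], reagents$reagent_id[i])][1]
  }, integer(1))
  lfc <- merged[, sel_idx, drop = FALSE] - ctrl_mean
  colnames(lfc) <- genes
  list(lfc = lfc,
       selected = data.frame(knocked_gene = genes,
                             reagent_id = reagents$reagent_id[sel_idx],
                             self_expr = self_expr[sel_idx],
                             stringsAsFactors = FALSE, row.names = NULL))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Ranks the profile by value descending (ties broken by gene id), then walks
#' the ranked list accumulating |r_j|^p / N_R at genes in the set (N_R being
#' the sum of |r_j|^p over set members) and -1/(N - N_H) elsewhere. The
#' enrichment score is the running-sum value of maximal absolute deviation
#' from zero, signed. With \code{p = 0} this is the classical unweighted KS
#' enrichment statistic.
#'
#' @param values named numeric profile over the gene universe.
#' @param gene_set character vector, a subset of \code{names(values)}.
#' @param p weight exponent >= 0 (default 1).
#' @return the enrichment score, in [-1, 1].
#' @export
weighted_es <- function(values, gene_set, p = 1) {
  stopifnot(p >= 0, !is.null(names(values)))
  if (!length(gene_set)) stop("empty gene set")
  if (length(bad <- setdiff(gene_set, names(values))))
    stop(sprintf("gene set members missing from profile: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  n <- length(values)
  n_h <- length(unique(gene_set))
  if (n_h >= n) stop("gene set must be a proper subset of the profile")
  ord <- order(-values, names(values))
  v <- values[ord]
  hit <- names(v) %in% gene_set
  w <- abs(v)^p
  n_r <- sum(w[hit])
  if (n_r == 0) {
    if (p > 0) stop("all hit values are zero: weighted score undefined")
    n_r <- n_h
  }
  step <- ifelse(hit, w / n_r, -1 / (n - n_h))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Combine up- and down-set enrichment scores (connectivity-map convention)
#'
#' Zero when both scores share a sign (the profile does not move the two
#' signature halves in opposite directions), otherwise half their difference.
#'
#' @param es_up,es_down enrichment scores in [-1, 1].
#' @return combined score in [-1, 1].
#' @export
combined_es <- function(es_up, es_down) {
  stopifnot(abs(es_up) <= 1, abs(es_down) <= 1)
  if (es_up != 0 && es_down != 0 && sign(es_up) == sign(es_down)) return(0)
  (es_up - es_down) / 2
}

#' Normalize combined enrichment scores to connectivity scores in [-1, 1]
#'
#' Positive scores are divided by the maximum positive score, negative scores
#' by the absolute minimum, so the strongest reverser attains exactly -1.
#'
#' @param es numeric vector of combined enrichment scores.
#' @return connectivity scores, same length and order.
#' @export
normalize_cs <- function(es) {
  if (!length(es)) stop("no enrichment scores supplied")
  if (all(es == 0)) {
    warning("all enrichment scores are zero")
    return(es)
  }
  pos_max <- if (any(es > 0)) max(es[es > 0]) else NA_real_
  neg_min <- if (any(es < 0)) min(es[es < 0]) else NA_real_
  cs <- numeric(length(es))
  cs[es > 0] <- es[es > 0] / pos_max
  cs[es < 0] <- es[es < 0] / abs(neg_min)
  cs
}

#' Score every reference profile against a two-sided query signature
#'
#' @param lfc gene x knocked-gene log-fold-change matrix from
#'   [process_reference()].
#' @param sig a \code{kd_signature} (or list with \code{up}, \code{down}).
#' @param p weight exponent (default 1).
#' @return data frame (one row per knocked gene): knocked_gene, es_up,
#'   es_down, es, cs.
#' @export
query_signature <- function(lfc, sig, p = 1) {
  stopifnot(!is.null(colnames(lfc)), !is.null(rownames(lfc)))
  res <- data.frame(knocked_gene = colnames(lfc),
                    es_up = NA_real_, es_down = NA_real_, es = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(lfc))) {
    v <- lfc[, i]
    names(v) <- rownames(lfc)
    res$es_up[i] <- weighted_es(v, sig$up, p)
    res$es_down[i] <- weighted_es(v, sig$down, p)
    res$es[i] <- combined_es(res$es_up[i], res$es_down[i])
  }
  res$cs <- normalize_cs(res$es)
  res
}

#' Candidate targets: knockdowns whose connectivity score reverses the query
#'
#' @param results data frame from [query_signature()].
#' @param threshold connectivity-score cutoff in (-1, 0); genes with
#'   cs strictly below it are selected (default -0.7).
#' @return data frame of selected rows, sorted by cs ascending.
#' @export
select_candidates <- function(results, threshold = -0.7) {
  stopifnot(threshold > -1, threshold < 0)
  out <- results[results$cs < threshold, , drop = FALSE]
  out[order(out$cs, out$knocked_gene), , drop = FALSE]
}
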