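#' Offset raw hgHeatmap-scale methylation values to beta values
#'
#' Raw values in [-0.5, 0.5] are shifted by +0.5 and clipped to
#' [eps, 1 - eps] so the logit (M-value) transform stays finite.
#'
#' @param raw numeric matrix (or vector) with values in [-0.5, 0.5].
#' @param eps clipping margin (default 1e-6).
#' @return beta values strictly inside (0, 1).
#' @export
offset_beta <- function(raw, eps = 1e-6) {
  if (any(raw < -0.5 | raw > 0.5))
    stop("raw methylation values must lie in [-0.5, 0.5]")
  beta <- raw + 0.5
  beta[beta < eps] <- eps
  beta[beta > 1 - eps] <- 1 - eps
  beta
}

#' Beta-value to M-value (base-2 logit) and back
#'
#' M = log2(beta / (1 - beta)); the inverse is beta = 2^M / (1 + 2^M).
#'
#' @param beta values strictly in (0, 1).
#' @return M values.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) stop("beta values must lie in (0, 1)")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m M values.
#' @export
m_to_beta <- function(m) {
  b <- 2^m / (1 + 2^m)
  b[is.infinite(m) & m > 0] <- 1
  b
}

#' Call differentially methylated positions (DMPs)
#'
#' Moderated-t differential testing on the M-value scale per probe, with the
#' effect size reported as the tumor-minus-normal difference of group mean
#' beta values. A probe is emitted when fdr < \code{fdr_cut} (strict) and
#' |delta_beta| >= \code{delta_cut}; direction is hypo when tumor
#' methylation is lower.
#'
#' @param beta probe x sample beta-value matrix, values in (0, 1).
#' @param tumor_ids,normal_ids column ids of the two groups (>= 2 each).
#' @param probe_map optional data frame (probe_id, gene) used to attach gene
#'   symbols.
#' @param fdr_cut,delta_cut thresholds (defaults 0.05 and 0.2).
#' @return data frame: probe, gene (NA if unmapped), delta_beta, fdr,
#'   direction.
#' @export
call_dmps <- function(beta, tumor_ids, normal_ids, probe_map = NULL,
                      fdr_cut = 0.05, delta_cut = 0.2) {
  m <- beta_to_m(beta)
  de <- moderated_t_de(m, tumor_ids, normal_ids)
  delta <- rowMeans(beta[, tumor_ids, drop = FALSE]) -
    rowMeans(beta[, normal_ids, drop = FALSE])
  keep <- de$table$fdr < fdr_cut & abs(delta) >= delta_cut
  out <- data.frame(probe = de$table$gene[keep],
                    delta_beta = delta[keep],
                    fdr = de$table$fdr[keep],
                    direction = ifelse(delta[keep] < 0, "hypo", "hyper"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$gene <- if (!is.null(probe_map)) {
    probe_map$gene[match(out$probe, probe_map$probe_id)]
  } else rep(NA_character_, nrow(out))
  out[, c("probe", "gene", "delta_beta", "fdr", "direction")]
}

#' Collapse probe-level DMPs to per-gene hypo/hyper flags
#'
#' A gene is flagged hypomethylated (hypermethylated) when at least one of
#' its probes is a hypo (hyper) DMP; both flags can coexist. Probes without a
#' gene mapping are dropped with a logged count.
#'
#' @param dmps data frame from [call_dmps()].
#' @param probe_map data frame (probe_id, gene); used to (re)map probes.
#' @return data frame: gene, hypo, hyper.
#' @export
gene_level_methylation <- function(dmps, probe_map) {
  gene <- probe_map$gene[match(dmps$probe, probe_map$probe_id)]
  unmapped <- is.na(gene)
  if (any(unmapped))
    message(sprintf("gene_level_methylation: dropped %d unmapped probe(s)",
                    sum(unmapped)))
  dmps <- dmps[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  genes <- sort(unique(gene))
  data.frame(
    gene = genes,
    hypo = vapply(genes, function(g)
      any(dmps$direction[gene == g] == "hypo"), logical(1)),
    hyper = vapply(genes, function(g)
      any(dmps$direction[gene == g] == "hyper"), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
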