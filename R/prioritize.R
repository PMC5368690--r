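#' Flag significantly up- and down-regulated genes
#'
#' Up: logFC > \code{logfc_cut} and fdr < \code{fdr_cut} (both strict);
#' down symmetric with logFC < -\code{logfc_cut}; everything else is
#' "intermediate".
#'
#' @param de DE table from [moderated_t_de()] (\code{$table}).
#' @param logfc_cut,fdr_cut thresholds (defaults 1 and 0.05).
#' @return data frame: gene, logFC, fdr, status.
#' @export
flag_upregulated <- function(de, logfc_cut = 1, fdr_cut = 0.05) {
  status <- rep("intermediate", nrow(de))
  status[de$logFC > logfc_cut & de$fdr < fdr_cut] <- "up"
  status[de$logFC < -logfc_cut & de$fdr < fdr_cut] <- "down"
  data.frame(gene = de$gene, logFC = de$logFC, fdr = de$fdr, status = status,
             stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing at least \code{k} successes when drawing
#' \code{n} items without replacement from a population of \code{N} items
#' containing \code{K} successes.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @param k observed successes.
#' @return the upper-tail probability.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0,
            K <= N, n <= N, k <= min(n, K))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assemble the per-gene, per-subtype filter ledger
#'
#' Combines the connectivity, expression, survival, methylation and
#' annotation filters into one assessment row per gene. A filter that was
#' not computed (argument \code{NULL}) is recorded as \code{NA} ("not
#' evaluated"), never silently \code{FALSE}; the final-target verdict is
#' \code{NA} whenever a required filter is missing. The verdict itself is
#' the conjunction candidate & up-regulated & hypomethylated & poor-survival.
#'
#' @param connectivity data frame from [query_signature()] (all scored
#'   knockdowns; candidacy is cs < \code{cs_cut}).
#' @param up_flags data frame from [flag_upregulated()] for the subtype.
#' @param survival_genes character vector of poor-survival genes, or NULL.
#' @param meth_flags data frame from [gene_level_methylation()], or NULL.
#' @param census data frame from [annotate_census()], or NULL.
#' @param drugs data frame from [annotate_drugs()], or NULL.
#' @param subtype subtype label stored on every row.
#' @param cs_cut candidate threshold (default -0.7, strict <).
#' @return data frame of class \code{kd_assessment}: gene, subtype, cs,
#'   is_candidate, logFC, fdr, is_up, is_down, poor_survival, hypo, hyper,
#'   census, census_breast, n_drugs, final_target.
#' @export
assess_genes <- function(connectivity, up_flags, survival_genes = NULL,
                         meth_flags = NULL, census = NULL, drugs = NULL,
                         subtype = NA_character_, cs_cut = -0.7) {
  genes <- connectivity$knocked_gene
  out <- data.frame(gene = genes, subtype = subtype,
                    cs = connectivity$cs,
                    is_candidate = connectivity$cs < cs_cut,
                    stringsAsFactors = FALSE)
  i <- match(genes, up_flags$gene)
  out$logFC <- up_flags$logFC[i]
  out$fdr <- up_flags$fdr[i]
  out$is_up <- up_flags$status[i] == "up"
  out$is_down <- up_flags$status[i] == "down"
  out$poor_survival <- if (is.null(survival_genes)) NA else
    genes %in% survival_genes
  if (is.null(meth_flags)) {
    out$hypo <- NA; out$hyper <- NA
  } else {
    j <- match(genes, meth_flags$gene)
    out$hypo <- !is.na(j) & meth_flags$hypo[j]
    out$hyper <- !is.na(j) & meth_flags$hyper[j]
  }
  out$census <- if (is.null(census)) NA else
    census$census[match(genes, census$gene)]
  out$census_breast <- if (is.null(census)) NA else
    census$census_breast[match(genes, census$gene)]
  out$n_drugs <- if (is.null(drugs)) NA_integer_ else
    drugs$n_drugs[match(genes, drugs$gene)]
  out$final_target <- out$is_candidate & out$is_up & out$hypo &
    out$poor_survival
  class(out) <- c("kd_assessment", class(out))
  out
}

#' Hypergeometric enrichment of filter intersections
#'
#' Within the candidate set (the population, size N), tests whether the
#' high-|CS| genes are enriched in the poor-survival set, and whether the
#' hypomethylated-and-up-regulated genes of each subtype are enriched among
#' the high-|CS| genes and among the poor-survival genes.
#'
#' @param assessments named list of \code{kd_assessment} data frames, one per
#'   subtype (candidate/poor-survival columns must agree across subtypes).
#' @param high_cs_cut absolute connectivity score above which a candidate
#'   counts as a high-scoring reverser (default 0.8, strict >).
#' @return data frame: test, subtype, N, K, n, k, p.
#' @export
enrichment_report <- function(assessments, high_cs_cut = 0.8) {
  a1 <- assessments[[1]]
  cand <- a1$gene[a1$is_candidate]
  high <- a1$gene[a1$is_candidate & abs(a1$cs) > high_cs_cut]
  poor <- a1$gene[a1$is_candidate & a1$poor_survival %in% TRUE]
  rows <- list()
  add <- function(test, subtype, set_k, set_n) {
    k <- length(intersect(set_k, set_n))
    rows[[length(rows) + 1]] <<- data.frame(
      test = test, subtype = subtype, N = length(cand), K = length(set_k),
      n = length(set_n), k = k,
      p = hypergeom_upper(length(cand), length(set_k), length(set_n), k),
      stringsAsFactors = FALSE)
  }
  add("poor_survival_vs_high_cs", "all", poor, high)
  for (st in names(assessments)) {
    a <- assessments[[st]]
    hypo_up <- a$gene[a$is_candidate & a$hypo %in% TRUE & a$is_up %in% TRUE]
    add("hypo_up_vs_high_cs", st, hypo_up, high)
    add("hypo_up_vs_poor_survival", st, hypo_up, poor)
  }
  do.call(rbind, rows)
}

#' Annotate genes against a cancer-gene census table
#'
#' @param genes character vector.
#' @param census_table data frame with columns \code{gene} and logical
#'   \code{breast} (breast-cancer specific membership).
#' @return data frame: gene, census, census_breast; overlap counts are
#'   reported via \code{message()}.
#' @export
annotate_census <- function(genes, census_table) {
  stopifnot(all(c("gene", "breast") %in% names(census_table)))
  res <- data.frame(gene = genes,
                    census = genes %in% census_table$gene,
                    census_breast = genes %in%
                      census_table$gene[census_table$breast],
                    stringsAsFactors = FALSE)
  message(sprintf("annotate_census: %d/%d in census, %d breast-specific",
                  sum(res$census), length(genes), sum(res$census_breast)))
  res
}

#' Count approved drugs (and anti-neoplastics) targeting each gene
#'
#' @param genes character vector.
#' @param drug_table data frame with columns drug_id, drug_name, target_gene,
#'   approved_flag, atc_code.
#' @return data frame: gene, n_drugs (distinct approved drugs),
#'   n_antineoplastic (ATC class L01), novel (no approved drug).
#' @export
annotate_drugs <- function(genes, drug_table) {
  stopifnot(all(c("drug_id", "drug_name", "target_gene", "approved_flag",
                  "atc_code") %in% names(drug_table)))
  appr <- drug_table[as.logical(drug_table$approved_flag), , drop = FALSE]
  n_drugs <- vapply(genes, function(g)
    length(unique(appr$drug_id[appr$target_gene == g])), integer(1))
  n_l01 <- vapply(genes, function(g)
    length(unique(appr$drug_id[appr$target_gene == g &
                                 startsWith(appr$atc_code, "L01")])),
    integer(1))
  data.frame(gene = genes, n_drugs = n_drugs, n_antineoplastic = n_l01,
             novel = n_drugs == 0, stringsAsFactors = FALSE, row.names = NULL)
}

#' Final per-subtype target table
#'
#' One row per gene that is a final target in at least one subtype, with the
#' connectivity score and log fold change printed per subtype ("-" where the
#' gene does not meet the final-target thresholds in that subtype), plus the
#' subtype-specificity class and approved-drug count.
#'
#' @param assessments named list of \code{kd_assessment} data frames, one per
#'   subtype.
#' @return data frame: gene, one CS/logFC character column pair per subtype,
#'   n_subtypes, specificity ("common" = all subtypes, "specific" = one,
#'   "shared" otherwise), n_drugs.
#' @export
final_table <- function(assessments) {
  stopifnot(length(assessments) >= 1, !is.null(names(assessments)))
  finals <- lapply(assessments, function(a) a$gene[a$final_target %in% TRUE])
  genes <- sort(unique(unlist(finals)))
  if (!length(genes)) {
    return(data.frame(gene = character(0)))
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (st in names(assessments)) {
    a <- assessments[[st]]
    i <- match(genes, a$gene)
    hit <- genes %in% finals[[st]]
    out[[paste0("CS_", st)]] <- ifelse(hit, sprintf("%.2f", a$cs[i]), "-")
    out[[paste0("logFC_", st)]] <- ifelse(hit, sprintf("%.2f", a$logFC[i]),
                                          "-")
  }
  n_sub <- rowSums(sapply(finals, function(f) genes %in% f))
  out$n_subtypes <- n_sub
  out$specificity <- ifelse(n_sub == length(assessments), "common",
                            ifelse(n_sub == 1, "specific", "shared"))
  nd <- assessments[[1]]$n_drugs[match(genes, assessments[[1]]$gene)]
  out$n_drugs <- nd
  out
}
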