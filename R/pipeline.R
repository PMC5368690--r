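#' Pipeline run configuration
#'
#' Exactly one of a synthetic-data configuration or a set of input file
#' paths must be supplied. All pipeline thresholds are surfaced here with
#' the defaults used throughout: candidate CS cut -0.7, high-|CS| cut 0.8,
#' DE-set |logFC| cut 2, up-regulation logFC cut 1, FDR cut 0.05,
#' delta-beta cut 0.2, survival p cut 0.05, 250 signature genes per side,
#' 1000 most-variable genes for outlier removal.
#'
#' @param synthetic a \code{sim_config}, or NULL when reading files.
#' @param paths named list of input paths (expression, annotation,
#'   reference_gct, reagent_map, survival, methylation, probe_map, census,
#'   drug_table); individual entries may be NULL, in which case the
#'   corresponding filter is recorded as "not evaluated".
#' @param signature_subtype subtype whose tumor-vs-normal contrast defines
#'   the query signature (default "LumA", matching an MCF7-like reference).
#' @param cs_cut,high_cs_cut,de_logfc_cut,up_logfc_cut,fdr_cut,delta_beta_cut,surv_p_cut
#'   thresholds as described above.
#' @param n_sig signature genes per direction.
#' @param n_var most-variable genes used in outlier removal.
#' @param gsea_p weight exponent of the enrichment statistic.
#' @param seed integer seed controlling synthetic generation.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(synthetic = NULL, paths = NULL,
                       signature_subtype = "LumA",
                       cs_cut = -0.7, high_cs_cut = 0.8,
                       de_logfc_cut = 2, up_logfc_cut = 1, fdr_cut = 0.05,
                       delta_beta_cut = 0.2, surv_p_cut = 0.05,
                       n_sig = 250, n_var = 1000, gsea_p = 1, seed = 1L) {
  if (is.null(synthetic) == is.null(paths))
    stop("supply exactly one of a synthetic config or input paths")
  stopifnot(cs_cut > -1, cs_cut < 0, high_cs_cut > 0, high_cs_cut < 1,
            de_logfc_cut > 0, up_logfc_cut > 0, fdr_cut > 0, fdr_cut < 1,
            delta_beta_cut > 0, surv_p_cut > 0, surv_p_cut < 1,
            n_sig >= 1, n_var >= 1, gsea_p >= 0)
  structure(list(synthetic = synthetic, paths = paths,
                 signature_subtype = signature_subtype, cs_cut = cs_cut,
                 high_cs_cut = high_cs_cut, de_logfc_cut = de_logfc_cut,
                 up_logfc_cut = up_logfc_cut, fdr_cut = fdr_cut,
                 delta_beta_cut = delta_beta_cut, surv_p_cut = surv_p_cut,
                 n_sig = n_sig, n_var = n_var, gsea_p = gsea_p,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a \code{synthetic}
#' block is forwarded to [sim_config()], a \code{paths} block taken as
#' input file paths.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(sim_config, y$synthetic) else NULL
  args <- y[setdiff(names(y), "synthetic")]
  do.call(run_config, c(list(synthetic = syn), args))
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sc <- cfg$synthetic
    ex <- gen_expression(sc)
    # signature must exist before reversal profiles can be planted, so the
    # synthetic route builds it from the signature subtype's DE up front
    annot <- ex$annot
    tum <- annot$sample_id[annot$subtype == cfg$signature_subtype]
    nor <- annot$sample_id[annot$subtype == "Normal"]
    de0 <- moderated_t_de(ex$expr, tum, nor)
    sig <- build_signature(de0$table,
                           min(cfg$n_sig, floor(nrow(ex$expr) / 4)))
    db <- gen_reference_db(sc, sig)
    sv <- gen_survival(sc, ex$expr, annot)
    mt <- gen_methylation(sc, annot)
    # bundled synthetic annotation fixtures (same gene universe)
    census <- utils::read.delim(
      system.file("extdata", "synthetic_cancer_census.tsv",
                  package = "kdscreen"), stringsAsFactors = FALSE)
    drugs <- utils::read.delim(
      system.file("extdata", "synthetic_drug_targets.tsv",
                  package = "kdscreen"), stringsAsFactors = FALSE)
    list(expr = ex$expr, annot = annot, profiles = db$profiles,
         reagent_map = db$reagent_map, survival = sv$survival,
         beta = mt$beta, probe_map = mt$probe_map,
         census = census, drugs = drugs, manifest = ex$manifest)
  } else {
    p <- cfg$paths
    need <- function(nm) if (is.null(p[[nm]])) NULL else p[[nm]]
    list(expr = read_matrix_tsv(p$expression),
         annot = read_annotation_tsv(p$annotation),
         profiles = read_gct(p$reference_gct),
         reagent_map = utils::read.delim(p$reagent_map,
                                         stringsAsFactors = FALSE),
         survival = if (is.null(need("survival"))) NULL else
           read_survival_tsv(p$survival),
         beta = if (is.null(need("methylation"))) NULL else
           read_matrix_tsv(p$methylation),
         probe_map = if (is.null(need("probe_map"))) NULL else
           read_probe_map_tsv(p$probe_map),
         census = if (is.null(need("census"))) NULL else
           utils::read.delim(p$census, stringsAsFactors = FALSE),
         drugs = if (is.null(need("drug_table"))) NULL else
           utils::read.delim(p$drug_table, stringsAsFactors = FALSE),
         manifest = NULL)
  }
}

#' Run the full target-discovery pipeline
#'
#' Executes, in order: gene-universe intersection with the reference
#' database, clustering-based outlier removal, per-subtype differential
#' expression, signature construction for the signature subtype, reference
#' processing, connectivity scoring, candidate selection, up-regulation
#' flags, the pooled survival screen, differential methylation, per-subtype
#' assessment with hypergeometric enrichment, census/drug annotation, and
#' the final target table. Every stage's output is written to
#' \code{out_dir} and a summary JSON records the counts at each filter.
#' When methylation (or survival) input is absent the affected filters are
#' recorded as not evaluated and the final-target stage is skipped.
#'
#' @param cfg a \code{run_config}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage outputs and the summary.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, fun) {
    message("stage: ", name)
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  inp <- stage("load_inputs", function() load_pipeline_inputs(cfg))
  summary <- list(seed = cfg$seed)

  # gene-universe intersection between expression and reference DB
  inp <- stage("gene_universe_intersection", function() {
    shared <- intersect(rownames(inp$expr), rownames(inp$profiles))
    if (length(shared) < 4) stop("expression/reference gene overlap too small")
    inp$expr <- inp$expr[shared, , drop = FALSE]
    inp$profiles <- inp$profiles[shared, , drop = FALSE]
    inp
  })
  summary$n_genes_shared <- nrow(inp$expr)

  retained <- stage("outlier_removal", function() {
    remove_outliers(inp$expr, inp$annot,
                    n_var = min(cfg$n_var, nrow(inp$expr)))$retained
  })
  summary$n_samples_retained <- length(retained)
  expr <- inp$expr[, retained, drop = FALSE]
  annot <- inp$annot[inp$annot$sample_id %in% retained, ]
  normal_ids <- annot$sample_id[annot$subtype == "Normal"]
  subtypes <- setdiff(unique(annot$subtype), "Normal")

  de <- stage("differential_expression", function() {
    out <- lapply(subtypes, function(st) {
      tum <- annot$sample_id[annot$subtype == st]
      moderated_t_de(expr, tum, normal_ids)
    })
    names(out) <- subtypes
    out
  })
  for (st in subtypes) {
    utils::write.table(de[[st]]$table,
                       file.path(out_dir, sprintf("de_%s.tsv", st)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary$n_de_genes <- lapply(de, function(d)
    length(de_gene_set(d$table, cfg$de_logfc_cut, cfg$fdr_cut)))

  sig <- stage("signature", function() {
    build_signature(de[[cfg$signature_subtype]]$table,
                    min(cfg$n_sig, floor(nrow(expr) / 4)))
  })
  utils::write.table(
    data.frame(direction = rep(c("up", "down"), each = length(sig$up)),
               gene = c(sig$up, sig$down)),
    file.path(out_dir, "signature.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  refdb <- stage("reference_processing", function() {
    process_reference(inp$profiles, inp$reagent_map)
  })
  conn <- stage("connectivity", function() {
    query_signature(refdb$lfc, sig, p = cfg$gsea_p)
  })
  utils::write.table(conn, file.path(out_dir, "connectivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- stage("candidate_selection", function() {
    select_candidates(conn, cfg$cs_cut)
  })
  summary$n_candidates <- nrow(cand)

  up_flags <- stage("up_regulation_flags", function() {
    out <- lapply(subtypes, function(st)
      flag_upregulated(de[[st]]$table, cfg$up_logfc_cut, cfg$fdr_cut))
    names(out) <- subtypes
    out
  })

  surv_screen <- if (is.null(inp$survival)) NULL else
    stage("survival_screen", function() {
      screen_survival_genes(expr, inp$survival, cand$knocked_gene,
                            p_cut = cfg$surv_p_cut)
    })
  summary$n_poor_survival <- if (is.null(surv_screen)) NA else
    length(surv_screen$genes)
  if (!is.null(surv_screen))
    utils::write.table(surv_screen$table,
                       file.path(out_dir, "survival_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  meth_flags <- if (is.null(inp$beta)) NULL else
    stage("methylation", function() {
      out <- lapply(subtypes, function(st) {
        tum <- intersect(annot$sample_id[annot$subtype == st],
                         colnames(inp$beta))
        nor <- intersect(normal_ids, colnames(inp$beta))
        dmps <- call_dmps(inp$beta, tum, nor, inp$probe_map,
                          fdr_cut = cfg$fdr_cut,
                          delta_cut = cfg$delta_beta_cut)
        gene_level_methylation(dmps, inp$probe_map)
      })
      names(out) <- subtypes
      out
    })

  census <- if (is.null(inp$census)) NULL else
    annotate_census(cand$knocked_gene, inp$census)
  drugs <- if (is.null(inp$drugs)) NULL else
    annotate_drugs(cand$knocked_gene, inp$drugs)

  assessments <- stage("assessment", function() {
    out <- lapply(subtypes, function(st)
      assess_genes(conn, up_flags[[st]],
                   survival_genes = if (is.null(surv_screen)) NULL else
                     surv_screen$genes,
                   meth_flags = meth_flags[[st]],
                   census = census, drugs = drugs,
                   subtype = st, cs_cut = cfg$cs_cut))
    names(out) <- subtypes
    out
  })
  for (st in subtypes)
    utils::write.table(assessments[[st]],
                       file.path(out_dir, sprintf("assessment_%s.tsv", st)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  enrich <- stage("enrichment", function() enrichment_report(
    assessments, cfg$high_cs_cut))
  utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (is.null(meth_flags) || is.null(surv_screen)) {
    message("final-target stage skipped: missing filter input; ",
            "partial assessment ledger emitted")
    final <- NULL
    summary$final_targets <- NA
  } else {
    final <- stage("final_table", function() final_table(assessments))
    utils::write.table(final, file.path(out_dir, "final_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$final_targets <- final$gene
    summary$n_final_per_subtype <- lapply(assessments, function(a)
      sum(a$final_target %in% TRUE))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(inputs = inp, de = de, signature = sig, refdb = refdb,
                 connectivity = conn, candidates = cand,
                 survival = surv_screen, methylation = meth_flags,
                 assessments = assessments, enrichment = enrich,
                 final = final, summary = summary))
}
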