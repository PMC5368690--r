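#' Simulation configuration for the knockdown-screen pipeline
#'
#' Bundles every knob of the synthetic-data generators: cohort sizes, the
#' knockdown reference layout, and the planted effects (differential
#' expression per subtype, signature-reversing knockdowns, survival hazard
#' multipliers, hypomethylated genes) that downstream recovery tests assert
#' against.
#'
#' @param n_genes number of genes in the universe.
#' @param n_tumor named integer vector of tumor sample counts per subtype
#'   (names from \code{LumA, LumB, HER2, TNBC}).
#' @param n_normal number of normal-tissue samples.
#' @param n_knockdowns number of genes knocked down in the reference database
#'   (planted reversal genes are always included).
#' @param n_reagents_per_gene shRNA reagents per knocked-down gene.
#' @param n_replicates replicate profiles per reagent (>= 2).
#' @param n_controls untreated control profiles.
#' @param planted_de named list (one element per subtype) of data frames with
#'   columns \code{gene} and \code{logfc} (log2 units): mean shifts applied to
#'   that subtype's tumor samples.
#' @param planted_reversal_genes genes whose knockdown profiles anti-correlate
#'   with the disease signature.
#' @param reversal_strength fraction in [0, 1] of signature genes flipped by a
#'   planted knockdown.
#' @param reversal_effect absolute log2 shift applied to flipped signature
#'   genes.
#' @param planted_hazard_genes data frame with columns \code{gene} and
#'   \code{hr}: samples above the median expression of \code{gene} have their
#'   death hazard multiplied by \code{hr}.
#' @param planted_hypo_genes data frame with columns \code{gene} and
#'   \code{delta_beta}: tumor-sample beta values on all probes of \code{gene}
#'   are lowered by \code{delta_beta}.
#' @param n_probes_per_gene methylation probes per gene.
#' @param noise_sd expression noise standard deviation (log2 units).
#' @param meth_noise_sd per-sample beta-value noise standard deviation.
#' @param censor_rate expected fraction of censored survival records under the
#'   null (independent exponential censoring).
#' @param baseline_hazard baseline death hazard per day.
#' @param seed integer RNG seed; all generators derive their streams from it.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_tumor = c(LumA = 30, LumB = 30, HER2 = 30, TNBC = 30),
                       n_normal = 30,
                       n_knockdowns = 100,
                       n_reagents_per_gene = 2,
                       n_replicates = 2,
                       n_controls = 10,
                       planted_de = list(),
                       planted_reversal_genes = character(),
                       reversal_strength = 0.8,
                       reversal_effect = 2,
                       planted_hazard_genes = NULL,
                       planted_hypo_genes = NULL,
                       n_probes_per_gene = 3,
                       noise_sd = 0.5,
                       meth_noise_sd = 0.05,
                       censor_rate = 0.3,
                       baseline_hazard = 1 / 1000,
                       seed = 1L) {
  stopifnot(n_genes >= 1, all(n_tumor >= 1), n_normal >= 1,
            n_knockdowns >= 1, n_reagents_per_gene >= 1,
            n_replicates >= 2, n_controls >= 1, n_probes_per_gene >= 1,
            noise_sd >= 0, meth_noise_sd >= 0,
            censor_rate >= 0, censor_rate < 1, baseline_hazard > 0)
  if (is.null(names(n_tumor)) || any(!nzchar(names(n_tumor))))
    stop("n_tumor must be a named vector of subtype sample counts")
  if (reversal_strength < 0 || reversal_strength > 1)
    stop("reversal_strength must lie in [0, 1]")
  universe <- sprintf("GENE%05d", seq_len(n_genes))
  check_genes <- function(g, what) {
    bad <- setdiff(g, universe)
    if (length(bad))
      stop(sprintf("%s not in gene universe: %s", what,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  for (st in names(planted_de)) {
    de <- planted_de[[st]]
    stopifnot(is.data.frame(de), all(c("gene", "logfc") %in% names(de)))
    check_genes(de$gene, sprintf("planted_de[%s] genes", st))
  }
  check_genes(planted_reversal_genes, "planted_reversal_genes")
  if (!is.null(planted_hazard_genes)) {
    stopifnot(is.data.frame(planted_hazard_genes),
              all(c("gene", "hr") %in% names(planted_hazard_genes)),
              all(planted_hazard_genes$hr > 0))
    check_genes(planted_hazard_genes$gene, "planted_hazard_genes")
  }
  if (!is.null(planted_hypo_genes)) {
    stopifnot(is.data.frame(planted_hypo_genes),
              all(c("gene", "delta_beta") %in% names(planted_hypo_genes)),
              all(planted_hypo_genes$delta_beta >= 0),
              all(planted_hypo_genes$delta_beta <= 1))
    check_genes(planted_hypo_genes$gene, "planted_hypo_genes")
  }
  cfg <- list(n_genes = as.integer(n_genes), n_tumor = n_tumor,
              n_normal = as.integer(n_normal),
              n_knockdowns = as.integer(n_knockdowns),
              n_reagents_per_gene = as.integer(n_reagents_per_gene),
              n_replicates = as.integer(n_replicates),
              n_controls = as.integer(n_controls),
              planted_de = planted_de,
              planted_reversal_genes = planted_reversal_genes,
              reversal_strength = reversal_strength,
              reversal_effect = reversal_effect,
              planted_hazard_genes = planted_hazard_genes,
              planted_hypo_genes = planted_hypo_genes,
              n_probes_per_gene = as.integer(n_probes_per_gene),
              noise_sd = noise_sd, meth_noise_sd = meth_noise_sd,
              censor_rate = censor_rate, baseline_hazard = baseline_hazard,
              seed = as.integer(seed), universe = universe)
  class(cfg) <- "sim_config"
  cfg
}

#' Gene universe of a simulation configuration
#' @param cfg a \code{sim_config}.
#' @return character vector of gene identifiers.
#' @export
gene_universe <- function(cfg) cfg$universe

#' Planted-truth manifest
#'
#' Machine-readable record of every planted effect, for recovery tests and
#' audit. Serializable to JSON via [write_manifest()].
#'
#' @param cfg a \code{sim_config}.
#' @return list with elements \code{planted_de}, \code{reversal_genes},
#'   \code{hazard_genes}, \code{hypo_genes}.
#' @export
sim_manifest <- function(cfg) {
  list(planted_de = cfg$planted_de,
       reversal_genes = cfg$planted_reversal_genes,
       reversal_strength = cfg$reversal_strength,
       hazard_genes = cfg$planted_hazard_genes,
       hypo_genes = cfg$planted_hypo_genes,
       seed = cfg$seed)
}

#' @rdname sim_manifest
#' @param path output JSON path.
#' @export
write_manifest <- function(cfg, path) {
  jsonlite::write_json(sim_manifest(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# Per-generator RNG streams derived from the master seed so that, e.g.,
# regenerating methylation does not perturb the expression draw.
sim_seed <- function(cfg, offset) (cfg$seed * 11L + offset) %% .Machine$integer.max

#' Generate a log2 expression matrix with planted subtype effects
#'
#' Gaussian baseline on the log2 scale (gene-wise means drawn uniformly in
#' [5, 12]); tumor samples of a subtype have the planted log fold changes
#' added on top. Normal samples reuse tumor barcode prefixes with the
#' TCGA-style "-11" suffix; tumor samples end in "-01".
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{expr} (gene x sample matrix), \code{annot}
#'   (data frame: sample_id, subtype, barcode_prefix) and \code{manifest}.
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 0L))
  genes <- cfg$universe
  subtypes <- names(cfg$n_tumor)
  prefix <- character(0); subtype <- character(0)
  for (st in subtypes) {
    prefix <- c(prefix, sprintf("SIM-%s-%04d", toupper(st),
                                seq_len(cfg$n_tumor[[st]])))
    subtype <- c(subtype, rep(st, cfg$n_tumor[[st]]))
  }
  tumor_ids <- paste0(prefix, "-01")
  # matched normals reuse the first tumor prefixes
  n_prefix <- rep_len(prefix, cfg$n_normal)
  if (cfg$n_normal > length(prefix))
    n_prefix <- c(prefix, sprintf("SIM-NORM-%04d",
                                  seq_len(cfg$n_normal - length(prefix))))
  normal_ids <- paste0(n_prefix, "-11")
  samples <- c(tumor_ids, normal_ids)
  annot <- data.frame(sample_id = samples,
                      subtype = c(subtype, rep("Normal", cfg$n_normal)),
                      barcode_prefix = c(prefix, n_prefix),
                      stringsAsFactors = FALSE)
  mu <- stats::runif(cfg$n_genes, 5, 12)
  expr <- matrix(stats::rnorm(cfg$n_genes * length(samples),
                              mean = mu, sd = cfg$noise_sd),
                 nrow = cfg$n_genes, ncol = length(samples),
                 dimnames = list(genes, samples))
  for (st in names(cfg$planted_de)) {
    de <- cfg$planted_de[[st]]
    cols <- annot$sample_id[annot$subtype == st]
    expr[de$gene, cols] <- expr[de$gene, cols] + de$logfc
  }
  list(expr = expr, annot = annot, manifest = sim_manifest(cfg))
}

#' Generate raw knockdown reference profiles plus untreated controls
#'
#' Each knocked-down gene gets \code{n_reagents_per_gene} reagents with
#' \code{n_replicates} replicate profiles each; reagents differ in knockdown
#' depth of their own target so exactly one reagent per gene has the lowest
#' self-expression. Planted reversal genes push a \code{reversal_strength}
#' fraction of the signature's up genes down (and down genes up) by
#' \code{reversal_effect} log2 units in every one of their reagents.
#'
#' @param cfg a \code{sim_config}.
#' @param sig a signature (list with \code{up} and \code{down} gene vectors);
#'   required when reversal genes are planted.
#' @return list with \code{profiles} (gene x column matrix, raw scale),
#'   \code{reagent_map} (data frame: column_id, reagent_id, knocked_gene,
#'   is_control) and \code{manifest}.
#' @export
gen_reference_db <- function(cfg, sig = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$planted_reversal_genes) && is.null(sig))
    stop("a signature is required to plant reversal profiles")
  if (!is.null(sig)) {
    bad <- setdiff(c(sig$up, sig$down), cfg$universe)
    if (length(bad)) stop("signature genes outside the gene universe")
  }
  set.seed(sim_seed(cfg, 1L))
  genes <- cfg$universe
  n_extra <- cfg$n_knockdowns - length(cfg$planted_reversal_genes)
  if (n_extra < 0) stop("n_knockdowns smaller than the planted reversal set")
  pool <- setdiff(genes, cfg$planted_reversal_genes)
  knocked <- c(cfg$planted_reversal_genes, sample(pool, n_extra))
  nu <- stats::runif(cfg$n_genes, 5, 12)
  names(nu) <- genes

  n_prof <- cfg$n_knockdowns * cfg$n_reagents_per_gene * cfg$n_replicates +
    cfg$n_controls
  profiles <- matrix(NA_real_, nrow = cfg$n_genes, ncol = n_prof,
                     dimnames = list(genes, NULL))
  col_id <- character(n_prof); reagent_id <- character(n_prof)
  knocked_gene <- character(n_prof); is_control <- logical(n_prof)
  j <- 0L
  for (g in knocked) {
    shift <- numeric(cfg$n_genes); names(shift) <- genes
    if (g %in% cfg$planted_reversal_genes) {
      n_up <- round(cfg$reversal_strength * length(sig$up))
      n_dn <- round(cfg$reversal_strength * length(sig$down))
      flip_up <- if (n_up > 0) sample(sig$up, n_up) else character(0)
      flip_dn <- if (n_dn > 0) sample(sig$down, n_dn) else character(0)
      shift[flip_up] <- -cfg$reversal_effect
      shift[flip_dn] <- cfg$reversal_effect
    }
    depths <- 3 + sample.int(cfg$n_reagents_per_gene) - 1
    for (r in seq_len(cfg$n_reagents_per_gene)) {
      rshift <- shift
      rshift[g] <- rshift[g] - depths[r]
      rid <- sprintf("%s_shR%d", g, r)
      for (rep_i in seq_len(cfg$n_replicates)) {
        j <- j + 1L
        profiles[, j] <- nu + rshift +
          stats::rnorm(cfg$n_genes, sd = cfg$noise_sd)
        col_id[j] <- sprintf("KD_%s_R%d_REP%d", g, r, rep_i)
        reagent_id[j] <- rid; knocked_gene[j] <- g; is_control[j] <- FALSE
      }
    }
  }
  for (c_i in seq_len(cfg$n_controls)) {
    j <- j + 1L
    profiles[, j] <- nu + stats::rnorm(cfg$n_genes, sd = cfg$noise_sd)
    col_id[j] <- sprintf("CTL_%03d", c_i)
    reagent_id[j] <- NA_character_; knocked_gene[j] <- NA_character_
    is_control[j] <- TRUE
  }
  colnames(profiles) <- col_id
  list(profiles = profiles,
       reagent_map = data.frame(column_id = col_id, reagent_id = reagent_id,
                                knocked_gene = knocked_gene,
                                is_control = is_control,
                                stringsAsFactors = FALSE),
       manifest = sim_manifest(cfg))
}

#' Generate exponential survival times tied to planted hazard genes
#'
#' Tumor samples get exponential event times whose hazard is the baseline
#' multiplied by each planted gene's hazard ratio when the sample's
#' expression of that gene is at or above the tumor-wide median. Censoring is
#' an independent exponential clock calibrated so that roughly
#' \code{censor_rate} of null-hazard records are censored.
#'
#' @param cfg a \code{sim_config}.
#' @param expr gene x sample expression matrix from [gen_expression()].
#' @param annot matching sample annotation.
#' @return list with \code{survival} (data frame: sample_id, time, event) and
#'   \code{manifest}.
#' @export
gen_survival <- function(cfg, expr, annot) {
  stopifnot(inherits(cfg, "sim_config"),
            all(annot$sample_id %in% colnames(expr)))
  set.seed(sim_seed(cfg, 2L))
  tumor <- annot$sample_id[annot$subtype != "Normal"]
  hz <- rep(cfg$baseline_hazard, length(tumor)); names(hz) <- tumor
  if (!is.null(cfg$planted_hazard_genes)) {
    for (i in seq_len(nrow(cfg$planted_hazard_genes))) {
      g <- cfg$planted_hazard_genes$gene[i]
      hr <- cfg$planted_hazard_genes$hr[i]
      x <- expr[g, tumor]
      hz[x >= stats::median(x)] <- hz[x >= stats::median(x)] * hr
    }
  }
  t_event <- stats::rexp(length(tumor), rate = hz)
  if (cfg$censor_rate > 0) {
    cens_rate <- cfg$baseline_hazard * cfg$censor_rate / (1 - cfg$censor_rate)
    t_cens <- stats::rexp(length(tumor), rate = cens_rate)
  } else {
    t_cens <- rep(Inf, length(tumor))
  }
  surv <- data.frame(sample_id = tumor,
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)
  list(survival = surv, manifest = sim_manifest(cfg))
}

#' Generate a bimodal beta-value methylation matrix with planted hypo blocks
#'
#' Probe baselines sit near 0.1 or 0.9 (equal-weight mixture, sd 0.05 per
#' sample). Probes of planted hypomethylated genes start from the methylated
#' (0.9) mode so the planted drop is observable; tumor samples on those
#' probes are lowered by the gene's \code{delta_beta}. Values are clipped to
#' (0, 1) exclusive so the M-value transform stays finite.
#'
#' @param cfg a \code{sim_config}.
#' @param annot sample annotation from [gen_expression()].
#' @return list with \code{beta} (probe x sample matrix), \code{probe_map}
#'   (data frame: probe_id, gene) and \code{manifest}.
#' @export
gen_methylation <- function(cfg, annot) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 3L))
  genes <- cfg$universe
  probe_map <- data.frame(
    probe_id = sprintf("cg_%s_%02d", rep(genes, each = cfg$n_probes_per_gene),
                       rep(seq_len(cfg$n_probes_per_gene), length(genes))),
    gene = rep(genes, each = cfg$n_probes_per_gene),
    stringsAsFactors = FALSE)
  n_probe <- nrow(probe_map)
  samples <- annot$sample_id
  hypo_genes <- if (is.null(cfg$planted_hypo_genes)) character(0) else
    cfg$planted_hypo_genes$gene
  mode_high <- stats::runif(n_probe) < 0.5
  mode_high[probe_map$gene %in% hypo_genes] <- TRUE
  centre <- ifelse(mode_high, 0.9, 0.1)
  beta <- matrix(stats::rnorm(n_probe * length(samples), mean = centre,
                              sd = cfg$meth_noise_sd),
                 nrow = n_probe, ncol = length(samples),
                 dimnames = list(probe_map$probe_id, samples))
  tumor <- annot$sample_id[annot$subtype != "Normal"]
  if (length(hypo_genes)) {
    for (i in seq_len(nrow(cfg$planted_hypo_genes))) {
      g <- cfg$planted_hypo_genes$gene[i]
      db <- cfg$planted_hypo_genes$delta_beta[i]
      rows <- probe_map$probe_id[probe_map$gene == g]
      beta[rows, tumor] <- beta[rows, tumor] - db
    }
  }
  eps <- 1e-6
  beta[beta < eps] <- eps
  beta[beta > 1 - eps] <- 1 - eps
  list(beta = beta, probe_map = probe_map, manifest = sim_manifest(cfg))
}

#' Demonstration simulation: planted targets for every filter
#'
#' A ready-made study design used by the examples and the end-to-end tests:
#' 1200 genes, 120 tumors per subtype plus 120 normals, and five planted
#' target genes that are knockdown reversers (candidates), up-regulated
#' (logFC 2.5) in their designated subtype(s), hypomethylated (delta beta
#' 0.3) and hazardous (planted HR 3.5; with several hazard genes stacking
#' multiplicatively, unobserved-frailty attenuation pulls each gene's
#' marginal hazard ratio below its planted value, so the plant and the
#' cohort are sized for the marginal effect to remain detectable).
#' GENE00005 is planted in all four subtypes; GENE00001-4
#' are specific to LumA, LumB, HER2 and TNBC respectively, one per subtype so
#' that the hazard burden is balanced across subtypes and each gene's
#' high/low expression split isolates its own hazard effect. Ten additional
#' reversal-only knockdowns and ten strongly differential decoy genes
#' exercise the candidate and signature stages without passing the full
#' filter conjunction.
#'
#' @param seed integer RNG seed.
#' @return a \code{sim_config}.
#' @export
demo_sim_config <- function(seed = 1L) {
  g <- function(i) sprintf("GENE%05d", i)
  targets <- list(LumA = g(c(1, 5)), LumB = g(c(2, 5)),
                  HER2 = g(c(3, 5)), TNBC = g(c(4, 5)))
  decoys <- g(7:16)
  planted_de <- lapply(targets, function(tg)
    data.frame(gene = c(tg, decoys),
               logfc = c(rep(2.5, length(tg)),
                         rep(c(3, -3), length.out = length(decoys)))))
  sim_config(
    n_genes = 1200,
    n_tumor = c(LumA = 120, LumB = 120, HER2 = 120, TNBC = 120),
    n_normal = 120,
    n_knockdowns = 80,
    planted_de = planted_de,
    planted_reversal_genes = g(c(1:5, 17:26)),
    reversal_strength = 0.8,
    planted_hazard_genes = data.frame(gene = g(1:5), hr = 3.5),
    planted_hypo_genes = data.frame(gene = g(1:5), delta_beta = 0.3),
    noise_sd = 0.5,
    seed = seed)
}

#' Planted final targets of a configuration, by subtype
#'
#' The genes expected to pass all four filters (candidate, up-regulated,
#' hypomethylated, poor-survival) in each subtype: the intersection of the
#' reversal, hazard and hypo plants with that subtype's planted up-regulation
#' above the given threshold.
#'
#' @param cfg a \code{sim_config}.
#' @param up_logfc_cut up-regulation threshold (default 1).
#' @return named list of gene vectors, one per subtype.
#' @export
planted_final_targets <- function(cfg, up_logfc_cut = 1) {
  base <- Reduce(intersect, list(
    cfg$planted_reversal_genes,
    if (is.null(cfg$planted_hazard_genes)) character(0) else
      cfg$planted_hazard_genes$gene,
    if (is.null(cfg$planted_hypo_genes)) character(0) else
      cfg$planted_hypo_genes$gene))
  lapply(cfg$planted_de, function(de)
    sort(intersect(base, de$gene[de$logfc > up_logfc_cut])))
}
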