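#' Dichotomize an expression vector into high/low groups
#'
#' \code{median}: every sample is kept, high = values at or above the median.
#' \code{tertile}/\code{quartile}: only the top and bottom third (quarter) of
#' samples, by expression rank, are kept as high/low; the middle is dropped.
#' Rank ties are broken by sample id for determinism.
#'
#' @param x named numeric vector (names = sample ids), length >= 4.
#' @param strategy one of "median", "tertile", "quartile".
#' @return named character vector ("high"/"low") over the retained samples.
#' @export
dichotomize <- function(x, strategy = c("median", "tertile", "quartile")) {
  strategy <- match.arg(strategy)
  stopifnot(length(x) >= 4, !is.null(names(x)))
  if (length(unique(x)) == 1)
    stop("all expression values equal: no grouping possible")
  if (strategy == "median") {
    g <- ifelse(x >= stats::median(x), "high", "low")
    names(g) <- names(x)
    return(g)
  }
  q <- if (strategy == "tertile") 3L else 4L
  k <- floor(length(x) / q)
  if (k < 1) stop("too few samples for this cut-off strategy")
  ord <- order(x, names(x))
  low_ids <- names(x)[ord[seq_len(k)]]
  high_ids <- names(x)[ord[seq(length(x) - k + 1, length(x))]]
  stats::setNames(c(rep("low", k), rep("high", k)), c(low_ids, high_ids))
}

#' Kaplan-Meier product-limit curve
#'
#' @param times non-negative event/censoring times.
#' @param events 1 = event, 0 = censored.
#' @return data frame with columns time, n_risk, n_event, surv (the
#'   right-continuous product-limit estimate after each observed time).
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  if (any(times < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param times,events survival data for all subjects.
#' @param group two-level grouping factor/vector aligned with \code{times}.
#' @return list with \code{chisq} (1 df statistic) and \code{p} (two-sided).
#'   When neither group has any event the test is undefined and p = 1 is
#'   returned with a warning.
#' @export
logrank_test <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("exactly two non-empty groups are required")
  if (sum(events) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chisq = 0, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  chisq <- sd_$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards estimate for a single binary covariate
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson. When all
#' events fall in one group the likelihood is monotone and the hazard ratio
#' is reported as \code{Inf} (or 0) with \code{monotone = TRUE} and no Wald
#' p-value.
#'
#' @param times,events survival data.
#' @param group binary indicator (logical, 0/1, or "high"/"low"); the hazard
#'   ratio is for group == high (or 1/TRUE) versus the reference.
#' @return list: hr, beta, se, p, monotone.
#' @export
cox_hr <- function(times, events, group) {
  x <- if (is.character(group) || is.factor(group)) {
    as.integer(as.character(group) == "high")
  } else as.integer(as.logical(group))
  stopifnot(length(times) == length(events), length(times) == length(x),
            all(x %in% 0:1))
  ev1 <- sum(events[x == 1]); ev0 <- sum(events[x == 0])
  if (ev1 + ev0 == 0) stop("no events: hazard ratio undefined")
  if (ev1 == 0 || ev0 == 0) {
    warning("all events in one group: monotone partial likelihood")
    return(list(hr = if (ev0 == 0) Inf else 0,
                beta = if (ev0 == 0) Inf else -Inf,
                se = NA_real_, p = NA_real_, monotone = TRUE))
  }
  # risk-set composition at each distinct event time (Breslow ties)
  etimes <- sort(unique(times[events == 1]))
  d <- s1 <- r1 <- r0 <- numeric(length(etimes))
  for (i in seq_along(etimes)) {
    t0 <- etimes[i]
    ev_here <- events == 1 & times == t0
    d[i] <- sum(ev_here)
    s1[i] <- sum(x[ev_here])
    at_risk <- times >= t0
    r1[i] <- sum(x[at_risk]); r0[i] <- sum(at_risk) - r1[i]
  }
  beta <- 0
  for (iter in 1:50) {
    eb <- exp(beta)
    denom <- r0 + r1 * eb
    u <- sum(s1) - sum(d * r1 * eb / denom)
    info <- sum(d * r0 * r1 * eb / denom^2)
    if (info <= 0) break
    step <- u / info
    beta <- beta + step
    if (abs(step) < 1e-10) break
  }
  se <- 1 / sqrt(info)
  list(hr = exp(beta), beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)), monotone = FALSE)
}

#' Screen genes for expression-linked poor survival
#'
#' For each gene and each dichotomization strategy, samples are split into
#' high/low expression groups, compared by log-rank test, and the hazard
#' ratio (high vs. low) estimated by Cox regression on the group indicator.
#' A gene is kept under a strategy when p < \code{p_cut} and HR > 1; the
#' poor-survival set is the union over strategies.
#'
#' @param expr gene x sample expression matrix.
#' @param surv data frame with sample_id, time, event.
#' @param genes genes to screen (must be rows of \code{expr}).
#' @param strategies subset of c("median", "tertile", "quartile").
#' @param p_cut log-rank significance threshold (default 0.05).
#' @return list with \code{table} (gene, strategy, p, hr, kept) and
#'   \code{genes} (the union poor-survival gene set).
#' @export
screen_survival_genes <- function(expr, surv, genes,
                                  strategies = c("median", "tertile",
                                                 "quartile"),
                                  p_cut = 0.05) {
  stopifnot(all(genes %in% rownames(expr)))
  ids <- intersect(colnames(expr), surv$sample_id)
  if (length(ids) < 4) stop("too few samples shared by expression and survival")
  surv <- surv[match(ids, surv$sample_id), ]
  rows <- list()
  for (g in genes) {
    x <- expr[g, ids]
    names(x) <- ids
    for (st in strategies) {
      res <- tryCatch({
        grp <- dichotomize(x, st)
        s_sub <- surv[match(names(grp), surv$sample_id), ]
        lr <- suppressWarnings(logrank_test(s_sub$time, s_sub$event, grp))
        cx <- suppressWarnings(cox_hr(s_sub$time, s_sub$event, grp))
        c(p = lr$p, hr = cx$hr)
      }, error = function(e) c(p = NA_real_, hr = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, strategy = st, p = res[["p"]], hr = res[["hr"]],
        kept = isTRUE(res[["p"]] < p_cut && res[["hr"]] > 1),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, genes = sort(unique(tab$gene[tab$kept])))
}
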