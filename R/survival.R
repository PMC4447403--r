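#' Construct a patient survival cohort
#'
#' @param meta data.frame with one row per patient: `patient_id`, follow-up
#'   `time` (> 0), `event` (0 = censored, 1 = death/relapse), optionally
#'   `endpoint` (`"OS"`/`"RFS"`), and marker probe intensities `esr_probe`,
#'   `mki67_probe`, `her2_probe` (linear scale, >= 0).
#' @param expression numeric matrix of log2 expression, patients x genes,
#'   rownames matching `meta$patient_id`.
#' @param cutoffs marker-probe cutoffs used to pre-compute the `subtype`
#'   column (see [classify_subtype()]).
#' @return an object of class `em_cohort`: list with `meta` (including a
#'   `subtype` column when probes are present) and `expression`.
#' @export
survival_cohort <- function(meta, expression,
                            cutoffs = c(esr = 500, mki67 = 470, her2 = 4800)) {
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(meta)))
    stop_input("meta must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$patient_id)) stop_input("duplicate patient ids")
  if (any(meta$time <= 0)) stop_input("follow-up times must be > 0")
  if (!all(meta$event %in% c(0, 1))) stop_input("event must be 0 or 1")
  if (!is.matrix(expression) || is.null(rownames(expression)))
    stop_input("expression must be a matrix with patient_id rownames")
  if (!setequal(rownames(expression), meta$patient_id))
    stop_input("expression rownames must match meta$patient_id")
  expression <- expression[as.character(meta$patient_id), , drop = FALSE]
  probes <- c("esr_probe", "mki67_probe", "her2_probe")
  if (all(probes %in% names(meta))) {
    if (any(stats::na.omit(unlist(meta[probes])) < 0))
      stop_input("probe values must be >= 0")
    meta$subtype <- classify_subtype(meta$esr_probe, meta$mki67_probe,
                                     meta$her2_probe, cutoffs = cutoffs)
  }
  structure(list(meta = meta, expression = expression), class = "em_cohort")
}

#' @export
print.em_cohort <- function(x, ...) {
  cat(sprintf("<em_cohort> %d patients, %d genes, %d events\n",
              nrow(x$meta), ncol(x$expression), sum(x$meta$event)))
  if (!is.null(x$meta$subtype)) print(table(x$meta$subtype))
  invisible(x)
}

#' Read a cohort CSV
#'
#' Column layout: `patient_id`, `time`, `event`, optional `endpoint` and
#' probe columns (`esr_probe`, `mki67_probe`, `her2_probe`); every remaining
#' column is treated as a log2 gene-expression value.
#'
#' @param path CSV path.
#' @inheritParams survival_cohort
#' @return an `em_cohort`.
#' @export
read_cohort <- function(path, cutoffs = c(esr = 500, mki67 = 470, her2 = 4800)) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(
    c("patient_id", "time", "event", "endpoint",
      "esr_probe", "mki67_probe", "her2_probe", "subtype"), names(tab))
  gene_cols <- setdiff(names(tab), meta_cols)
  expr <- as.matrix(tab[, gene_cols, drop = FALSE])
  rownames(expr) <- as.character(tab$patient_id)
  survival_cohort(tab[, setdiff(meta_cols, "subtype"), drop = FALSE], expr,
                  cutoffs = cutoffs)
}

#' Write a cohort to CSV
#'
#' @param cohort an `em_cohort`.
#' @param path CSV output path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "em_cohort"))
  out <- cbind(cohort$meta, as.data.frame(cohort$expression))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify breast cancer subtype from three marker probes
#'
#' Clinico-pathological surrogate rule on the ESR, MKI67 and HER2 probe
#' intensities: luminal A (ESR+, HER2-, MKI67 low), luminal B (ESR+, HER2-,
#' MKI67 high; or ESR+, HER2+), basal (ESR-, HER2-), HER2 (ESR-, HER2+).
#' Positivity means strictly greater than the cutoff. Records with a missing
#' probe are labelled `"unclassified"` with a warning.
#'
#' @param esr,mki67,her2 probe intensities (linear scale), vectorized.
#' @param cutoffs named numeric vector with elements `esr`, `mki67`, `her2`.
#' @return character vector of subtype labels.
#' @examples
#' classify_subtype(600, 300, 1000)  # luminalA
#' classify_subtype(100, 900, 100)   # basal
#' @export
classify_subtype <- function(esr, mki67, her2,
                             cutoffs = c(esr = 500, mki67 = 470, her2 = 4800)) {
  n <- max(length(esr), length(mki67), length(her2))
  esr <- rep_len(esr, n); mki67 <- rep_len(mki67, n); her2 <- rep_len(her2, n)
  miss <- is.na(esr) | is.na(mki67) | is.na(her2)
  if (any(miss))
    warning(sum(miss), " record(s) with missing probes left unclassified")
  esr_pos <- esr > cutoffs[["esr"]]
  ki_high <- mki67 > cutoffs[["mki67"]]
  her_pos <- her2 > cutoffs[["her2"]]
  out <- ifelse(esr_pos,
                ifelse(her_pos, "luminalB",
                       ifelse(ki_high, "luminalB", "luminalA")),
                ifelse(her_pos, "HER2", "basal"))
  out[miss] <- "unclassified"
  out
}

#' Score patients by the mean expression of a signature
#'
#' The score is the unweighted mean of the log2 expression over the
#' signature genes present in the expression data; missing genes are
#' dropped with a warning.
#'
#' @param expression numeric matrix (patients x genes) or a named vector
#'   for a single patient.
#' @param signature an [gene_signature()].
#' @return numeric vector of scores (one per patient) with attribute
#'   `n_missing`, the count of signature genes absent from the data.
#' @export
score_signature <- function(expression, signature) {
  stopifnot(inherits(signature, "em_signature"))
  if (!is.matrix(expression))
    expression <- matrix(expression, nrow = 1L,
                         dimnames = list("patient", names(expression)))
  genes <- signature_genes(signature)
  present <- intersect(genes, colnames(expression))
  if (length(present) == 0L)
    stop_input("no signature gene overlaps the expression data")
  n_missing <- length(genes) - length(present)
  if (n_missing > 0L)
    warning(n_missing, " of ", length(genes),
            " signature genes absent; scoring the rest")
  scores <- rowMeans(expression[, present, drop = FALSE])
  attr(scores, "n_missing") <- n_missing
  scores
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` -- the right-continuous step estimate at each observed time.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) stop_input("empty input")
  if (any(time <= 0)) stop_input("times must be > 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

# fast two-group logrank: returns c(chi2, p, o_minus_e1)
logrank_stat <- function(time, event, grp2) {
  dt <- sort(unique(time[event == 1]))
  if (length(dt) == 0L) stop_input("no events: logrank statistic undefined")
  # at-risk and event counts per distinct event time, by group
  n1_at <- vapply(dt, function(t) sum(time >= t & !grp2), 0)
  n_at <- vapply(dt, function(t) sum(time >= t), 0)
  d1 <- vapply(dt, function(t) sum(time == t & event == 1 & !grp2), 0)
  d <- vapply(dt, function(t) sum(time == t & event == 1), 0)
  e1 <- d * n1_at / n_at
  v <- ifelse(n_at > 1,
              d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1),
              0)
  vsum <- sum(v)
  if (vsum <= 0) return(c(chi2 = 0, p = 1, o_minus_e1 = 0))
  ome <- sum(d1) - sum(e1)
  chi2 <- ome^2 / vsum
  c(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
    o_minus_e1 = ome)
}

#' Two-group logrank test
#'
#' Standard logrank statistic (observed minus expected events over the
#' shared risk sets), referred to a chi-square distribution with 1 df.
#'
#' @param time1,event1 follow-up and event indicator of group A.
#' @param time2,event2 follow-up and event indicator of group B.
#' @return list with `chi2`, `p` and `o_minus_e` (observed minus expected
#'   events in group A; positive = more events than expected in A).
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  if (length(time1) == 0L || length(time2) == 0L)
    stop_input("both groups must be non-empty")
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp2 <- rep(c(FALSE, TRUE), c(length(time1), length(time2)))
  s <- logrank_stat(time, event, grp2)
  list(chi2 = unname(s["chi2"]), p = unname(s["p"]),
       o_minus_e = unname(s["o_minus_e1"]))
}

#' Select the best dichotomizing cutoff for a score
#'
#' Evaluates the logrank p-value at each candidate quantile of the score
#' (default: quartiles, tertiles and the median) and returns the candidate
#' with the smallest p. Patients with score strictly greater than the
#' cutoff value form the high group. Candidates leaving fewer than two
#' patients on either side are skipped.
#'
#' @param scores per-patient signature scores.
#' @param time,event follow-up times and event indicators.
#' @param candidates candidate quantiles.
#' @return list with `quantile`, `cutoff` (score value), `high` (logical
#'   grouping), `p`, `chi2` and `candidate_p` (named p per candidate).
#' @export
select_best_cutoff <- function(scores, time, event,
                               candidates = c(0.25, 1 / 3, 0.5, 2 / 3, 0.75)) {
  if (length(scores) != length(time) || length(time) != length(event))
    stop_input("scores, time, event must have equal length")
  res <- lapply(candidates, function(q) {
    cut <- quantile(scores, q, names = FALSE)
    high <- scores > cut
    if (sum(high) < 2L || sum(!high) < 2L) return(NULL)
    s <- tryCatch(logrank_stat(time, event, high), error = function(e) NULL)
    if (is.null(s)) return(NULL)
    list(q = q, cut = cut, high = high, chi2 = s[["chi2"]], p = s[["p"]])
  })
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok))
    stop_input("degenerate cohort: no candidate cutoff yields two usable groups")
  res <- res[ok]
  ps <- vapply(res, `[[`, 0, "p")
  best <- res[[which.min(ps)]]
  list(quantile = best$q, cutoff = best$cut, high = best$high,
       p = best$p, chi2 = best$chi2,
       candidate_p = setNames(ps, signif(vapply(res, `[[`, 0, "q"), 4)))
}

#' Cox proportional-hazards ratio for a binary grouping
#'
#' Single-covariate Cox partial-likelihood fit (Breslow ties) of the high
#' vs low group, with Wald 95% confidence interval. Divergent fits
#' (complete separation) are flagged with an infinite hazard ratio.
#'
#' @param high logical (or 2-level) group indicator; `TRUE` = high.
#' @param time,event follow-up times and event indicators.
#' @return list with `hr`, `ci_low`, `ci_high`, `coef`, `se`,
#'   `diverged` (logical).
#' @export
cox_hr <- function(high, time, event) {
  high <- as.logical(high)
  if (!any(high) || all(high)) stop_input("both groups must be non-empty")
  if (sum(event) == 0L) stop_input("no events: hazard ratio undefined")
  fit <- survival::coxph(survival::Surv(time, event) ~ x,
                         data = data.frame(time = time, event = event,
                                           x = high),
                         ties = "breslow")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  diverged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15
  if (diverged) {
    hr <- if (is.finite(beta) && beta < 0) 0 else Inf
    return(list(hr = hr, ci_low = NA_real_, ci_high = NA_real_,
                coef = beta, se = se, diverged = TRUE))
  }
  list(hr = exp(beta),
       ci_low = exp(beta - qnorm(0.975) * se),
       ci_high = exp(beta + qnorm(0.975) * se),
       coef = beta, se = se, diverged = FALSE)
}

#' Signature survival analysis: score, dichotomize, logrank and Cox
#'
#' Pipeline used for every signature-cohort evaluation: score patients with
#' the signature mean, pick the best-cutoff dichotomization among the
#' candidate quantiles, then report the logrank test and the Cox hazard
#' ratio of the high- vs low-scoring group.
#'
#' @param cohort an `em_cohort`.
#' @param signature an [gene_signature()].
#' @param endpoint optional endpoint label; when the cohort has an
#'   `endpoint` column only matching records are used.
#' @param subtype optional subtype filter (see [classify_subtype()]).
#' @param candidates candidate cutoff quantiles
#'   (see [select_best_cutoff()]).
#' @param fixed_cutoff optional quantile in (0,1); when supplied the cutoff
#'   search is skipped and the score is split at this quantile.
#' @return an object of class `em_survfit`: list with `hr`, `ci_low`,
#'   `ci_high`, `logrank_chi2`, `logrank_p`, `cutoff` (quantile used),
#'   `cutoff_value`, `n_high`, `n_low`, `diverged`.
#' @export
evaluate_signature_survival <- function(cohort, signature, endpoint = NULL,
                                        subtype = NULL,
                                        candidates = c(0.25, 1 / 3, 0.5,
                                                       2 / 3, 0.75),
                                        fixed_cutoff = NULL) {
  stopifnot(inherits(cohort, "em_cohort"))
  keep <- rep(TRUE, nrow(cohort$meta))
  if (!is.null(endpoint) && !is.null(cohort$meta$endpoint))
    keep <- keep & cohort$meta$endpoint == endpoint
  if (!is.null(subtype)) {
    if (is.null(cohort$meta$subtype))
      stop_input("cohort has no subtype column; provide marker probes")
    keep <- keep & cohort$meta$subtype == subtype
  }
  if (sum(keep) < 4L) stop_input("fewer than 4 patients after filtering")
  meta <- cohort$meta[keep, , drop = FALSE]
  expr <- cohort$expression[keep, , drop = FALSE]
  scores <- score_signature(expr, signature)
  if (is.null(fixed_cutoff)) {
    sel <- select_best_cutoff(scores, meta$time, meta$event, candidates)
  } else {
    cut <- quantile(scores, fixed_cutoff, names = FALSE)
    high <- scores > cut
    if (sum(high) < 2L || sum(!high) < 2L)
      stop_input("fixed cutoff leaves fewer than 2 patients in a group")
    s <- logrank_stat(meta$time, meta$event, high)
    sel <- list(quantile = fixed_cutoff, cutoff = cut, high = high,
                p = s[["p"]], chi2 = s[["chi2"]])
  }
  cox <- cox_hr(sel$high, meta$time, meta$event)
  structure(list(hr = cox$hr, ci_low = cox$ci_low, ci_high = cox$ci_high,
                 logrank_chi2 = sel$chi2, logrank_p = sel$p,
                 cutoff = sel$quantile, cutoff_value = sel$cutoff,
                 n_high = sum(sel$high), n_low = sum(!sel$high),
                 diverged = cox$diverged),
            class = "em_survfit")
}

#' @export
print.em_survfit <- function(x, ...) {
  cat(sprintf(
    "<em_survfit> HR %.3f (95%% CI %.3f-%.3f), logrank p %.3g\n",
    x$hr, x$ci_low, x$ci_high, x$logrank_p))
  cat(sprintf("  cutoff quantile %.3g (score > %.3g): %d high vs %d low\n",
              x$cutoff, x$cutoff_value, x$n_high, x$n_low))
  invisible(x)
}
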