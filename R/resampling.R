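#' Random-gene-set permutation null for a signature's prognostic value
#'
#' Draws `n_perm` random gene sets of the same size as the signature from
#' the cohort's gene universe and pushes each through the identical
#' scoring/best-cutoff/logrank/Cox pipeline. Extremeness is ordered by the
#' signed logrank statistic `z = sign(log HR) * sqrt(chi2)` -- larger z
#' means stronger evidence of poor outcome -- and a null set counts as at
#' least as extreme when its z is at least the observed one (for an
#' observed HR > 1 this is exactly "logrank p no larger than observed
#' with the HR on the same, poor-outcome side of 1"); with
#' `two_sided = TRUE` the ordering is by `|z|`. Both orderings make the
#' permuted p exactly uniform under the null. The permuted p-value uses
#' the add-one estimator `(1 + extreme) / (n_perm + 1)`, so it is never 0.
#'
#' @param cohort an `em_cohort`.
#' @param signature an [gene_signature()].
#' @param n_perm number of random gene sets.
#' @param seed RNG seed for the draws.
#' @param two_sided order extremeness by `|z|`, ignoring the direction of
#'   the hazard ratio.
#' @param fixed_cutoff optional quantile passed to
#'   [evaluate_signature_survival()]; by default the full best-cutoff
#'   search is re-run for every draw.
#' @param endpoint,subtype optional filters, as in
#'   [evaluate_signature_survival()].
#' @return list of class `em_permutation`: `observed` (`em_survfit`),
#'   `null_stats` (data.frame of hr and logrank_p per draw), `n_perm`,
#'   `permuted_p`.
#' @export
permutation_null <- function(cohort, signature, n_perm = 1000, seed = NULL,
                             two_sided = FALSE, fixed_cutoff = NULL,
                             endpoint = NULL, subtype = NULL) {
  stopifnot(inherits(cohort, "em_cohort"), inherits(signature, "em_signature"))
  universe <- colnames(cohort$expression)
  k <- nrow(signature$members)
  if (length(universe) < 10L * k)
    stop_input("gene universe (", length(universe),
               ") smaller than 10 x signature size (", k, ")")
  observed <- evaluate_signature_survival(cohort, signature,
                                          endpoint = endpoint,
                                          subtype = subtype,
                                          fixed_cutoff = fixed_cutoff)
  null_stats <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_perm), function(i) {
      genes <- sample(universe, k)
      rnd <- gene_signature(
        sprintf("null_%d", i),
        data.frame(gene = genes, direction = "E", rank = seq_len(k),
                   effect_size = NA_real_, stringsAsFactors = FALSE))
      fit <- evaluate_signature_survival(cohort, rnd, endpoint = endpoint,
                                         subtype = subtype,
                                         fixed_cutoff = fixed_cutoff)
      data.frame(hr = fit$hr, logrank_p = fit$logrank_p)
    }))
  })
  zstat <- function(hr, chi2_from_p) {
    # signed root of the logrank chi-square; + = poor outcome (HR > 1)
    z <- sqrt(stats::qchisq(chi2_from_p, df = 1, lower.tail = FALSE))
    ifelse(hr >= 1, z, -z)
  }
  z_null <- zstat(null_stats$hr, null_stats$logrank_p)
  z_obs <- zstat(observed$hr, observed$logrank_p)
  extreme <- if (two_sided) sum(abs(z_null) >= abs(z_obs))
             else sum(z_null >= z_obs)
  structure(list(observed = observed, null_stats = null_stats,
                 n_perm = n_perm,
                 permuted_p = (1 + extreme) / (n_perm + 1)),
            class = "em_permutation")
}

#' @export
print.em_permutation <- function(x, ...) {
  cat(sprintf("<em_permutation> %d random gene sets, permuted p = %.4g\n",
              x$n_perm, x$permuted_p))
  invisible(x)
}

#' Prognostic stability of gene subsets drawn from a pool
#'
#' Draws `n_sets` gene sets of size `subsig_size` (without replacement
#' within each set, sets independent) from a gene pool -- e.g. the most
#' EM-specific genes -- and evaluates each with the full survival pipeline,
#' summarizing how often the subsets point to poor outcome.
#'
#' @param cohort an `em_cohort`.
#' @param gene_pool an [gene_signature()] or character vector of gene ids.
#' @param subsig_size genes per subset.
#' @param n_sets number of subsets.
#' @param seed RNG seed.
#' @param ... passed to [evaluate_signature_survival()].
#' @return list of class `em_bootstrap`: `fits` (data.frame with hr,
#'   logrank_p per subset), `frac_hr_gt1`, `frac_significant`
#'   (logrank p < 0.05 and hr > 1).
#' @export
bootstrap_subsignatures <- function(cohort, gene_pool, subsig_size, n_sets,
                                    seed = NULL, ...) {
  pool <- if (inherits(gene_pool, "em_signature")) signature_genes(gene_pool)
          else as.character(gene_pool)
  if (subsig_size > length(pool))
    stop_input("subsig_size (", subsig_size, ") exceeds pool size (",
               length(pool), ")")
  fits <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_sets), function(i) {
      genes <- sample(pool, subsig_size)
      s <- gene_signature(
        sprintf("subsig_%d", i),
        data.frame(gene = genes, direction = "E",
                   rank = seq_len(subsig_size), effect_size = NA_real_,
                   stringsAsFactors = FALSE))
      fit <- evaluate_signature_survival(cohort, s, ...)
      data.frame(hr = fit$hr, logrank_p = fit$logrank_p)
    }))
  })
  structure(list(fits = fits,
                 frac_hr_gt1 = mean(fits$hr > 1),
                 frac_significant = mean(fits$hr > 1 & fits$logrank_p < 0.05)),
            class = "em_bootstrap")
}

#' @export
print.em_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<em_bootstrap> %d subsets: %.1f%% HR>1, %.1f%% significant poor outcome\n",
    nrow(x$fits), 100 * x$frac_hr_gt1, 100 * x$frac_significant))
  invisible(x)
}
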