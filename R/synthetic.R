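#' Simulate a clone-labelled expression matrix with planted E/M genes
#'
#' Emulates the clone comparison design: `n_e` epithelial and `n_m`
#' mesenchymal clone arrays over `n_genes` probes. Baseline log2
#' intensities are i.i.d. Normal(`base_mean`, `noise_sd`); the first
#' `n_planted` genes are shifted `+effect_size` in the E samples (E-up),
#' the next `n_planted` are shifted `+effect_size` in the M samples (M-up),
#' and each array receives a global offset so that array normalization is
#' exercised.
#'
#' @param n_genes total number of genes.
#' @param n_e,n_m samples per clone group.
#' @param n_planted planted genes per direction.
#' @param effect_size planted log2 shift.
#' @param noise_sd per-observation noise standard deviation (log2 units).
#' @param base_mean baseline log2 intensity.
#' @param sample_offset_sd standard deviation of per-array offsets.
#' @param seed RNG seed.
#' @return list with `matrix` (an [expression_matrix()], groups
#'   `"Eclone"`/`"Mclone"`) and `truth` (list with `e_up`, `m_up` gene ids).
#' @export
generate_clone_matrix <- function(n_genes = 1000, n_e = 6, n_m = 4,
                                  n_planted = 30, effect_size = 3,
                                  noise_sd = 1, base_mean = 8,
                                  sample_offset_sd = 0.3, seed = NULL) {
  if (n_genes < 2L * n_planted)
    stop_input("n_genes must be at least twice n_planted")
  if (n_e < 1L || n_m < 1L) stop_input("need at least one sample per group")
  with_seed(seed, {
    n_s <- n_e + n_m
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- c(sprintf("E%d", seq_len(n_e)), sprintf("M%d", seq_len(n_m)))
    groups <- setNames(rep(c("Eclone", "Mclone"), c(n_e, n_m)), samples)
    v <- matrix(rnorm(n_genes * n_s, base_mean, noise_sd), n_genes, n_s,
                dimnames = list(genes, samples))
    e_up <- genes[seq_len(n_planted)]
    m_up <- genes[n_planted + seq_len(n_planted)]
    v[e_up, seq_len(n_e)] <- v[e_up, seq_len(n_e)] + effect_size
    v[m_up, n_e + seq_len(n_m)] <- v[m_up, n_e + seq_len(n_m)] + effect_size
    v <- sweep(v, 2L, rnorm(n_s, 0, sample_offset_sd), `+`)
    list(matrix = expression_matrix(v, groups),
         truth = list(e_up = e_up, m_up = m_up))
  })
}

#' Simulate a survival cohort whose hazard depends on a signature score
#'
#' Each patient carries a latent score `s ~ Normal(0, 1)`; every signature
#' gene reads `base_mean + loading * s + noise`, other genes are pure
#' noise. Survival times are exponential with hazard
#' `h0 * exp(beta * s)`; censoring times are uniform on `(0, c_max)` with
#' `c_max` calibrated so the expected censoring fraction matches
#' `censor_frac`. Marker probes are drawn to populate the four breast
#' cancer subtypes around the classification cutoffs.
#'
#' @param n_patients cohort size.
#' @param signature an [gene_signature()] (its genes are guaranteed to be
#'   in the generated universe).
#' @param beta log-hazard per unit latent score.
#' @param n_genes size of the gene universe (signature genes included).
#' @param loading signal loading of signature genes on the latent score.
#' @param noise_sd per-gene expression noise.
#' @param base_mean baseline log2 expression.
#' @param h0 baseline hazard (events per month).
#' @param censor_frac target censoring fraction, in `[0, 1)`.
#' @param subtype_probs probabilities of luminalA, luminalB, basal, HER2.
#' @param cutoffs marker-probe cutoffs (see [classify_subtype()]).
#' @param seed RNG seed.
#' @return list with `cohort` (an `em_cohort`) and `truth` (list with
#'   `score`, `beta`, `subtype`).
#' @export
generate_cohort <- function(n_patients, signature, beta = 0, n_genes = 200,
                            loading = 1, noise_sd = 1, base_mean = 8,
                            h0 = 0.02, censor_frac = 0.2,
                            subtype_probs = c(luminalA = 0.35,
                                              luminalB = 0.25,
                                              basal = 0.2, HER2 = 0.2),
                            cutoffs = c(esr = 500, mki67 = 470, her2 = 4800),
                            seed = NULL) {
  stopifnot(inherits(signature, "em_signature"))
  sig_genes <- signature_genes(signature)
  if (length(sig_genes) == 0L) stop_input("signature is empty")
  if (censor_frac < 0 || censor_frac >= 1)
    stop_input("censor_frac must be in [0, 1)")
  with_seed(seed, {
    universe <- unique(c(sig_genes, sprintf("u%04d", seq_len(n_genes))))
    universe <- universe[seq_len(max(n_genes, length(sig_genes)))]
    n_p <- n_patients
    s <- rnorm(n_p)
    expr <- matrix(rnorm(n_p * length(universe), base_mean, noise_sd),
                   n_p, length(universe),
                   dimnames = list(sprintf("p%04d", seq_len(n_p)), universe))
    expr[, sig_genes] <- expr[, sig_genes] + loading * s
    t_event <- rexp(n_p, rate = h0 * exp(beta * s))
    if (censor_frac > 0) {
      # uniform censoring horizon: E[P(C < T)] = mean(min(t/cmax, 1))
      f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censor_frac
      cmax <- uniroot(f, lower = min(t_event) * 1e-3,
                      upper = max(t_event) * 1e3, tol = 1e-8)$root
      cens <- runif(n_p, 0, cmax)
    } else {
      cens <- rep(Inf, n_p)
    }
    event <- as.integer(t_event <= cens)
    time <- pmax(pmin(t_event, cens), 1e-6)
    subtype <- sample(names(subtype_probs), n_p, replace = TRUE,
                      prob = subtype_probs)
    draw_pos <- function(n, cut) cut * (1 + rexp(n, rate = 2))
    draw_neg <- function(n, cut) cut * runif(n)
    esr <- ifelse(subtype %in% c("luminalA", "luminalB"),
                  draw_pos(n_p, cutoffs[["esr"]]),
                  draw_neg(n_p, cutoffs[["esr"]]))
    her2_pos <- subtype == "HER2" |
      (subtype == "luminalB" & runif(n_p) < 0.5)
    her2 <- ifelse(her2_pos, draw_pos(n_p, cutoffs[["her2"]]),
                   draw_neg(n_p, cutoffs[["her2"]]))
    ki_high <- subtype == "luminalB" | runif(n_p) < 0.3
    mki67 <- ifelse(ki_high, draw_pos(n_p, cutoffs[["mki67"]]),
                    draw_neg(n_p, cutoffs[["mki67"]]))
    meta <- data.frame(patient_id = rownames(expr), time = time,
                       event = event, endpoint = "OS",
                       esr_probe = esr, mki67_probe = mki67,
                       her2_probe = her2, stringsAsFactors = FALSE)
    list(cohort = survival_cohort(meta, expr, cutoffs = cutoffs),
         truth = list(score = s, beta = beta, subtype = subtype))
  })
}

#' Simulate a two-group cohort with a known hazard ratio
#'
#' Direct simulation for Cox/logrank parameter recovery: half the patients
#' in each of two groups, exponential event times with rates `h0` and
#' `h0 * hr`, uniform censoring calibrated to `censor_frac`.
#'
#' @param n total patients (split evenly).
#' @param hr true hazard ratio of group `"high"` vs `"low"`.
#' @param h0 baseline hazard.
#' @param censor_frac target censoring fraction.
#' @param seed RNG seed.
#' @return data.frame with `time`, `event`, `high` (logical).
#' @export
generate_twogroup_survival <- function(n = 300, hr = 2, h0 = 0.02,
                                       censor_frac = 0.2, seed = NULL) {
  with_seed(seed, {
    high <- rep(c(FALSE, TRUE), length.out = n)
    t_event <- rexp(n, rate = h0 * ifelse(high, hr, 1))
    if (censor_frac > 0) {
      f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censor_frac
      cmax <- uniroot(f, lower = min(t_event) * 1e-3,
                      upper = max(t_event) * 1e3, tol = 1e-8)$root
      cens <- runif(n, 0, cmax)
    } else {
      cens <- rep(Inf, n)
    }
    data.frame(time = pmax(pmin(t_event, cens), 1e-6),
               event = as.integer(t_event <= cens), high = high)
  })
}

#' Default latent archetypes for simulated Cq plates
#'
#' Mean log2 expression of each panel in each latent state. Epithelial
#' cells express the E panel highly and the M panel at a low but
#' detectable level (they are promiscuous); mesenchymal cells express the
#' M panel highly and the E panel far below detection (they are
#' exclusive); hybrid cells sit at half the pure-state linear level on
#' both panels.
#'
#' @return a 3 x 2 matrix, rows `E`/`hybrid`/`M` states, columns
#'   `E`/`M` panels.
#' @export
default_archetypes <- function() {
  hi <- 6; lo <- 1; off <- -3
  rbind(E = c(E = hi, M = lo),
        hybrid = c(E = hi - 1, M = hi - 1),  # half the pure linear level
        M = c(E = off, M = hi))
}

#' Simulate a single-cell qPCR Cq plate with latent E/hybrid/M states
#'
#' Each cell draws a latent log2 expression per gene from its state
#' archetype (plus cell-to-cell noise); detection is Bernoulli with a
#' logistic probability in the latent log2 expression (dropout); detected
#' reactions report `Cq = cbg - log2(expression) + noise`, values at or
#' beyond the background come out as no amplification. Pooled wells sum
#' 100 latent draws; NTC wells amplify only rarely and late.
#'
#' @param n_e,n_hybrid,n_m single cells per latent state.
#' @param n_pool 100-cell pooled wells (drawn from the E state).
#' @param n_ntc no-template control wells.
#' @param archetypes 3 x 2 matrix of latent log2 panel means
#'   (see [default_archetypes()]).
#' @param cell_sd cell-to-cell standard deviation of latent log2 expression.
#' @param cbg true background cycle.
#' @param noise_sd Cq measurement noise.
#' @param dropout_slope,dropout_mid logistic slope and midpoint of the
#'   detection probability versus latent log2 expression.
#' @param ntc_rate probability that an NTC reaction amplifies (at or above
#'   background).
#' @param seed RNG seed.
#' @return list with `plate` (a [cq_plate()]) and `truth` (list with
#'   per-well `state`).
#' @export
generate_cq_plate <- function(n_e = 24, n_hybrid = 0, n_m = 24, n_pool = 4,
                              n_ntc = 2, archetypes = default_archetypes(),
                              cell_sd = 1, cbg = 24, noise_sd = 0.5,
                              dropout_slope = 1.2, dropout_mid = 1.5,
                              ntc_rate = 0.02, seed = NULL) {
  if (any(!is.finite(archetypes))) stop_input("archetypes must be finite")
  with_seed(seed, {
    panels <- em_panels()
    genes <- c(panels$E, panels$M)
    panel_of <- rep(c("E", "M"), c(length(panels$E), length(panels$M)))
    states <- rep(c("E", "hybrid", "M"), c(n_e, n_hybrid, n_m))
    n_cells <- length(states)
    well_ids <- c(sprintf("c%03d", seq_len(n_cells)),
                  if (n_pool) sprintf("pool%02d", seq_len(n_pool)),
                  if (n_ntc) sprintf("ntc%02d", seq_len(n_ntc)))
    cq <- matrix(NA_real_, length(well_ids), length(genes),
                 dimnames = list(well_ids, genes))
    emit <- function(latent_log2) {
      # latent linear expression -> measured Cq (NA = no amplification)
      p_det <- stats::plogis(dropout_slope * (latent_log2 - dropout_mid))
      det <- runif(length(latent_log2)) < p_det
      cqv <- cbg - latent_log2 + rnorm(length(latent_log2), 0, noise_sd)
      cqv[!det | cqv >= cbg] <- NA_real_
      pmax(cqv, 1e-3)
    }
    for (i in seq_len(n_cells)) {
      mu <- archetypes[states[i], panel_of]
      cq[i, ] <- emit(mu + rnorm(length(genes), 0, cell_sd))
    }
    for (j in seq_len(n_pool)) {
      mu <- archetypes["E", panel_of]
      latent <- vapply(seq_along(genes), function(g)
        sum(2^(mu[g] + rnorm(100, 0, cell_sd))), 0)
      cq[n_cells + j, ] <- emit(log2(latent))
    }
    for (j in seq_len(n_ntc)) {
      amp <- runif(length(genes)) < ntc_rate
      row <- rep(NA_real_, length(genes))
      row[amp] <- cbg + abs(rnorm(sum(amp), 0, 1))
      cq[n_cells + n_pool + j, ] <- row
    }
    wells <- data.frame(
      well_id = well_ids,
      group = c(states, rep("pool_E", n_pool), rep("NTC", n_ntc)),
      cells = c(rep(1L, n_cells), rep(100L, n_pool), rep(0L, n_ntc)),
      ntc = c(rep(FALSE, n_cells + n_pool), rep(TRUE, n_ntc)),
      stringsAsFactors = FALSE)
    list(plate = cq_plate(cq, wells),
         truth = list(state = setNames(
           c(states, rep("pool_E", n_pool), rep("NTC", n_ntc)), well_ids)))
  })
}
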