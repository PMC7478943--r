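#' Grade-driven dose-adjustment rule
#'
#' Encodes a label-style (SmPC-like) capecitabine dose-modification scheme
#' applied at cycle boundaries: grades 0--1 maintain the dose; for grades 2
#' and 3 the n-th occurrence maps to a fraction of the *starting* dose, and
#' occurrences beyond the listed fractions trigger a discontinuation
#' recommendation. The applied dose never increases (no re-escalation).
#'
#' @param grade2 fractions of the starting dose for the 1st, 2nd, ...
#'   occurrence of grade 2; further occurrences recommend discontinuation.
#' @param grade3 same for grade 3.
#' @return object of class `dose_rule`.
#' @export
smpc_rule <- function(grade2 = c(1, 0.75, 0.5), grade3 = c(0.75, 0.5)) {
  for (fr in list(grade2, grade3)) {
    if (any(fr <= 0 | fr > 1) || any(diff(fr) > 0)) {
      stop("dose fractions must be in (0, 1] and non-increasing with occurrence")
    }
  }
  structure(list(grade2 = grade2, grade3 = grade3), class = "dose_rule")
}

# Rule lookup: fraction of starting dose for the k-th occurrence of a grade,
# or NA for "discontinuation recommended".
rule_fraction <- function(rule, grade, occurrence) {
  if (grade <= 1) return(1)
  fr <- if (grade == 2) rule$grade2 else rule$grade3
  if (occurrence <= length(fr)) fr[occurrence] else NA_real_
}

#' Sample body surface areas
#'
#' Normal draws truncated to a physiological range. The default moments are
#' implementer assumptions (documented, not study-reported values).
#'
#' @param n number of draws.
#' @param mean_m2,sd_m2 mean and SD in m^2.
#' @param lower,upper truncation bounds in m^2.
#' @return numeric vector of BSA values.
#' @export
sample_bsa <- function(n, mean_m2 = 1.8, sd_m2 = 0.2,
                       lower = 1.2, upper = 2.6) {
  if (!is.finite(mean_m2) || mean_m2 <= 0 || !is.finite(sd_m2) || sd_m2 < 0) {
    stop("domain error: invalid BSA moments")
  }
  if (sd_m2 == 0) return(rep(pmin(pmax(mean_m2, lower), upper), n))
  plo <- stats::pnorm(lower, mean_m2, sd_m2)
  phi <- stats::pnorm(upper, mean_m2, sd_m2)
  stats::qnorm(runif(n, plo, phi), mean_m2, sd_m2)
}

# nearest daily dose achievable with 150-mg and 500-mg tablets (twice daily,
# equal morning/evening dose)
round_to_tablets <- function(dose) {
  half <- dose / 2
  best <- half
  err <- Inf
  for (b in 0:ceiling(half / 500)) {
    a <- max(0, round((half - b * 500) / 150))
    for (aa in unique(pmax(0, a + (-1:1)))) {
      cand <- aa * 150 + b * 500
      if (abs(cand - half) < err) {
        err <- abs(cand - half)
        best <- cand
      }
    }
  }
  2 * best
}

#' Simulate a virtual dosing scenario
#'
#' Simulates `n_patients` virtual patients for `n_cycles` cycles starting at a
#' BSA-based daily dose of `2 x 1250 x BSA` mg (1250 mg/m^2 twice daily),
#' either at constant dose (`rule = NULL`) or with grade-driven dose
#' adjustments applied after each conducted cycle. Per cycle the probability
#' state is propagated at the current dose, the modal (highest-probability)
#' grade is used to assess toxicity (ties broken toward the lower grade),
#' occurrence counters are updated, and the rule sets the next cycle's dose.
#' Patients for whom discontinuation would be recommended are kept in the
#' analysis at their last assigned dose, so both scenarios keep the same n.
#'
#' With the same `seed`, the random effects and BSA values are identical
#' across calls, so a rule/no-rule pair forms matched scenarios.
#'
#' @param n_patients,n_cycles scenario size.
#' @param params an [mctmm_params()] object.
#' @param rule a [smpc_rule()] or `NULL` for no adjustments.
#' @param bsa_mean,bsa_sd,bsa_range BSA distribution (see [sample_bsa()]).
#' @param reset `"none"` (default) carries the full probability state forward
#'   across cycles, so per-patient probability trajectories evolve smoothly
#'   while the modal grade only drives toxicity assessment and dose decisions;
#'   `"modal"` instead restarts each cycle's propagation from the previous
#'   cycle's modal-grade indicator.
#' @param round_tablets round daily doses to 150/500-mg tablet combinations.
#' @param seed RNG seed.
#' @return object of class `mctmm_scenario`: `summary` data.frame (per
#'   cycle x grade: median probability and order-statistic 95% CI of the
#'   median), `transitions` (4x4 modal-grade transition counts between
#'   consecutive cycles), plus the raw `probs` (n x cycles x 4), `modal`,
#'   `dose` and `discontinued` arrays.
#' @export
run_scenario <- function(n_patients = 1000, n_cycles = 6,
                         params = default_params(), rule = NULL,
                         bsa_mean = 1.8, bsa_sd = 0.2,
                         bsa_range = c(1.2, 2.6),
                         reset = c("none", "modal"),
                         round_tablets = FALSE, seed = NULL) {
  reset <- match.arg(reset)
  stopifnot(inherits(params, "mctmm_params"))
  if (!is.null(rule)) stopifnot(inherits(rule, "dose_rule"))
  with_seed(seed, {
    bsa <- sample_bsa(n_patients, bsa_mean, bsa_sd,
                      bsa_range[1], bsa_range[2])
    eta <- cbind(rnorm(n_patients, 0, params$omega_alpha),
                 rnorm(n_patients, 0, params$omega_met))
    probs <- array(NA_real_, c(n_patients, n_cycles, 4))
    modal <- matrix(NA_integer_, n_patients, n_cycles)
    dose_trail <- matrix(NA_real_, n_patients, n_cycles)
    disc <- logical(n_patients)

    for (i in seq_len(n_patients)) {
      start_dose <- 2 * 1250 * bsa[i]
      if (round_tablets) start_dose <- round_to_tablets(start_dose)
      dose <- start_dose
      cur <- 0L
      state <- c(1, 0, 0, 0)
      occ <- c(0L, 0L)  # occurrences of grade 2, grade 3
      for (cyc in seq_len(n_cycles)) {
        T <- transition_matrix(params, dose, elapsed = 1,
                               eta_alpha = eta[i, 1], eta_met = eta[i, 2])
        if (reset == "modal") {
          pvec <- as.numeric(T[cur + 1, ])
        } else {
          state <- as.numeric(state %*% T)
          pvec <- state
        }
        probs[i, cyc, ] <- pvec
        dose_trail[i, cyc] <- dose
        g <- which.max(pvec) - 1L  # ties -> lower grade
        modal[i, cyc] <- g
        if (g >= 2) occ[g - 1] <- occ[g - 1] + 1L
        cur <- g
        if (!is.null(rule) && cyc < n_cycles) {
          fr <- rule_fraction(rule, g, if (g >= 2) occ[g - 1] else 0L)
          if (is.na(fr)) {
            disc[i] <- TRUE  # recommended; patient kept at current dose
          } else {
            new_dose <- fr * start_dose
            if (round_tablets) new_dose <- round_to_tablets(new_dose)
            dose <- min(dose, new_dose)
          }
        }
      }
    }

    med_ci <- function(x) {
      n <- length(x)
      xs <- sort(x)
      lo <- max(1, stats::qbinom(0.025, n, 0.5))
      hi <- min(n, stats::qbinom(0.975, n, 0.5) + 1)
      c(median = stats::median(x), lo95 = xs[lo], hi95 = xs[hi])
    }
    rows <- expand.grid(cycle = seq_len(n_cycles), grade = 0:3)
    sm <- t(vapply(seq_len(nrow(rows)), function(k) {
      med_ci(probs[, rows$cycle[k], rows$grade[k] + 1])
    }, c(median = 0, lo95 = 0, hi95 = 0)))
    summary <- cbind(rows, as.data.frame(sm))

    trans <- matrix(0L, 4, 4, dimnames = list(from = paste0("grade", 0:3),
                                              to = paste0("grade", 0:3)))
    if (n_cycles >= 2) {
      for (cyc in seq_len(n_cycles - 1)) {
        tb <- table(factor(modal[, cyc], levels = 0:3),
                    factor(modal[, cyc + 1], levels = 0:3))
        trans <- trans + unclass(tb)
      }
    }
    structure(list(summary = summary, transitions = trans, probs = probs,
                   modal = modal, dose = dose_trail, discontinued = disc,
                   bsa = bsa, rule = rule, reset = reset,
                   n_patients = n_patients, n_cycles = n_cycles),
              class = "mctmm_scenario")
  })
}

#' @export
print.mctmm_scenario <- function(x, ...) {
  cat("mCTMM dose-policy scenario:", x$n_patients, "virtual patients,",
      x$n_cycles, "cycles,",
      if (is.null(x$rule)) "no dose adjustments" else "with dose adjustments",
      "\n")
  cat("modal-grade transition counts:\n")
  print(x$transitions)
  invisible(x)
}
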