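#' Design of a synthetic observational cohort
#'
#' Configuration of the virtual study design used by [generate_design()] /
#' [generate_cohort()]: marginal targets mirroring the observed summary of a
#' 150-patient capecitabine cohort (daily dose median 3000 mg in 500-mg steps
#' over 1000--5000 mg, up to six 3-week cycles with on average about five
#' questionnaires per patient, 56 treatment discontinuations of which 25
#' patients kept returning questionnaires with dose set to zero, 39 male /
#' 101 female, tumor entities 71 colorectal / 67 breast / 12 other, 71 on
#' monotherapy, age 28--93 with median 62).
#'
#' @param n_patients cohort size.
#' @param max_cycles maximum number of 3-week cycles.
#' @param dose_levels,dose_weights support and sampling weights of the base
#'   daily dose (mg); combination-therapy patients draw from the lower half
#'   of the support.
#' @param cycles_weights sampling weights of the planned number of
#'   questionnaire occasions 1..`max_cycles` (calibrated so the realized mean
#'   number of observed cycles is about 5.2 after discontinuation truncation).
#' @param n_combination,entity_counts,n_male,n_discontinue exact counts;
#'   `NULL` scales the 150-patient study counts to `n_patients`.
#' @param frac_disc_return fraction of discontinuing patients who keep
#'   returning questionnaires (dose 0 afterwards).
#' @param adherence_probs probabilities of the >100% / 90-100% / <90%
#'   adherence groups (assumed, not reported).
#' @param age_median,age_sd,age_range age distribution (rounded truncated
#'   normal).
#' @param dose_change_prob probability that a patient has one 500-mg dose
#'   reduction at a random cycle.
#' @param miss_prob probability that a non-final questionnaire is missing
#'   (dosing row retained).
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 150, max_cycles = 6,
                          dose_levels = seq(1000, 5000, by = 500),
                          dose_weights = c(2, 3, 6, 10, 40, 10, 6, 3, 2),
                          cycles_weights = c(0.01, 0.01, 0.03, 0.06, 0.14, 0.75),
                          n_combination = NULL, entity_counts = NULL,
                          n_male = NULL, n_discontinue = NULL,
                          frac_disc_return = 25 / 56,
                          adherence_probs = c(0.25, 0.55, 0.20),
                          age_median = 62, age_sd = 13,
                          age_range = c(28, 93),
                          dose_change_prob = 0.15, miss_prob = 0.03) {
  # default counts follow the 150-patient study proportions
  if (is.null(n_combination)) n_combination <- round(79 / 150 * n_patients)
  if (is.null(n_male)) n_male <- round(39 / 150 * n_patients)
  if (is.null(n_discontinue)) n_discontinue <- round(56 / 150 * n_patients)
  if (is.null(entity_counts)) {
    entity_counts <- round(c(colorectal = 71, breast = 67, other = 12) /
                             150 * n_patients)
    entity_counts[1] <- n_patients - sum(entity_counts[-1])
  }
  if (n_combination > n_patients || n_male > n_patients ||
      n_discontinue > n_patients || sum(entity_counts) != n_patients) {
    stop("design error: counts exceed or do not match n_patients")
  }
  if (length(dose_weights) != length(dose_levels)) {
    stop("design error: dose_weights must match dose_levels")
  }
  if (length(cycles_weights) != max_cycles) {
    stop("design error: cycles_weights must have length max_cycles")
  }
  structure(as.list(environment()), class = "cohort_design")
}

#' Generate the design of a synthetic cohort (doses and covariates, no grades)
#'
#' Draws covariates and per-cycle daily doses matching the marginal targets of
#' a [cohort_design()]. Discontinuations truncate dosing (dose 0 afterwards);
#' a configurable fraction of discontinued patients keep returning
#' questionnaires. Grades are left `NA` at every observation occasion.
#'
#' @param design a [cohort_design()].
#' @param seed RNG seed.
#' @return list of subject records (see [read_dataset()] for the equivalent
#'   tabular format; convert with [generate_cohort()] or internal helpers).
#' @export
generate_design <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    n <- design$n_patients
    sex <- rep("female", n)
    sex[sample.int(n, design$n_male)] <- "male"
    entity <- sample(rep(names(design$entity_counts), design$entity_counts))
    mono <- rep(FALSE, n)
    mono[sample.int(n, n - design$n_combination)] <- TRUE
    adherence <- sample(adh_levels, n, replace = TRUE,
                        prob = design$adherence_probs)
    age <- pmin(pmax(round(rnorm(n, design$age_median, design$age_sd)),
                     design$age_range[1]), design$age_range[2])

    lev <- design$dose_levels
    w <- design$dose_weights
    low <- lev <= stats::median(lev)
    dose_base <- numeric(n)
    comb <- !mono
    dose_base[comb] <- sample(lev[low], sum(comb), replace = TRUE,
                              prob = w[low])
    dose_base[!comb] <- sample(lev, sum(!comb), replace = TRUE, prob = w)

    planned <- sample.int(design$max_cycles, n, replace = TRUE,
                          prob = design$cycles_weights)
    disc <- sample.int(n, design$n_discontinue)
    returns <- disc[sample.int(length(disc),
                               round(design$frac_disc_return * length(disc)))]

    records <- vector("list", n)
    for (i in seq_len(n)) {
      nc <- planned[i]
      doses <- rep(dose_base[i], nc)
      if (nc >= 2 && runif(1) < design$dose_change_prob) {
        j <- if (nc == 2) 2L else sample(2:nc, 1)
        doses[j:nc] <- pmax(doses[j:nc] - 500, min(lev))
      }
      if (i %in% disc && nc >= 2) {
        # discontinuation after cycle d: dose 0 from cycle d+1 on
        d <- sample(max(1, nc - 2):(nc - 1), 1)
        if (i %in% returns) {
          doses[(d + 1):nc] <- 0
        } else {
          nc <- d
          doses <- doses[seq_len(nc)]
        }
      }
      observed <- runif(nc) >= design$miss_prob
      observed[nc] <- TRUE  # at least the last occasion is observed
      records[[i]] <- list(
        id = i, age = age[i], sex = sex[i], entity = entity[i],
        mono = mono[i], adherence = adherence[i],
        cycles = data.frame(cycle = seq_len(nc), time = as.numeric(seq_len(nc)),
                            dose = doses, grade = NA_integer_))
      # which occasions will carry an observation once grades are simulated
      attr(records[[i]]$cycles, "observed") <- observed
    }
    records
  })
}

#' Generate a full synthetic cohort with simulated grades
#'
#' Composes [generate_design()] with the mCTMM simulator: grades are sampled
#' from the model at every planned observation occasion, starting from the
#' asymptomatic (grade 0) baseline.
#'
#' @inheritParams generate_design
#' @param params simulation truth, an [mctmm_params()] object (default:
#'   [default_params()]).
#' @param spec covariate specification of the simulating model.
#' @param coefs optional extra natural-scale coefficients.
#' @return dataset `data.frame` in the standard long format (see
#'   [read_dataset()]); compare its [transition_counts()] with the observed
#'   study's from-to table.
#' @export
generate_cohort <- function(design = cohort_design(), params = default_params(),
                            spec = mctmm_covspec(intercept = "dose"),
                            coefs = NULL, seed = NULL) {
  with_seed(seed, {
    records <- generate_design(design)
    cfg <- model_config(params, spec, coefs)
    subjects <- build_subjects(records, spec, cfg$dose_center)
    n <- length(records)
    eta <- cbind(rnorm(n, 0, cfg$wa), rnorm(n, 0, cfg$wm))
    u <- lapply(subjects, function(s) runif(length(s$dt)))
    paths <- cpp_simulate_cohort(subjects, cfg$alpha1, cfg$b2, cfg$b3,
                                 cfg$met, cfg$beta_int, cfg$beta_met, eta, u)
    for (i in seq_len(n)) {
      observed <- attr(records[[i]]$cycles, "observed")
      if (is.null(observed)) observed <- rep(TRUE, nrow(records[[i]]$cycles))
      records[[i]]$cycles$grade[observed] <- paths[[i]][observed]
    }
    records_to_data(records)
  })
}
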