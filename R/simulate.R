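# Rebuild the standard long-format data.frame from a list of subject records.
records_to_data <- function(records) {
  rows <- lapply(records, function(r) {
    nc <- nrow(r$cycles)
    data.frame(ID = r$id,
               CYCLE = c(0L, r$cycles$cycle),
               TIME = c(0, r$cycles$time),
               DOSE = c(NA_real_, r$cycles$dose),
               DV = c(0L, r$cycles$grade),
               AGE = r$age, SEX = r$sex, ENTITY = r$entity,
               MONO = as.integer(r$mono), ADH = r$adherence)
  })
  do.call(rbind, rows)
}

#' Simulate one subject's grade trajectory
#'
#' Draws (or accepts) the subject's random effects and samples the grade at
#' every cycle by walking the continuous-time Markov chain segment by segment
#' from the grade-0 baseline, using the template's dose schedule and times.
#' Grades are reported only at the template's observed cycles.
#'
#' @param template one subject record (or one-subject dataset `data.frame`)
#'   supplying times, doses and the observation pattern.
#' @inheritParams individual_loglik
#' @param eta optional length-2 random-effect values; drawn from
#'   `N(0, diag(omega^2))` when `NULL`.
#' @return the record with simulated grades in place of the observed ones.
#' @export
simulate_subject <- function(template, params,
                             spec = mctmm_covspec(intercept = "dose"),
                             coefs = NULL, eta = NULL) {
  if (is.data.frame(template)) {
    template <- records_from_data(validate_dataset(template))[[1]]
  }
  cfg <- model_config(params, spec, coefs)
  subj <- build_subject(template, spec, cfg$dose_center)
  if (is.null(eta)) eta <- rnorm(2, 0, c(cfg$wa, cfg$wm))
  u <- runif(length(subj$dt))
  path <- cpp_simulate_path(subj, cfg$alpha1, cfg$b2, cfg$b3, cfg$met,
                            cfg$beta_int, cfg$beta_met, eta[1], eta[2], u)
  obs <- !is.na(template$cycles$grade)
  template$cycles$grade[obs] <- path[obs]
  template
}

#' Simulate a replicate dataset on an observed design
#'
#' Simulates every subject of a dataset with [simulate_subject()], reusing the
#' observed design (times, doses, covariates, observation pattern) verbatim.
#'
#' @inheritParams marginal_ofv
#' @param seed RNG seed.
#' @return dataset `data.frame` with simulated `DV`.
#' @export
simulate_dataset <- function(data, params,
                             spec = mctmm_covspec(intercept = "dose"),
                             coefs = NULL, seed = NULL) {
  records <- if (is.data.frame(data)) {
    records_from_data(validate_dataset(data))
  } else data
  cfg <- model_config(params, spec, coefs)
  subjects <- build_subjects(records, spec, cfg$dose_center)
  with_seed(seed, {
    n <- length(records)
    eta <- cbind(rnorm(n, 0, cfg$wa), rnorm(n, 0, cfg$wm))
    u <- lapply(subjects, function(s) runif(length(s$dt)))
    paths <- cpp_simulate_cohort(subjects, cfg$alpha1, cfg$b2, cfg$b3,
                                 cfg$met, cfg$beta_int, cfg$beta_met, eta, u)
    for (i in seq_len(n)) {
      obs <- !is.na(records[[i]]$cycles$grade)
      records[[i]]$cycles$grade[obs] <- paths[[i]][obs]
    }
    records_to_data(records)
  })
}

#' Categorical visual predictive check
#'
#' Simulates `n_sim` replicate datasets on the observed design and, per cycle
#' and grade, computes the 2.5--97.5 empirical percentile band of the
#' simulated proportion of patients at that grade, overlaid with the observed
#' proportion.
#'
#' @inheritParams simulate_dataset
#' @param n_sim number of simulated replicate datasets.
#' @return data.frame of class `mctmm_vpc` with columns `cycle`, `grade`,
#'   `observed_prop`, `lo95`, `hi95`, `n` (subjects observed at that cycle).
#' @export
categorical_vpc <- function(data, params,
                            spec = mctmm_covspec(intercept = "dose"),
                            coefs = NULL, n_sim = 1000, seed = NULL) {
  stopifnot(n_sim >= 1)
  records <- if (is.data.frame(data)) {
    records_from_data(validate_dataset(data))
  } else data
  cfg <- model_config(params, spec, coefs)
  subjects <- build_subjects(records, spec, cfg$dose_center)
  nrec <- length(records)

  # flat index of every observed segment in the concatenated path vector
  seg_len <- vapply(subjects, function(s) length(s$dt), 0L)
  offset <- cumsum(c(0L, seg_len[-nrec]))
  obs_pos <- integer(0)
  obs_cycle <- integer(0)
  obs_grade <- integer(0)
  for (i in seq_len(nrec)) {
    o <- which(!is.na(records[[i]]$cycles$grade))
    obs_pos <- c(obs_pos, offset[i] + o)
    obs_cycle <- c(obs_cycle, records[[i]]$cycles$cycle[o])
    obs_grade <- c(obs_grade, records[[i]]$cycles$grade[o])
  }
  cycles <- sort(unique(obs_cycle))
  cyc_f <- factor(obs_cycle, levels = cycles)
  n_at_cycle <- as.integer(table(cyc_f))

  prop_table <- function(grades) {
    tab <- table(cyc_f, factor(grades, levels = 0:3))
    sweep(unclass(tab), 1, n_at_cycle, "/")
  }
  obs_prop <- prop_table(obs_grade)

  sim_props <- array(NA_real_, c(n_sim, length(cycles), 4))
  with_seed(seed, {
    for (s in seq_len(n_sim)) {
      eta <- cbind(rnorm(nrec, 0, cfg$wa), rnorm(nrec, 0, cfg$wm))
      u <- lapply(subjects, function(x) runif(length(x$dt)))
      paths <- cpp_simulate_cohort(subjects, cfg$alpha1, cfg$b2, cfg$b3,
                                   cfg$met, cfg$beta_int, cfg$beta_met,
                                   eta, u)
      sim_props[s, , ] <- prop_table(unlist(paths)[obs_pos])
    }
  })
  lo <- apply(sim_props, c(2, 3), quantile, probs = 0.025, names = FALSE)
  hi <- apply(sim_props, c(2, 3), quantile, probs = 0.975, names = FALSE)

  out <- data.frame(cycle = rep(cycles, 4),
                    grade = rep(0:3, each = length(cycles)),
                    observed_prop = as.vector(obs_prop),
                    lo95 = as.vector(lo), hi95 = as.vector(hi),
                    n = rep(n_at_cycle, 4))
  class(out) <- c("mctmm_vpc", "data.frame")
  attr(out, "n_sim") <- n_sim
  out
}

#' Plot a categorical VPC
#'
#' Four-panel plot (one per grade) of observed proportions over cycles with
#' the 95% simulation band. Requires ggplot2.
#'
#' @param vpc result of [categorical_vpc()].
#' @return a ggplot object.
#' @export
plot_vpc <- function(vpc) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_vpc requires the ggplot2 package")
  }
  df <- as.data.frame(vpc)
  df$grade_lab <- paste("Grade", df$grade)
  ggplot2::ggplot(df, ggplot2::aes(x = cycle)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo95, ymax = hi95),
                         fill = "grey70", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = observed_prop)) +
    ggplot2::facet_wrap(~grade_lab) +
    ggplot2::labs(x = "Cycle", y = "Proportion of patients") +
    ggplot2::theme_bw()
}
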