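# ---- model configuration: natural-scale parameters -> scaled engine inputs --

# cfg is the flat structure consumed by the C++ kernels: alpha1, b2, b3, met,
# beta_int / beta_met on the scaled-column scale, and the random-effect SDs.
model_config <- function(params, spec, coefs = NULL,
                         dose_center = params$dose_center) {
  stopifnot(inherits(params, "mctmm_params"), inherits(spec, "mctmm_covspec"))
  nat_for <- function(target) {
    cols <- design_colnames(spec[[target]])
    if (!length(cols)) return(numeric(0))
    nat <- setNames(rep(0, length(cols)), cols)
    if (target == "intercept" && "dose" %in% cols) {
      nat["dose"] <- params$theta_dose
    }
    user <- coefs[[target]]
    if (!is.null(user)) {
      if (is.null(names(user))) {
        if (length(user) != length(cols)) {
          stop("configuration error: coefs$", target, " must have length ",
               length(cols))
        }
        nat[] <- user
      } else {
        unknown <- setdiff(names(user), cols)
        if (length(unknown)) {
          stop("configuration error: unknown coefficient(s) ",
               paste(unknown, collapse = ", "))
        }
        nat[names(user)] <- user
      }
    }
    nat
  }
  nat_int <- nat_for("intercept")
  nat_met <- nat_for("met")
  list(alpha1 = params$alpha1, b2 = params$b2, b3 = params$b3,
       met = params$met,
       beta_int = unname(nat_int / design_scales(spec$intercept)),
       beta_met = unname(nat_met / design_scales(spec$met)),
       wa = params$omega_alpha, wm = params$omega_met,
       dose_center = dose_center)
}

# ---- individual and marginal likelihood --------------------------------------

#' Conditional log-likelihood of one subject
#'
#' Log-likelihood of a subject's observed grade sequence given the random
#' effects: the sum over consecutive observation pairs of the log transition
#' probability under the interval's (piecewise-constant) dose, starting from
#' the deterministic grade-0 baseline.
#'
#' @param record one subject record (element of the list produced internally
#'   from a dataset; see [read_dataset()]), or a one-subject dataset
#'   `data.frame`.
#' @param params an [mctmm_params()] object.
#' @param eta length-2 numeric: random effects `(eta_alpha, eta_met)`.
#' @param spec an [mctmm_covspec()]; the default is the final dose-toxicity
#'   model (dose on the logit intercepts, slope taken from
#'   `params$theta_dose`).
#' @param coefs optional natural-scale covariate coefficients (see
#'   [covariate_adjustment()]).
#' @return scalar log-likelihood.
#' @export
individual_loglik <- function(record, params, eta = c(0, 0),
                              spec = mctmm_covspec(intercept = "dose"),
                              coefs = NULL) {
  if (is.data.frame(record)) record <- records_from_data(validate_dataset(record))[[1]]
  cfg <- model_config(params, spec, coefs)
  subj <- build_subject(record, spec, cfg$dose_center)
  -cpp_subject_nll(subj, cfg$alpha1, cfg$b2, cfg$b3, cfg$met,
                   cfg$beta_int, cfg$beta_met, eta[1], eta[2])
}

# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) by Golub-Welsch.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- a
  J[cbind(i + 1, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Adaptive Gauss-Hermite -log marginal likelihood for one subject: nodes are
# centered at the penalised-likelihood mode and scaled by the inverse
# square-root curvature.
agq_subject_nll <- function(subj, cfg, nodes = 21) {
  active <- c(cfg$wa, cfg$wm) > 1e-8
  d <- sum(active)
  nll <- function(ea, em) {
    cpp_subject_nll(subj, cfg$alpha1, cfg$b2, cfg$b3, cfg$met,
                    cfg$beta_int, cfg$beta_met, ea, em)
  }
  if (d == 0) return(nll(0, 0))
  em_fit <- cpp_eta_mode(subj, cfg$alpha1, cfg$b2, cfg$b3, cfg$met,
                         cfg$beta_int, cfg$beta_met, cfg$wa, cfg$wm)
  mode_act <- em_fit$eta[active]
  H <- (em_fit$hessian + t(em_fit$hessian)) / 2
  L <- t(chol(solve(H)))
  gh <- gauss_hermite(nodes)
  if (d == 1) {
    Z <- matrix(gh$nodes, ncol = 1)
    logw <- log(gh$weights) + gh$nodes^2
  } else {
    g <- expand.grid(i = seq_len(nodes), j = seq_len(nodes))
    Z <- cbind(gh$nodes[g$i], gh$nodes[g$j])
    logw <- log(gh$weights[g$i]) + gh$nodes[g$i]^2 +
      log(gh$weights[g$j]) + gh$nodes[g$j]^2
  }
  w_act <- c(cfg$wa, cfg$wm)[active]
  lt <- vapply(seq_len(nrow(Z)), function(k) {
    eta_act <- mode_act + sqrt(2) * as.numeric(L %*% Z[k, ])
    eta_full <- c(0, 0)
    eta_full[active] <- eta_act
    -nll(eta_full[1], eta_full[2]) +
      sum(dnorm(eta_act, 0, w_act, log = TRUE)) + logw[k]
  }, 0)
  logmarg <- (d / 2) * log(2) + sum(log(diag(L))) + logsumexp(lt)
  -logmarg
}

#' Marginal objective function value (OFV)
#'
#' Minus twice the log marginal likelihood of the cohort at given population
#' parameters: the subject-level random effects are integrated out either by
#' the Laplace approximation at the per-subject mode (the estimation method)
#' or by adaptive Gauss-Hermite quadrature (the higher-accuracy cross-check).
#'
#' @param data dataset `data.frame` (see [read_dataset()]) or a list of
#'   subject records.
#' @inheritParams individual_loglik
#' @param method `"laplace"` or `"agq"`.
#' @param nodes quadrature nodes per random-effect dimension for `"agq"`.
#' @return scalar OFV.
#' @export
marginal_ofv <- function(data, params,
                         spec = mctmm_covspec(intercept = "dose"),
                         coefs = NULL, method = c("laplace", "agq"),
                         nodes = 21) {
  method <- match.arg(method)
  records <- if (is.data.frame(data)) {
    records_from_data(validate_dataset(data))
  } else data
  cfg <- model_config(params, spec, coefs)
  subjects <- build_subjects(records, spec, cfg$dose_center)
  if (method == "laplace") {
    cpp_cohort_ofv_laplace(subjects, cfg$alpha1, cfg$b2, cfg$b3, cfg$met,
                           cfg$beta_int, cfg$beta_met, cfg$wa, cfg$wm)
  } else {
    2 * sum(vapply(subjects, agq_subject_nll, 0, cfg = cfg, nodes = nodes))
  }
}

# ---- parameter packing for the optimizer -------------------------------------

# Transformed scale: alpha1 and the covariate coefficients unconstrained,
# log(-b2), log(-b3), log(met), log(omega) for the constrained parameters.
pack_info <- function(spec, fix_omega = NULL) {
  int_cols <- design_colnames(spec$intercept)
  met_cols <- design_colnames(spec$met)
  est_wa <- !("omega_alpha" %in% names(fix_omega))
  est_wm <- !("omega_met" %in% names(fix_omega))
  nm <- c("alpha1", "lb2", "lb3", "lmet",
          if (length(int_cols)) paste0("bi.", int_cols),
          if (length(met_cols)) paste0("bm.", met_cols),
          if (est_wa) "lwa", if (est_wm) "lwm")
  list(names = nm, int_cols = int_cols, met_cols = met_cols,
       int_scales = design_scales(spec$intercept),
       met_scales = design_scales(spec$met),
       est_wa = est_wa, est_wm = est_wm,
       fix_wa = if (!est_wa) unname(fix_omega["omega_alpha"]) else NA_real_,
       fix_wm = if (!est_wm) unname(fix_omega["omega_met"]) else NA_real_)
}

pack_start <- function(start, info, spec) {
  cfg <- model_config(start$params, spec, start$coefs)
  v <- c(cfg$alpha1, log(-cfg$b2), log(-cfg$b3), log(cfg$met),
         cfg$beta_int, cfg$beta_met,
         if (info$est_wa) log(max(cfg$wa, 1e-3)),
         if (info$est_wm) log(max(cfg$wm, 1e-3)))
  setNames(v, info$names)
}

unpack_par <- function(par, info) {
  ni <- length(info$int_cols)
  nm <- length(info$met_cols)
  k <- 4
  beta_int <- if (ni) par[(k + 1):(k + ni)] else numeric(0)
  k <- k + ni
  beta_met <- if (nm) par[(k + 1):(k + nm)] else numeric(0)
  k <- k + nm
  wa <- if (info$est_wa) exp(par[(k <- k + 1)]) else info$fix_wa
  wm <- if (info$est_wm) exp(par[k + 1]) else info$fix_wm
  list(alpha1 = unname(par[1]), b2 = -exp(unname(par[2])),
       b3 = -exp(unname(par[3])), met = exp(unname(par[4])),
       beta_int = unname(beta_int), beta_met = unname(beta_met),
       wa = unname(wa), wm = unname(wm))
}

# ---- fitting -----------------------------------------------------------------

#' Fit the mCTMM by marginal maximum likelihood
#'
#' Minimizes the marginal OFV (Laplace approximation by default) over the
#' transformed parameter space (log scale for MET, the omegas and the negated
#' intercept increments). Standard errors come from the finite-difference
#' Hessian of the OFV at the optimum: `cov = 2 * solve(H_OFV)` on the
#' transformed scale, mapped to the natural scale by the delta method.
#'
#' @inheritParams marginal_ofv
#' @param start starting values: an [mctmm_params()] object, optionally with
#'   a `coefs` attribute-style list via `start_coefs`; `NULL` uses generic
#'   defaults.
#' @param start_coefs optional list of natural-scale starting coefficients
#'   for covariates beyond the dose slope.
#' @param fix_omega optional named numeric, e.g.
#'   `c(omega_alpha = 0, omega_met = 0)`, fixing random-effect SDs instead of
#'   estimating them.
#' @param se compute standard errors (skipped e.g. inside the bootstrap).
#' @param quiet suppress progress messages.
#' @param control passed to [stats::nlminb()].
#' @return object of class `mctmm_fit` with elements `params` (the estimated
#'   [mctmm_params()]), `coefs` (natural-scale covariate coefficients),
#'   `table` (estimate / SE / RSE% per parameter), `ofv`, `convergence`,
#'   `n_subjects`, `n_obs`.
#' @export
mctmm_fit <- function(data, spec = mctmm_covspec(intercept = "dose"),
                      start = NULL, start_coefs = NULL,
                      method = c("laplace", "agq"), fix_omega = NULL,
                      dose_center = 3000, nodes = 21, se = TRUE,
                      quiet = FALSE, control = list()) {
  method <- match.arg(method)
  records <- if (is.data.frame(data)) {
    records_from_data(validate_dataset(data))
  } else data
  records <- drop_empty_records(records, quiet = quiet)
  if (!length(records)) stop("no subjects with post-baseline observations")
  subjects <- build_subjects(records, spec, dose_center)
  n_obs <- sum(vapply(subjects, function(s) sum(s$obs >= 0), 0L))

  info <- pack_info(spec, fix_omega)
  if (is.null(start)) {
    start <- mctmm_params(alpha1 = 1, b2 = -1.5, b3 = -1.5, met = 1,
                          theta_dose = if ("dose" %in% spec$intercept) 5e-4 else 0,
                          omega_alpha = 0.5, omega_met = 0.5,
                          dose_center = dose_center)
  }
  par0 <- pack_start(list(params = start, coefs = start_coefs), info, spec)

  objective <- function(par) {
    u <- unpack_par(par, info)
    if (method == "laplace") {
      cpp_cohort_ofv_laplace(subjects, u$alpha1, u$b2, u$b3, u$met,
                             u$beta_int, u$beta_met, u$wa, u$wm)
    } else {
      cfg <- c(u, list(dose_center = dose_center))
      2 * sum(vapply(subjects, agq_subject_nll, 0, cfg = cfg, nodes = nodes))
    }
  }

  # central-difference gradient with a step well above the objective's
  # numerical noise floor (the inner Laplace mode is found to ~1e-8, which
  # leaves ~1e-6 roughness in the OFV; default optimizer steps are too small)
  gradient <- function(par) {
    vapply(seq_along(par), function(i) {
      e <- rep(0, length(par)); e[i] <- 1e-4
      (objective(par + e) - objective(par - e)) / 2e-4
    }, 0)
  }

  nb <- length(par0) - 4 - info$est_wa - info$est_wm
  lower <- c(-20, log(1e-3), log(1e-3), log(1e-3), rep(-50, nb),
             if (info$est_wa) log(1e-4), if (info$est_wm) log(1e-4))
  upper <- c(20, log(30), log(30), log(50), rep(50, nb),
             if (info$est_wa) log(20), if (info$est_wm) log(20))
  ctrl <- utils::modifyList(list(iter.max = 500, eval.max = 2000,
                                 rel.tol = 1e-8), control)
  opt <- nlminb(par0, objective, gradient = gradient, lower = lower,
                upper = upper, control = ctrl)

  grad <- gradient(opt$par)
  # nlminb reports "false convergence" when the line search stalls on the
  # objective's noise floor; with a small gradient that is convergence
  converged <- opt$convergence == 0 || sqrt(sum(grad^2)) < 5

  u <- unpack_par(opt$par, info)
  nat <- c(alpha1 = u$alpha1, b2 = u$b2, b3 = u$b3, met = u$met,
           if (length(info$int_cols))
             setNames(u$beta_int * info$int_scales,
                      paste0("beta_int.", info$int_cols)),
           if (length(info$met_cols))
             setNames(u$beta_met * info$met_scales,
                      paste0("beta_met.", info$met_cols)),
           omega_alpha = u$wa, omega_met = u$wm)
  if ("beta_int.dose" %in% names(nat)) {
    names(nat)[names(nat) == "beta_int.dose"] <- "theta_dose"
  }

  se_nat <- rep(NA_real_, length(nat))
  cov_t <- NULL
  if (se) {
    H <- fd_hessian(objective, opt$par, eps = 5e-3)
    cov_t <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) {
      if (!quiet) warning("singular OFV Hessian; ridged for standard errors")
      2 * solve((H + t(H)) / 2 + diag(1e-4, nrow(H)))
    })
    se_t <- sqrt(pmax(diag(cov_t), 0))
    # delta method: d(natural)/d(transformed) is diagonal here
    jac <- c(1, abs(u$b2), abs(u$b3), u$met,
             if (length(info$int_cols)) info$int_scales,
             if (length(info$met_cols)) info$met_scales,
             if (info$est_wa) u$wa, if (info$est_wm) u$wm)
    se_full <- se_t * jac
    keep <- rep(TRUE, length(nat))
    if (!info$est_wa) keep[names(nat) == "omega_alpha"] <- FALSE
    if (!info$est_wm) keep[names(nat) == "omega_met"] <- FALSE
    se_nat[keep] <- se_full
  }

  theta_dose <- if ("theta_dose" %in% names(nat)) nat[["theta_dose"]] else 0
  est_params <- mctmm_params(alpha1 = nat[["alpha1"]], b2 = nat[["b2"]],
                             b3 = nat[["b3"]], met = nat[["met"]],
                             theta_dose = theta_dose,
                             omega_alpha = nat[["omega_alpha"]],
                             omega_met = nat[["omega_met"]],
                             dose_center = dose_center)
  coef_int <- if (length(info$int_cols)) {
    setNames(u$beta_int * info$int_scales, info$int_cols)
  } else numeric(0)
  coef_met <- if (length(info$met_cols)) {
    setNames(u$beta_met * info$met_scales, info$met_cols)
  } else numeric(0)

  structure(list(
    params = est_params,
    coefs = list(intercept = coef_int, met = coef_met),
    table = data.frame(parameter = names(nat), estimate = unname(nat),
                       se = se_nat,
                       rse_pct = 100 * se_nat / abs(unname(nat))),
    ofv = opt$objective,
    convergence = list(converged = converged, code = opt$convergence,
                       message = opt$message, iterations = opt$iterations,
                       grad_norm = sqrt(sum(grad^2))),
    n_subjects = length(records), n_obs = n_obs,
    spec = spec, dose_center = dose_center, method = method,
    transformed = list(par = opt$par, info = info, cov = cov_t),
    se_note = "SE = sqrt(diag(2 * solve(H_OFV))), delta method to natural scale; LRT df = number of added parameters"
  ), class = "mctmm_fit")
}

#' @export
print.mctmm_fit <- function(x, ...) {
  cat("mCTMM fit (", x$method, " marginal likelihood)\n", sep = "")
  cat("  subjects:", x$n_subjects, "  observations:", x$n_obs, "\n")
  cat("  OFV:", format(x$ofv, digits = 8), " converged:",
      x$convergence$converged, "\n\n")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$rse_pct <- signif(tab$rse_pct, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# ---- likelihood-ratio test ---------------------------------------------------

#' Likelihood-ratio test between nested mCTMM fits
#'
#' Chi-square test of the OFV drop when parameters are added to a nested
#' model. The decision threshold is p <= 0.01, i.e. an OFV decrease of at
#' least 6.64 for one added parameter.
#'
#' @param ofv_reduced,ofv_full OFVs of the reduced and full model (or
#'   `mctmm_fit` objects).
#' @param df number of added parameters (1 or 2).
#' @return list of class `mctmm_lrt`: `delta_ofv` (full minus reduced),
#'   `df`, `p_value`, `significant` (at p <= 0.01).
#' @export
likelihood_ratio_test <- function(ofv_reduced, ofv_full, df = 1) {
  if (inherits(ofv_reduced, "mctmm_fit")) ofv_reduced <- ofv_reduced$ofv
  if (inherits(ofv_full, "mctmm_fit")) ofv_full <- ofv_full$ofv
  if (!df %in% c(1, 2)) stop("df must be 1 or 2")
  delta <- ofv_full - ofv_reduced
  stat <- max(-delta, 0)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(delta_ofv = delta, df = df, p_value = p,
                 significant = p <= 0.01),
            class = "mctmm_lrt")
}

#' @export
print.mctmm_lrt <- function(x, ...) {
  cat(sprintf("LRT: dOFV = %.3f (df = %d), p = %.4g -> %s at p <= 0.01\n",
              x$delta_ofv, x$df, x$p_value,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Univariate covariate screen
#'
#' Fits the base model and, for each candidate effect, the base model extended
#' by that single covariate effect, and tabulates the likelihood-ratio test
#' against the base model (adherence contributes two indicators, hence 2 df).
#'
#' @inheritParams mctmm_fit
#' @param effects list of `c(covariate, target)` pairs; the default screens
#'   every allowed covariate on both the logit intercepts and MET.
#' @param base_fit optional pre-computed base-model fit.
#' @return data.frame with one row per candidate effect: `covariate`,
#'   `target`, `delta_ofv`, `df`, `p_value`, `significant`.
#' @export
covariate_screen <- function(data, effects = NULL, base_fit = NULL,
                             start = NULL, dose_center = 3000,
                             quiet = TRUE, ...) {
  records <- if (is.data.frame(data)) {
    records_from_data(validate_dataset(data))
  } else data
  if (is.null(effects)) {
    covs <- c("sex", "dose", "mono", "breast", "colorectal", "other",
              "age", "adherence", "time")
    effects <- c(lapply(covs, function(v) c(v, "intercept")),
                 lapply(covs, function(v) c(v, "met")))
  }
  if (is.null(base_fit)) {
    base_fit <- mctmm_fit(records, spec = mctmm_covspec(), start = start,
                          dose_center = dose_center, se = FALSE,
                          quiet = quiet, ...)
  }
  rows <- lapply(effects, function(e) {
    spec <- if (e[2] == "intercept") {
      mctmm_covspec(intercept = e[1])
    } else {
      mctmm_covspec(met = e[1])
    }
    df <- length(design_colnames(e[1]))
    fit <- tryCatch(
      mctmm_fit(records, spec = spec, start = base_fit$params,
                dose_center = dose_center, se = FALSE, quiet = quiet, ...),
      error = function(err) NULL)
    if (is.null(fit)) {
      return(data.frame(covariate = e[1], target = e[2], delta_ofv = NA,
                        df = df, p_value = NA, significant = NA))
    }
    lrt <- likelihood_ratio_test(base_fit$ofv, fit$ofv, df = df)
    data.frame(covariate = e[1], target = e[2], delta_ofv = lrt$delta_ofv,
               df = df, p_value = lrt$p_value, significant = lrt$significant)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_ofv") <- base_fit$ofv
  out
}

# ---- non-parametric bootstrap ------------------------------------------------

#' Non-parametric bootstrap of an mCTMM fit
#'
#' Resamples subjects with replacement to the original cohort size, refits
#' each replicate (starting from the original estimates), and reports the
#' per-parameter median and percentile 95% confidence interval. Failed
#' replicates are excluded and counted; more than 20% failures triggers a
#' warning.
#'
#' @inheritParams mctmm_fit
#' @param fit the original `mctmm_fit` (supplies spec, dose centering and
#'   starting values).
#' @param n_replicates number of bootstrap datasets.
#' @param seed RNG seed for reproducible resampling.
#' @return object of class `mctmm_bootstrap`: `summary` data.frame
#'   (`parameter`, `estimate`, `median`, `lo95`, `hi95`), `replicates`
#'   matrix, `n_fail`.
#' @export
mctmm_bootstrap <- function(data, fit, n_replicates = 1000, seed = NULL,
                            quiet = TRUE, control = list()) {
  stopifnot(inherits(fit, "mctmm_fit"), n_replicates >= 1)
  records <- if (is.data.frame(data)) {
    records_from_data(validate_dataset(data))
  } else data
  n <- length(records)
  par_names <- fit$table$parameter
  with_seed(seed, {
    reps <- matrix(NA_real_, n_replicates, length(par_names),
                   dimnames = list(NULL, par_names))
    n_fail <- 0L
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot_records <- records[idx]
      for (k in seq_along(boot_records)) boot_records[[k]]$id <- k
      rfit <- tryCatch(
        mctmm_fit(boot_records, spec = fit$spec, start = fit$params,
                  start_coefs = fit$coefs, dose_center = fit$dose_center,
                  se = FALSE, quiet = TRUE, control = control),
        error = function(e) NULL)
      if (is.null(rfit) || any(!is.finite(rfit$table$estimate))) {
        n_fail <- n_fail + 1L
      } else {
        reps[b, ] <- rfit$table$estimate
      }
    }
    ok <- stats::complete.cases(reps)
    if (n_fail > 0.2 * n_replicates) {
      warning("bootstrap: ", n_fail, " of ", n_replicates,
              " replicates failed (> 20%)")
    }
    qs <- apply(reps[ok, , drop = FALSE], 2, quantile,
                probs = c(0.025, 0.5, 0.975), names = FALSE)
    structure(list(
      summary = data.frame(parameter = par_names,
                           estimate = fit$table$estimate,
                           median = qs[2, ], lo95 = qs[1, ], hi95 = qs[3, ]),
      replicates = reps[ok, , drop = FALSE],
      n_fail = n_fail, n_replicates = n_replicates),
      class = "mctmm_bootstrap")
  })
}

#' @export
print.mctmm_bootstrap <- function(x, ...) {
  cat("mCTMM non-parametric bootstrap:",
      nrow(x$replicates), "successful /", x$n_replicates, "replicates\n")
  tab <- x$summary
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
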