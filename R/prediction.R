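#' Empirical-Bayes (MAP) random effects for one subject
#'
#' Maximizes `log L_i(eta) + log phi(eta; Omega)` over the subject's random
#' effects with population parameters fixed, using the observations available
#' in the (possibly truncated) record. With no observations the prior mode
#' `eta = 0` is returned.
#'
#' @inheritParams individual_loglik
#' @return length-2 numeric `(eta_alpha, eta_met)`.
#' @export
map_eta <- function(record, params,
                    spec = mctmm_covspec(intercept = "dose"), coefs = NULL) {
  if (is.data.frame(record)) {
    record <- records_from_data(validate_dataset(record))[[1]]
  }
  cfg <- model_config(params, spec, coefs)
  subj <- build_subject(record, spec, cfg$dose_center)
  em <- cpp_eta_mode(subj, cfg$alpha1, cfg$b2, cfg$b3, cfg$met,
                     cfg$beta_int, cfg$beta_met, cfg$wa, cfg$wm)
  setNames(as.numeric(em$eta), c("eta_alpha", "eta_met"))
}

# truncate a record to observations strictly before `cycle`, keeping the
# dosing rows up to and including `cycle`
truncate_record <- function(record, cycle) {
  keep <- record$cycles$cycle <= cycle
  r <- record
  r$cycles <- record$cycles[keep, , drop = FALSE]
  r$cycles$grade[r$cycles$cycle >= cycle] <- NA_integer_
  r
}

#' Predict the next cycle's grade for one subject
#'
#' One-interval propagation from the subject's last observed grade to the
#' target cycle at the known (piecewise per-cycle) doses, using given random
#' effects (typically the MAP estimates from the preceding cycles). The modal
#' grade is the argmax of the propagated distribution, ties broken toward the
#' lower grade.
#'
#' @inheritParams individual_loglik
#' @param cycle target cycle to predict; dosing rows up to this cycle must be
#'   present in the record.
#' @param eta random-effect values, e.g. from [map_eta()].
#' @return list with `dist` (probability vector over grades 0--3) and
#'   `modal` (predicted grade).
#' @export
predict_next_cycle <- function(record, cycle, params, eta = c(0, 0),
                               spec = mctmm_covspec(intercept = "dose"),
                               coefs = NULL) {
  if (is.data.frame(record)) {
    record <- records_from_data(validate_dataset(record))[[1]]
  }
  seg <- record$cycles
  if (!cycle %in% seg$cycle) {
    stop("missing next dose: no dosing row for cycle ", cycle)
  }
  prior <- seg[seg$cycle < cycle, , drop = FALSE]
  obs_prior <- prior[!is.na(prior$grade), , drop = FALSE]
  if (nrow(obs_prior)) {
    last_grade <- obs_prior$grade[nrow(obs_prior)]
    last_time <- obs_prior$time[nrow(obs_prior)]
  } else {
    last_grade <- 0L
    last_time <- 0
  }
  span <- seg[seg$time > last_time & seg$cycle <= cycle, , drop = FALSE]
  cfg <- model_config(params, spec, coefs)
  gadd <- if (length(cfg$beta_int)) {
    as.numeric(design_matrix(spec$intercept, record, span,
                             cfg$dose_center) %*% cfg$beta_int)
  } else rep(0, nrow(span))
  metl <- if (length(cfg$beta_met)) {
    as.numeric(design_matrix(spec$met, record, span,
                             cfg$dose_center) %*% cfg$beta_met)
  } else rep(0, nrow(span))
  dts <- diff(c(last_time, span$time))
  state <- diag(4)[last_grade + 1, ]
  for (k in seq_len(nrow(span))) {
    T <- cpp_transition_matrix(cfg$alpha1, cfg$b2, cfg$b3,
                               gadd[k] + eta[1],
                               cfg$met * exp(eta[2] + metl[k]), dts[k])
    state <- as.numeric(state %*% T)
  }
  dist <- setNames(state, paste0("grade", 0:3))
  list(dist = dist, modal = unname(which.max(dist)) - 1L)
}

#' Individual prediction table
#'
#' For every subject and every observed cycle from 2 on, estimates the MAP
#' random effects from the preceding cycles and predicts the cycle's modal
#' grade from the last observed grade at the known dose. Baseline (cycle 0)
#' is deterministic and excluded.
#'
#' @inheritParams marginal_ofv
#' @return data.frame of class `mctmm_predictions`: `id`, `cycle`,
#'   `predicted`, `observed`, and the clinically relevant grouping flags
#'   `predicted_ge2`, `observed_ge2`.
#' @export
prediction_table <- function(data, params,
                             spec = mctmm_covspec(intercept = "dose"),
                             coefs = NULL) {
  records <- if (is.data.frame(data)) {
    records_from_data(validate_dataset(data))
  } else data
  rows <- list()
  for (r in records) {
    obs_cycles <- r$cycles$cycle[!is.na(r$cycles$grade)]
    for (cyc in obs_cycles[obs_cycles >= 2]) {
      prefix <- truncate_record(r, cyc)
      eta <- map_eta(prefix, params, spec, coefs)
      pred <- predict_next_cycle(r, cyc, params, eta, spec, coefs)
      obs <- r$cycles$grade[r$cycles$cycle == cyc]
      rows[[length(rows) + 1]] <- data.frame(
        id = r$id, cycle = cyc, predicted = pred$modal, observed = obs)
    }
  }
  out <- do.call(rbind, rows)
  out$predicted_ge2 <- out$predicted >= 2
  out$observed_ge2 <- out$observed >= 2
  class(out) <- c("mctmm_predictions", "data.frame")
  out
}

#' Positive and negative predictive value of grade >= 2 predictions
#'
#' PPV = correctly predicted grade >= 2 events / all predicted grade >= 2
#' events; NPV = correctly predicted grade <= 1 events / all predicted
#' grade <= 1 events. Empty denominators yield `NA`.
#'
#' @param table a [prediction_table()] (or any data.frame with `predicted`
#'   and `observed` grade columns).
#' @param by_cycle also return per-cycle values.
#' @return if `by_cycle = FALSE`, named numeric `c(ppv, npv)`; otherwise a
#'   data.frame with one row per cycle plus a pooled row.
#' @export
ppv_npv <- function(table, by_cycle = FALSE) {
  if (!nrow(table)) stop("empty prediction table")
  one <- function(tab) {
    pos <- tab$predicted >= 2
    neg <- !pos
    ppv <- if (any(pos)) sum(tab$observed[pos] >= 2) / sum(pos) else NA_real_
    npv <- if (any(neg)) sum(tab$observed[neg] <= 1) / sum(neg) else NA_real_
    c(ppv = ppv, npv = npv)
  }
  if (!by_cycle) return(one(table))
  cycles <- sort(unique(table$cycle))
  out <- do.call(rbind, lapply(cycles, function(cyc) {
    v <- one(table[table$cycle == cyc, , drop = FALSE])
    data.frame(cycle = as.character(cyc), n = sum(table$cycle == cyc),
               ppv = v["ppv"], npv = v["npv"])
  }))
  v <- one(table)
  rbind(out, data.frame(cycle = "pooled", n = nrow(table),
                        ppv = v["ppv"], npv = v["npv"]))
}
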