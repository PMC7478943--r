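#' Build the 4x4 generator of the mCTMM
#'
#' Constructs the tridiagonal continuous-time transition-rate matrix from a
#' target grade distribution and an (individual) mean equilibration time:
#' `K(i -> j) = p_j / (met * (p_i + p_j))` for adjacent grades j, so that
#' each adjacent pair of states, taken in isolation, equilibrates with time
#' constant exactly `met`. The construction satisfies detailed balance
#' `p_i K(i->j) = p_j K(j->i)` exactly, so the target distribution is the
#' stationary distribution of the chain.
#'
#' @param target probability vector over grades 0--3 (floored at 1e-12 and
#'   renormalized before rate construction).
#' @param met mean equilibration time in cycles (> 0).
#' @return 4x4 rate matrix (rows sum to zero), units 1/cycle.
#' @export
build_generator <- function(target, met) {
  if (!is.numeric(met) || length(met) != 1 || !is.finite(met) || met <= 0) {
    stop("domain error: met must be a single positive number")
  }
  p <- as.numeric(target)
  if (length(p) != 4 || any(!is.finite(p)) || any(p < 0)) {
    stop("domain error: target must be 4 non-negative probabilities")
  }
  p <- pmax(p, 1e-12)
  p <- p / sum(p)
  q <- matrix(0, 4, 4, dimnames = list(paste0("grade", 0:3),
                                       paste0("grade", 0:3)))
  for (i in 1:3) {
    s <- met * (p[i] + p[i + 1])
    q[i, i + 1] <- p[i + 1] / s
    q[i + 1, i] <- p[i] / s
  }
  diag(q) <- -rowSums(q)
  q
}

#' Stationary distribution of a generator matrix
#'
#' Solves `pi Q = 0` with `sum(pi) = 1` by a least-squares linear solve.
#'
#' @param q a 4x4 generator (rows summing to zero).
#' @return probability vector over grades 0--3.
#' @export
stationary_distribution <- function(q) {
  A <- rbind(t(q), rep(1, ncol(q)))
  pi <- qr.solve(A, c(rep(0, nrow(q)), 1))
  setNames(as.numeric(pi), paste0("grade", 0:3))
}

#' Propagate state probabilities of the mCTMM
#'
#' Solves the probability-compartment differential equations over a
#' constant-dose interval by the matrix exponential, starting from the
#' indicator distribution of `start_grade` (the Markov reset at an
#' observation).
#'
#' @param gen generator matrix from [build_generator()].
#' @param start_grade integer grade 0--3 occupied at interval start.
#' @param elapsed interval length in cycles (>= 0).
#' @return probability vector over grades 0--3 at interval end.
#' @export
propagate <- function(gen, start_grade, elapsed) {
  if (!is.numeric(elapsed) || length(elapsed) != 1 || !is.finite(elapsed) ||
      elapsed < 0) {
    stop("domain error: elapsed must be a single non-negative number")
  }
  if (!start_grade %in% 0:3) stop("domain error: start_grade must be 0..3")
  T <- cpp_expm(unname(as.matrix(gen)), elapsed)
  setNames(as.numeric(T[start_grade + 1, ]), paste0("grade", 0:3))
}

#' Interval transition matrix of the mCTMM
#'
#' Probability of occupying grade j at interval end given grade i at interval
#' start, for a dose history that is piecewise constant over sub-intervals
#' (e.g. per treatment cycle). Stacks [propagate()] over all four start
#' grades; with several sub-intervals the per-segment matrices are multiplied
#' in time order (Chapman-Kolmogorov).
#'
#' @param params an [mctmm_params()] object.
#' @param dose numeric vector of daily doses (mg), one per sub-interval.
#' @param elapsed sub-interval lengths in cycles (same length as `dose`,
#'   default all 1).
#' @param eta_alpha,eta_met individual random-effect values; MET is
#'   individualized as `met * exp(eta_met)`.
#' @param extra additional per-sub-interval additive logit adjustment
#'   (recycled).
#' @return 4x4 stochastic matrix (rows sum to 1).
#' @export
transition_matrix <- function(params, dose, elapsed = rep(1, length(dose)),
                              eta_alpha = 0, eta_met = 0, extra = 0) {
  stopifnot(inherits(params, "mctmm_params"))
  if (length(elapsed) != length(dose)) {
    stop("domain error: dose and elapsed must have equal length")
  }
  extra <- rep_len(extra, length(dose))
  met_i <- params$met * exp(eta_met)
  T <- diag(4)
  for (k in seq_along(dose)) {
    l <- cumulative_logits(params, dose[k], eta_alpha = eta_alpha,
                           extra = extra[k])
    p <- grade_distribution(l)
    T <- T %*% cpp_expm(build_generator(p, met_i), elapsed[k])
  }
  dimnames(T) <- list(paste0("grade", 0:3), paste0("grade", 0:3))
  T
}
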