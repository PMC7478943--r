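#' Cumulative logits of the proportional-odds model
#'
#' Computes the three cumulative logits `logit P(grade >= n)`, n = 1..3, for
#' one subject-occasion: ordered intercepts plus the centered linear dose term
#' plus any additional logit-scale adjustment (covariates, random effect).
#'
#' @param params an [mctmm_params()] object.
#' @param daily_dose absolute daily dose in mg (0 after discontinuation).
#' @param eta_alpha additive subject-level deviation on the logit intercepts.
#' @param extra additional additive logit-scale adjustment (e.g. from
#'   [covariate_adjustment()]).
#' @param dose_center centering dose in mg; defaults to the value stored in
#'   `params`.
#' @return numeric vector of length 3, strictly decreasing.
#' @examples
#' cumulative_logits(default_params(), daily_dose = 3000)  # 1.81 0.01 -2.07
#' @export
cumulative_logits <- function(params, daily_dose, eta_alpha = 0, extra = 0,
                              dose_center = params$dose_center) {
  stopifnot(inherits(params, "mctmm_params"))
  if (!is.finite(daily_dose) || daily_dose < 0) {
    stop("invalid parameter: daily_dose must be finite and >= 0")
  }
  if (!is.finite(eta_alpha) || !is.finite(extra)) {
    stop("invalid parameter: eta_alpha and extra must be finite")
  }
  if (dose_center <= 0) stop("invalid parameter: dose_center must be > 0")
  g <- params$theta_dose * (daily_dose - dose_center) + extra + eta_alpha
  a <- c(params$alpha1,
         params$alpha1 + params$b2,
         params$alpha1 + params$b2 + params$b3)
  a + g
}

#' Grade probabilities from cumulative logits
#'
#' Maps three strictly decreasing cumulative logits to the probability vector
#' over grades 0--3 via the inverse logit:
#' `P(grade = n) = expit(l_n) - expit(l_{n+1})` with `expit(l_0) = 1` and
#' `expit(l_4) = 0`.
#'
#' @param logits numeric vector of length 3, strictly decreasing.
#' @return named numeric vector `grade0..grade3`, non-negative, summing to 1.
#' @export
grade_distribution <- function(logits) {
  if (length(logits) != 3 || any(!is.finite(logits))) {
    stop("invalid parameter: logits must be 3 finite values")
  }
  if (any(diff(logits) >= 0)) {
    stop("ordering violation: cumulative logits must be strictly decreasing")
  }
  cum <- expit(logits)
  p <- c(1 - cum[1], cum[1] - cum[2], cum[2] - cum[3], cum[3])
  names(p) <- paste0("grade", 0:3)
  p
}

# ---- covariate-effect configuration -----------------------------------------

cov_names_allowed <- c("dose", "time", "age", "sex", "mono",
                       "breast", "colorectal", "other", "adherence")

#' Covariate-effect configuration
#'
#' Declares which covariates act on which part of the model: additively on the
#' shared logit intercepts (`intercept`) or multiplicatively, as the
#' exponential of a linear term, on the mean equilibration time (`met`).
#' Allowed covariate names: `dose` (absolute daily dose, mg, centered),
#' `time` (cycle time, centered at 3 cycles), `age` (years, centered at 62),
#' `sex` (indicator: female), `mono` (indicator: monotherapy), `breast`,
#' `colorectal`, `other` (tumor-entity indicators), and `adherence` (two
#' indicators for the 90-100% and <90% groups, reference >100%; 2 df).
#'
#' The final dose-toxicity model is `mctmm_covspec(intercept = "dose")`.
#'
#' @param intercept character vector of covariates acting on the logit
#'   intercepts.
#' @param met character vector of covariates acting on MET.
#' @return object of class `mctmm_covspec`.
#' @export
mctmm_covspec <- function(intercept = character(), met = character()) {
  for (v in c(intercept, met)) {
    if (!v %in% cov_names_allowed) {
      stop("configuration error: unknown covariate '", v, "'; allowed: ",
           paste(cov_names_allowed, collapse = ", "))
    }
  }
  structure(list(intercept = intercept, met = met), class = "mctmm_covspec")
}

#' @export
print.mctmm_covspec <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat("mCTMM covariate specification\n")
  cat("  on logit intercepts:", fmt(x$intercept), "\n")
  cat("  on MET:             ", fmt(x$met), "\n")
  invisible(x)
}

# Expanded design columns for one covariate: names and the scale factor that
# maps the internally scaled coefficient back to natural units.
cov_column_info <- function(name) {
  switch(name,
    dose       = list(cols = "dose", scale = 1e-3,
                      label = "per mg"),
    time       = list(cols = "time", scale = 1, label = "per cycle"),
    age        = list(cols = "age", scale = 0.1, label = "per year"),
    sex        = list(cols = "sex_female", scale = 1, label = "female vs male"),
    mono       = list(cols = "mono", scale = 1, label = "mono vs combination"),
    breast     = list(cols = "breast", scale = 1, label = "breast vs rest"),
    colorectal = list(cols = "colorectal", scale = 1,
                      label = "colorectal vs rest"),
    other      = list(cols = "other", scale = 1, label = "other entity vs rest"),
    adherence  = list(cols = c("adh_90_100", "adh_lt90"), scale = c(1, 1),
                      label = "vs >100% adherence"),
    stop("configuration error: unknown covariate '", name, "'")
  )
}

AGE_CENTER <- 62
TIME_CENTER <- 3

# Scaled per-segment column values for one covariate of one record.
# `seg` is the record's cycle data.frame (cycle, time, dose, grade).
cov_column_values <- function(name, record, seg, dose_center) {
  n <- nrow(seg)
  switch(name,
    dose       = matrix((seg$dose - dose_center) * 1e-3, ncol = 1),
    time       = matrix(seg$time - TIME_CENTER, ncol = 1),
    age        = matrix(rep((record$age - AGE_CENTER) * 0.1, n), ncol = 1),
    sex        = matrix(rep(as.numeric(record$sex == "female"), n), ncol = 1),
    mono       = matrix(rep(as.numeric(record$mono), n), ncol = 1),
    breast     = matrix(rep(as.numeric(record$entity == "breast"), n), ncol = 1),
    colorectal = matrix(rep(as.numeric(record$entity == "colorectal"), n),
                        ncol = 1),
    other      = matrix(rep(as.numeric(record$entity == "other"), n), ncol = 1),
    adherence  = cbind(rep(as.numeric(record$adherence == "90-100%"), n),
                       rep(as.numeric(record$adherence == "<90%"), n)),
    stop("configuration error: unknown covariate '", name, "'")
  )
}

# Scaled design matrix (n_segments x n_coefficients) for one target of a
# covariate specification.
design_matrix <- function(cov_list, record, seg, dose_center) {
  if (!length(cov_list)) return(matrix(0, nrow(seg), 0))
  do.call(cbind, lapply(cov_list, cov_column_values, record = record,
                        seg = seg, dose_center = dose_center))
}

design_colnames <- function(cov_list) {
  unlist(lapply(cov_list, function(v) cov_column_info(v)$cols))
}

design_scales <- function(cov_list) {
  unlist(lapply(cov_list, function(v) cov_column_info(v)$scale))
}

#' Covariate adjustments for a single subject-occasion
#'
#' Evaluates a covariate-effect configuration for one covariate vector:
#' returns the additive adjustment on the logit intercepts and the
#' multiplicative adjustment on MET (`exp` of the linear MET-scale term).
#' Coefficients are on the natural scale (e.g. per mg for `dose`).
#'
#' @param spec an [mctmm_covspec()].
#' @param coefs named list with elements `intercept` and `met`, each a numeric
#'   vector of natural-scale coefficients in the expanded-column order of the
#'   specification (see [mctmm_covspec()]); missing elements mean zero effect.
#' @param cov named list describing the subject-occasion: `daily_dose` (mg),
#'   `time` (cycles), `age`, `sex` (`"male"`/`"female"`), `entity`
#'   (`"colorectal"`/`"breast"`/`"other"`), `mono` (logical), `adherence`
#'   (`">100%"`/`"90-100%"`/`"<90%"`).
#' @param dose_center centering dose in mg.
#' @return list with `logit` (additive) and `met_mult` (multiplicative).
#' @export
covariate_adjustment <- function(spec, coefs = list(), cov,
                                 dose_center = 3000) {
  stopifnot(inherits(spec, "mctmm_covspec"))
  record <- list(age = cov$age %||% AGE_CENTER,
                 sex = cov$sex %||% "female",
                 entity = cov$entity %||% "other",
                 mono = cov$mono %||% FALSE,
                 adherence = cov$adherence %||% ">100%")
  seg <- data.frame(cycle = 1, time = cov$time %||% TIME_CENTER,
                    dose = cov$daily_dose %||% dose_center, grade = NA)
  eval_target <- function(cov_list, beta_nat) {
    if (!length(cov_list)) return(0)
    X <- design_matrix(cov_list, record, seg, dose_center)
    sc <- design_scales(cov_list)
    if (is.null(beta_nat)) beta_nat <- rep(0, ncol(X))
    if (length(beta_nat) != ncol(X)) {
      stop("configuration error: expected ", ncol(X),
           " coefficient(s), got ", length(beta_nat))
    }
    # natural-scale coefficient = scaled coefficient * scale, so the scaled
    # coefficient applied to the scaled column is beta_nat / scale * column
    sum((beta_nat / sc) * X[1, ])
  }
  list(logit = eval_target(spec$intercept, coefs$intercept),
       met_mult = exp(eval_target(spec$met, coefs$met)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
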