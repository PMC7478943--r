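#' Population parameters of the mCTMM
#'
#' Container for the estimable parameter vector of the minimal continuous-time
#' Markov model: ordered logit intercepts (`alpha1` plus strictly negative
#' increments `b2`, `b3`, so that the three cumulative-probability intercepts
#' are `alpha1`, `alpha1 + b2`, `alpha1 + b2 + b3`), the mean equilibration
#' time `met` (in treatment cycles), the slope `theta_dose` of the linear
#' daily-dose effect on the logit scale (per mg, centered at `dose_center`),
#' and the standard deviations of the two subject-level random effects: an
#' additive shift on the logit intercepts (`omega_alpha`) and a log-normal
#' multiplier on MET (`omega_met`).
#'
#' @param alpha1 logit-scale intercept for grade >= 1.
#' @param b2,b3 strictly negative increments giving the grade >= 2 and
#'   grade >= 3 intercepts.
#' @param met mean equilibration time in cycles (> 0).
#' @param theta_dose slope of the daily-dose effect on the logit scale
#'   (per mg).
#' @param omega_alpha,omega_met random-effect standard deviations (>= 0).
#' @param dose_center centering dose in mg for the dose effect (> 0).
#' @return an object of class `mctmm_params` (a named list).
#' @seealso [default_params()] for the reference estimates used throughout
#'   the examples and as simulation truth.
#' @export
mctmm_params <- function(alpha1, b2, b3, met, theta_dose = 0,
                         omega_alpha = 0, omega_met = 0, dose_center = 3000) {
  vals <- c(alpha1 = alpha1, b2 = b2, b3 = b3, met = met,
            theta_dose = theta_dose, omega_alpha = omega_alpha,
            omega_met = omega_met, dose_center = dose_center)
  if (any(!is.finite(vals))) {
    stop("invalid parameter: all mCTMM parameters must be finite, got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (b2 >= 0 || b3 >= 0) {
    stop("invalid parameter: b2 and b3 must be strictly negative ",
         "(ordered cumulative intercepts)")
  }
  if (met <= 0) stop("invalid parameter: met must be > 0")
  if (omega_alpha < 0 || omega_met < 0) {
    stop("invalid parameter: omega_alpha and omega_met must be >= 0")
  }
  if (dose_center <= 0) stop("invalid parameter: dose_center must be > 0")
  structure(list(alpha1 = alpha1, b2 = b2, b3 = b3, met = met,
                 theta_dose = theta_dose, omega_alpha = omega_alpha,
                 omega_met = omega_met, dose_center = dose_center),
            class = "mctmm_params")
}

#' Reference parameter set for capecitabine-induced hand-foot syndrome
#'
#' Point estimates from a published population analysis of patient-reported
#' hand-foot syndrome severity under capecitabine (150 patients, up to six
#' 3-week cycles). Used as documented defaults, as the simulation truth in
#' the package's recovery experiments, and as example values throughout.
#'
#' @return an [mctmm_params()] object with `alpha1 = 1.81`, `b2 = -1.80`,
#'   `b3 = -2.08`, `met = 1.09` cycles, `theta_dose = 8.33e-4` per mg,
#'   `omega_alpha = 1.12`, `omega_met = 0.542`, `dose_center = 3000` mg.
#' @export
default_params <- function() {
  mctmm_params(alpha1 = 1.81, b2 = -1.80, b3 = -2.08, met = 1.09,
               theta_dose = 8.33e-4, omega_alpha = 1.12, omega_met = 0.542,
               dose_center = 3000)
}

#' @export
print.mctmm_params <- function(x, ...) {
  cat("mCTMM population parameters\n")
  cat(sprintf("  alpha1      %10.4g   (logit intercept, grade >= 1)\n", x$alpha1))
  cat(sprintf("  b2          %10.4g   (increment, grade >= 2)\n", x$b2))
  cat(sprintf("  b3          %10.4g   (increment, grade >= 3)\n", x$b3))
  cat(sprintf("  met         %10.4g   cycles\n", x$met))
  cat(sprintf("  theta_dose  %10.4g   per mg (centered at %g mg)\n",
              x$theta_dose, x$dose_center))
  cat(sprintf("  omega_alpha %10.4g\n", x$omega_alpha))
  cat(sprintf("  omega_met   %10.4g\n", x$omega_met))
  invisible(x)
}

param_names <- c("alpha1", "b2", "b3", "met", "theta_dose",
                 "omega_alpha", "omega_met", "dose_center")

#' Read or write an mCTMM parameter file
#'
#' Plain-text key-value configuration (`name = value`, one per line, `#`
#' comments allowed) with names exactly `alpha1, b2, b3, met, theta_dose,
#' omega_alpha, omega_met, dose_center`.
#'
#' @param path file path.
#' @return `read_params()` returns an [mctmm_params()] object;
#'   `write_params()` invisibly returns `path`.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  unknown <- setdiff(keys, param_names)
  if (length(unknown)) stop("unknown parameter name(s): ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(param_names, keys)
  if (length(missing)) stop("missing parameter name(s): ",
                            paste(missing, collapse = ", "))
  if (any(is.na(vals))) stop("non-numeric parameter value for: ",
                             paste(keys[is.na(vals)], collapse = ", "))
  v <- setNames(vals, keys)
  g <- function(k) unname(v[k])
  mctmm_params(alpha1 = g("alpha1"), b2 = g("b2"), b3 = g("b3"),
               met = g("met"), theta_dose = g("theta_dose"),
               omega_alpha = g("omega_alpha"), omega_met = g("omega_met"),
               dose_center = g("dose_center"))
}

#' @param params an [mctmm_params()] object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "mctmm_params"))
  lines <- sprintf("%s = %.15g", param_names,
                   vapply(param_names, function(k) params[[k]], 0))
  writeLines(lines, path)
  invisible(path)
}
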