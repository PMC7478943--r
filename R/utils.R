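#' Inverse logit (expit)
#'
#' @param x numeric vector of log-odds.
#' @return probabilities `1 / (1 + exp(-x))`.
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Logit transform
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return log-odds `log(p / (1 - p))`.
#' @export
logit <- function(p) log(p / (1 - p))

# Evaluate `code` under a locally fixed RNG seed, restoring the caller's
# RNG state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Central finite-difference Hessian of a scalar function.
fd_hessian <- function(f, x, eps = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- xp[i] + eps
        xm[i] <- xm[i] - eps
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / eps^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- xpp[c(i, j)] + eps
        xmm[c(i, j)] <- xmm[c(i, j)] - eps
        xpm[i] <- xpm[i] + eps; xpm[j] <- xpm[j] - eps
        xmp[i] <- xmp[i] - eps; xmp[j] <- xmp[j] + eps
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * eps^2)
      }
    }
  }
  H
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
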