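#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rlnorm rgamma runif rbinom rmultinom rpois
#'   quantile median optim lowess approx dpois ppois sd qnorm pnorm t.test fft
#' @importFrom utils head tail
NULL

# Derive a reproducible 31-bit child seed from a parent seed and a stage label.
# Keeps every stochastic stage independently re-runnable from the global seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single probability in [0, 1]", name),
          class = "switchscope_config_error")
  x
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(if (strict) x > 0 else x >= 0)
  if (!ok)
    abort(sprintf("`%s` must be %s", name,
                  if (strict) "positive and finite" else "nonnegative and finite"),
          class = "switchscope_config_error")
  x
}

# Lognormal (meanlog, sdlog) whose *truncated* mean and sd on [lo, hi] match
# the requested arithmetic mean and sd.  Solved by damped fixed-point iteration
# on the matching untruncated moments; used for the birth-to-max distribution.
trunc_lnorm_params <- function(mean, sd, lo, hi) {
  sl2 <- log(1 + (sd / mean)^2)
  ml <- log(mean) - sl2 / 2
  sl <- sqrt(sl2)
  for (i in 1:200) {
    mo <- trunc_lnorm_moments(ml, sl, lo, hi)
    ml <- ml + 0.8 * (log(mean) - log(mo$mean))
    sl <- sl * (sd / mo$sd)^0.8
    if (abs(mo$mean - mean) < 1e-10 && abs(mo$sd - sd) < 1e-10) break
  }
  list(meanlog = ml, sdlog = sl)
}

trunc_lnorm_moments <- function(meanlog, sdlog, lo, hi) {
  a <- (log(lo) - meanlog) / sdlog
  b <- (log(hi) - meanlog) / sdlog
  z <- pnorm(b) - pnorm(a)
  m1 <- exp(meanlog + sdlog^2 / 2) * (pnorm(b - sdlog) - pnorm(a - sdlog)) / z
  m2 <- exp(2 * meanlog + 2 * sdlog^2) *
    (pnorm(b - 2 * sdlog) - pnorm(a - 2 * sdlog)) / z
  list(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  u <- runif(n, pnorm((log(lo) - meanlog) / sdlog),
             pnorm((log(hi) - meanlog) / sdlog))
  exp(meanlog + sdlog * qnorm(u))
}

# log-spaced sequence
lseq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}
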