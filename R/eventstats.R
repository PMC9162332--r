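#' Count switching events per trap under a counting scheme
#'
#' The three schemes formalize progressively stronger dependence between
#' observed switching cells:
#' \describe{
#'   \item{scheme 1}{every synchronous mother-daughter switching pair is an
#'     independent event (a trap's count is the total number of pairs);}
#'   \item{scheme 2}{pairs connected through uninterrupted chains of
#'     switching cells (direct patterns, including the four-cell pattern)
#'     merge into one event (the count is the number of connected groups);}
#'   \item{scheme 3}{groups belonging to the same mixed-fate pedigree (the
#'     same lineage tree of the recorded pedigree) also merge.}
#' }
#'
#' @param groups Output of [group_switching_cells()].
#' @param scheme Counting scheme, 1, 2 or 3.
#' @param trap_ids Vector of all trap identifiers in the experiment
#'   (including traps without events, which must appear with count zero).
#' @return A tibble of class `trap_event_table` with `trap_id` and `count`,
#'   one row per trap; the scheme is kept as an attribute.
#' @export
count_events <- function(groups, scheme, trap_ids = NULL) {
  if (!scheme %in% 1:3)
    abort("`scheme` must be 1, 2 or 3", class = "switchscope_config_error")
  if (is.null(trap_ids))
    trap_ids <- if (is.null(groups) || !nrow(groups)) 1L else unique(groups$trap_id)
  counts <- stats::setNames(rep(0L, length(trap_ids)), trap_ids)
  if (!is.null(groups) && nrow(groups)) {
    per <- switch(as.character(scheme),
      "1" = tapply(groups$n_pairs, groups$trap_id, sum),
      "2" = tapply(rep(1L, nrow(groups)), groups$trap_id, sum),
      "3" = tapply(groups$set_id, groups$trap_id,
                   function(s) length(unique(s))))
    counts[names(per)] <- as.integer(per)
  }
  out <- tibble(trap_id = trap_ids, count = as.integer(unname(counts)))
  attr(out, "scheme") <- scheme
  class(out) <- c("trap_event_table", class(out))
  out
}

#' Zero-class estimator of the Poisson event rate
#'
#' Estimates the per-trap event rate from the fraction of traps with no
#' events: `lambda = -log(n_zero / n_total)`.  This is the
#' maximum-likelihood rate given only the zero/nonzero dichotomy, and by
#' construction the fitted Poisson expectation reproduces the zero class
#' exactly.
#'
#' @param n_zero Number of traps with zero events (> 0).
#' @param n_total Total number of traps.
#' @return The rate `lambda` (events per trap).
#' @export
#' @examples
#' estimate_lambda(134, 168)  # -log(134/168)
estimate_lambda <- function(n_zero, n_total) {
  if (n_total <= 0 || n_zero > n_total)
    abort("need 0 < n_zero <= n_total", class = "switchscope_data_error")
  if (n_zero <= 0)
    abort("zero-class estimator undefined when no trap has zero events",
          class = "switchscope_data_error")
  -log(n_zero / n_total)
}

#' Expected Poisson class counts with a pooled tail
#'
#' @param lambda Event rate per trap.
#' @param n_traps Number of traps.
#' @param k_max Counts `>= k_max` are pooled into a single tail class.
#' @return A list of class `poisson_null`: `lambda`, `n_traps`, `classes`
#'   (labels), `expected` (counts summing to `n_traps`), `prob`.
#' @export
poisson_expected <- function(lambda, n_traps, k_max = 4) {
  check_pos(lambda, "lambda", strict = FALSE)
  p <- c(dpois(seq_len(k_max) - 1, lambda), 1 - ppois(k_max - 1, lambda))
  structure(list(lambda = lambda, n_traps = n_traps, k_max = k_max,
                 classes = c(as.character(seq_len(k_max) - 1),
                             paste0(">=", k_max)),
                 prob = p, expected = n_traps * p),
            class = "poisson_null")
}

#' Monte-Carlo chi-squared goodness-of-fit against a Poisson null
#'
#' Pearson chi-squared statistic of the observed per-trap event counts
#' (binned into the null's classes) against the Poisson expectation, with
#' the p-value computed by simulating multinomial draws of `n_traps` traps
#' from the null class probabilities.  The add-one estimator
#' `p = (1 + #\{chi2_sim >= chi2_obs\}) / (reps + 1)` is used, so p is never
#' exactly zero.
#'
#' @param observed A `trap_event_table` from [count_events()], or a vector
#'   of per-trap counts.
#' @param null A `poisson_null` from [poisson_expected()].
#' @param reps Number of Monte-Carlo replicates (default 2000).
#' @param seed Optional integer seed for the simulation.
#' @return A list of class `gof_test`: `chi2`, `p_value`, `reps`,
#'   `observed`, `expected`.
#' @export
gof_monte_carlo <- function(observed, null, reps = 2000, seed = NULL) {
  stopifnot(inherits(null, "poisson_null"))
  if (reps < 1) abort("`reps` must be >= 1", class = "switchscope_config_error")
  counts <- if (is.data.frame(observed)) observed$count else observed
  if (length(counts) != null$n_traps)
    abort("observed table and null cover different numbers of traps",
          class = "switchscope_data_error")
  k_max <- null$k_max
  binned <- tabulate(pmin(counts, k_max) + 1L, nbins = k_max + 1L)
  chi2 <- sum((binned - null$expected)^2 / null$expected)
  with_seed(seed, {
    sims <- rmultinom(reps, null$n_traps, null$prob)
    chi2_sim <- colSums((sims - null$expected)^2 / null$expected)
  })
  structure(list(chi2 = chi2, p_value = (1 + sum(chi2_sim >= chi2)) / (reps + 1),
                 reps = reps, observed = binned, expected = null$expected,
                 classes = null$classes),
            class = "gof_test")
}

#' @export
print.gof_test <- function(x, ...) {
  cat("Monte-Carlo chi-squared goodness-of-fit\n")
  m <- rbind(observed = x$observed, expected = round(x$expected, 2))
  colnames(m) <- x$classes
  print(m)
  cat(sprintf("chi2 = %.3f, p = %.4g (%d replicates)\n", x$chi2, x$p_value,
              x$reps))
  invisible(x)
}

#' Sectored-colony frequency with its standard error
#'
#' Sample proportion of colonies showing at least one sector, with the
#' standard error of a sample proportion, `sqrt(p * (1 - p) / n)`.
#'
#' @param n_sectored Colonies with at least one sector.
#' @param n_colonies Total colonies (> 0).
#' @return A tibble: `proportion`, `se`, `n`.
#' @export
sector_frequency <- function(n_sectored, n_colonies) {
  if (n_colonies <= 0)
    abort("`n_colonies` must be positive", class = "switchscope_data_error")
  if (n_sectored > n_colonies || n_sectored < 0)
    abort("`n_sectored` must be between 0 and `n_colonies`",
          class = "switchscope_data_error")
  p <- n_sectored / n_colonies
  tibble(proportion = p, se = sqrt(p * (1 - p) / n_colonies), n = n_colonies)
}
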