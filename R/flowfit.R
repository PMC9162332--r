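#' Filter flow events through scatter and fluorescence gates
#'
#' Removes events outside either gate of a [flow_gates()] set (debris, cell
#' aggregates, contaminants).  Gates are defined on the raw channels, so
#' gating commutes with forward-scatter normalization.
#'
#' @param events A `flow_plate` tibble (or any table with `fsc`, `ssc`,
#'   `gfp`, `v670` columns).
#' @param gates A [flow_gates()] object.
#' @return The passing events, with per-well pass counts in attribute
#'   `pass_counts` (tibble `well`, `n_in`, `n_pass`).
#' @export
gate_events <- function(events, gates = flow_gates()) {
  if (!nrow(events))
    abort("empty event table", class = "switchscope_data_error")
  inb <- function(x, b) x >= b[1] & x <= b[2]
  pass <- inb(events$fsc, gates$scatter$fsc) &
    inb(events$ssc, gates$scatter$ssc) &
    inb(events$v670, gates$fluor$v670) &
    inb(events$gfp, gates$fluor$gfp)
  well <- if ("well" %in% names(events)) events$well else "all"
  pc <- tibble(well = well, pass = pass) |>
    dplyr::summarise(n_in = dplyr::n(), n_pass = sum(.data$pass),
                     .by = "well")
  out <- events[pass, ]
  if (!nrow(out)) warn("all events removed by gating")
  attr(out, "pass_counts") <- pc
  out
}

#' Normalize fluorescence channels by forward scatter
#'
#' Appends `gfp_n = gfp / fsc` and `mcherry_n = mcherry / fsc` (cell-size
#' correction); original channels are retained.  Events with nonpositive
#' forward scatter are dropped and tallied in attribute `n_dropped`.
#'
#' @param events Event table with `fsc`, `gfp`, `mcherry` columns.
#' @return The table with normalized columns appended.
#' @export
normalize_events <- function(events) {
  bad <- !(events$fsc > 0)
  out <- events[!bad, ]
  out$gfp_n <- out$gfp / out$fsc
  out$mcherry_n <- out$mcherry / out$fsc
  attr(out, "n_dropped") <- sum(bad)
  out
}

hill4 <- function(lx, theta) {
  theta[1] + (theta[2] - theta[1]) /
    (1 + exp(-exp(theta[4]) * (lx - theta[3])))
}

#' Robust four-parameter log-logistic (Hill) fit
#'
#' Fits `log10(y) = c + (d - c) / (1 + exp(-h (ln x - log_K)))` to pooled
#' single-cell points: lower asymptote `c`, upper asymptote `d`, natural-log
#' half-max `log_K`, Hill coefficient `h > 0`.  The fit is seeded by
#' ordinary least squares from a coarse multi-start grid and then, when
#' `robust = "median"`, polished by minimizing the median of squared
#' residuals (least median of squares) via multi-start Nelder-Mead — the
#' median-type loss resists the gross outliers produced by cell clumping
#' and autofluorescence artifacts.
#'
#' `x` is clipped below at its 0.1th positive percentile before taking
#' logs.  When `x_max_conc` is given (with per-point `conc`), points from
#' wells at hormone `>= x_max_conc` are excluded before fitting — used for
#' dimerizing-fusion strains whose reporter declines at high hormone.
#'
#' @param x Predictor (e.g. forward-scatter-normalized GFP), positive.
#' @param y Response (e.g. normalized mCherry).
#' @param conc Optional per-point hormone concentration (nM).
#' @param x_max_conc Optional concentration cutoff (nM); requires `conc`.
#' @param log10_response Fit `log10(y)` (default) rather than `y`.
#' @param robust `"median"` (least median of squares polish) or `"ols"`.
#' @return A list of class `hill_fit`: `c`, `d`, `log_K`, `K`, `h`,
#'   `residual_scale` (median absolute residual), `n_points`, `converged`.
#' @export
fit_hill <- function(x, y, conc = NULL, x_max_conc = NULL,
                     log10_response = TRUE, robust = c("median", "ols")) {
  robust <- match.arg(robust)
  if (!is.null(x_max_conc)) {
    if (is.null(conc))
      abort("`x_max_conc` requires per-point `conc`", class = "switchscope_config_error")
    keep <- conc < x_max_conc
    x <- x[keep]; y <- y[keep]
  }
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 50)
    abort("need at least 50 finite positive points", class = "switchscope_data_error")
  floor_x <- quantile(x, 0.001, names = FALSE)
  lx <- log(pmax(x, floor_x))
  if (diff(range(lx)) < log(10))
    abort("predictor must span at least one decade", class = "switchscope_data_error")
  ly <- if (log10_response) log10(y) else y

  sse <- function(th) { r <- ly - hill4(lx, th); sum(r * r) }
  c0 <- quantile(ly, 0.02, names = FALSE)
  d0 <- quantile(ly, 0.98, names = FALSE)
  starts <- expand.grid(logK = quantile(lx, c(0.3, 0.5, 0.7), names = FALSE),
                        logh = log(c(1, 2, 4)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- optim(c(c0, d0, starts$logK[i], starts$logh[i]), sse,
                 method = "BFGS", control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  converged <- best$convergence == 0

  if (robust == "median") {
    lms <- function(th) { r <- ly - hill4(lx, th); median(r * r) }
    cand <- list(theta)
    scl <- abs(theta) + 0.1
    for (j in 1:4) cand[[j + 1]] <- theta + 0.05 * scl * (2 * (j %% 2) - 1) *
        (seq_len(4) == j)
    bestr <- NULL
    for (th0 in cand) {
      fit <- optim(th0, lms, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(bestr) || fit$value < bestr$value) bestr <- fit
    }
    if (bestr$value <= lms(theta) + 1e-12) {
      theta <- bestr$par
      converged <- converged || bestr$convergence == 0
    }
  }

  r <- ly - hill4(lx, theta)
  # report with d >= c (activation form, h > 0)
  cc <- min(theta[1], theta[2]); dd <- max(theta[1], theta[2])
  structure(list(c = cc, d = dd, log_K = theta[3], K = exp(theta[3]),
                 h = exp(theta[4]), residual_scale = median(abs(r)),
                 n_points = length(x), converged = converged,
                 robust = robust),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> c = %.3f, d = %.3f, K = %.4g (log_K = %.3f), h = %.3f\n",
    x$c, x$d, x$K, x$log_K, x$h))
  cat(sprintf("  n = %d, median |resid| = %.4f, robust = %s, converged = %s\n",
              x$n_points, x$residual_scale, x$robust, x$converged))
  invisible(x)
}

#' Aggregate replicate Hill fits per construct
#'
#' Given per-strain-day fits, reports per-construct mean and sd of the Hill
#' coefficient and of the half-max level, the ratio of mean half-max levels
#' between two constructs, and Welch two-sample comparisons of `h` and of
#' `log K`.
#'
#' @param fits A tibble with columns `construct` and `h`, `log_K` (e.g. one
#'   row per strain-day fit), or a list of `hill_fit` objects plus a
#'   `construct` vector.
#' @param ratio_of Character length-2: constructs whose mean-K ratio
#'   (first / second) is reported.
#' @return A list: `by_construct` (tibble of n, mean/sd of h, mean K),
#'   `K_ratio`, `p_h`, `p_logK` (Welch p-values; NA with a single construct).
#' @export
summarize_fits <- function(fits, ratio_of = NULL) {
  if (is.list(fits) && !is.data.frame(fits)) {
    construct <- attr(fits, "construct")
    fits <- tibble(construct = construct,
                   h = vapply(fits, `[[`, 0, "h"),
                   log_K = vapply(fits, `[[`, 0, "log_K"))
  }
  if (any(table(fits$construct) < 2))
    warn("fewer than 2 fits for some construct: sd undefined")
  by <- fits |>
    dplyr::summarise(n = dplyr::n(), h_mean = mean(.data$h),
                     h_sd = sd(.data$h), K_mean = mean(exp(.data$log_K)),
                     logK_mean = mean(.data$log_K),
                     .by = "construct")
  if (is.null(ratio_of) && nrow(by) == 2) ratio_of <- by$construct
  K_ratio <- p_h <- p_logK <- NA_real_
  if (!is.null(ratio_of)) {
    a <- fits[fits$construct == ratio_of[1], ]
    b <- fits[fits$construct == ratio_of[2], ]
    K_ratio <- mean(exp(a$log_K)) / mean(exp(b$log_K))
    if (nrow(a) >= 2 && nrow(b) >= 2 && (sd(a$h) > 0 || sd(b$h) > 0)) {
      p_h <- t.test(a$h, b$h)$p.value
      p_logK <- t.test(a$log_K, b$log_K)$p.value
    }
  }
  list(by_construct = by, K_ratio = K_ratio, ratio_of = ratio_of,
       p_h = p_h, p_logK = p_logK)
}

#' Simulate and fit one replicate strain-day dataset
#'
#' Convenience wrapper for replicate analyses: simulates a plate restricted
#' to one strain with a derived seed, gates, normalizes, and fits the Hill
#' response on pooled single-cell points.  For strains with the
#' high-concentration reporter decline the configured cutoff is applied.
#'
#' @param cfg A [flow_model_config()].
#' @param strain Strain name in `cfg$strains`.
#' @param replicate Integer replicate index (drives the derived seed).
#' @param gates Gate set.
#' @return A `hill_fit`.
#' @export
fit_strain_day <- function(cfg, strain, replicate, gates = flow_gates()) {
  seed <- derive_seed(cfg$rng_seed, paste0("flow/", strain, "/", replicate))
  plate <- simulate_flow_plate(cfg, strains = strain, seed = seed)
  ev <- normalize_events(gate_events(plate, gates))
  cutoff <- if (isTRUE(cfg$strains[[strain]]$decline))
    cfg$gfp_decline_threshold else NULL
  fit_hill(ev$gfp_n, ev$mcherry_n, conc = ev$conc_nM, x_max_conc = cutoff)
}
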