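rlength_class <- function(n, d) {
  base <- rlnorm(n, d$meanlog, d$sdlog)
  if (is.null(d$elong_frac) || d$elong_frac <= 0) return(base)
  el <- runif(n) < d$elong_frac
  base[el] <- rlnorm(sum(el), d$elong_meanlog, d$elong_sdlog)
  base
}

#' Generate a synthetic cell-length dataset
#'
#' Draws cell lengths (pixels, at bud initiation) for switching
#' mother-daughter pairs and for white and opaque reference cells from the
#' configured per-class distributions.  With the default
#' [default_length_dists()], switching mothers and daughters are mixtures
#' of a round white-like mode and an elongated pseudohyphal mode,
#' calibrated so that 14% of mothers and 80% of daughters exceed the true
#' white 95th-percentile length.
#'
#' @param n_pairs Number of switching mother-daughter pairs (default 248).
#' @param n_ref White and opaque reference cells each (default 100).
#' @param dists Per-class length distributions.
#' @param seed Optional integer seed.
#' @return A list of numeric vectors: `mothers`, `daughters`, `white_ref`,
#'   `opaque_ref`.
#' @export
make_length_dataset <- function(n_pairs = 248, n_ref = 100,
                                dists = default_length_dists(), seed = NULL) {
  with_seed(seed, {
    out <- list(
      mothers = rlength_class(n_pairs, dists$switching_mother),
      daughters = rlength_class(n_pairs, dists$switching_daughter),
      white_ref = rlength_class(n_ref, dists$white),
      opaque_ref = rlength_class(n_ref, dists$opaque))
  })
  out
}
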