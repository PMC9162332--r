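# Saturating protein-induction curve shared across strains (relative units).
induced_protein <- function(conc_nM, ind) {
  ind[["basal"]] + ind[["vmax"]] * conc_nM / (conc_nM + ind[["k"]])
}

# Reporter response: log10 normalized-mCherry follows a 4-parameter
# log-logistic (Hill) curve in log protein.
reporter_log10 <- function(protein, h, K, c, d) {
  c + (d - c) / (1 + exp(-h * (log(protein) - log(K))))
}

#' Simulate a synthetic flow-cytometry plate
#'
#' Draws per-event flow channels (FSC, SSC, GFP, mCherry, V670) for every
#' strain and hormone concentration of the configuration.  Intact cells get
#' a lognormal size (driving FSC/SSC), a per-cell induced protein level
#' (lognormal around the well mean), a GFP channel proportional to protein
#' times size (plus an autofluorescence floor), and an mCherry channel whose
#' log10 forward-scatter-normalized value follows the strain's Hill response
#' to that cell's protein.  Dimerizing-fusion strains additionally show a
#' power-law reporter decline at hormone above `gfp_decline_threshold`.
#' Debris events have low scatter, aggregates high scatter and high violet
#' (670 nm) autofluorescence.  Every event carries its ground-truth
#' subpopulation label and true protein/reporter values.
#'
#' @param cfg A [flow_model_config()].
#' @param strains Optional character vector restricting the strain panel.
#' @param seed Optional integer overriding `cfg$rng_seed`.
#' @return A tibble of class `flow_plate`: `strain`, `conc_nM`, `well`,
#'   channels `fsc`, `ssc`, `gfp`, `mcherry`, `v670`, and ground truth
#'   `true_subpop`, `true_protein`, `true_log10_reporter`.
#' @export
simulate_flow_plate <- function(cfg, strains = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "flow_model_config"))
  if (is.null(strains)) strains <- names(cfg$strains)
  if (is.null(seed)) seed <- cfg$rng_seed
  nz <- cfg$noise
  with_seed(seed, {
    wells <- expand.grid(strain = strains, conc_nM = cfg$hormone_concs,
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(wells)), function(w) {
      simulate_well(cfg, wells$strain[w], wells$conc_nM[w], nz)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flow_plate", class(out))
  out
}

simulate_well <- function(cfg, strain, conc, nz) {
  st <- cfg$strains[[strain]]
  n <- cfg$events_per_well
  n_deb <- rbinom(1, n, cfg$subpop_fracs[["debris"]])
  n_agg <- rbinom(1, n - n_deb,
                  cfg$subpop_fracs[["aggregate"]] /
                    (1 - cfg$subpop_fracs[["debris"]]))
  n_ok <- n - n_deb - n_agg

  # intact cells
  size <- rlnorm(n_ok, 0, nz[["size_sdlog"]])
  fsc <- cfg$fsc_ref * size * rlnorm(n_ok, 0, nz[["gfp_cv"]])
  ssc <- 0.4 * cfg$fsc_ref * size^1.2 * rlnorm(n_ok, 0, nz[["ssc_sdlog"]])
  v670 <- 800 * size * rlnorm(n_ok, 0, nz[["v670_sdlog"]])

  well_protein <- induced_protein(conc, cfg$induction)
  protein <- well_protein * rlnorm(n_ok, 0, nz[["protein_sdlog"]])
  gfp_scale <- switch(st$type,
                      free_gfp = cfg$induction[["free_gfp_scale"]],
                      no_gfp = 0, 1)
  gfp_n_true <- cfg$af_gfp + gfp_scale * protein
  gfp <- gfp_n_true * fsc * rlnorm(n_ok, 0, nz[["gfp_cv"]])

  if (st$type %in% c("fusion", "no_gfp")) {
    y10 <- reporter_log10(protein, st$h, st$K, cfg$reporter_c, cfg$reporter_d)
    if (isTRUE(st$decline) && conc > cfg$gfp_decline_threshold)
      y10 <- y10 - cfg$decline_exponent *
        log10(conc / cfg$gfp_decline_threshold)
  } else {
    y10 <- rep(cfg$reporter_c, n_ok)
  }
  mch_n <- 10^(y10 + rnorm(n_ok, 0, nz[["reporter_sdlog10"]]))
  mch <- mch_n * fsc * rlnorm(n_ok, 0, nz[["mch_cv"]])

  intact <- tibble(fsc = fsc, ssc = ssc, gfp = gfp, mcherry = mch,
                   v670 = v670, true_subpop = "intact",
                   true_protein = protein, true_log10_reporter = y10)

  debris <- tibble(
    fsc = rlnorm(n_deb, log(2000), 0.5),
    ssc = rlnorm(n_deb, log(800), 0.5),
    gfp = rlnorm(n_deb, log(50), 0.6),
    mcherry = rlnorm(n_deb, log(30), 0.6),
    v670 = rlnorm(n_deb, log(300), 0.5),
    true_subpop = "debris", true_protein = NA_real_,
    true_log10_reporter = NA_real_)

  aggregate <- tibble(
    fsc = rlnorm(n_agg, log(4e5), 0.30),
    ssc = rlnorm(n_agg, log(3e5), 0.35),
    gfp = rlnorm(n_agg, log(2 * cfg$fsc_ref * cfg$af_gfp * 4), 0.6),
    mcherry = rlnorm(n_agg, log(1500), 0.6),
    v670 = rlnorm(n_agg, log(3e4), 0.40),
    true_subpop = "aggregate", true_protein = NA_real_,
    true_log10_reporter = NA_real_)

  out <- dplyr::bind_rows(intact, debris, aggregate)
  out$strain <- strain
  out$conc_nM <- conc
  out$well <- paste0(strain, "@", signif(conc, 3))
  out[, c("strain", "conc_nM", "well", "fsc", "ssc", "gfp", "mcherry",
          "v670", "true_subpop", "true_protein", "true_log10_reporter")]
}

#' Default rectangular gates for the synthetic plates
#'
#' Two gates in the style of debris/aggregate removal: a scatter gate
#' (closed rectangle in FSC x SSC) and a fluorescence gate bounding the
#' violet-excited 670 nm autofluorescence channel against GFP.  An event
#' passes only if inside both.
#'
#' @param fsc,ssc,v670,gfp Numeric `c(min, max)` bounds per channel.
#' @return A list of class `gate_set`.
#' @export
flow_gates <- function(fsc = c(8e3, 3e5), ssc = c(1e3, 2.5e5),
                       v670 = c(0, 8e3), gfp = c(0, Inf)) {
  structure(list(scatter = list(fsc = fsc, ssc = ssc),
                 fluor = list(v670 = v670, gfp = gfp)),
            class = "gate_set")
}
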