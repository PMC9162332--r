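#' Configuration for the two-step switching simulation
#'
#' Builds the configuration object for the synthetic trap-movie / pedigree
#' generator.  The generator implements a minimal two-step stochastic model of
#' white-opaque switching: at any cell division a lineage may acquire a
#' heritable *predisposition* (first stochastic event); within a predisposed
#' lineage any division may then trigger *activation* of the master regulator
#' (second stochastic event), which always captures the current
#' mother-daughter pair jointly and is inherited by all descendants.
#'
#' Defaults encode the study conditions: 12-min frame cadence over 24 h,
#' 168 trap fields, roughly 400 resident cells per trap by 12 h, a 40-fold
#' opaque/white reporter ratio, a 3 h 10-90% rise, and a birth-to-maximum
#' distribution with mean 9.9 h and sd 3.2 h truncated to 5.4-17.2 h.
#' The event probabilities `p_predispose` and `p_activate` are calibrated
#' (and frozen here) so that the expected fraction of traps without any
#' switching event equals 134/168 and roughly a fifth of event-bearing
#' pedigrees are mixed-fate; this is a calibration, not a prediction.
#'
#' @param frame_interval Minutes between frames.
#' @param n_frames Number of frames (121 frames = 24 h at 12 min).
#' @param division_time Named numeric, `mean` and `sd` of the per-cell
#'   division time in minutes (Gamma distributed).
#' @param n_founders Cells loaded per trap at time zero.
#' @param trap_capacity Resident cells a trap can hold; newborns beyond this
#'   are pushed out of the field.
#' @param p_predispose Per-division probability of the first (predisposing)
#'   stochastic event.
#' @param predispose_span Integer vector of possible heritability spans
#'   (divisions) of the predisposed state; drawn uniformly per event.
#' @param p_activate Per-division probability, within a predisposed lineage,
#'   of the second (activating) event.
#' @param birth_to_max Named numeric `mean`, `sd`, `min`, `max` (hours): the
#'   truncated-lognormal distribution of time from cell birth to maximal
#'   reporter level, parameterized by its truncated moments.
#' @param rise_time_10_90 Hours between the 10% and 90% points of the
#'   reporter rise during switching.
#' @param rise_offset_min Minutes from the activating division to the
#'   midpoint of the reporter rise.
#' @param white_level,opaque_level Reporter intensity (arbitrary units) of
#'   the two stable states; 40-fold apart under defaults.
#' @param trace_noise_cv Multiplicative (lognormal) noise cv on trace values.
#' @param white_area,opaque_area Typical cell areas in pixels.
#' @param length_dists Per-class cell-length distributions (pixels, log
#'   scale); see [make_length_dataset()].
#' @param n_traps Number of trap fields per experiment.
#' @param rng_seed Integer seed.
#'
#' @return A list of class `switch_model_config`.
#' @export
#' @examples
#' cfg <- switch_model_config(n_traps = 4, trap_capacity = 60)
#' exp <- simulate_pedigrees(cfg)
switch_model_config <- function(frame_interval = 12,
                                n_frames = 121,
                                division_time = c(mean = 95, sd = 18),
                                n_founders = 2,
                                trap_capacity = 400,
                                p_predispose = 1.63e-04,
                                predispose_span = 1:4,
                                p_activate = 0.10,
                                birth_to_max = c(mean = 9.9, sd = 3.2,
                                                 min = 5.4, max = 17.2),
                                rise_time_10_90 = 3,
                                rise_offset_min = 60,
                                white_level = 1,
                                opaque_level = 40,
                                trace_noise_cv = 0.05,
                                white_area = 1750,
                                opaque_area = 2500,
                                length_dists = default_length_dists(),
                                n_traps = 168,
                                rng_seed = 1L) {
  check_pos(frame_interval, "frame_interval")
  if (n_frames < 2) abort("`n_frames` must be >= 2", class = "switchscope_config_error")
  check_pos(division_time[["mean"]], "division_time['mean']")
  check_pos(division_time[["sd"]], "division_time['sd']")
  check_prob(p_predispose, "p_predispose")
  check_prob(p_activate, "p_activate")
  if (!is.numeric(predispose_span) || length(predispose_span) < 1 ||
      any(predispose_span < 1) || any(predispose_span != round(predispose_span)))
    abort("`predispose_span` must be positive integers", class = "switchscope_config_error")
  check_pos(unname(birth_to_max), "birth_to_max")
  check_pos(rise_time_10_90, "rise_time_10_90")
  check_pos(c(white_level, opaque_level), "reporter levels")
  if (opaque_level <= white_level)
    abort("`opaque_level` must exceed `white_level`", class = "switchscope_config_error")
  check_pos(c(white_area, opaque_area), "cell areas")
  check_pos(n_traps, "n_traps")

  btm <- trunc_lnorm_params(birth_to_max[["mean"]], birth_to_max[["sd"]],
                            birth_to_max[["min"]], birth_to_max[["max"]])
  structure(list(
    frame_interval = frame_interval, n_frames = n_frames,
    division_time = division_time, n_founders = as.integer(n_founders),
    trap_capacity = as.integer(trap_capacity),
    p_predispose = p_predispose,
    predispose_span = as.integer(predispose_span),
    p_activate = p_activate,
    birth_to_max = birth_to_max,
    birth_to_max_lnorm = btm,
    rise_time_10_90 = rise_time_10_90,
    rise_offset_min = rise_offset_min,
    white_level = white_level, opaque_level = opaque_level,
    trace_noise_cv = trace_noise_cv,
    white_area = white_area, opaque_area = opaque_area,
    length_dists = length_dists,
    n_traps = as.integer(n_traps), rng_seed = as.integer(rng_seed)
  ), class = "switch_model_config")
}

#' Default per-class cell-length distributions
#'
#' Lengths are lognormal in pixels.  The switching-mother and
#' switching-daughter classes are two-component mixtures of a round,
#' white-like mode and an elongated (pseudohyphal) mode; the elongated
#' fractions are calibrated so that 14% of switching mothers and 80% of
#' switching daughters exceed the true white 95th-percentile length.
#'
#' @return Named list of per-class parameter lists.
#' @export
default_length_dists <- function() {
  list(
    white              = list(meanlog = log(50), sdlog = 0.06),
    opaque             = list(meanlog = log(58), sdlog = 0.07),
    switching_mother   = list(meanlog = log(50), sdlog = 0.06,
                              elong_frac = 0.09556,
                              elong_meanlog = log(85), elong_sdlog = 0.18),
    switching_daughter = list(meanlog = log(50), sdlog = 0.06,
                              elong_frac = 0.79636,
                              elong_meanlog = log(85), elong_sdlog = 0.18)
  )
}

#' Configuration for the synthetic flow-cytometry plate generator
#'
#' Emulates the synthetic-induction experiment: strains carrying a
#' hormone-inducible master regulator (or control constructs) and a
#' fluorescent transcriptional reporter of its autoregulated control region,
#' measured by flow cytometry across a progesterone dilution series.
#'
#' Each well draws intact cells, debris and aggregates.  For intact cells the
#' induced protein level follows a saturating curve in hormone (shared shape
#' across strains, with a 10-fold higher scale for free GFP); the reporter
#' log10 level follows a four-parameter log-logistic (Hill) response in log
#' protein with strain-specific Hill coefficient and half-max.  Defaults:
#' Hill 3.2 for the non-dimerizing fusion (Wor1-mGFP), 4.3 for the
#' dimerizing fusion (Wor1-GFP), and a 5-fold half-max ratio (K_mGFP/K_GFP).
#' The dimerizing fusion additionally shows a gradual reporter decline above
#' `gfp_decline_threshold` (2 nM).
#'
#' @param hormone_concs Progesterone concentrations in nM (default 10
#'   log-spaced values).
#' @param strains Named list of per-strain models; each has a `type`
#'   (`"fusion"`, `"free_gfp"` or `"no_gfp"`), Hill parameters `h` and `K`
#'   (K in protein units), and a `decline` flag for the high-concentration
#'   reporter decrease.
#' @param reporter_c,reporter_d Lower/upper asymptotes of the reporter
#'   response, log10 normalized-mCherry units.
#' @param induction Saturating protein-induction curve parameters: `basal`,
#'   `vmax`, `k` (nM), plus `free_gfp_scale` (fold).
#' @param gfp_decline_threshold nM above which the dimerizing-fusion
#'   reporter declines.
#' @param decline_exponent Power-law exponent of that decline.
#' @param af_gfp Autofluorescence floor of normalized GFP (protein-equivalent
#'   units).
#' @param events_per_well Events drawn per well before gating.
#' @param subpop_fracs Named fractions of `debris` and `aggregate` events.
#' @param noise Named list of channel noise scales (lognormal sd on log
#'   scale, or cv for measurement noise).
#' @param fsc_ref Reference forward-scatter scale (arbitrary units).
#' @param rng_seed Integer seed.
#'
#' @return A list of class `flow_model_config`.
#' @export
#' @examples
#' cfg <- flow_model_config(events_per_well = 500)
#' plate <- simulate_flow_plate(cfg)
flow_model_config <- function(hormone_concs = lseq(0.02, 40, 10),
                              strains = default_flow_strains(),
                              reporter_c = -1.7,
                              reporter_d = 0.3,
                              induction = c(basal = 1, vmax = 300, k = 5,
                                            free_gfp_scale = 10),
                              gfp_decline_threshold = 2,
                              decline_exponent = 0.25,
                              af_gfp = 0.1,
                              events_per_well = 7500,
                              subpop_fracs = c(debris = 0.04, aggregate = 0.03),
                              noise = c(protein_sdlog = 0.25, gfp_cv = 0.05,
                                        reporter_sdlog10 = 0.06, mch_cv = 0.05,
                                        size_sdlog = 0.30, ssc_sdlog = 0.20,
                                        v670_sdlog = 0.35),
                              fsc_ref = 5e4,
                              rng_seed = 1L) {
  if (length(hormone_concs) == 0)
    abort("`hormone_concs` must be a nonempty vector of concentrations (nM)",
          class = "switchscope_config_error")
  check_pos(hormone_concs, "hormone_concs", strict = FALSE)
  if (reporter_d <= reporter_c)
    abort("`reporter_d` must exceed `reporter_c`", class = "switchscope_config_error")
  for (s in names(strains)) {
    st <- strains[[s]]
    if (st$type == "fusion") {
      check_pos(st$h, sprintf("strains$%s$h", s))
      check_pos(st$K, sprintf("strains$%s$K", s))
    }
  }
  check_prob(sum(subpop_fracs), "sum(subpop_fracs)")
  check_pos(events_per_well, "events_per_well")
  check_pos(gfp_decline_threshold, "gfp_decline_threshold")

  structure(list(
    hormone_concs = hormone_concs, strains = strains,
    reporter_c = reporter_c, reporter_d = reporter_d,
    induction = induction,
    gfp_decline_threshold = gfp_decline_threshold,
    decline_exponent = decline_exponent,
    af_gfp = af_gfp,
    events_per_well = as.integer(events_per_well),
    subpop_fracs = subpop_fracs, noise = noise,
    fsc_ref = fsc_ref, rng_seed = as.integer(rng_seed)
  ), class = "flow_model_config")
}

#' Default strain panel for the flow-plate generator
#'
#' Four constructs: the non-dimerizing fusion (`Wor1-mGFP`, Hill 3.2,
#' half-max 40 protein units), the dimerizing fusion (`Wor1-GFP`, Hill 4.3,
#' half-max 8, with the high-concentration reporter decline), free GFP
#' (induced 10-fold higher, reporter stays basal) and untagged regulator
#' (`Wor1`, reporter responds, GFP channel at autofluorescence).
#'
#' @return Named list of strain models.
#' @export
default_flow_strains <- function() {
  list(
    `Wor1-mGFP` = list(type = "fusion",   h = 3.2, K = 40, decline = FALSE),
    `Wor1-GFP`  = list(type = "fusion",   h = 4.3, K = 8,  decline = TRUE),
    GFP         = list(type = "free_gfp", h = NA,  K = NA, decline = FALSE),
    Wor1        = list(type = "no_gfp",   h = 3.2, K = 40, decline = FALSE)
  )
}

#' @export
print.switch_model_config <- function(x, ...) {
  cat("<switch_model_config>\n")
  cat(sprintf("  %d traps, %d frames x %g min, capacity %d (founders %d)\n",
              x$n_traps, x$n_frames, x$frame_interval, x$trap_capacity,
              x$n_founders))
  cat(sprintf("  p_predispose = %.3g/division (span %s), p_activate = %.3g\n",
              x$p_predispose, paste(range(x$predispose_span), collapse = "-"),
              x$p_activate))
  cat(sprintf("  reporter: white %g, opaque %g; rise 10-90%% = %g h\n",
              x$white_level, x$opaque_level, x$rise_time_10_90))
  invisible(x)
}

#' @export
print.flow_model_config <- function(x, ...) {
  cat("<flow_model_config>\n")
  cat(sprintf("  %d concentrations (%.3g-%.3g nM), %d strains, %d events/well\n",
              length(x$hormone_concs), min(x$hormone_concs),
              max(x$hormone_concs), length(x$strains), x$events_per_well))
  invisible(x)
}
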