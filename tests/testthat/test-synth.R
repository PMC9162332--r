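test_that("configuration constructors validate probabilities, times and lists", {
  expect_error(switch_model_config(p_predispose = 1.2),
               class = "switchscope_config_error")
  expect_error(switch_model_config(p_activate = -0.1),
               class = "switchscope_config_error")
  expect_error(switch_model_config(rise_time_10_90 = 0),
               class = "switchscope_config_error")
  expect_error(switch_model_config(opaque_level = 0.5, white_level = 1),
               class = "switchscope_config_error")
  expect_error(switch_model_config(predispose_span = c(0, 2)),
               class = "switchscope_config_error")
  expect_error(flow_model_config(hormone_concs = numeric(0)),
               class = "switchscope_config_error")
  expect_error(flow_model_config(reporter_c = 1, reporter_d = 0),
               class = "switchscope_config_error")
})

test_that("defaults encode the study conditions", {
  cfg <- switch_model_config()
  expect_equal(cfg$opaque_level / cfg$white_level, 40)
  expect_true(all(cfg$predispose_span %in% 1:4))
  expect_equal(cfg$n_traps, 168)
  expect_equal((cfg$n_frames - 1) * cfg$frame_interval, 24 * 60)
  expect_equal(cfg$white_area, 1750)
  expect_equal(cfg$opaque_area, 2500)
  # truncated birth-to-max distribution reproduces the stated moments
  m <- switchscope:::trunc_lnorm_moments(cfg$birth_to_max_lnorm$meanlog,
                                         cfg$birth_to_max_lnorm$sdlog,
                                         5.4, 17.2)
  expect_equal(m$mean, 9.9, tolerance = 1e-6)
  expect_equal(m$sd, 3.2, tolerance = 1e-6)

  fcfg <- flow_model_config()
  expect_equal(fcfg$strains[["Wor1-mGFP"]]$K / fcfg$strains[["Wor1-GFP"]]$K, 5)
  expect_equal(fcfg$strains[["Wor1-mGFP"]]$h, 3.2)
  expect_equal(fcfg$strains[["Wor1-GFP"]]$h, 4.3)
  expect_equal(fcfg$gfp_decline_threshold, 2)
  expect_length(fcfg$hormone_concs, 10)
})

test_that("without the first stochastic event no switching ever occurs", {
  cfg <- small_switch_cfg(p_predispose = 0)
  exp <- simulate_pedigrees(cfg)
  expect_equal(nrow(exp$events), 0)
  expect_equal(nrow(exp$predispositions), 0)
  expect_true(all(exp$cells$class == "white"))
})

test_that("identical seeds give bit-identical pedigrees, traces and plates", {
  a <- simulate_pedigrees(small_switch_cfg(p_predispose = 2e-3, seed = 21))
  b <- simulate_pedigrees(small_switch_cfg(p_predispose = 2e-3, seed = 21))
  expect_identical(a$cells, b$cells)
  expect_identical(a$events, b$events)
  expect_identical(simulate_traces(a), simulate_traces(b))

  fa <- simulate_flow_plate(small_flow_cfg(events_per_well = 200, seed = 5),
                            strains = "Wor1-mGFP")
  fb <- simulate_flow_plate(small_flow_cfg(events_per_well = 200, seed = 5),
                            strains = "Wor1-mGFP")
  expect_identical(fa, fb)
})

test_that("certain activation stays within the drawn heritability span", {
  cfg <- small_switch_cfg(p_predispose = 1.5e-3, p_activate = 1,
                          predispose_span = 4, seed = 31)
  cfg$n_traps <- 20L
  exp <- simulate_pedigrees(cfg)
  expect_gt(nrow(exp$events), 0)
  expect_true(all(exp$events$depth >= 1 & exp$events$depth <= 4))
  # with p_activate = 1 the very first trial division succeeds
  expect_true(all(exp$events$depth == 1))
})

test_that("uniform-span pedigrees keep switching within 1-4 divisions of establishment", {
  cfg <- small_switch_cfg(p_predispose = 2e-3, p_activate = 0.5, seed = 41)
  cfg$n_traps <- 20L
  exp <- simulate_pedigrees(cfg)
  expect_gt(nrow(exp$events), 5)
  expect_true(all(exp$events$depth >= 1 & exp$events$depth <= 4))
  spans <- exp$predispositions$span[match(
    paste(exp$events$trap_id, exp$events$predis_id),
    paste(exp$predispositions$trap_id, exp$predispositions$predis_id))]
  expect_true(all(exp$events$depth <= spans))
})

test_that("activated lineages stay opaque and propagate to all descendants", {
  cfg <- small_switch_cfg(p_predispose = 2e-3, p_activate = 0.5, seed = 51)
  exp <- simulate_pedigrees(cfg)
  sw <- exp$cells[exp$cells$class %in% c("switching", "opaque"), ]
  expect_gt(sum(sw$class == "switching"), 0)
  # direct daughters budded after the activation are born opaque
  # (branches budded before the event keep their own predisposed fate)
  n_checked <- 0
  for (i in seq_len(nrow(sw))) {
    after <- if (sw$class[i] == "switching") sw$event_min[i] else -Inf
    kids <- exp$cells[exp$cells$trap_id == sw$trap_id[i] &
                        !is.na(exp$cells$parent_id) &
                        exp$cells$parent_id == sw$cell_id[i] &
                        exp$cells$birth_min > after, ]
    n_checked <- n_checked + nrow(kids)
    if (nrow(kids)) expect_true(all(kids$class == "opaque"))
  }
  expect_gt(n_checked, 0)
})

test_that("standalone switching traces reproduce the configured kinetics", {
  cfg <- switch_model_config(rng_seed = 61)
  cfg$trace_noise_cv <- 1e-9
  sw <- make_switch_traces(30, cfg)
  gt <- sw$ground_truth
  expect_true(all(gt$birth_to_max_h >= 5.4 & gt$birth_to_max_h <= 17.2))
  for (k in c(1, 15, 30)) {
    tr <- tibble::tibble(frame = sw$traces$frames[[k]],
                         value = sw$traces$values[[k]])
    t_h <- tr$frame * cfg$frame_interval / 60
    t10 <- approx(tr$value, t_h, xout = 1 + 0.1 * 39)$y
    t90 <- approx(tr$value, t_h, xout = 1 + 0.9 * 39)$y
    expect_equal(t90 - t10, 3, tolerance = 0.02)
    # the configured birth-to-max is the 95%-of-plateau crossing
    t95 <- approx(tr$value, t_h, xout = 0.95 * 40)$y
    expect_equal(t95, gt$birth_to_max_h[k], tolerance = 0.1)
  }
})

test_that("flow plate hits basal level, exact half-max and the free-GFP contract", {
  # hormone chosen so the induced protein equals K of the mGFP strain (40)
  conc_at_K <- 5 * 39 / (300 - 39)
  cfg <- noiseless_flow_cfg(hormone_concs = c(1e-6, conc_at_K),
                            events_per_well = 60)
  plate <- simulate_flow_plate(cfg, strains = c("Wor1-mGFP", "GFP"))
  m <- plate[plate$strain == "Wor1-mGFP", ]
  lo <- m[m$conc_nM == 1e-6, ]
  expect_equal(log10(lo$mcherry / lo$fsc), rep(cfg$reporter_c, nrow(lo)),
               tolerance = 1e-3)
  hi <- m[m$conc_nM == conc_at_K, ]
  expect_equal(log10(hi$mcherry / hi$fsc),
               rep((cfg$reporter_c + cfg$reporter_d) / 2, nrow(hi)),
               tolerance = 1e-9)
  # free GFP: reporter basal everywhere, GFP induced 10-fold higher
  g <- plate[plate$strain == "GFP", ]
  expect_equal(log10(g$mcherry / g$fsc), rep(cfg$reporter_c, nrow(g)),
               tolerance = 1e-9)
  hi_g <- g[g$conc_nM == conc_at_K, ]
  expect_equal(median(hi_g$gfp / hi_g$fsc) / median(hi$gfp / hi$fsc),
               (0.1 + 10 * 40) / (0.1 + 40), tolerance = 1e-6)
})

test_that("every event is labeled and intact medians rise monotonically", {
  cfg <- small_flow_cfg(events_per_well = 600, seed = 71)
  plate <- simulate_flow_plate(cfg, strains = c("Wor1-mGFP", "Wor1-GFP"))
  expect_true(all(plate$true_subpop %in% c("intact", "debris", "aggregate")))
  expect_true(all(table(plate$true_subpop) > 0))
  for (s in c("Wor1-mGFP", "Wor1-GFP")) {
    sub <- plate[plate$strain == s & plate$true_subpop == "intact" &
                   plate$conc_nM < cfg$gfp_decline_threshold, ]
    med <- tapply(sub$mcherry / sub$fsc, sub$conc_nM, median)
    med <- med[order(as.numeric(names(med)))]
    expect_true(all(diff(med) > -1e-3))
  }
  # the dimerizing fusion declines above the threshold
  gg <- plate[plate$strain == "Wor1-GFP" & plate$true_subpop == "intact", ]
  med <- tapply(log10(gg$mcherry / gg$fsc), gg$conc_nM, median)
  med <- med[order(as.numeric(names(med)))]
  top <- which(as.numeric(names(med)) >= cfg$gfp_decline_threshold)
  expect_lt(med[length(med)], max(med))
})

test_that("rendered movies, masks and ground truth stay consistent", {
  cfg <- switch_model_config()
  cells <- tibble::tibble(cell_id = c("0", "0.1", "0.2"),
                          birth_frame = c(0L, 0L, 2L), end_frame = 5L,
                          class = c("white", "opaque", "white"))
  mv <- render_movie(cells, cfg, canvas = c(300, 300), n_frames = 6, seed = 1)
  expect_length(mv$dropped, 0)
  # every rendered object maps to exactly one ground-truth cell
  expect_setequal(setdiff(unique(as.vector(mv$masks[, , 1])), 0L), c(1L, 2L))
  expect_setequal(setdiff(unique(as.vector(mv$masks[, , 4])), 0L), 1:3)
  # areas within 5% of the configured values
  a1 <- sum(mv$masks[, , 1] == 1)
  expect_equal(a1, cfg$white_area, tolerance = 0.05)
  expect_equal(sum(mv$masks[, , 1] == 2), cfg$opaque_area, tolerance = 0.05)
  # top-300 metric reads back the configured levels
  expect_equal(as.numeric(top_pixels_metric(mv$gfp[, , 1], mv$masks[, , 1],
                                            label = 1)),
               cfg$white_level, tolerance = 0.05)
  expect_equal(as.numeric(top_pixels_metric(mv$gfp[, , 1], mv$masks[, , 1],
                                            label = 2)),
               cfg$opaque_level, tolerance = 0.05)
  # injected drift is recorded exactly
  drift <- matrix(0, 6, 2); drift[3, ] <- c(3, -2)
  mv2 <- render_movie(cells, cfg, canvas = c(300, 300), n_frames = 6,
                      drift = drift, seed = 1)
  expect_equal(mv2$offsets$dy, c(0, 0, 3, 3, 3, 3))
  expect_equal(mv2$offsets$dx, c(0, 0, -2, -2, -2, -2))
  # canvas overflow drops cells and reports them
  expect_message(
    mv3 <- render_movie(cells, cfg, canvas = c(80, 80), n_frames = 2),
    "dropped")
  expect_gt(length(mv3$dropped), 0)
})

test_that("movies round-trip through TIFF", {
  cfg <- switch_model_config()
  cells <- tibble::tibble(cell_id = "0", birth_frame = 0L, end_frame = 2L,
                          class = "opaque")
  mv <- render_movie(cells, cfg, canvas = c(120, 120), n_frames = 3, seed = 2)
  pre <- file.path(withr::local_tempdir(), "trap")
  write_trap_movie(mv, pre)
  back <- read_trap_movie(pre)
  expect_equal(back$gfp, mv$gfp, tolerance = 1e-6)
  expect_identical(back$masks, mv$masks)
  expect_equal(back$offsets$dy, mv$offsets$dy)
})
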