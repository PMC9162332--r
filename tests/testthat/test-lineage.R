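test_that("dotted names build the expected forest and reject orphans", {
  p <- build_pedigree(c("0", "0.1", "0.2", "0.2.1"))
  expect_equal(p$parent_id[match(c("0", "0.1", "0.2", "0.2.1"), p$cell_id)],
               c(NA, "0", "0", "0.2"))
  expect_equal(p$depth[match(c("0", "0.2.1"), p$cell_id)], c(0L, 2L))
  expect_equal(sort(p$cell_id[which(p$parent_id == "0.2")]), "0.2.1")

  expect_error(build_pedigree(c("0", "1.1")),
               class = "switchscope_structural_error")
  expect_error(build_pedigree(c("0", "0")),
               class = "switchscope_structural_error")
  expect_error(build_pedigree(c("0", "a.b")),
               class = "switchscope_structural_error")

  single <- build_pedigree("0")
  expect_equal(nrow(single), 1)
  expect_true(is.na(single$parent_id))
})

test_that("name -> forest -> name round trip is the identity on random pedigrees", {
  set.seed(7)
  for (r in 1:10) {
    ids <- "0"
    for (i in 1:30) {
      parent <- sample(ids, 1)
      kids <- sum(startsWith(ids, paste0(parent, ".")) &
                    !grepl(".", sub(paste0("^", gsub("\\.", "\\\\.", parent),
                                           "\\."), "", ids), fixed = TRUE))
      ids <- c(ids, paste0(parent, ".", kids + 1))
    }
    p <- build_pedigree(ids)
    expect_setequal(p$cell_id, ids)
    # every non-root's parent is present and one level shallower
    non_root <- p[!is.na(p$parent_id), ]
    expect_true(all(non_root$parent_id %in% p$cell_id))
    expect_equal(p$depth[match(non_root$parent_id, p$cell_id)],
                 non_root$depth - 1L)
  }
})

test_that("trace smoothing is exact on constants and faithful on smooth rises", {
  const <- tibble::tibble(frame = 0:40, value = 5)
  expect_equal(smooth_trace(const)$smoothed, rep(5, 41))
  expect_error(smooth_trace(const, span = 0), class = "switchscope_config_error")
  expect_error(smooth_trace(const, span = 1.5), class = "switchscope_config_error")
  expect_error(smooth_trace(const[1:3, ]), class = "switchscope_data_error")

  cfg <- switch_model_config()
  t_min <- (0:120) * 12
  curve <- switchscope:::reporter_curve(t_min, 10 * 60, cfg)
  noiseless <- tibble::tibble(frame = 0:120, value = curve)
  sm <- smooth_trace(noiseless, span = 0.04)
  expect_lt(max(abs(sm$smoothed - curve)), 0.01 * diff(range(curve)))

  set.seed(3)
  noise_sd <- 0.05 * cfg$opaque_level
  noisy <- tibble::tibble(frame = 0:120,
                          value = curve + rnorm(121, 0, noise_sd))
  sm2 <- smooth_trace(noisy, span = 0.08)
  expect_lt(max(abs(sm2$smoothed - curve)), 3 * noise_sd)
})

test_that("switch classification separates white, switching and opaque traces", {
  cfg <- switch_model_config()
  flat <- tibble::tibble(frame = 0:60, value = rep(1, 61))
  expect_equal(classify_switch(flat, 1, 40)$state, "white")

  t_min <- (0:120) * 12
  rise <- tibble::tibble(frame = 0:120,
                         value = switchscope:::reporter_curve(t_min, 9 * 60, cfg))
  cs <- classify_switch(rise, 1, 40)
  expect_equal(cs$state, "switching")
  expect_equal(cs$rise_10_90, 3, tolerance = 0.15)
  expect_equal(cs$t_max, 9 + (3 / (2 * log(9))) * log(19), tolerance = 0.25)

  high <- tibble::tibble(frame = 0:60, value = rep(40, 61))
  expect_equal(classify_switch(high, 1, 40)$state, "opaque")

  short <- tibble::tibble(frame = 0:1, value = c(1, 1))
  out <- classify_switch(short, 1, 40)
  expect_equal(out$state, "white")
  expect_true(out$low_confidence)

  expect_error(classify_switch(flat, 40, 1), class = "switchscope_config_error")
})

test_that("raising every trace value never flips a call away from opaque", {
  cfg <- switch_model_config()
  set.seed(9)
  t_min <- (0:120) * 12
  for (r in 1:15) {
    t_mid <- runif(1, 3, 20) * 60
    base <- switchscope:::reporter_curve(t_min, t_mid, cfg)
    v <- base * rlnorm(121, 0, 0.05)
    tr <- tibble::tibble(frame = 0:120, value = v)
    s1 <- classify_switch(tr, 1, 40)$state
    tr_up <- tibble::tibble(frame = 0:120, value = v + runif(1, 0.5, 10))
    s2 <- classify_switch(tr_up, 1, 40)$state
    rank <- c(white = 1, switching = 2, opaque = 2)
    expect_gte(rank[[s2]], rank[[s1]])
  }
})

test_that("synchronous pairs, four-cell patterns and mixed fates group correctly", {
  fi <- 12
  cells <- tibble::tibble(trap_id = 1L,
                          cell_id = c("0", "0.1", "0.2", "0.3", "0.1.1"),
                          birth_frame = c(0L, 10L, 30L, 50L, 50L))

  # direct pair: mother activates with newest daughter at frame 50
  calls <- dplyr::bind_rows(fake_calls(c("0", "0.3"), c(0, 50), 50),
                            white_call(c("0.1", "0.2", "0.1.1"),
                                       c(10, 30, 50)))
  g <- group_switching_cells(cells, calls, fi)
  expect_equal(nrow(g), 1)
  expect_equal(g$label, "direct-pair")
  expect_equal(g$n_pairs, 1L)
  expect_equal(count_events(g, 1)$count, 1L)
  expect_equal(count_events(g, 2)$count, 1L)
  expect_equal(count_events(g, 3)$count, 1L)

  # four-cell pattern: mother + previous daughter + new daughter +
  # granddaughter all activating simultaneously
  calls4 <- dplyr::bind_rows(
    fake_calls(c("0", "0.1", "0.3", "0.1.1"), c(0, 10, 50, 50), 50),
    white_call("0.2", 30))
  g4 <- group_switching_cells(cells, calls4, fi)
  expect_equal(nrow(g4), 1)
  expect_equal(g4$label, "four-cell")
  expect_equal(g4$n_cells, 4L)
  expect_equal(g4$n_pairs, 2L)
  expect_equal(count_events(g4, 1)$count, 2L)
  expect_equal(count_events(g4, 2)$count, 1L)
  expect_equal(count_events(g4, 3)$count, 1L)

  # mixed fate: first daughter's lineage switches at frame 60, the mother
  # with her third daughter at frame 50; second daughter never switches
  calls_m <- dplyr::bind_rows(
    fake_calls(c("0", "0.3"), c(0, 50), 50),
    fake_calls(c("0.1", "0.1.1"), c(10, 50), 60),
    white_call("0.2", 30))
  gm <- group_switching_cells(cells, calls_m, fi)
  expect_equal(nrow(gm), 2)
  expect_true(all(gm$label == "mixed-fate-member"))
  expect_equal(sort(gm$divisions_from_ancestor), c(0L, 1L))
  expect_equal(count_events(gm, 1)$count, 2L)
  expect_equal(count_events(gm, 2)$count, 2L)
  expect_equal(count_events(gm, 3)$count, 1L)

  # two unrelated founders switching independently stay separate under
  # every scheme
  cells2 <- tibble::tibble(trap_id = 1L, cell_id = c("0", "0.1", "1", "1.1"),
                           birth_frame = c(0L, 20L, 0L, 40L))
  calls2 <- dplyr::bind_rows(fake_calls(c("0", "0.1"), c(0, 20), 20),
                             fake_calls(c("1", "1.1"), c(0, 40), 40))
  g2 <- group_switching_cells(cells2, calls2, fi)
  expect_equal(count_events(g2, 3)$count, 2L)
})

test_that("calls missing for pedigree cells raise a structural error", {
  cells <- tibble::tibble(trap_id = 1L, cell_id = c("0", "0.1"),
                          birth_frame = c(0L, 5L))
  calls <- white_call("0")
  expect_error(group_switching_cells(cells, calls),
               class = "switchscope_data_error")
})

test_that("full runs keep mixed-fate separations inside the heritable span", {
  cfg <- small_switch_cfg(p_predispose = 2e-3, p_activate = 0.4, seed = 77)
  cfg$n_traps <- 15L
  exp <- simulate_pedigrees(cfg)
  expect_gt(nrow(exp$events), 0)
  expect_true(all(exp$events$depth >= 1 & exp$events$depth <= 4))
  traces <- simulate_traces(exp)
  calls <- classify_cells(traces, cfg$white_level, cfg$opaque_level)
  g <- group_switching_cells(exp$cells, calls)
  # scheme monotonicity on real grouped output
  for (sc in list(c(1, 2), c(2, 3))) {
    a <- count_events(g, sc[1], trap_ids = 1:15)$count
    b <- count_events(g, sc[2], trap_ids = 1:15)$count
    expect_true(all(a >= b))
  }
})
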