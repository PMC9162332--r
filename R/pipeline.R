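#' Assemble a full-run configuration
#'
#' Bundles the stage configurations with a single global seed; every
#' stochastic stage derives its own seed deterministically from the global
#' seed and the stage name, so any stage can be re-run in isolation from
#' its on-disk inputs.
#'
#' @param switch_cfg A [switch_model_config()].
#' @param flow_cfg A [flow_model_config()].
#' @param seg_params A [segmentation_params()].
#' @param schemes Event-counting schemes to evaluate.
#' @param gof_reps Monte-Carlo replicates for the goodness-of-fit test.
#' @param k_max Tail-pooling class for the Poisson null.
#' @param flow_strains Constructs to fit (must have `type = "fusion"`).
#' @param flow_replicates Replicate strain-day datasets per construct.
#' @param n_render_traps Traps to render and push through the imaging path
#'   (registration, segmentation, tracking) as a pipeline self-check.
#' @param seed Global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(switch_cfg = switch_model_config(),
                       flow_cfg = flow_model_config(),
                       seg_params = segmentation_params(),
                       schemes = c(1, 2, 3), gof_reps = 2000, k_max = 4,
                       flow_strains = c("Wor1-mGFP", "Wor1-GFP"),
                       flow_replicates = 8,
                       n_render_traps = 0,
                       seed = 1L) {
  switch_cfg$rng_seed <- derive_seed(seed, "simulate")
  flow_cfg$rng_seed <- derive_seed(seed, "flow")
  structure(list(switch_cfg = switch_cfg, flow_cfg = flow_cfg,
                 seg_params = seg_params, schemes = schemes,
                 gof_reps = gof_reps, k_max = k_max,
                 flow_strains = flow_strains,
                 flow_replicates = flow_replicates,
                 n_render_traps = n_render_traps,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order `simulate` (pedigrees and
#' traces), `segment` (render a subset of traps and recover traces through
#' registration, segmentation and tracking), `call` (trace smoothing and
#' switch classification), `eventstats` (per-scheme event counts, Poisson
#' zero-class null, Monte-Carlo goodness-of-fit), and `flowfit` (replicate
#' synthetic plates, gating, normalization, robust Hill fits, per-construct
#' summary).  Intermediate artifacts are written as plain TSV/CSV/JSON so
#' every stage can be re-run from disk; the machine-readable report
#' collects all headline numbers and provenance.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("simulate", "segment", "call", "eventstats", "flowfit")`.
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return The run report (list), invisibly written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "call", "eventstats", "flowfit"),
                         out_dir = NULL) {
  stages <- match.arg(stages, c("simulate", "segment", "call", "eventstats",
                                "flowfit"), several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  scfg <- config$switch_cfg
  report <- list(seed = config$seed, stages = stages,
                 defaults = list(
                   p_predispose = scfg$p_predispose,
                   p_activate = scfg$p_activate,
                   predispose_span = scfg$predispose_span,
                   n_traps = scfg$n_traps,
                   frame_interval = scfg$frame_interval,
                   gof_reps = config$gof_reps, k_max = config$k_max))
  state <- list()

  need <- function(what, stage) {
    if (is.null(state[[what]]))
      abort(sprintf("stage '%s' needs '%s': run the '%s' stage first",
                    stage, what,
                    c(experiment = "simulate", traces = "simulate",
                      calls = "call")[[what]]),
            class = "switchscope_data_error")
    state[[what]]
  }

  if ("simulate" %in% stages) {
    state$experiment <- simulate_pedigrees(scfg)
    state$traces <- simulate_traces(state$experiment)
    report$simulate <- list(
      n_cells = nrow(state$experiment$cells),
      n_events = nrow(state$experiment$events),
      n_predispositions = nrow(state$experiment$predispositions))
    if (!is.null(out_dir)) {
      write_pedigree_tsv(state$experiment$cells,
                         file.path(out_dir, "pedigree.tsv"))
      write_traces_tsv(state$traces, file.path(out_dir, "traces.tsv"))
    }
  }

  if ("segment" %in% stages && config$n_render_traps > 0) {
    exp <- need("experiment", "segment")
    traps <- unique(exp$cells$trap_id[exp$cells$class == "switching"])
    if (!length(traps)) traps <- unique(exp$cells$trap_id)
    traps <- head(traps, config$n_render_traps)
    seg_summary <- lapply(traps, function(tr) {
      cells <- exp$cells[exp$cells$trap_id == tr, ]
      cells <- head(cells[order(cells$birth_frame), ], 12)
      mv <- render_movie(cells, scfg, n_frames = min(scfg$n_frames, 30),
                         seed = derive_seed(scfg$rng_seed, paste0("render", tr)))
      tk <- extract_traces(mv, config$seg_params)
      list(trap_id = tr, n_tracks = length(unique(tk$track_id)),
           n_cells_rendered = nrow(cells) - length(mv$dropped))
    })
    report$segment <- seg_summary
  }

  if ("call" %in% stages) {
    traces <- need("traces", "call")
    state$calls <- classify_cells(traces, scfg$white_level, scfg$opaque_level,
                                  frame_interval = scfg$frame_interval)
    report$call <- list(states = as.list(table(state$calls$state)))
    if (!is.null(out_dir))
      write_calls_tsv(state$calls, file.path(out_dir, "calls.tsv"))
  }

  if ("eventstats" %in% stages) {
    calls <- need("calls", "eventstats")
    exp <- need("experiment", "eventstats")
    groups <- group_switching_cells(exp$cells, calls,
                                    frame_interval = scfg$frame_interval)
    res <- list()
    for (sc in config$schemes) {
      tab <- count_events(groups, sc, trap_ids = seq_len(scfg$n_traps))
      n0 <- sum(tab$count == 0)
      entry <- list(scheme = sc, n_zero = n0, n_traps = scfg$n_traps,
                    total_events = sum(tab$count))
      if (n0 > 0 && n0 < scfg$n_traps) {
        lam <- estimate_lambda(n0, scfg$n_traps)
        gof <- gof_monte_carlo(tab, poisson_expected(lam, scfg$n_traps,
                                                     config$k_max),
                               reps = config$gof_reps,
                               seed = derive_seed(config$seed,
                                                  paste0("gof", sc)))
        entry <- c(entry, list(lambda = lam, chi2 = gof$chi2,
                               p_value = gof$p_value, reps = gof$reps))
      }
      res[[paste0("scheme", sc)]] <- entry
      if (!is.null(out_dir))
        utils::write.table(tab, file.path(out_dir,
                                          paste0("counts_scheme", sc, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    report$eventstats <- res
  }

  if ("flowfit" %in% stages) {
    fits <- list(); construct <- character(0)
    for (strain in config$flow_strains) {
      for (r in seq_len(config$flow_replicates)) {
        fits[[length(fits) + 1L]] <- fit_strain_day(config$flow_cfg, strain, r)
        construct <- c(construct, strain)
      }
    }
    ftab <- tibble(construct = construct,
                   replicate = unlist(lapply(table(construct)[unique(construct)],
                                             seq_len)),
                   h = vapply(fits, `[[`, 0, "h"),
                   log_K = vapply(fits, `[[`, 0, "log_K"),
                   c = vapply(fits, `[[`, 0, "c"),
                   d = vapply(fits, `[[`, 0, "d"),
                   converged = vapply(fits, `[[`, TRUE, "converged"))
    smry <- summarize_fits(ftab)
    report$flowfit <- list(
      by_construct = lapply(seq_len(nrow(smry$by_construct)), function(i)
        as.list(smry$by_construct[i, ])),
      K_ratio = smry$K_ratio, p_h = smry$p_h, p_logK = smry$p_logK)
    if (!is.null(out_dir)) {
      utils::write.table(ftab, file.path(out_dir, "hill_fits.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
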