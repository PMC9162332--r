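#' Simulate trap pedigrees under the two-step switching model
#'
#' Grows one clonal population per microfluidic trap from `n_founders` cells,
#' with Gamma-distributed division times, and applies the two-step stochastic
#' switching model: a per-division Bernoulli *predisposition* event whose
#' heritable span (in divisions) is drawn uniformly from
#' `cfg$predispose_span`, and, within predisposed lineages, a per-division
#' Bernoulli *activation* event that always captures the current
#' mother-daughter pair jointly.  Activated cells and all their descendants
#' remain opaque.
#'
#' Trap crowding is modeled with a fixed resident capacity: once a trap is
#' full, newborn cells are pushed out of the field and leave the record,
#' except newborns of predisposed or activated lineages, which stay and
#' displace a random unremarkable white resident.  This retention bias
#' emulates manually curated tracking that follows event lineages.
#'
#' Dotted cell names encode the pedigree: cell `"2.1"` is the first daughter
#' of cell `"2"`.  Founders get single-token names `"0"`, `"1"`, ...
#'
#' @param cfg A [switch_model_config()].
#' @param seed Optional integer overriding `cfg$rng_seed`.
#'
#' @return An object of class `trap_experiment`: a list with
#'   \describe{
#'     \item{cells}{tibble of tracked cells: `trap_id`, `cell_id`,
#'       `parent_id`, `birth_min`, `end_min`, `birth_frame`, `end_frame`,
#'       `class` (white / predisposed / switching / opaque), `predis_id`,
#'       `event_id`, `event_min`, `event_depth`, `t_mid_min` (reporter rise
#'       midpoint, inherited by descendants of an event).}
#'     \item{events}{ground-truth activation events (one per mother-daughter
#'       pair): trap, predisposition id, time, depth in divisions from the
#'       establishment of the predisposed pedigree.}
#'     \item{predispositions}{ground-truth first events: trap, time, drawn
#'       heritability span, establishing cell.}
#'     \item{pushed_out}{per-trap count of cells pushed out of the field.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_pedigrees <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "switch_model_config"))
  with_seed(if (is.null(seed)) cfg$rng_seed else seed, {
    traps <- lapply(seq_len(cfg$n_traps), function(tr) simulate_one_trap(cfg, tr))
  })
  structure(list(
    cells = dplyr::bind_rows(lapply(traps, `[[`, "cells")),
    events = dplyr::bind_rows(lapply(traps, `[[`, "events")),
    predispositions = dplyr::bind_rows(lapply(traps, `[[`, "predis")),
    pushed_out = tibble(trap_id = seq_len(cfg$n_traps),
                        n = vapply(traps, `[[`, 0L, "pushed")),
    config = cfg
  ), class = "trap_experiment")
}

#' @export
print.trap_experiment <- function(x, ...) {
  cat(sprintf("<trap_experiment> %d traps, %d tracked cells, %d activation events (%d predispositions)\n",
              x$config$n_traps, nrow(x$cells), nrow(x$events),
              nrow(x$predispositions)))
  invisible(x)
}

# Event-driven simulation of a single trap.  State codes: 0 white,
# 1 predisposed, 2 opaque (activated or born opaque).
simulate_one_trap <- function(cfg, trap_id) {
  total_min <- (cfg$n_frames - 1) * cfg$frame_interval
  gshape <- (cfg$division_time[["mean"]] / cfg$division_time[["sd"]])^2
  grate <- gshape / cfg$division_time[["mean"]]
  cap <- cfg$trap_capacity

  nmax <- cap + 64L
  id <- character(nmax); parent <- rep(NA_integer_, nmax)
  birth <- numeric(nmax); endt <- rep(NA_real_, nmax)
  nextd <- rep(Inf, nmax); ndau <- integer(nmax)
  state <- integer(nmax); remaining <- integer(nmax)
  predis <- rep(NA_integer_, nmax); ever_pred <- logical(nmax)
  event <- rep(NA_integer_, nmax); event_min <- rep(NA_real_, nmax)
  event_depth <- rep(NA_integer_, nmax); tmid <- rep(NA_real_, nmax)
  resident <- logical(nmax)

  n <- cfg$n_founders
  for (i in seq_len(n)) {
    id[i] <- as.character(i - 1L)
    birth[i] <- 0; nextd[i] <- rgamma(1, gshape, grate); resident[i] <- TRUE
  }
  n_res <- n
  pushed <- 0L
  spans <- integer(0)      # heritability span per predisposition id
  ev_rows <- list(); pd_rows <- list()

  grow <- function() {
    add <- nmax
    id <<- c(id, character(add)); parent <<- c(parent, rep(NA_integer_, add))
    birth <<- c(birth, numeric(add)); endt <<- c(endt, rep(NA_real_, add))
    nextd <<- c(nextd, rep(Inf, add)); ndau <<- c(ndau, integer(add))
    state <<- c(state, integer(add)); remaining <<- c(remaining, integer(add))
    predis <<- c(predis, rep(NA_integer_, add)); ever_pred <<- c(ever_pred, logical(add))
    event <<- c(event, rep(NA_integer_, add)); event_min <<- c(event_min, rep(NA_real_, add))
    event_depth <<- c(event_depth, rep(NA_integer_, add)); tmid <<- c(tmid, rep(NA_real_, add))
    resident <<- c(resident, logical(add))
    nmax <<- nmax + add
  }

  repeat {
    i <- which.min(nextd)
    t <- nextd[i]
    if (!is.finite(t) || t > total_min) break
    nextd[i] <- t + rgamma(1, gshape, grate)
    ndau[i] <- ndau[i] + 1L

    # daughter's provisional state follows the pair rules below
    d_state <- 0L; d_rem <- 0L; d_predis <- NA_integer_
    d_event <- NA_integer_; d_tmid <- NA_real_; d_depth <- NA_integer_
    activated <- FALSE

    if (state[i] == 2L) {                       # opaque mother -> opaque daughter
      d_state <- 2L; d_tmid <- tmid[i]; d_predis <- predis[i]
    } else if (state[i] == 1L) {                # activation trial
      if (runif(1) < cfg$p_activate) {
        activated <- TRUE
        pid <- predis[i]
        dep <- spans[pid] - remaining[i] + 1L
        ev <- length(ev_rows) + 1L
        state[i] <- 2L; event[i] <- ev; event_min[i] <- t
        event_depth[i] <- dep; tmid[i] <- t + cfg$rise_offset_min
        d_state <- 2L; d_event <- ev; d_tmid <- tmid[i]
        d_depth <- dep; d_predis <- pid
        ev_rows[[ev]] <- tibble(trap_id = trap_id, event_id = ev,
                                predis_id = pid, t_min = t, depth = dep,
                                mother = id[i])
      } else {
        r <- remaining[i] - 1L
        d_predis <- predis[i]; d_rem <- r
        d_state <- if (r > 0L) 1L else 0L
        remaining[i] <- r
        if (r == 0L) state[i] <- 0L
      }
    } else if (runif(1) < cfg$p_predispose) {   # establishment of predisposition
      pid <- length(pd_rows) + 1L
      s <- if (length(cfg$predispose_span) == 1L) cfg$predispose_span
           else sample(cfg$predispose_span, 1L)
      spans <- c(spans, as.integer(s))
      state[i] <- 1L; remaining[i] <- as.integer(s); predis[i] <- pid
      ever_pred[i] <- TRUE
      d_state <- 1L; d_rem <- as.integer(s); d_predis <- pid
      pd_rows[[pid]] <- tibble(trap_id = trap_id, predis_id = pid, t_min = t,
                               span = as.integer(s), cell = id[i])
    }

    keep <- n_res < cap
    displaced <- FALSE
    if (!keep && d_state != 0L) {
      # event/predisposed lineages stay; displace a random white resident
      cand <- which(resident & state == 0L)
      if (length(cand)) {
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        resident[j] <- FALSE; endt[j] <- t; nextd[j] <- Inf
        keep <- TRUE; displaced <- TRUE
      }
    }
    if (keep) {
      n <- n + 1L
      if (n > nmax) grow()
      id[n] <- paste0(id[i], ".", ndau[i])
      parent[n] <- i; birth[n] <- t
      nextd[n] <- t + rgamma(1, gshape, grate)
      state[n] <- d_state; remaining[n] <- d_rem; predis[n] <- d_predis
      ever_pred[n] <- d_state == 1L
      event[n] <- d_event; event_min[n] <- if (is.na(d_event)) NA_real_ else t
      event_depth[n] <- d_depth; tmid[n] <- d_tmid
      resident[n] <- TRUE
      if (!displaced) n_res <- n_res + 1L
    } else {
      pushed <- pushed + 1L
      if (activated) ev_rows[[length(ev_rows)]]$daughter_pushed <- TRUE
    }
  }

  keep_idx <- seq_len(n)
  endt[is.na(endt[keep_idx])] <- total_min
  fi <- cfg$frame_interval
  cls <- c("white", "predisposed", "opaque")[state[keep_idx] + 1L]
  cls[state[keep_idx] == 0L & ever_pred[keep_idx]] <- "predisposed"
  cls[!is.na(event[keep_idx])] <- "switching"
  cells <- tibble(
    trap_id = trap_id,
    cell_id = id[keep_idx],
    parent_id = ifelse(is.na(parent[keep_idx]), NA_character_, id[parent[keep_idx]]),
    birth_min = birth[keep_idx], end_min = endt[keep_idx],
    birth_frame = as.integer(ceiling(birth[keep_idx] / fi)),
    end_frame = pmax(as.integer(floor(endt[keep_idx] / fi)),
                     as.integer(ceiling(birth[keep_idx] / fi))),
    class = cls,
    predis_id = predis[keep_idx],
    event_id = event[keep_idx], event_min = event_min[keep_idx],
    event_depth = event_depth[keep_idx], t_mid_min = tmid[keep_idx]
  )
  list(cells = cells,
       events = if (length(ev_rows)) dplyr::bind_rows(ev_rows) else
         tibble(trap_id = integer(), event_id = integer(), predis_id = integer(),
                t_min = numeric(), depth = integer(), mother = character()),
       predis = if (length(pd_rows)) dplyr::bind_rows(pd_rows) else
         tibble(trap_id = integer(), predis_id = integer(), t_min = numeric(),
                span = integer(), cell = character()),
       pushed = pushed)
}

# Logistic reporter rise: white -> opaque with 10-90% span rise_time_10_90
# hours centered at t_mid (minutes).
reporter_curve <- function(t_min, t_mid_min, cfg) {
  s_h <- cfg$rise_time_10_90 / (2 * log(9))
  f <- stats::plogis((t_min - t_mid_min) / 60 / s_h)
  cfg$white_level + (cfg$opaque_level - cfg$white_level) * f
}

#' Simulate per-cell reporter traces for a trap experiment
#'
#' Generates the top-pixel reporter metric per tracked cell and frame without
#' rendering images: white and predisposed cells fluctuate around
#' `white_level`; cells of an activation event (and their descendants) follow
#' the configured logistic rise to `opaque_level`, all members of one event
#' sharing the same rise midpoint (synchronous activation).  Multiplicative
#' lognormal noise of cv `trace_noise_cv` is applied.
#'
#' @param experiment A `trap_experiment` from [simulate_pedigrees()].
#' @param seed Optional integer seed (default derives from the experiment's
#'   config seed).
#' @return A tibble with one row per cell: `trap_id`, `cell_id`,
#'   `birth_frame`, `end_frame`, and list-columns `frames`, `values`.
#' @export
simulate_traces <- function(experiment, seed = NULL) {
  stopifnot(inherits(experiment, "trap_experiment"))
  cfg <- experiment$config
  if (is.null(seed)) seed <- derive_seed(cfg$rng_seed, "traces")
  cells <- experiment$cells
  fi <- cfg$frame_interval
  with_seed(seed, {
    frames <- mapply(seq, cells$birth_frame, cells$end_frame, SIMPLIFY = FALSE)
    values <- vector("list", nrow(cells))
    sdlog <- sqrt(log(1 + cfg$trace_noise_cv^2))
    for (k in seq_len(nrow(cells))) {
      fr <- frames[[k]]
      base <- if (is.na(cells$t_mid_min[k])) rep(cfg$white_level, length(fr))
              else reporter_curve(fr * fi, cells$t_mid_min[k], cfg)
      values[[k]] <- base * rlnorm(length(fr), -sdlog^2 / 2, sdlog)
    }
  })
  tibble(trap_id = cells$trap_id, cell_id = cells$cell_id,
         birth_frame = cells$birth_frame, end_frame = cells$end_frame,
         frames = frames, values = values)
}

#' Generate standalone switching-cell traces
#'
#' Draws `n` single-cell reporter traces of cells that switch, with the time
#' from birth to maximal reporter level drawn from the configured truncated
#' lognormal (defaults: mean 9.9 h, sd 3.2 h, truncated to 5.4-17.2 h) and
#' the configured 10-90% rise time (default 3 h).  Used to study activation
#' kinetics in isolation from pedigree structure.
#'
#' @param n Number of traces.
#' @param cfg A [switch_model_config()].
#' @param seed Optional integer seed.
#' @return A list with `traces` (tibble of `cell_id`, list-columns `frames`,
#'   `values`) and `ground_truth` (tibble of drawn `birth_to_max_h` and rise
#'   midpoint `t_mid_h`).
#' @export
make_switch_traces <- function(n, cfg = switch_model_config(), seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(cfg$rng_seed, "switch_traces")
  fi <- cfg$frame_interval
  fr <- seq(0L, cfg$n_frames - 1L)
  s_h <- cfg$rise_time_10_90 / (2 * log(9))
  sdlog <- sqrt(log(1 + cfg$trace_noise_cv^2))
  with_seed(seed, {
    btm <- rlnorm_trunc(n, cfg$birth_to_max_lnorm$meanlog,
                        cfg$birth_to_max_lnorm$sdlog,
                        cfg$birth_to_max[["min"]], cfg$birth_to_max[["max"]])
    # the cell reaches 95% of its plateau (the operational "maximum") at
    # t_mid + s * log(0.95/0.05 * ...): place the midpoint accordingly
    t_mid <- btm - s_h * log(19)
    values <- lapply(seq_len(n), function(k) {
      base <- reporter_curve(fr * fi, t_mid[k] * 60, cfg)
      base * rlnorm(length(fr), -sdlog^2 / 2, sdlog)
    })
  })
  list(traces = tibble(cell_id = as.character(seq_len(n)),
                       birth_frame = 0L, end_frame = cfg$n_frames - 1L,
                       frames = rep(list(fr), n), values = values),
       ground_truth = tibble(cell_id = as.character(seq_len(n)),
                             birth_to_max_h = btm, t_mid_h = t_mid))
}
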