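#' Build a pedigree forest from dotted cell names
#'
#' Dotted names encode lineage: the parent of `"2.1"` is `"2"`; root cells
#' have single-token names.  Returns the forest implied by the names, with
#' daughter order given by the numeric suffix.
#'
#' @param records A character vector of cell names, or a data frame with a
#'   `cell_id` column.
#' @return A tibble of class `pedigree`: `cell_id`, `parent_id` (`NA` for
#'   roots), `root_id`, `depth` (divisions from the root), `daughter_rank`.
#' @export
#' @examples
#' build_pedigree(c("0", "0.1", "0.2", "0.2.1"))
build_pedigree <- function(records) {
  ids <- if (is.character(records)) records else records$cell_id
  if (anyDuplicated(ids))
    abort(paste0("duplicated cell names: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "switchscope_structural_error")
  bad <- ids[!grepl("^[0-9]+(\\.[0-9]+)*$", ids)]
  if (length(bad))
    abort(paste0("malformed cell names: ", paste(bad, collapse = ", ")),
          class = "switchscope_structural_error")
  parent <- sub("\\.[0-9]+$", "", ids)
  parent[!grepl(".", ids, fixed = TRUE)] <- NA_character_
  orphan <- !is.na(parent) & !(parent %in% ids)
  if (any(orphan))
    abort(paste0("parent cell(s) missing from record: ",
                 paste(unique(parent[orphan]), collapse = ", ")),
          class = "switchscope_structural_error")
  depth <- lengths(regmatches(ids, gregexpr(".", ids, fixed = TRUE)))
  depth[!grepl(".", ids, fixed = TRUE)] <- 0L
  rank <- suppressWarnings(as.integer(sub("^.*\\.", "", ids)))
  rank[is.na(parent)] <- NA_integer_
  root <- sub("\\..*$", "", ids)
  out <- tibble(cell_id = ids, parent_id = parent, root_id = root,
                depth = as.integer(depth), daughter_rank = rank)
  out <- out[order(out$root_id, out$depth, out$parent_id, out$daughter_rank), ]
  class(out) <- c("pedigree", class(out))
  out
}

#' Smooth a single-cell trace
#'
#' Locally weighted linear (LOESS-family) smoothing of a reporter trace via
#' [stats::lowess()] with zero robustness iterations, so the smoother is a
#' linear operator in the values (constant traces pass through unchanged and
#' raising every value can only raise the smooth).
#'
#' @param trace A data frame with `frame` and `value` columns.
#' @param span Smoothing span as a fraction of points, in (0, 1].
#' @return The trace with a `smoothed` column appended.
#' @export
smooth_trace <- function(trace, span = 0.3) {
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    abort("`span` must be in (0, 1]", class = "switchscope_config_error")
  if (nrow(trace) < 5)
    abort("trace must have at least 5 points", class = "switchscope_data_error")
  sm <- lowess(trace$frame, trace$value, f = span, iter = 0)
  trace$smoothed <- sm$y
  trace
}

first_upcross <- function(t, y, thr) {
  i <- which(y >= thr)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  t[i - 1] + (t[i] - t[i - 1]) * (thr - y[i - 1]) / (y[i] - y[i - 1])
}

#' Classify the switching state of a single-cell trace
#'
#' A cell is called *opaque-level* when its smoothed trace exceeds the
#' geometric mean of the white and opaque reference levels for at least
#' `persistence` consecutive frames (a scale-free midpoint in log space,
#' robust to single-frame noise).  Cells that were already above that
#' threshold at birth are `"opaque"`; cells that crossed it during their
#' trace are `"switching"`; anything else is `"white"`.
#'
#' Kinetic quantities are measured on a lightly smoothed trace (span
#' `kin_span`, default 0.05) with linear interpolation between frames:
#' `t_activation_start` is the first crossing of 10% of the white-to-opaque
#' range, `rise_10_90` the time between the 10% and 90% crossings, and
#' `t_max` the first time the trace reaches 95% of the cell's own plateau
#' (median of values above the 90% threshold).  Times are hours from the
#' cell's birth (its first frame).
#'
#' @param trace Data frame with `frame`, `value` (and optionally `smoothed`)
#'   columns.
#' @param white_level,opaque_level Reference reporter levels,
#'   `opaque_level > white_level`.
#' @param frame_interval Minutes per frame.
#' @param span Smoothing span for state calling.
#' @param kin_span Smoothing span for kinetic measurements.
#' @param persistence Consecutive frames required above threshold.
#' @return A one-row tibble: `state`, `t_activation_start`, `t_max`,
#'   `rise_10_90` (hours), the thresholds used, and a `low_confidence` flag
#'   for traces shorter than the persistence window.
#' @export
classify_switch <- function(trace, white_level, opaque_level,
                            frame_interval = 12, span = 0.3,
                            kin_span = 0.05, persistence = 3) {
  if (opaque_level <= white_level)
    abort("`opaque_level` must exceed `white_level`",
          class = "switchscope_config_error")
  thr_gate <- sqrt(white_level * opaque_level)
  thr10 <- white_level + 0.10 * (opaque_level - white_level)
  thr90 <- white_level + 0.90 * (opaque_level - white_level)
  empty <- tibble(state = "white", t_activation_start = NA_real_,
                  t_threshold = NA_real_, t_max = NA_real_,
                  rise_10_90 = NA_real_,
                  thr_gate = thr_gate, thr10 = thr10, thr90 = thr90,
                  low_confidence = TRUE)
  if (nrow(trace) < max(5, persistence)) return(empty)

  if (!("smoothed" %in% names(trace))) trace <- smooth_trace(trace, span)
  above <- trace$smoothed > thr_gate
  r <- rle(above)
  sustained <- any(r$values & r$lengths >= persistence)
  if (!sustained)
    return(tibble(state = "white", t_activation_start = NA_real_,
                  t_threshold = NA_real_, t_max = NA_real_,
                  rise_10_90 = NA_real_,
                  thr_gate = thr_gate, thr10 = thr10, thr90 = thr90,
                  low_confidence = FALSE))

  state <- if (trace$smoothed[1] >= thr_gate) "opaque" else "switching"
  kin <- lowess(trace$frame, trace$value, f = kin_span, iter = 0)
  t_h <- (kin$x - trace$frame[1]) * frame_interval / 60
  y <- kin$y
  plateau <- if (any(y >= thr90)) median(y[y >= thr90]) else max(y)
  t_act <- first_upcross(t_h, y, thr10)
  t90 <- first_upcross(t_h, y, thr90)
  rise <- if (is.na(t_act) || is.na(t90)) NA_real_ else t90 - t_act
  t_max <- first_upcross(t_h, y, 0.95 * plateau)
  t_gate <- first_upcross(t_h, y, thr_gate)
  tibble(state = state, t_activation_start = t_act, t_threshold = t_gate,
         t_max = t_max, rise_10_90 = rise, thr_gate = thr_gate,
         thr10 = thr10, thr90 = thr90, low_confidence = FALSE)
}

#' Classify every cell trace of an experiment
#'
#' Applies [classify_switch()] to each row of a trace table (as produced by
#' [simulate_traces()] or read from a trace TSV).  Traces whose raw maximum
#' stays below the 10% rise threshold cannot reach the (higher) calling
#' threshold under a linear smoother and are assigned `"white"` directly.
#'
#' @param traces Tibble with `cell_id`, `birth_frame`, and list-columns
#'   `frames`, `values` (plus optional `trap_id`).
#' @param white_level,opaque_level Reference levels.
#' @inheritParams classify_switch
#' @return A tibble with one row per cell: identifiers, `birth_frame`, and
#'   the [classify_switch()] fields.
#' @export
classify_cells <- function(traces, white_level, opaque_level,
                           frame_interval = 12, span = 0.3,
                           kin_span = 0.05, persistence = 3) {
  thr10 <- white_level + 0.10 * (opaque_level - white_level)
  n <- nrow(traces)
  out <- vector("list", n)
  white_row <- classify_switch(
    tibble(frame = 1:10, value = rep(white_level, 10)),
    white_level, opaque_level, frame_interval, 1, 1, persistence)
  for (k in seq_len(n)) {
    v <- traces$values[[k]]
    if (max(v) < thr10) {
      out[[k]] <- white_row
    } else {
      out[[k]] <- classify_switch(
        tibble(frame = traces$frames[[k]], value = v),
        white_level, opaque_level, frame_interval, span, kin_span, persistence)
    }
  }
  calls <- dplyr::bind_rows(out)
  id_cols <- intersect(c("trap_id", "cell_id", "birth_frame"), names(traces))
  dplyr::bind_cols(traces[id_cols], calls)
}

#' Group switching cells into pedigree-connected events
#'
#' Finds maximal sets of switching cells connected by mother-daughter edges
#' within each trap's pedigree (sister cells connect only through a
#' switching mother, so switching groups separated by non-switching
#' divisions stay distinct).  Each group records the number of synchronous
#' mother-daughter activation pairs it contains (`n_pairs`: daughters that
#' activated at birth; a lone switching cell counts as one pair-event).
#'
#' Groups that share a lineage-tree root of the recorded pedigree are
#' assigned the same `set_id` (the unit of the "mixed-fate pedigree"
#' counting scheme); when a set holds several groups, all its groups are
#' labeled `"mixed-fate-member"` and the number of divisions separating each
#' group's first switching cell from the set's latest common ancestor is
#' reported.  Otherwise a group is a `"direct-pair"` (one pair) or a
#' `"four-cell"` pattern (two or more synchronous pairs in one connected
#' component).
#'
#' @param cells Pedigree table with `cell_id` (dotted names) and optionally
#'   `trap_id`; typically `experiment$cells` or a curated tracking table.
#' @param calls Output of [classify_cells()] (must cover all cells).
#' @param frame_interval Minutes per frame.
#' @param sync_frames Maximum frames between a daughter's birth and its
#'   activation start for the division to count as a synchronous pair.
#' @return A tibble with one row per group: `trap_id`, `set_id`, `group_id`,
#'   `label`, `n_cells`, `n_pairs`, `first_act_frame`,
#'   `divisions_from_ancestor`, and a `cells` list-column.
#' @export
group_switching_cells <- function(cells, calls, frame_interval = 12,
                                  sync_frames = 2) {
  if (!"trap_id" %in% names(cells)) cells$trap_id <- 1L
  if (!"trap_id" %in% names(calls)) calls$trap_id <- 1L
  missing <- setdiff(cells$cell_id, calls$cell_id)
  if (length(missing))
    abort(paste0("calls missing for ", length(missing), " cell(s)"),
          class = "switchscope_data_error")
  res <- lapply(split(seq_len(nrow(cells)), cells$trap_id), function(idx) {
    group_one_trap(cells[idx, ], calls[calls$trap_id == cells$trap_id[idx[1]], ],
                   frame_interval, sync_frames)
  })
  dplyr::bind_rows(res)
}

group_one_trap <- function(cells, calls, frame_interval, sync_frames) {
  calls <- calls[match(cells$cell_id, calls$cell_id), ]
  sw <- which(calls$state == "switching")
  if (!length(sw)) return(NULL)
  ids <- cells$cell_id
  depth <- lengths(regmatches(ids, gregexpr(".", ids, fixed = TRUE)))
  parent <- sub("\\.[0-9]+$", "", ids)
  parent[depth == 0L] <- NA_character_
  # cells of one activation event share the same rise curve, so their
  # absolute threshold-crossing times coincide; connect parent-child
  # switching cells only when those times agree within the sync window
  abs_gate <- cells$birth_frame[sw] +
    calls$t_threshold[sw] * 60 / frame_interval
  comp <- seq_along(sw)
  names(comp) <- ids[sw]
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  sw_set <- ids[sw]
  for (j in seq_along(sw)) {
    p <- parent[sw[j]]
    if (!is.na(p) && p %in% sw_set) {
      jp <- match(p, sw_set)
      if (is.na(abs_gate[j]) || is.na(abs_gate[jp]) ||
          abs(abs_gate[j] - abs_gate[jp]) > sync_frames) next
      a <- find(j); b <- find(jp)
      if (a != b) comp[a] <- b
    }
  }
  groups <- vapply(seq_along(sw), find, 0)
  abs_act <- cells$birth_frame[sw] +
    calls$t_activation_start[sw] * 60 / frame_interval
  root <- sub("\\..*$", "", ids[sw])

  out <- lapply(unique(groups), function(g) {
    m <- which(groups == g)
    cid <- ids[sw][m]
    # synchronous pairs: daughters that activated at (or within sync of) birth
    at_birth <- calls$t_activation_start[sw][m] * 60 / frame_interval <= sync_frames
    is_child_of_group <- sub("\\.[0-9]+$", "", cid) %in% cid
    n_pairs <- max(1L, sum(at_birth & is_child_of_group))
    tibble(trap_id = cells$trap_id[1], set_id = root[m[1]],
           group_id = paste0(cells$trap_id[1], ":", g),
           n_cells = length(cid), n_pairs = n_pairs,
           first_act_frame = min(abs_act[m]),
           first_cell = cid[which.min(abs_act[m])],
           cells = list(cid))
  })
  out <- dplyr::bind_rows(out)
  # mixed-fate labeling and divisions from the set ancestor
  out$label <- ifelse(out$n_pairs >= 2, "four-cell", "direct-pair")
  out$divisions_from_ancestor <- NA_integer_
  for (s in unique(out$set_id)) {
    m <- which(out$set_id == s)
    if (length(m) >= 2) {
      out$label[m] <- "mixed-fate-member"
      anc <- common_ancestor(unlist(out$cells[m]))
      anc_depth <- length(strsplit(anc, ".", fixed = TRUE)[[1]]) - 1L
      for (g in m) {
        d <- length(strsplit(out$first_cell[g], ".", fixed = TRUE)[[1]]) - 1L
        out$divisions_from_ancestor[g] <- d - anc_depth
      }
    }
  }
  out
}

# latest common ancestor of dotted names = longest common token prefix
common_ancestor <- function(ids) {
  toks <- strsplit(ids, ".", fixed = TRUE)
  pre <- toks[[1]]
  for (tk in toks[-1]) {
    n <- min(length(pre), length(tk))
    eq <- which(pre[seq_len(n)] != tk[seq_len(n)])
    pre <- pre[seq_len(if (length(eq)) eq[1] - 1 else n)]
  }
  paste(pre, collapse = ".")
}
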