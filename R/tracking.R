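#' Extract per-cell fluorescence traces from a movie
#'
#' The automated end of the semiautomated pipeline: registers the movie,
#' segments every DIC frame, measures each object's top-k fluorescence
#' metric and geometry, and links objects across frames by nearest-centroid
#' matching within `max_disp` pixels (an automated aid; ambiguous links in
#' crowded fields are deferred to curated tracking tables).
#'
#' @param movie A `trap_movie`.
#' @param params A [segmentation_params()].
#' @param k Top-pixel count for the metric.
#' @param max_disp Maximum centroid displacement (pixels) to link an object
#'   to an existing track.
#' @param register Register frames before segmentation (default `TRUE`).
#' @return A tibble: `track_id`, `frame`, `cy`, `cx`, `area`, `length`,
#'   `metric`.
#' @export
extract_traces <- function(movie, params = segmentation_params(), k = 300,
                           max_disp = 15, register = TRUE) {
  if (register) movie <- register_frames(movie)$corrected
  nf <- dim(movie$dic)[3]
  rows <- list()
  last_pos <- matrix(numeric(0), 0, 2)
  last_id <- integer(0)
  next_id <- 1L
  for (f in seq_len(nf)) {
    seg <- segment_frame(movie$dic[, , f], params)
    np <- nrow(seg$props)
    if (!np) { last_pos <- matrix(numeric(0), 0, 2); last_id <- integer(0); next }
    ids <- integer(np)
    taken <- logical(length(last_id))
    for (o in seq_len(np)) {
      if (nrow(last_pos)) {
        d <- sqrt((last_pos[, 1] - seg$props$cy[o])^2 +
                    (last_pos[, 2] - seg$props$cx[o])^2)
        d[taken] <- Inf
        j <- which.min(d)
        if (length(j) && d[j] <= max_disp) {
          ids[o] <- last_id[j]; taken[j] <- TRUE; next
        }
      }
      ids[o] <- next_id; next_id <- next_id + 1L
    }
    metric <- vapply(seq_len(np), function(o)
      as.numeric(top_pixels_metric(movie$gfp[, , f], seg$labels,
                                   k = k, label = o)), 0)
    rows[[f]] <- tibble(track_id = ids, frame = f - 1L,
                        cy = seg$props$cy, cx = seg$props$cx,
                        area = seg$props$area,
                        length = seg$props$major_axis, metric = metric)
    last_pos <- cbind(seg$props$cy, seg$props$cx)
    last_id <- ids
  }
  dplyr::bind_rows(rows)
}
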