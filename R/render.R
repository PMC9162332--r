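#' Render a trap pedigree into a two-channel synthetic movie
#'
#' Draws each tracked cell as a filled ellipse on a DIC-like channel
#' (medium-gray background, dark cell interior, bright rim — the contrast
#' pattern the morphological segmenter expects) and as a
#' nuclear-concentrated spot on the GFP channel: a nuclear disc of about
#' 300 pixels at the cell's current reporter level over cytoplasm at half
#' that level, so the top-300-pixel metric reads back the generating level.
#' Switching cells follow the configured logistic rise; an optional global
#' per-frame drift is applied to both channels and recorded in the ground
#' truth.
#'
#' @param cells Tibble describing one trap's cells: `cell_id`,
#'   `birth_frame`, `end_frame`, `class`, optional `t_mid_min` (rise
#'   midpoint for switching lineages), and optional geometry overrides
#'   `cy`, `cx`, `area`, `aspect`, `theta`.
#' @param cfg A [switch_model_config()] (levels, areas, cadence).
#' @param canvas `c(rows, cols)` canvas size in pixels.
#' @param n_frames Frames to render (default `cfg$n_frames`).
#' @param drift Per-frame incremental (row, col) drift: `n_frames x 2`
#'   matrix, or `NULL` for none.
#' @param noise_sd Additive Gaussian noise sd, `c(dic, gfp)`; GFP noise is
#'   in reporter units.
#' @param seed Optional seed for the noise.
#' @return A list of class `trap_movie`: `dic`, `gfp` (arrays rows x cols x
#'   frames), `masks` (integer label arrays; label = row index in `cells`),
#'   `offsets` (tibble of the cumulative applied drift), `cells` (geometry
#'   used), `dropped` (cell ids beyond the canvas), `frame_interval`.
#' @export
render_movie <- function(cells, cfg, canvas = c(360, 360), n_frames = NULL,
                         drift = NULL, noise_sd = c(dic = 0.01, gfp = 0.02),
                         seed = NULL) {
  if (is.null(n_frames)) n_frames <- cfg$n_frames
  H <- canvas[1]; W <- canvas[2]
  n <- nrow(cells)
  cells <- as_tibble(cells)
  if (!"area" %in% names(cells))
    cells$area <- ifelse(cells$class %in% c("opaque", "switching"),
                         cfg$opaque_area, cfg$white_area)
  if (!"aspect" %in% names(cells)) cells$aspect <- 1.2
  if (!"theta" %in% names(cells))
    cells$theta <- (seq_len(n) * 2.399) %% pi
  if (!"cy" %in% names(cells) || !"cx" %in% names(cells)) {
    # sunflower layout, spacing >= largest cell diameter
    spacing <- 1.25 * 2 * sqrt(max(cells$area) * max(cells$aspect) / pi)
    k <- seq_len(n)
    r <- spacing * sqrt(k - 1)
    ang <- k * 2.399963
    cells$cy <- H / 2 + r * sin(ang)
    cells$cx <- W / 2 + r * cos(ang)
  }
  a <- sqrt(cells$area * cells$aspect / pi)   # semi-major
  b <- cells$area / (pi * a)                  # semi-minor
  margin <- a + 3
  ok <- cells$cy - margin >= 1 & cells$cy + margin <= H &
    cells$cx - margin >= 1 & cells$cx + margin <= W
  dropped <- cells$cell_id[!ok]
  if (length(dropped))
    message(length(dropped), " cell(s) beyond the trap canvas were dropped")
  if (is.null(drift)) drift <- matrix(0, n_frames, 2)
  cum <- apply(drift, 2, cumsum)

  dic <- array(0.5, c(H, W, n_frames))
  gfp <- array(0, c(H, W, n_frames))
  masks <- array(0L, c(H, W, n_frames))
  rim <- 2.5
  nuc_r <- sqrt(300 / pi)
  fi <- cfg$frame_interval

  for (f in seq_len(n_frames)) {
    fr <- f - 1L
    dicf <- matrix(0.5, H, W); gfpf <- matrix(0, H, W)
    maskf <- matrix(0L, H, W)
    for (i in which(ok)) {
      if (fr < cells$birth_frame[i] || fr > cells$end_frame[i]) next
      lev <- if ("t_mid_min" %in% names(cells) && !is.na(cells$t_mid_min[i]))
        reporter_curve(fr * fi, cells$t_mid_min[i], cfg)
      else if (cells$class[i] == "opaque") cfg$opaque_level
      else cfg$white_level
      cy <- cells$cy[i] + cum[f, 1]; cx <- cells$cx[i] + cum[f, 2]
      ext <- ceiling(a[i] + rim + 2)
      ys <- max(1, floor(cy - ext)):min(H, ceiling(cy + ext))
      xs <- max(1, floor(cx - ext)):min(W, ceiling(cx + ext))
      if (!length(ys) || !length(xs)) next
      yy <- outer(ys - cy, rep(1, length(xs)))
      xx <- outer(rep(1, length(ys)), xs - cx)
      ct <- cos(cells$theta[i]); st <- sin(cells$theta[i])
      u <- (yy * ct + xx * st) / a[i]
      v <- (-yy * st + xx * ct) / b[i]
      rr <- sqrt(u^2 + v^2)
      inside <- rr <= 1
      # rim: a band of ~rim px just inside the boundary (in minor-axis units)
      band <- rr > 1 - rim / b[i] & inside
      dsub <- dicf[ys, xs]
      dsub[inside] <- 0.36
      dsub[band] <- 0.78
      dicf[ys, xs] <- dsub
      gsub <- gfpf[ys, xs]
      gsub[inside] <- lev / 2
      nuc <- (yy^2 + xx^2) <= nuc_r^2 & inside
      gsub[nuc] <- lev
      gfpf[ys, xs] <- gsub
      msub <- maskf[ys, xs]
      msub[inside] <- i
      maskf[ys, xs] <- msub
    }
    dic[, , f] <- dicf; gfp[, , f] <- gfpf; masks[, , f] <- maskf
  }
  with_seed(seed, {
    dic <- dic + array(rnorm(length(dic), 0, noise_sd[["dic"]]), dim(dic))
    gfp <- gfp + array(rnorm(length(gfp), 0, noise_sd[["gfp"]]), dim(gfp))
  })
  structure(list(dic = dic, gfp = gfp, masks = masks,
                 offsets = tibble(frame = seq_len(n_frames) - 1L,
                                  dy = cum[, 1], dx = cum[, 2]),
                 cells = cells, dropped = dropped,
                 frame_interval = fi),
            class = "trap_movie")
}

#' Write / read a trap movie as multi-frame TIFF
#'
#' Channels are written as separate multi-frame 32-bit float TIFFs (values
#' scaled to `[0, 1]` by a factor recorded in a JSON sidecar) and the label
#' masks as a 16-bit TIFF.
#'
#' @param movie A `trap_movie`.
#' @param prefix Output path prefix; writes `<prefix>_dic.tif`,
#'   `<prefix>_gfp.tif`, `<prefix>_masks.tif`, `<prefix>_meta.json`.
#' @return `prefix`, invisibly.
#' @export
write_trap_movie <- function(movie, prefix) {
  split_frames <- function(arr) lapply(seq_len(dim(arr)[3]), function(f) arr[, , f])
  # affine-map each channel to [0, 1]; the map is recorded in the sidecar
  dmin <- min(movie$dic); dspan <- max(max(movie$dic) - dmin, 1e-9)
  gmin <- min(movie$gfp); gspan <- max(max(movie$gfp) - gmin, 1e-9)
  tiff::writeTIFF(split_frames((movie$dic - dmin) / dspan),
                  paste0(prefix, "_dic.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(split_frames((movie$gfp - gmin) / gspan),
                  paste0(prefix, "_gfp.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(split_frames(movie$masks / 65535),
                  paste0(prefix, "_masks.tif"), bits.per.sample = 16L)
  jsonlite::write_json(list(dic_min = dmin, dic_span = dspan,
                            gfp_min = gmin, gfp_span = gspan,
                            frame_interval = movie$frame_interval,
                            offsets = movie$offsets),
                       paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_trap_movie
#' @export
read_trap_movie <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  stack <- function(path) {
    fr <- tiff::readTIFF(path, all = TRUE)
    array(unlist(fr), c(dim(fr[[1]]), length(fr)))
  }
  msk <- stack(paste0(prefix, "_masks.tif"))
  structure(list(
    dic = stack(paste0(prefix, "_dic.tif")) * meta$dic_span + meta$dic_min,
    gfp = stack(paste0(prefix, "_gfp.tif")) * meta$gfp_span + meta$gfp_min,
    masks = array(as.integer(round(msk * 65535)), dim(msk)),
    offsets = as_tibble(meta$offsets),
    frame_interval = meta$frame_interval,
    cells = NULL, dropped = character()),
    class = "trap_movie")
}
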