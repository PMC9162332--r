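#' Segmentation parameters
#'
#' Structuring-element radii (pixels) for the morphological border detector
#' and the object-property ranges used to select cells.  Defaults are tuned
#' on the synthetic renderer (disc radii about a quarter of the cell
#' radius); the border threshold is Otsu's method on the filtered response
#' unless a numeric threshold is given.
#'
#' @param bottomhat_radius,tophat_radius,dilation_radius,erosion_radius
#'   Disc radii in pixels (>= 1).
#' @param area_range,perimeter_range Object selection ranges in pixels.
#' @param eccentricity_range Selection range in `[0, 1]`.
#' @param threshold `"otsu"` or a numeric threshold on the normalized
#'   border response.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(bottomhat_radius = 6, tophat_radius = 6,
                                dilation_radius = 3, erosion_radius = 3,
                                area_range = c(500, 12000),
                                perimeter_range = c(40, 2000),
                                eccentricity_range = c(0, 0.99),
                                threshold = "otsu") {
  radii <- c(bottomhat_radius, tophat_radius, dilation_radius, erosion_radius)
  if (any(radii < 1)) abort("radii must be >= 1", class = "switchscope_config_error")
  for (rg in list(area_range, perimeter_range, eccentricity_range))
    if (length(rg) != 2 || rg[2] <= rg[1])
      abort("ranges must be c(min, max) with max > min",
            class = "switchscope_config_error")
  structure(list(bottomhat_radius = bottomhat_radius,
                 tophat_radius = tophat_radius,
                 dilation_radius = dilation_radius,
                 erosion_radius = erosion_radius,
                 area_range = area_range, perimeter_range = perimeter_range,
                 eccentricity_range = eccentricity_range,
                 threshold = threshold),
            class = "segmentation_params")
}

# FFT cross-correlation translation estimate of frame b relative to frame a,
# with parabolic subpixel refinement around the correlation peak.
estimate_shift <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    warn("featureless frame: returning zero offset")
    return(c(0, 0))
  }
  A <- fft(a - mean(a)); B <- fft(b - mean(b))
  cc <- Re(fft(A * Conj(B), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  n <- dim(cc)
  sub <- function(axis) {
    i <- pk[axis]
    im <- if (i == 1) n[axis] else i - 1
    ip <- if (i == n[axis]) 1 else i + 1
    y0 <- if (axis == 1) cc[im, pk[2]] else cc[pk[1], im]
    y1 <- cc[pk[1], pk[2]]
    y2 <- if (axis == 1) cc[ip, pk[2]] else cc[pk[1], ip]
    den <- y0 - 2 * y1 + y2
    d <- if (abs(den) > 0) 0.5 * (y0 - y2) / den else 0
    s <- i - 1 + d
    if (s > n[axis] / 2) s <- s - n[axis]
    s
  }
  # peak at index (i,j) means b is a by (i-1, j-1) wrapped shift of a
  -c(sub(1), sub(2))
}

#' Register the frames of a trap movie
#'
#' Estimates the per-frame (row, col) translation relative to the first
#' frame by FFT cross-correlation between consecutive frames with parabolic
#' subpixel refinement (trap fields translate but do not rotate), and
#' returns the movie corrected by the rounded cumulative offsets, with
#' uncovered border pixels zero-filled.
#'
#' @param movie A `trap_movie` (see [render_movie()]) or a 3-D array
#'   `(rows, cols, frames)`.
#' @return A list: `offsets` (tibble `frame`, `dy`, `dx`: cumulative drift
#'   of each frame relative to frame 0, pixels) and `corrected` (the
#'   drift-corrected movie or array).
#' @export
register_frames <- function(movie) {
  arrs <- if (inherits(movie, "trap_movie"))
    list(dic = movie$dic, gfp = movie$gfp) else list(dic = movie)
  a <- arrs$dic
  nf <- dim(a)[3]
  if (nf < 2) abort("need at least 2 frames", class = "switchscope_data_error")
  step <- matrix(0, nf, 2)
  for (f in 2:nf) step[f, ] <- estimate_shift(a[, , f - 1], a[, , f])
  cum <- apply(step, 2, cumsum)
  shift_int <- round(cum)
  shift_back <- function(arr) {
    out <- array(0, dim(arr))
    nr <- dim(arr)[1]; nc <- dim(arr)[2]
    for (f in seq_len(nf)) {
      dy <- shift_int[f, 1]; dx <- shift_int[f, 2]
      sr <- max(1, 1 + dy):min(nr, nr + dy)
      sc <- max(1, 1 + dx):min(nc, nc + dx)
      out[sr - dy, sc - dx, f] <- arr[sr, sc, f]
    }
    out
  }
  corrected <- lapply(arrs, shift_back)
  if (inherits(movie, "trap_movie")) {
    movie$dic <- corrected$dic; movie$gfp <- corrected$gfp
    corrected <- movie
  } else corrected <- corrected$dic
  list(offsets = tibble(frame = seq_len(nf) - 1L,
                        dy = cum[, 1], dx = cum[, 2]),
       corrected = corrected)
}

#' Segment cells in a single DIC-like frame
#'
#' Cell borders are detected from the difference of the top-hat and
#' bottom-hat morphological responses (bright cell rims against locally
#' dark interiors), thresholded, closed by dilation, hole-filled, refined
#' by erosion, labeled, and filtered by object area, perimeter and
#' eccentricity ranges.
#'
#' @param image Single-channel numeric matrix.
#' @param params A [segmentation_params()].
#' @return A list of class `labeled_frame`: `labels` (integer matrix,
#'   0 = background, objects labeled 1..n consecutively) and `props`
#'   (tibble: `label`, `area`, `perimeter`, `eccentricity`, `cy`, `cx`,
#'   `major_axis`).
#' @export
segment_frame <- function(image, params = segmentation_params()) {
  img <- EBImage::Image(image)
  br <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  th <- EBImage::whiteTopHat(img, br(params$tophat_radius))
  bh <- EBImage::blackTopHat(img, br(params$bottomhat_radius))
  resp <- th - bh
  rng <- range(resp)
  empty <- list(labels = matrix(0L, nrow(image), ncol(image)),
                props = tibble(label = integer(), area = numeric(),
                               perimeter = numeric(), eccentricity = numeric(),
                               cy = numeric(), cx = numeric(),
                               major_axis = numeric()))
  class(empty) <- "labeled_frame"
  if (diff(rng) == 0) return(empty)
  rn <- (resp - rng[1]) / diff(rng)
  thr <- if (identical(params$threshold, "otsu")) EBImage::otsu(rn)
         else params$threshold
  bw <- rn > thr
  bw <- EBImage::dilate(bw, br(params$dilation_radius))
  bw <- EBImage::fillHull(bw)
  bw <- EBImage::erode(bw, br(params$erosion_radius))
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) return(empty)
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  # EBImage's m.cx runs along the first matrix dimension; report 0-based
  # (row, col) centroids
  props <- tibble(label = seq_len(nrow(sh)),
                  area = sh[, "s.area"], perimeter = sh[, "s.perimeter"],
                  eccentricity = mo[, "m.eccentricity"],
                  cy = mo[, "m.cx"] - 1, cx = mo[, "m.cy"] - 1,
                  major_axis = mo[, "m.majoraxis"])
  keep <- props$area >= params$area_range[1] &
    props$area <= params$area_range[2] &
    props$perimeter >= params$perimeter_range[1] &
    props$perimeter <= params$perimeter_range[2] &
    props$eccentricity >= params$eccentricity_range[1] &
    props$eccentricity <= params$eccentricity_range[2]
  labmat <- matrix(as.integer(EBImage::imageData(lab)), nrow(image), ncol(image))
  relab <- integer(max(labmat))
  relab[props$label[keep]] <- seq_len(sum(keep))
  labmat[labmat > 0] <- relab[labmat[labmat > 0]]
  props <- props[keep, ]
  props$label <- seq_len(nrow(props))
  structure(list(labels = labmat, props = props), class = "labeled_frame")
}

#' Top-k-pixel fluorescence metric
#'
#' Mean of the `k` highest-intensity pixels of an object in the
#' fluorescence channel (default 300) — a nuclear-weighted expression
#' metric for a nuclear-localized regulator.  Objects with fewer than `k`
#' pixels are averaged whole and flagged via attribute `partial`.
#'
#' @param gfp_frame Fluorescence channel matrix.
#' @param mask Logical matrix (or 0/1, or integer labels with `label`) of
#'   the object's pixels.
#' @param k Number of top pixels.
#' @param label If `mask` is a label matrix, which object to measure.
#' @return The metric (numeric scalar).
#' @export
top_pixels_metric <- function(gfp_frame, mask, k = 300, label = NULL) {
  sel <- if (!is.null(label)) mask == label else mask > 0
  px <- gfp_frame[sel]
  if (!length(px)) abort("empty mask", class = "switchscope_data_error")
  partial <- length(px) < k
  v <- mean(if (partial) px else sort(px, decreasing = TRUE)[seq_len(k)])
  attr(v, "partial") <- partial
  v
}

#' Cell length from an object mask
#'
#' Major-axis length of the object (the automated surrogate for a line
#' drawn along the cell's long axis), computed from the eigenvalues of the
#' pixel-coordinate covariance: for a filled ellipse the full major axis is
#' four times the root of the leading eigenvalue.  Invariant to rotation of
#' the mask.
#'
#' @param mask Logical/0-1 matrix, or a label matrix with `label`.
#' @param label Optional object label.
#' @return Length in pixels.
#' @export
cell_length <- function(mask, label = NULL) {
  sel <- if (!is.null(label)) mask == label else mask > 0
  idx <- which(sel, arr.ind = TRUE)
  if (!nrow(idx)) abort("empty mask", class = "switchscope_data_error")
  if (nrow(idx) == 1) return(1)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  4 * sqrt(max(ev))
}

#' Fractions of cells longer than the white 95th percentile
#'
#' Computes the 95th percentile of the white reference lengths (linear
#' interpolation between order statistics) and the fraction of each group
#' strictly above it.
#'
#' @param mothers,daughters Lengths (pixels) of switching mothers and
#'   daughters.
#' @param white_ref White-cell reference lengths (>= 20 values).
#' @return A tibble: `group`, `n`, `fraction_above`, plus the threshold in
#'   attribute `white_p95`.
#' @export
length_percentile_stats <- function(mothers, daughters, white_ref) {
  if (length(white_ref) < 20)
    abort("need at least 20 white reference lengths", class = "switchscope_data_error")
  p95 <- quantile(white_ref, 0.95, type = 7, names = FALSE)
  frac <- function(x) {
    if (!length(x)) { warn("empty group"); return(NA_real_) }
    mean(x > p95)
  }
  out <- tibble(group = c("mothers", "daughters"),
                n = c(length(mothers), length(daughters)),
                fraction_above = c(frac(mothers), frac(daughters)))
  attr(out, "white_p95") <- p95
  out
}
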