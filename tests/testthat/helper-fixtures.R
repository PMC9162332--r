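# Shared fixtures and independent oracles for the test suite.

# Small, fast trap experiment for structural tests.
small_switch_cfg <- function(..., seed = 11) {
  switch_model_config(n_traps = 6, n_founders = 1, trap_capacity = 60,
                      rng_seed = seed, ...)
}

# Flow config with reduced event counts for fast fits.
small_flow_cfg <- function(..., events_per_well = 800, seed = 11) {
  flow_model_config(events_per_well = events_per_well, rng_seed = seed, ...)
}

# Noise-free flow config (every stochastic scale zeroed).
noiseless_flow_cfg <- function(...) {
  flow_model_config(
    noise = c(protein_sdlog = 0, gfp_cv = 0, reporter_sdlog10 = 0,
              mch_cv = 0, size_sdlog = 0, ssc_sdlog = 0, v670_sdlog = 0),
    subpop_fracs = c(debris = 0, aggregate = 0), ...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Best-match Jaccard of ground-truth object `i` against any segmented label.
best_jaccard <- function(gt_labels, seg_labels, i) {
  cand <- setdiff(unique(seg_labels[gt_labels == i]), 0L)
  if (!length(cand)) return(0)
  max(vapply(cand, function(l) jaccard(gt_labels == i, seg_labels == l), 0))
}

# Independent zero-class rate oracle: 1-D likelihood grid search over the
# zero/nonzero dichotomy P(zero) = exp(-lambda).
oracle_lambda_grid <- function(n_zero, n_total, grid = seq(1e-4, 3, 1e-4)) {
  ll <- n_zero * (-grid) + (n_total - n_zero) * log(1 - exp(-grid))
  grid[which.max(ll)]
}

# Sort-and-average oracle for the top-k pixel metric.
oracle_top_k <- function(values, k) {
  s <- sort(values, decreasing = TRUE)
  mean(s[seq_len(min(k, length(s)))])
}

# Exact 4PL curve in log10-response form.
curve_4pl <- function(x, c, d, K, h) c + (d - c) / (1 + exp(-h * (log(x) - log(K))))

# A filled-ellipse mask with semi-axes (a, b) rotated by theta.
ellipse_mask <- function(nrow, ncol, cy, cx, a, b, theta = 0) {
  yy <- outer(seq_len(nrow) - cy, rep(1, ncol))
  xx <- outer(rep(1, nrow), seq_len(ncol) - cx)
  u <- (yy * cos(theta) + xx * sin(theta)) / a
  v <- (-yy * sin(theta) + xx * cos(theta)) / b
  u^2 + v^2 <= 1
}

# Hand-built switch-call table for grouping tests: every listed cell is
# "switching" with the given absolute activation frame (frames from trap
# start); t_* fields are converted to hours from birth.
fake_calls <- function(cell_id, birth_frame, act_frame, trap_id = 1L,
                       frame_interval = 12) {
  tibble::tibble(
    trap_id = trap_id, cell_id = cell_id, birth_frame = as.integer(birth_frame),
    state = "switching",
    t_activation_start = (act_frame - birth_frame) * frame_interval / 60,
    t_threshold = (act_frame - birth_frame) * frame_interval / 60,
    t_max = NA_real_, rise_10_90 = NA_real_,
    thr_gate = sqrt(40), thr10 = 4.9, thr90 = 36.1, low_confidence = FALSE)
}

white_call <- function(cell_id, birth_frame = 0L, trap_id = 1L) {
  tibble::tibble(trap_id = trap_id, cell_id = cell_id,
                 birth_frame = as.integer(birth_frame), state = "white",
                 t_activation_start = NA_real_, t_threshold = NA_real_,
                 t_max = NA_real_, rise_10_90 = NA_real_,
                 thr_gate = sqrt(40), thr10 = 4.9, thr90 = 36.1,
                 low_confidence = FALSE)
}
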