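# Shared fixtures and independent oracles, built in code.

# A perfectly linear track: length = slope * time, sampled every `dt`.
linear_track <- function(slope, dt = 5, duration = 100, id = "f1",
                         fov = "FOV-1") {
  t <- seq(0, duration, by = dt)
  tibble::tibble(filament_id = id, fov_id = fov, time = t,
                 length = slope * t, condition = "test")
}

# Track with a flat stretch of `n_stalled` increments inserted mid-movie.
stalled_track <- function(slope = 0.1, dt = 5, n_before = 4, n_stalled = 3,
                          n_after = 4, id = "f1") {
  grow <- c(rep(slope * dt, n_before), rep(0, n_stalled),
            rep(slope * dt, n_after))
  tibble::tibble(filament_id = id, fov_id = "FOV-1",
                 time = seq(0, by = dt, length.out = length(grow) + 1),
                 length = cumsum(c(0, grow)), condition = "test")
}

# Brute-force survival counter: S(t) = #(dwell > t) / n on uncensored dwells.
brute_survival <- function(dwells, times) {
  vapply(times, function(t) mean(dwells > t), numeric(1))
}

# Recall of ground-truth pauses: a true pause counts as recovered when a
# detected pause on the same filament overlaps it in time.
pause_recall <- function(truth, detected) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    d <- detected[detected$filament_id == truth$filament_id[i], ]
    any(d$start < truth$end[i] & d$end > truth$start[i])
  }, logical(1))
  mean(hit)
}

# Noise-free staircase photobleaching trace.
staircase_trace <- function(levels, dwell_frames = 20, dt = 0.5,
                            id = "mol-1") {
  y <- rep(levels, each = dwell_frames)
  tibble::tibble(molecule_id = id,
                 time = seq(0, by = dt, length.out = length(y)),
                 intensity = y)
}

# Rasterized disk / rectangle masks.
disk_mask_px <- function(radius, pad = 4) {
  n <- 2 * radius + 2 * pad
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(0, n, n)
  inside <- (g$r - n / 2)^2 + (g$c - n / 2)^2 <= radius^2
  m[as.matrix(g[inside, ])] <- 1
  m
}

rect_mask_px <- function(h, w, pad = 5) {
  m <- matrix(0, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- 1
  m
}
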