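# Shared fixtures: all built in code at test time.

# Disc painted into a zero matrix (1-based center, 0/1 values times label).
disc_mask <- function(size, cx, cy, r, label = 1L) {
  m <- matrix(0L, size, size)
  for (row in max(1, cy - r):min(size, cy + r)) {
    half <- floor(sqrt(max(0, r^2 - (row - cy)^2)))
    cols <- max(1, cx - half):min(size, cx + half)
    m[row, cols] <- label
  }
  m
}

# Axis-aligned rectangle mask.
rect_mask <- function(size, r1, r2, c1, c2, label = 1L) {
  m <- matrix(0L, size, size)
  m[r1:r2, c1:c2] <- label
  m
}

# Small mixed-category simulation reused across tests (moderate size so the
# whole suite stays fast). 48 h keeps at least one full division round.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sim_config(image_size_px = 192, duration_h = 48,
                       n_initial_cells = 6, dose_Gy = 2, seed = 42)
      cache <<- list(config = sc, sim = simulate_movie(sc, render = FALSE))
    }
    cache
  }
})

# Full-length simulation (96 h) for classification / lineage tests.
long_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sim_config(image_size_px = 256, duration_h = 95.5,
                       n_initial_cells = 8, dose_Gy = 3, seed = 7)
      cache <<- list(config = sc, sim = simulate_movie(sc, render = FALSE))
    }
    cache
  }
})

# Track + link + trees on given masks.
run_tracking <- function(masks, um_per_px, dt_h = 0.5, gate = 0.9,
                         tau_div = 0.5) {
  tr <- track_movie(masks, gate = gate, um_per_px = um_per_px, dt_h = dt_h)
  tr <- link_tracks(tr, masks, tau_div = tau_div)
  build_trees(tr)$tracks
}
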