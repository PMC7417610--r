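# Shared fixtures: profiles are built in code, never stored.

# A smoothed_profile from explicit grid/values, for estimator unit tests.
make_smoothed <- function(grid, values, dimension = "length", level = "cell",
                          step = min(diff(grid))) {
  structure(
    tibble::tibble(grid_mm = grid, mean = values,
                   se = rep(0, length(grid)), n = rep(1L, length(grid))),
    dimension = dimension, level = level, grid_step = step,
    class = c("smoothed_profile", class(tibble::tibble()))
  )
}

# Piecewise ramp: linear 0 -> top over [0, knee], flat at top to xmax.
ramp_profile <- function(knee = 20, top = 100, xmax = 40, step = 1) {
  grid <- seq(0, xmax, by = step)
  make_smoothed(grid, pmin(grid / knee, 1) * top)
}

# Small raw profile table for one replicate.
raw_profile_df <- function(positions, sizes, replicate = "r1",
                           dimension = "length", level = "cell") {
  data.frame(replicate = replicate, dimension = dimension, level = level,
             position_mm = positions, size = sizes)
}

# Default simulated dataset, cached per session (used by several files).
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_growth_zone(sim_config(seed = 1))
    cache
  }
})

# Material-point travel time through [a, b] against velocity field v,
# explicit time stepping dx = v dt (independent trajectory oracle).
trajectory_time <- function(v, a, b, dt = 0.001) {
  x <- a
  t <- 0
  while (x < b) {
    x <- x + v(x) * dt
    t <- t + dt
    if (t > 1e4) stop("trajectory did not reach b")
  }
  t
}
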