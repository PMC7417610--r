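#' Read size-vs-position profiles from a delimited text file
#'
#' Expects columns `replicate, dimension, level, position_mm, size`
#' (comma- or tab-separated; the delimiter is sniffed from the header).
#' `dimension` must be one of `length`, `width`, `thickness`; `level` one
#' of `cell`, `organ` (cell level carries all three dimensions, organ level
#' only width and thickness — organ length enters the analysis through the
#' leaf elongation rate, not as a profile). Repeated measurements at the
#' same (replicate, dimension, level, position) — e.g. the ~20 cells
#' measured per position — are averaged into one record, with the
#' measurement count kept in `n_obs`.
#'
#' Units follow field convention: positions in mm from the visible leaf
#' base; cell sizes and blade thickness in um; leaf width in mm.
#'
#' @param path File path.
#' @return A list of `size_profile` objects (tibbles with columns
#'   `position_mm`, `size`, `n_obs` and attributes `replicate`,
#'   `dimension`, `level`), one per replicate x dimension x level.
#' @export
read_profiles <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_size_profiles(df)
}

#' Validate and split a profile table into size_profile objects
#'
#' @param df Data frame with columns `replicate, dimension, level,
#'   position_mm, size` (one row per individual measurement).
#' @return A list of `size_profile` objects; see [read_profiles()].
#' @export
as_size_profiles <- function(df) {
  required <- c("replicate", "dimension", "level", "position_mm", "size")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  bad_dim <- which(!df$dimension %in% c("length", "width", "thickness"))
  if (length(bad_dim))
    stop("unknown dimension '", df$dimension[bad_dim[1]], "' at row ", bad_dim[1])
  bad_lvl <- which(!df$level %in% c("cell", "organ"))
  if (length(bad_lvl))
    stop("unknown level '", df$level[bad_lvl[1]], "' at row ", bad_lvl[1])
  bad_combo <- which(df$level == "organ" & df$dimension == "length")
  if (length(bad_combo))
    stop("organ-level length is not a profile (use the leaf elongation rate); row ",
         bad_combo[1])
  bad_size <- which(!is.finite(df$size) | df$size <= 0)
  if (length(bad_size))
    stop("non-positive or non-finite size at row ", bad_size[1])
  bad_pos <- which(!is.finite(df$position_mm) | df$position_mm < 0)
  if (length(bad_pos))
    stop("negative or non-finite position at row ", bad_pos[1])

  key <- interaction(df$replicate, df$dimension, df$level, drop = TRUE)
  lapply(split(df, key), function(d) {
    agg <- stats::aggregate(size ~ position_mm, data = d, FUN = mean)
    cnt <- stats::aggregate(size ~ position_mm, data = d, FUN = length)
    out <- tibble::tibble(position_mm = agg$position_mm, size = agg$size,
                          n_obs = cnt$size)
    out <- out[order(out$position_mm), ]
    structure(out, replicate = d$replicate[1], dimension = d$dimension[1],
              level = d$level[1],
              class = c("size_profile", class(tibble::tibble())))
  })
}

#' Smooth one size profile onto a regular spatial grid
#'
#' Local polynomial smoothing with tricube weights (via [stats::loess()]
#' with `surface = "direct"`), evaluated on a regular grid. `bandwidth` is
#' the loess span: the fraction of data points entering each local fit.
#' The grid runs at `grid_step` spacing from 0 to the most distal sampled
#' position but is clipped to the sampled range — no extrapolation, so
#' position 0 appears only if it was sampled.
#'
#' @param profile A `size_profile` (see [read_profiles()]), or any data
#'   frame with columns `position_mm` and `size` (one value per position).
#' @param bandwidth Span, in (0, 1]; fraction of points per local fit.
#' @param degree Local polynomial degree, 1 or 2.
#' @param grid_step Grid spacing in mm (default 1).
#' @return A `smoothed_profile`: tibble with columns `grid_mm`, `mean`,
#'   `se` (0 for a single replicate), `n` and attributes `dimension`,
#'   `level`, `grid_step`, `bandwidth`, `degree`.
#' @export
smooth_profile <- function(profile, bandwidth = 0.3, degree = 2, grid_step = 1) {
  stopifnot(bandwidth > 0, bandwidth <= 1, degree %in% c(1, 2), grid_step > 0)
  x <- profile$position_mm
  y <- profile$size
  ux <- unique(x)
  if (length(ux) < degree + 2)
    stop("need at least ", degree + 2, " distinct positions, got ", length(ux))
  if (diff(range(ux)) == 0) stop("all positions identical")

  span <- max(bandwidth, min(1, (degree + 2) / length(ux)))
  grid <- seq(0, max(x), by = grid_step)
  grid <- grid[grid >= min(x) & grid <= max(x)]
  # loess grumbles numerically on sparse clustered supports (pseudoinverse
  # fallback); those conditions are handled internally and not actionable
  mu <- withCallingHandlers({
    fit <- stats::loess(y ~ x, span = span, degree = degree,
                        surface = "direct",
                        control = stats::loess.control(statistics = "none"))
    as.numeric(stats::predict(fit, newdata = data.frame(x = grid)))
  }, warning = function(w) {
    if (grepl("pseudoinverse|neighborhood radius|reciprocal condition|singularities",
              conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  if (any(mu <= 0))
    warning("smoothed profile is non-positive at ", sum(mu <= 0), " grid point(s)")

  structure(
    tibble::tibble(grid_mm = grid, mean = mu, se = rep(0, length(grid)),
                   n = rep(1L, length(grid))),
    dimension = attr(profile, "dimension"), level = attr(profile, "level"),
    replicate = attr(profile, "replicate"),
    grid_step = grid_step, bandwidth = bandwidth, degree = degree,
    class = c("smoothed_profile", class(tibble::tibble()))
  )
}

#' Average smoothed replicate profiles
#'
#' Pointwise mean and standard error (sd/sqrt(n)) across replicates on the
#' common grid (the intersection of the replicate grids). With a single
#' replicate the mean is the input and the SE is 0 by convention.
#'
#' @param smoothed A list of `smoothed_profile` objects.
#' @return A `smoothed_profile` with cross-replicate `mean`, `se` and `n`.
#' @export
aggregate_replicates <- function(smoothed) {
  if (length(smoothed) == 0) stop("no replicates to aggregate")
  r6 <- function(z) round(z, 6)  # guard float grid comparison
  grids <- lapply(smoothed, function(s) r6(s$grid_mm))
  grid <- Reduce(intersect, grids)
  if (length(grid) == 0) stop("replicate grids do not overlap")
  grid <- sort(grid)
  vals <- vapply(smoothed, function(s) s$mean[match(grid, r6(s$grid_mm))],
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- ncol(vals)
  mu <- rowMeans(vals)
  se <- if (n == 1) rep(0, length(grid)) else apply(vals, 1, stats::sd) / sqrt(n)

  template <- smoothed[[1]]
  structure(
    tibble::tibble(grid_mm = grid, mean = mu, se = se, n = rep(n, length(grid))),
    dimension = attr(template, "dimension"), level = attr(template, "level"),
    grid_step = attr(template, "grid_step"),
    bandwidth = attr(template, "bandwidth"), degree = attr(template, "degree"),
    class = c("smoothed_profile", class(tibble::tibble()))
  )
}
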