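#' Leaf elongation rate from daily length measurements
#'
#' LER is the mean of successive length increments divided by their time
#' intervals (observations are typically ~24 h apart).
#'
#' @param time_h Observation times, h; strictly increasing.
#' @param length_mm Leaf lengths, mm.
#' @return LER in mm/h. A decrease between observations triggers a warning
#'   (negative rates are reported, not censored).
#' @export
leaf_elongation_rate <- function(time_h, length_mm) {
  stopifnot(length(time_h) >= 2, length(time_h) == length(length_mm),
            all(diff(time_h) > 0))
  rates <- diff(length_mm) / diff(time_h)
  if (any(rates < 0))
    warning("leaf length decreased between observations; LER may be negative")
  mean(rates)
}

#' Cell production rate
#'
#' `P = LER / l_mat`: under steady state, each mature cell appearing at the
#' distal end of the growth zone accounts for `l_mat` of length gain.
#'
#' @param LER Leaf elongation rate, mm/h.
#' @param l_mat Mature cell length, mm.
#' @return P in cells per file per hour.
#' @export
cell_production_rate <- function(LER, l_mat) {
  if (l_mat <= 0) stop("mature cell length must be positive")
  LER / l_mat
}

#' Cell number between two positions from a cell-length profile
#'
#' Continuity-equation cell count `N = integral of dx / l(x)` over
#' `[a, b]`. The profile is treated as piecewise linear between grid
#' points, for which each segment integrates in closed form to
#' `dx * log(l2/l1) / (l2 - l1)`; the count is therefore exact on linear
#' profiles (and reduces to `dx / l` on flat segments). Endpoints not on
#' the grid are filled in by linear interpolation.
#'
#' @param profile A `smoothed_profile` of cell length, or a data frame with
#'   columns `grid_mm` and `mean`.
#' @param a,b Interval bounds, mm; must lie within the profile grid.
#' @param size_unit Unit of the profile values: `"mm"` (default) or
#'   `"um"`. Positions are always mm.
#' @return The (real-valued) number of cells in `[a, b]`.
#' @export
count_cells <- function(profile, a, b, size_unit = c("mm", "um")) {
  size_unit <- match.arg(size_unit)
  if (a >= b) stop("need a < b, got [", a, ", ", b, "]")
  grid <- profile$grid_mm
  l <- profile$mean
  if (size_unit == "um") l <- l / 1000
  if (a < min(grid) - 1e-9 || b > max(grid) + 1e-9)
    stop("[a, b] extends beyond the profile grid [",
         min(grid), ", ", max(grid), "]")
  if (any(l <= 0)) stop("cell-length profile must be positive")

  x <- sort(unique(c(a, b, grid[grid > a & grid < b])))
  lx <- stats::approx(grid, l, xout = x)$y
  x1 <- x[-length(x)]; x2 <- x[-1]
  l1 <- lx[-length(lx)]; l2 <- lx[-1]
  seg <- ifelse(abs(l2 - l1) < 1e-12 * pmax(l1, l2),
                (x2 - x1) / l1,
                (x2 - x1) * log(l2 / l1) / (l2 - l1))
  sum(seg)
}

#' Division rate, cell cycle duration and meristem residence time
#'
#' `D = P / N_mer` (average division rate), `T_c = ln(2) / D` (cell cycle
#' duration; the ln 2 accounts for the exponential nature of division), and
#' `T_mer = log2(N_mer) * T_c` (time to traverse the meristem: a cell
#' entering at the base divides `log2(N_mer)` times before leaving).
#'
#' @param P Cell production rate, cells/h.
#' @param N_mer Number of cells in the meristem.
#' @return A list with `D` (1/h), `T_c` (h), `T_mer` (h).
#' @export
division_params <- function(P, N_mer) {
  if (N_mer <= 0) stop("N_mer must be positive")
  D <- P / N_mer
  list(D = D, T_c = log(2) / D, T_mer = log2(N_mer) * log(2) / D)
}

#' Residence time in the elongation zone
#'
#' `T_el = N_el / P`: beyond the meristem the cell flux is constant and
#' equal to the production rate, so the time to traverse the elongation
#' zone is the number of cells it holds divided by the flux. For width and
#' thickness, `N_el` is counted on the cell-length profile up to the
#' dimension-specific growth-zone length (meristem length and timing are
#' shared with the proximodistal axis).
#'
#' @param N_el Number of cells in the elongation zone.
#' @param P Cell production rate (= flux), cells/h.
#' @return T_el in hours.
#' @export
elongation_residence <- function(N_el, P) {
  if (P <= 0) stop("cell production rate must be positive")
  N_el / P
}

#' Cell flux profile
#'
#' Within the meristem the flux rises linearly from 0 at the leaf base to
#' `P` at the meristem boundary; beyond it the flux is constant at `P`.
#'
#' @param grid Positions, mm.
#' @param P Cell production rate, cells/h.
#' @param L_mer Meristem length, mm.
#' @return Flux at each grid position, cells/h.
#' @export
flux_profile <- function(grid, P, L_mer) {
  if (L_mer <= 0) stop("meristem length must be positive")
  ifelse(grid <= L_mer, P * grid / L_mer, P)
}

#' Velocity profile
#'
#' `v(x) = l(x) * F(x)`: the displacement velocity of tissue at position x
#' is the local cell length times the local cell flux. `v(0) = 0` at the
#' leaf base; at the meristem boundary v equals P times the local cell
#' length. Units follow the inputs (cell length in mm and flux in cells/h
#' give v in mm/h).
#'
#' @param cell_length Cell lengths on the grid.
#' @param flux Cell flux on the same grid (see [flux_profile()]).
#' @return Velocity on the grid.
#' @export
velocity_profile <- function(cell_length, flux) {
  stopifnot(length(cell_length) == length(flux))
  cell_length * flux
}

#' Relative elemental growth rate in length
#'
#' `RGR_length(x) = dv/dx`, evaluated by central finite differences on the
#' uniform grid (one-sided differences at the two ends).
#'
#' @param velocity Velocity on a uniform grid.
#' @param grid Grid positions, mm (uniform spacing).
#' @return RGR_length at each grid position, 1/h.
#' @export
rgr_length_profile <- function(velocity, grid) {
  n <- length(velocity)
  stopifnot(n == length(grid), n >= 2)
  h <- diff(grid)
  if (max(h) - min(h) > 1e-8 * max(h)) stop("grid must be uniform")
  h <- h[1]
  d <- numeric(n)
  d[1] <- (velocity[2] - velocity[1]) / h
  d[n] <- (velocity[n] - velocity[n - 1]) / h
  if (n > 2) d[2:(n - 1)] <- (velocity[3:n] - velocity[1:(n - 2)]) / (2 * h)
  d
}

#' Zone-averaged relative growth rate between two sizes
#'
#' Average RGR of a tissue element that grows from `size1` to `size2` over
#' `dt`. For the meristem, `size1` is the profile value at the most basal
#' position, `size2` at the meristem boundary and `dt = T_mer`; for the
#' elongation zone the boundaries are the end of the meristem and the end
#' of the growth zone with `dt = T_el`.
#'
#' The default `"log"` mode, `log(size2/size1)/dt`, is the average relative
#' growth rate proper (units 1/h, consistent with the spatial RGR profile
#' in the uniform-growth limit). `"difference"` gives the absolute rate
#' `(size2 - size1)/dt`; `"simple-relative"` the naive
#' `((size2 - size1)/size1)/dt`.
#'
#' @param size1,size2 Sizes at the zone boundaries (positive in log mode).
#' @param dt Residence time in the zone, h (> 0).
#' @param mode Averaging mode; see Details.
#' @return The zone-averaged RGR (1/h) or absolute rate (size-unit/h).
#' @export
zone_rgr <- function(size1, size2, dt,
                     mode = c("log", "difference", "simple-relative")) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be positive")
  if (mode == "log" && (size1 <= 0 || size2 <= 0))
    stop("sizes must be positive in log mode")
  switch(mode,
         "log" = log(size2 / size1) / dt,
         "difference" = (size2 - size1) / dt,
         "simple-relative" = ((size2 - size1) / size1) / dt)
}

#' Growth anisotropy ratios
#'
#' Ratios of the longitudinal zone RGR to the lateral and dorsoventral
#' zone RGRs; values > 1 indicate preferentially longitudinal growth.
#'
#' @param rgr_length,rgr_width,rgr_thickness Zone-averaged RGRs (1/h).
#' @return Named vector `length_width`, `length_thickness`.
#' @export
anisotropy_ratios <- function(rgr_length, rgr_width, rgr_thickness) {
  if (rgr_length == 0) stop("longitudinal RGR is zero; ratios undefined")
  c(length_width = rgr_length / rgr_width,
    length_thickness = rgr_length / rgr_thickness)
}

#' Percent difference between genotype means
#'
#' `100 * (treatment - control) / control`, rounded to the nearest integer
#' with ties away from zero (the convention of published dimension
#' tables), or unrounded with `rounded = FALSE`.
#'
#' @param control,treatment Group means; `control` must be non-zero.
#' @param rounded Round to integer percent (default TRUE).
#' @return Percent difference.
#' @export
percent_difference <- function(control, treatment, rounded = TRUE) {
  if (any(control == 0)) stop("control mean must be non-zero")
  pct <- 100 * (treatment - control) / control
  if (!rounded) return(pct)
  sign(pct) * floor(abs(pct) + 0.5)
}
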