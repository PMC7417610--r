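#' Configure a synthetic steady-state growth-zone experiment
#'
#' Builds and validates the parameter set for [simulate_growth_zone()]. The
#' defaults describe a vigorously elongating maize fourth leaf: a 10-mm
#' meristem producing 16 cells per file per hour, cells elongating from 20 to
#' 147 um over a 30-mm growth zone, lateral and dorsoventral expansion at
#' half and a quarter of the longitudinal relative growth rate, and the
#' sampling design used for kinematic harvests (length/width every 5 mm over
#' the basal 10 cm, cross-sections at nine fixed positions up to 17 cm,
#' about 20 cells measured per position, 3-5 replicate plants).
#'
#' @param L_mer Meristem (division-zone) length, mm.
#' @param L_gz Named numeric: position where growth ceases for each of
#'   `length`, `width`, `thickness`, mm. A single number is recycled.
#' @param l_div Cell length within the meristem, mm.
#' @param l_mat Mature cell length, mm.
#' @param w_base,h_base Epidermal cell width / height at the leaf base, um.
#' @param aniso_w,aniso_h Ratio of the lateral / dorsoventral relative growth
#'   rate to the longitudinal relative growth rate in the elongation zone
#'   (dimensionless, >= 0; 0 means no expansion in that direction).
#' @param P Cell production rate, cells per file per hour.
#' @param n_files Number of lateral cell files; organ width is
#'   `n_files` x mean cell width.
#' @param thickness_factor Whole-blade thickness is
#'   `(1 + thickness_factor)` x epidermal cell height (inner tissues scale
#'   with the epidermis).
#' @param n_reps Number of replicate plants.
#' @param cv_noise Coefficient of variation of the multiplicative
#'   (lognormal) measurement noise on sizes.
#' @param sample_positions_lw Positions (mm from the leaf base) where cell
#'   length/width and leaf width are sampled.
#' @param sample_positions_t Positions (mm) of the cross-sections used for
#'   cell height and blade thickness.
#' @param cells_per_position Individual cells measured per position
#'   (cell level; organ-level traits get one measurement per position).
#' @param leaf_length0 Leaf length at the first daily observation, mm.
#' @param n_obs Number of daily leaf-length observations (24-h spacing).
#' @param length_sd Additive measurement error on daily leaf length, mm
#'   (ruler precision).
#' @param midvein_artifact Logical; if `TRUE`, organ-level width
#'   measurements are depressed towards the leaf base, mimicking the
#'   unseparated midvein of rolled-up leaves.
#' @param midvein_magnitude Maximal fractional width underestimation at the
#'   leaf base when `midvein_artifact` is on.
#' @param seed Optional RNG seed recorded in the config.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_growth_zone()], [growth_zone_model()]
#' @export
sim_config <- function(L_mer = 10,
                       L_gz = c(length = 30, width = 30, thickness = 30),
                       l_div = 0.02, l_mat = 0.147,
                       w_base = 9, h_base = 11,
                       aniso_w = 0.5, aniso_h = 0.25,
                       P = 16,
                       n_files = 950,
                       thickness_factor = 4,
                       n_reps = 5,
                       cv_noise = 0.05,
                       sample_positions_lw = seq(5, 100, by = 5),
                       sample_positions_t = c(5, 10, 15, 20, 30, 40, 60, 100, 170),
                       cells_per_position = 20,
                       leaf_length0 = 200,
                       n_obs = 4,
                       length_sd = 1,
                       midvein_artifact = FALSE,
                       midvein_magnitude = 0.15,
                       seed = NULL) {
  if (length(L_gz) == 1L) L_gz <- c(length = L_gz, width = L_gz, thickness = L_gz)
  if (is.null(names(L_gz)) || !all(c("length", "width", "thickness") %in% names(L_gz)))
    names(L_gz) <- c("length", "width", "thickness")
  L_gz <- L_gz[c("length", "width", "thickness")]

  stopifnot(
    "L_mer must be positive" = L_mer > 0,
    "meristem must end before growth ceases (L_mer < min(L_gz))" = L_mer < min(L_gz) || l_div == l_mat,
    "meristem cell length cannot exceed mature cell length" = l_div <= l_mat,
    "sizes and rates must be strictly positive" =
      all(c(l_div, l_mat, w_base, h_base, P, n_files) > 0),
    "anisotropy ratios must be non-negative" = aniso_w >= 0 && aniso_h >= 0,
    "cv_noise must be non-negative" = cv_noise >= 0,
    "need at least one replicate" = n_reps >= 1,
    "sampling positions must be non-negative" =
      all(sample_positions_lw >= 0) && all(sample_positions_t >= 0),
    "cells_per_position must be >= 1" = cells_per_position >= 1,
    "need at least two daily observations" = n_obs >= 2
  )
  if (l_mat < l_div) stop("l_mat < l_div: shrinking cells are not supported")

  structure(list(
    L_mer = L_mer, L_gz = L_gz, l_div = l_div, l_mat = l_mat,
    w_base = w_base, h_base = h_base, aniso_w = aniso_w, aniso_h = aniso_h,
    P = P, n_files = n_files, thickness_factor = thickness_factor,
    n_reps = n_reps, cv_noise = cv_noise,
    sample_positions_lw = sort(unique(sample_positions_lw)),
    sample_positions_t = sort(unique(sample_positions_t)),
    cells_per_position = cells_per_position,
    leaf_length0 = leaf_length0, n_obs = n_obs, length_sd = length_sd,
    midvein_artifact = midvein_artifact, midvein_magnitude = midvein_magnitude,
    seed = seed
  ), class = "sim_config")
}

#' Analytic steady-state model behind the simulator
#'
#' Returns the noise-free spatial model implied by a [sim_config()]:
#' within the meristem the cell flux rises linearly from 0 to `P` and cell
#' length is constant at `l_div`, so velocity `v(x) = l_div * P * x / L_mer`;
#' in the elongation zone the flux is constant at `P` and the relative
#' elemental growth rate in length declines linearly from its peak at the
#' meristem boundary to zero where growth ceases, which fixes the peak at
#' `R_el = 2 P (l_mat - l_div) / (L_gz - L_mer)` and gives the velocity by
#' integration; cell length is `v(x)/P`. Cell width and height grow along
#' material trajectories at `aniso_w` / `aniso_h` times a relative growth
#' rate ramp of the same shape scaled to their own growth-zone lengths, and
#' are constant within the meristem (division maintains lateral size
#' equilibrium).
#'
#' @param config A [sim_config()].
#' @return A list of vectorised functions of position x (mm): `v` (velocity,
#'   mm/h), `l` (cell length, mm), `w`, `h` (cell width/height, um),
#'   `rgr_length`, `rgr_width`, `rgr_thickness` (h^-1), plus constants
#'   `R_mer` (meristem RGR, h^-1), `R_el` (peak elongation-zone RGR, h^-1),
#'   `w_mat`, `h_mat` (mature width/height, um).
#' @export
growth_zone_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c_ <- config
  Lgz_len <- unname(c_$L_gz[["length"]])
  Lgz_w <- unname(c_$L_gz[["width"]])
  Lgz_h <- unname(c_$L_gz[["thickness"]])
  dL <- Lgz_len - c_$L_mer
  R_mer <- c_$l_div * c_$P / c_$L_mer
  R_el <- if (dL > 0) 2 * c_$P * (c_$l_mat - c_$l_div) / dL else 0

  v <- function(x) {
    u <- pmin(pmax(x - c_$L_mer, 0), dL)
    base <- c_$l_div * c_$P * pmin(x, c_$L_mer) / c_$L_mer
    ifelse(x <= c_$L_mer, base,
           c_$l_div * c_$P + R_el * (u - u^2 / (2 * max(dL, .Machine$double.eps))))
  }
  l <- function(x) ifelse(x <= c_$L_mer, c_$l_div, v(x) / c_$P)

  # per-dimension RGR ramp: peak R_el at the meristem boundary, zero at L_gz[dim]
  ramp <- function(x, Lgz, aniso) {
    dLd <- Lgz - c_$L_mer
    if (dLd <= 0 || aniso == 0 || R_el == 0) return(rep(0, length(x)))
    ifelse(x >= c_$L_mer & x <= Lgz, aniso * R_el * (Lgz - x) / dLd, 0)
  }
  rgr_length <- function(x) {
    ifelse(x <= c_$L_mer, R_mer,
           ifelse(x < Lgz_len,
                  R_el * (Lgz_len - x) / max(dL, .Machine$double.eps), 0))
  }
  rgr_width <- function(x) ramp(x, Lgz_w, c_$aniso_w)
  rgr_thickness <- function(x) ramp(x, Lgz_h, c_$aniso_h)

  # lateral/dorsoventral sizes: d log(size)/dx = rgr_dim(x) / v(x), from L_mer
  log_growth <- function(x_to, rgr_fun) {
    vapply(x_to, function(xt) {
      upper <- min(xt, max(c_$L_gz))
      if (upper <= c_$L_mer) return(0)
      stats::integrate(function(s) rgr_fun(s) / v(s), c_$L_mer, upper,
                       rel.tol = 1e-10, subdivisions = 500L)$value
    }, numeric(1))
  }
  w <- function(x) c_$w_base * exp(log_growth(x, rgr_width))
  h <- function(x) c_$h_base * exp(log_growth(x, rgr_thickness))
  w_mat <- unname(w(max(c_$L_gz)))
  h_mat <- unname(h(max(c_$L_gz)))

  list(v = v, l = l, w = w, h = h,
       rgr_length = rgr_length, rgr_width = rgr_width,
       rgr_thickness = rgr_thickness,
       R_mer = unname(R_mer), R_el = unname(R_el),
       w_mat = w_mat, h_mat = h_mat)
}

# 95%-of-mature crossing of a monotone noise-free size function: the
# operational growth-zone length that a threshold estimator can recover.
.threshold_crossing <- function(size_fun, mature, L_mer, L_stop, threshold = 0.95) {
  target <- threshold * mature
  if (size_fun(0) >= target) return(0)
  if (size_fun(L_stop) < target) return(NA_real_)
  stats::uniroot(function(x) size_fun(x) - target, c(0, L_stop),
                 tol = 1e-9)$root
}

.lognorm_pars <- function(cv) {
  s2 <- log(1 + cv^2)
  list(meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a steady-state growth-zone dataset with known ground truth
#'
#' Draws a complete synthetic kinematic experiment from the analytic model
#' of [growth_zone_model()]: per-replicate cell length/width/height and
#' organ width/thickness profiles at the configured sampling positions
#' (each sampled size multiplied by lognormal noise with mean 1 and CV
#' `cv_noise`; `cells_per_position` draws per position at the cell level),
#' daily leaf-length series, per-replicate measured meristem lengths, and
#' the noise-free ground truth every estimator should recover.
#'
#' The ground truth distinguishes the generative growth cutoff
#' (`L_gz_model`, where the relative growth rate reaches zero) from the
#' operational growth-zone length (`L_gz`, the position where the
#' noise-free profile reaches 95% of its mature size). Because the model
#' approaches the mature size tangentially, the two differ by several mm;
#' threshold-based estimators target the latter.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return An object of class `synthetic_growth_zone`: a list with
#'   `profiles` (tibble: replicate, dimension, level, position_mm, size),
#'   `leaf_lengths` (tibble: replicate, time_h, length_mm),
#'   `meristem` (tibble: replicate, L_mer_mm),
#'   `truth` (class `ground_truth`), `model` (see [growth_zone_model()])
#'   and `config`.
#' @export
simulate_growth_zone <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  c_ <- config
  m <- growth_zone_model(config)
  truth <- ground_truth(config, model = m)

  ln <- .lognorm_pars(c_$cv_noise)
  noise <- function(n) {
    if (c_$cv_noise == 0) rep(1, n) else stats::rlnorm(n, ln$meanlog, ln$sdlog)
  }

  midvein_factor <- function(x) {
    if (!c_$midvein_artifact) return(rep(1, length(x)))
    1 - c_$midvein_magnitude * pmax(0, 1 - x / c_$L_gz["width"])
  }

  rows <- list()
  add <- function(rep_id, dimension, level, pos, true_sizes, k) {
    n <- length(pos) * k
    tibble::tibble(
      replicate = rep_id, dimension = dimension, level = level,
      position_mm = rep(pos, each = k),
      size = rep(true_sizes, each = k) * noise(n)
    )
  }

  pos_lw <- c_$sample_positions_lw
  pos_t <- c_$sample_positions_t
  l_um <- m$l(pos_lw) * 1000
  w_um <- m$w(pos_lw)
  h_um <- m$h(pos_t)
  organ_w_mm <- c_$n_files * m$w(pos_lw) / 1000 * midvein_factor(pos_lw)
  organ_t_um <- (1 + c_$thickness_factor) * m$h(pos_t)

  for (r in seq_len(c_$n_reps)) {
    rid <- sprintf("rep%02d", r)
    rows[[length(rows) + 1L]] <- add(rid, "length", "cell", pos_lw, l_um, c_$cells_per_position)
    rows[[length(rows) + 1L]] <- add(rid, "width", "cell", pos_lw, w_um, c_$cells_per_position)
    rows[[length(rows) + 1L]] <- add(rid, "thickness", "cell", pos_t, h_um, c_$cells_per_position)
    rows[[length(rows) + 1L]] <- add(rid, "width", "organ", pos_lw, organ_w_mm, 1L)
    rows[[length(rows) + 1L]] <- add(rid, "thickness", "organ", pos_t, organ_t_um, 1L)
  }
  profiles <- do.call(rbind, rows)

  times <- 24 * (seq_len(c_$n_obs) - 1)
  leaf_lengths <- do.call(rbind, lapply(seq_len(c_$n_reps), function(r) {
    err <- if (c_$length_sd > 0) stats::rnorm(length(times), 0, c_$length_sd) else 0
    tibble::tibble(replicate = sprintf("rep%02d", r), time_h = times,
                   length_mm = c_$leaf_length0 + truth$LER * times + err)
  }))

  meristem <- tibble::tibble(
    replicate = sprintf("rep%02d", seq_len(c_$n_reps)),
    L_mer_mm = c_$L_mer * noise(c_$n_reps)
  )

  structure(list(profiles = profiles, leaf_lengths = leaf_lengths,
                 meristem = meristem, truth = truth, model = m,
                 config = config),
            class = "synthetic_growth_zone")
}

#' Noise-free ground truth for a simulator configuration
#'
#' Computes every kinematic quantity implied by the analytic model:
#' `LER = P * l_mat`, `N_mer = L_mer / l_div`, `D = P / N_mer`,
#' `T_c = ln(2)/D`, `T_mer = log2(N_mer) * T_c`, per-dimension
#' elongation-zone cell numbers `N_el = integral of dx/l(x)` and residence
#' times `T_el = N_el / P` (equal to the material-point travel time
#' `integral of dx/v(x)` in the elongation zone), mature sizes,
#' zone-averaged relative growth rates and anisotropy ratios. All values
#' refer to the noise-free model.
#'
#' @param config A [sim_config()].
#' @param model Optional precomputed [growth_zone_model()].
#' @param threshold Mature-size fraction defining the operational
#'   growth-zone length (default 0.95).
#' @return An object of class `ground_truth` (named list); see Details.
#' @export
ground_truth <- function(config, model = growth_zone_model(config),
                         threshold = 0.95) {
  c_ <- config
  m <- model
  N_mer <- c_$L_mer / c_$l_div
  LER <- c_$P * c_$l_mat
  D <- c_$P / N_mer
  T_c <- log(2) / D
  T_mer <- log2(N_mer) * T_c

  inv_l <- function(x) 1 / m$l(x)
  n_between <- function(a, b) {
    if (b <= a) return(0)
    stats::integrate(inv_l, a, b, rel.tol = 1e-10, subdivisions = 500L)$value
  }

  dims <- c("length", "width", "thickness")
  L_gz_model <- c_$L_gz
  if (m$R_el == 0) L_gz_model[] <- c_$L_mer  # degenerate: growth stops at the meristem

  mature <- c(length = c_$l_mat * 1000, width = m$w_mat, thickness = m$h_mat)
  size_funs <- list(length = function(x) m$l(x) * 1000, width = m$w, thickness = m$h)

  L_gz95 <- vapply(dims, function(d) {
    if (m$R_el == 0) return(0)
    .threshold_crossing(size_funs[[d]], mature[[d]], c_$L_mer,
                        max(c_$L_gz), threshold)
  }, numeric(1))

  N_el_model <- vapply(dims, function(d) n_between(c_$L_mer, L_gz_model[[d]]), numeric(1))
  T_el_model <- N_el_model / c_$P
  N_el <- vapply(dims, function(d) {
    if (is.na(L_gz95[[d]]) || L_gz95[[d]] <= c_$L_mer) return(0)
    n_between(c_$L_mer, L_gz95[[d]])
  }, numeric(1))
  T_el <- N_el / c_$P

  base_size <- c(length = c_$l_div * 1000, width = c_$w_base, thickness = c_$h_base)
  rgr_el <- vapply(dims, function(d) {
    if (T_el_model[[d]] <= 0) return(0)
    log(mature[[d]] / base_size[[d]]) / T_el_model[[d]]
  }, numeric(1))
  aniso <- c(length_width = unname(rgr_el["length"] / rgr_el["width"]),
             length_thickness = unname(rgr_el["length"] / rgr_el["thickness"]))

  structure(list(
    P = c_$P, D = D, T_c = T_c, N_mer = N_mer, T_mer = T_mer, LER = LER,
    L_gz_model = L_gz_model, L_gz = L_gz95, threshold = threshold,
    mature_size = mature,
    N_el_model = N_el_model, T_el_model = T_el_model,
    N_el = N_el, T_el = T_el,
    rgr_meristem_length = m$R_mer,
    rgr_el = rgr_el, anisotropy = aniso,
    v = m$v, l = m$l
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth (noise-free steady-state model)\n")
  cat(sprintf("  P = %.4g cells/h, D = %.4g 1/h, T_c = %.4g h\n", x$P, x$D, x$T_c))
  cat(sprintf("  N_mer = %.4g, T_mer = %.4g h, LER = %.4g mm/h\n",
              x$N_mer, x$T_mer, x$LER))
  cat(sprintf("  L_gz (95%% rule): %s mm\n",
              paste(sprintf("%s=%.2f", names(x$L_gz), x$L_gz), collapse = ", ")))
  cat(sprintf("  T_el: %s h\n",
              paste(sprintf("%s=%.2f", names(x$T_el), x$T_el), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes `profiles.csv`, `leaf_lengths.csv` and `meristem.csv` into `dir`,
#' in the column layout accepted by [read_profiles()] and the pipeline.
#'
#' @param dataset A `synthetic_growth_zone` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_growth_zone"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("profiles.csv", "leaf_lengths.csv", "meristem.csv"))
  utils::write.csv(dataset$profiles, paths[1], row.names = FALSE)
  utils::write.csv(dataset$leaf_lengths, paths[2], row.names = FALSE)
  utils::write.csv(dataset$meristem, paths[3], row.names = FALSE)
  invisible(paths)
}
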