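#' Full kinematic analysis of one genotype
#'
#' Runs the whole estimation chain on one genotype's raw measurements:
#' per-replicate profile aggregation and smoothing, cross-replicate
#' averaging, growth-zone delimitation per dimension and level, leaf
#' elongation rate, cell production and division parameters, per-dimension
#' elongation-zone cell numbers and residence times, zone-averaged
#' relative growth rates at the cell and organ level, anisotropy ratios,
#' and the flux/velocity/RGR spatial profiles.
#'
#' @param profiles Data frame of raw measurements (columns `replicate,
#'   dimension, level, position_mm, size`; cell sizes and blade thickness
#'   in um, leaf width in mm).
#' @param leaf_lengths Data frame with `replicate, time_h, length_mm`.
#' @param meristem Data frame with `replicate, L_mer_mm` (externally
#'   measured meristem length, e.g. from DAPI-stained mitotic figures).
#' @param bandwidth,degree,grid_step Smoothing settings (see
#'   [smooth_profile()]); thickness profiles, sampled at sparse section
#'   positions, use `bandwidth_thickness`.
#' @param bandwidth_thickness Span for thickness profiles (default 0.5).
#' @param threshold Mature-size fraction for [estimate_growth_zone()].
#' @param nmer_method How to count meristem cells: `"meristem_mean"`
#'   (default) divides the measured meristem length by the mean of the raw
#'   cell lengths observed within the meristem (division-zone cells sit at
#'   a size equilibrium, and the smoothed profile is boundary-biased at
#'   the sparsely sampled base); `"integral"` integrates 1/l(x) over the
#'   smoothed profile, extending the most basal smoothed value to the
#'   leaf base.
#' @param rgr_mode Zone RGR averaging mode (see [zone_rgr()]).
#' @param boundary_sizes Where zone-averaged RGRs take their boundary
#'   sizes: `"raw"` (default) interpolates the cross-replicate mean of the
#'   per-position measurement means — unbiased where the profile bends
#'   sharply at the meristem boundary, with SE ~ cv/sqrt(cells x reps);
#'   `"smoothed"` reads the smoothed profile, which is also what the
#'   growth-zone boundaries and cell counts always use.
#' @return A `genotype_kinematics` list: `smoothed` (per dimension/level),
#'   `growth_zones` (tibble), `params` (scalar kinematic parameters),
#'   `zone_rgr` (tibble), `anisotropy` (tibble), `profile_table`
#'   (x, flux, velocity, rgr_length).
#' @export
analyze_genotype <- function(profiles, leaf_lengths, meristem,
                             bandwidth = 0.3, bandwidth_thickness = 0.5,
                             degree = 2, grid_step = 1, threshold = 0.95,
                             nmer_method = c("meristem_mean", "integral"),
                             rgr_mode = "log",
                             boundary_sizes = c("raw", "smoothed")) {
  nmer_method <- match.arg(nmer_method)
  boundary_sizes <- match.arg(boundary_sizes)
  sps <- as_size_profiles(as.data.frame(profiles))

  combos <- unique(do.call(rbind, lapply(sps, function(p)
    data.frame(dimension = attr(p, "dimension"), level = attr(p, "level")))))
  smoothed <- list()
  for (i in seq_len(nrow(combos))) {
    d <- combos$dimension[i]; lv <- combos$level[i]
    reps <- Filter(function(p) attr(p, "dimension") == d && attr(p, "level") == lv, sps)
    bw <- if (d == "thickness") bandwidth_thickness else bandwidth
    sm <- lapply(reps, smooth_profile, bandwidth = bw, degree = degree,
                 grid_step = grid_step)
    smoothed[[paste(d, lv, sep = ".")]] <- aggregate_replicates(sm)
  }

  gz <- lapply(smoothed, estimate_growth_zone, threshold = threshold)
  growth_zones <- tibble::tibble(
    dimension = unname(vapply(gz, `[[`, "", "dimension")),
    level = unname(vapply(gz, `[[`, "", "level")),
    L_gz_mm = unname(vapply(gz, `[[`, 0, "L_gz")),
    mature_size = unname(vapply(gz, `[[`, 0, "mature_size")),
    converged = unname(vapply(gz, `[[`, TRUE, "converged")),
    plateau_detected = unname(vapply(gz, `[[`, TRUE, "plateau_detected"))
  )

  ler_reps <- vapply(split(leaf_lengths, leaf_lengths$replicate), function(d)
    leaf_elongation_rate(d$time_h, d$length_mm), numeric(1))
  LER <- mean(ler_reps)
  L_mer <- mean(meristem$L_mer_mm)

  len_cell <- smoothed[["length.cell"]]
  l_mat_um <- gz[["length.cell"]]$mature_size
  P <- cell_production_rate(LER, l_mat_um / 1000)

  N_mer <- if (nmer_method == "meristem_mean") {
    mer_lengths <- unlist(lapply(sps, function(p) {
      if (attr(p, "dimension") == "length" && attr(p, "level") == "cell")
        p$size[p$position_mm <= L_mer] else NULL
    }))
    if (length(mer_lengths) == 0)
      stop("no cell-length measurements within the meristem (L_mer = ", L_mer, " mm)")
    L_mer / (mean(mer_lengths) / 1000)
  } else {
    base_gap <- min(len_cell$grid_mm)
    n_gap <- if (base_gap > 0) base_gap / (len_cell$mean[1] / 1000) else 0
    n_gap + count_cells(len_cell, min(len_cell$grid_mm), L_mer, size_unit = "um")
  }
  div <- division_params(P, N_mer)

  # dimension-specific residence times from the dimension's growth zone
  gz_for_tel <- function(key) {
    est <- gz[[key]]
    min(est$L_gz, max(len_cell$grid_mm))
  }
  tel_tab <- do.call(rbind, lapply(names(gz), function(key) {
    Lg <- gz_for_tel(key)
    N_el <- if (Lg > L_mer)
      count_cells(len_cell, L_mer, Lg, size_unit = "um") else 0
    tibble::tibble(dimension = gz[[key]]$dimension, level = gz[[key]]$level,
                   L_gz_mm = gz[[key]]$L_gz, N_el = N_el,
                   T_el_h = elongation_residence(N_el, P))
  }))

  # cross-replicate mean of the per-position measurement means, for
  # boundary-size evaluation free of smoothing bias
  raw_profiles <- lapply(stats::setNames(nm = names(smoothed)), function(key) {
    sm <- smoothed[[key]]
    reps <- Filter(function(p) attr(p, "dimension") == attr(sm, "dimension") &&
                     attr(p, "level") == attr(sm, "level"), sps)
    all_pos <- sort(unique(unlist(lapply(reps, `[[`, "position_mm"))))
    vals <- rowMeans(vapply(reps, function(p)
      stats::approx(p$position_mm, p$size, xout = all_pos, rule = 2)$y,
      numeric(length(all_pos))))
    list(position_mm = all_pos, mean = vals)
  })

  prof_value <- function(key, x) {
    if (boundary_sizes == "raw") {
      rp <- raw_profiles[[key]]
      stats::approx(rp$position_mm, rp$mean, xout = x, rule = 2)$y
    } else {
      sm <- smoothed[[key]]
      stats::approx(sm$grid_mm, sm$mean, xout = x, rule = 2)$y
    }
  }
  zone_tab <- do.call(rbind, lapply(names(smoothed), function(key) {
    sm <- smoothed[[key]]
    row <- tel_tab[tel_tab$dimension == attr(sm, "dimension") &
                     tel_tab$level == attr(sm, "level"), ]
    s_base <- prof_value(key, min(sm$grid_mm))
    s_mer <- prof_value(key, L_mer)
    s_gz <- prof_value(key, row$L_gz_mm)
    tibble::tibble(
      dimension = rep(row$dimension, 2), level = rep(row$level, 2),
      zone = c("meristem", "elongation"),
      size1 = c(s_base, s_mer), size2 = c(s_mer, s_gz),
      dt_h = c(div$T_mer, row$T_el_h),
      rgr = c(zone_rgr(s_base, s_mer, div$T_mer, mode = rgr_mode),
              if (row$T_el_h > 0)
                zone_rgr(s_mer, s_gz, row$T_el_h, mode = rgr_mode) else NA_real_)
    )
  }))

  aniso <- do.call(rbind, lapply(c("cell", "organ"), function(lv) {
    do.call(rbind, lapply(c("meristem", "elongation"), function(z) {
      pick <- function(d, l) {
        # organ-level length RGR equals the cell-level one (computed from
        # cell length data); fall back accordingly
        key <- zone_tab$dimension == d & zone_tab$level == l & zone_tab$zone == z
        if (!any(key) && d == "length")
          key <- zone_tab$dimension == d & zone_tab$level == "cell" & zone_tab$zone == z
        if (!any(key)) return(NA_real_)
        zone_tab$rgr[key][1]
      }
      rl <- pick("length", lv); rw <- pick("width", lv); rt <- pick("thickness", lv)
      if (any(is.na(c(rl, rw, rt))) || rl == 0) return(NULL)
      tibble::tibble(level = lv, zone = z,
                     length_width = rl / rw, length_thickness = rl / rt)
    }))
  }))

  grid <- len_cell$grid_mm
  flux <- flux_profile(grid, P, L_mer)
  vel <- velocity_profile(len_cell$mean / 1000, flux)
  profile_table <- tibble::tibble(
    x_mm = grid, flux_cells_h = flux, velocity_mm_h = vel,
    rgr_length_h = rgr_length_profile(vel, grid)
  )

  structure(list(
    smoothed = smoothed, growth_zones = growth_zones,
    params = list(LER = LER, L_mer = L_mer, l_mat_um = l_mat_um, P = P,
                  N_mer = N_mer, D = div$D, T_c = div$T_c, T_mer = div$T_mer),
    residence = tel_tab, zone_rgr = zone_tab, anisotropy = aniso,
    profile_table = profile_table
  ), class = "genotype_kinematics")
}

#' Run the end-to-end kinematic pipeline and compare genotypes
#'
#' Accepts exactly one of `sim_configs` (named list of [sim_config()];
#' each genotype is simulated with the shared `seed`), `datasets` (named
#' list of [simulate_growth_zone()] results) or `input_paths` (named list;
#' each element a list with file paths `profiles`, `leaf_lengths`,
#' `meristem` readable by [read_profiles()] / `read.csv`). The first
#' genotype is the control: the report carries percent differences of
#' every scalar parameter for each other genotype against it.
#'
#' @param sim_configs,datasets,input_paths Input source; supply one.
#' @param seed RNG seed used for every simulated genotype (ignored for
#'   file/dataset input).
#' @param out_dir Optional directory; if given, smoothed profiles, the
#'   growth-zone table, the kinematic parameter table and the comparison
#'   table are written as CSV with a provenance header line.
#' @param ... Analysis settings passed to [analyze_genotype()].
#' @return A `comparison_report`: list with `genotypes` (per-genotype
#'   `genotype_kinematics`), `parameters` (long tibble of scalar
#'   parameters), `comparison` (percent differences vs the control),
#'   `provenance` (seed, config hash, package version).
#' @export
run_pipeline <- function(sim_configs = NULL, datasets = NULL,
                         input_paths = NULL, seed = NULL, out_dir = NULL, ...) {
  n_src <- sum(!vapply(list(sim_configs, datasets, input_paths), is.null, TRUE))
  if (n_src != 1)
    stop("supply exactly one of sim_configs, datasets, input_paths")

  if (!is.null(sim_configs)) {
    stopifnot(!is.null(names(sim_configs)))
    datasets <- lapply(sim_configs, function(cf)
      simulate_growth_zone(cf, seed = if (!is.null(cf$seed)) cf$seed else seed))
  }
  if (!is.null(datasets)) {
    stopifnot(!is.null(names(datasets)))
    inputs <- lapply(datasets, function(d)
      list(profiles = d$profiles, leaf_lengths = d$leaf_lengths,
           meristem = d$meristem))
  } else {
    stopifnot(!is.null(names(input_paths)))
    inputs <- lapply(input_paths, function(p) {
      list(profiles = utils::read.csv(p$profiles),
           leaf_lengths = utils::read.csv(p$leaf_lengths),
           meristem = utils::read.csv(p$meristem))
    })
  }

  genotypes <- lapply(inputs, function(inp)
    analyze_genotype(inp$profiles, inp$leaf_lengths, inp$meristem, ...))

  parameters <- do.call(rbind, lapply(names(genotypes), function(g) {
    gk <- genotypes[[g]]
    scalars <- c(unlist(gk$params),
                 stats::setNames(gk$residence$T_el_h,
                                 paste0("T_el_", gk$residence$dimension, "_",
                                        gk$residence$level)),
                 stats::setNames(gk$growth_zones$L_gz_mm,
                                 paste0("L_gz_", gk$growth_zones$dimension, "_",
                                        gk$growth_zones$level)),
                 stats::setNames(gk$growth_zones$mature_size,
                                 paste0("mature_", gk$growth_zones$dimension, "_",
                                        gk$growth_zones$level)))
    tibble::tibble(genotype = g, parameter = names(scalars),
                   value = unname(scalars))
  }))

  control <- names(genotypes)[1]
  comparison <- NULL
  if (length(genotypes) > 1) {
    ctrl <- parameters[parameters$genotype == control, ]
    comparison <- do.call(rbind, lapply(names(genotypes)[-1], function(g) {
      trt <- parameters[parameters$genotype == g, ]
      m <- merge(ctrl, trt, by = "parameter", suffixes = c("_control", "_treatment"))
      ok <- m$value_control != 0 & is.finite(m$value_control) & is.finite(m$value_treatment)
      tibble::tibble(
        control = control, treatment = g, parameter = m$parameter,
        value_control = m$value_control, value_treatment = m$value_treatment,
        percent = ifelse(ok, percent_difference(ifelse(ok, m$value_control, 1),
                                                m$value_treatment), NA_real_)
      )
    }))
  }

  provenance <- list(seed = seed, version = as.character(utils::packageVersion("anisokin")),
                     config_hash = .hash_object(lapply(inputs, function(i)
                       list(i$profiles, i$leaf_lengths, i$meristem))))

  report <- structure(list(genotypes = genotypes, parameters = parameters,
                           comparison = comparison, provenance = provenance),
                      class = "comparison_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# md5 of a serialized object, for provenance headers
.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write the pipeline report tables to a directory
#'
#' @param report A `comparison_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the file paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# anisokin %s seed=%s config=%s",
                 report$provenance$version,
                 report$provenance$seed %||% "NA", report$provenance$config_hash)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  paths <- c(emit(report$parameters, "kinematic_params.csv"))
  gzt <- do.call(rbind, lapply(names(report$genotypes), function(g)
    cbind(genotype = g, report$genotypes[[g]]$growth_zones)))
  paths <- c(paths, emit(gzt, "growth_zones.csv"))
  smt <- do.call(rbind, lapply(names(report$genotypes), function(g) {
    gk <- report$genotypes[[g]]
    do.call(rbind, lapply(names(gk$smoothed), function(key) {
      s <- gk$smoothed[[key]]
      cbind(genotype = g, dimension = attr(s, "dimension"),
            level = attr(s, "level"), as.data.frame(s))
    }))
  }))
  paths <- c(paths, emit(smt, "smoothed_profiles.csv"))
  if (!is.null(report$comparison))
    paths <- c(paths, emit(report$comparison, "comparison.csv"))
  invisible(paths)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Kinematic comparison report (", length(x$genotypes), " genotype(s))\n", sep = "")
  for (g in names(x$genotypes)) {
    p <- x$genotypes[[g]]$params
    cat(sprintf("  %s: LER=%.3g mm/h, P=%.3g cells/h, T_c=%.3g h, l_mat=%.3g um\n",
                g, p$LER, p$P, p$T_c, p$l_mat_um))
  }
  if (!is.null(x$comparison))
    cat("  ", nrow(x$comparison), " percent-difference contrasts vs control '",
        x$comparison$control[1], "'\n", sep = "")
  invisible(x)
}
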