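#' Generate a synthetic survey landscape
#'
#' Creates a table of grid cells with the covariates the occupancy model
#' uses: a projected northing coordinate ("latitude"), mean elevation, mean
#' canopy height, and a forest-unit membership. Forests are contiguous
#' blocks along the northing axis so forest means genuinely differ, and
#' elevation is generated with a latitudinal trend so that residualizing
#' elevation on latitude (as the design-builder does) is a meaningful step.
#'
#' @param n_cells number of grid cells (>= 1).
#' @param n_forests number of forest units (>= 1).
#' @param covariate_config list overriding any of: `northing_range` (m),
#'   `elev_mean`, `elev_sd`, `elev_lat_slope` (m of elevation per m of
#'   northing), `canopy_mean`, `canopy_sd` (all in metres).
#' @param seed RNG seed (required; generators are pure in (inputs, seed)).
#' @return data.frame with columns cell_id, forest_id, northing, elevation,
#'   canopy_height.
#' @export
gen_landscape <- function(n_cells, n_forests = 7, covariate_config = list(),
                          seed) {
  if (n_cells < 1 || n_forests < 1) stop("n_cells and n_forests must be >= 1")
  if (n_forests > n_cells) stop("cannot have more forests than cells")
  cfg <- utils::modifyList(list(
    northing_range = c(0, 550e3),  # ~ latitudinal span of a mountain range
    elev_mean = 1700, elev_sd = 450,
    elev_lat_slope = -1.5e-3,      # lower terrain toward the north
    canopy_mean = 22, canopy_sd = 8
  ), covariate_config)
  set.seed(seed)
  northing <- sort(stats::runif(n_cells, cfg$northing_range[1],
                                cfg$northing_range[2]))
  # contiguous forest blocks along northing
  forest_id <- if (n_forests == 1) rep(1L, n_cells) else
    as.integer(cut(seq_len(n_cells), breaks = n_forests, labels = FALSE))
  elevation <- cfg$elev_mean +
    cfg$elev_lat_slope * (northing - mean(cfg$northing_range)) +
    stats::rnorm(n_cells, 0, cfg$elev_sd)
  elevation <- pmax(elevation, 0)
  canopy <- pmax(stats::rnorm(n_cells, cfg$canopy_mean, cfg$canopy_sd), 0)
  data.frame(
    cell_id = sprintf("C%04d", seq_len(n_cells)),
    forest_id = forest_id,
    northing = northing,
    elevation = elevation,
    canopy_height = canopy,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic fire history
#'
#' Fires are drawn as a Poisson number per year (`fire_rate` fires/year);
#' each fire burns a contiguous block of cells (cells are ordered along
#' northing, so blocks are spatially coherent) and each affected cell
#' receives a newly-burned high-severity fraction drawn from a Beta
#' distribution. A cell may burn in multiple years.
#'
#' @param cells landscape table from [gen_landscape()].
#' @param years integer vector of fire years (contiguous range).
#' @param fire_rate expected number of fires per year (>= 0).
#' @param severity_beta_params shape1/shape2 of the Beta distribution of the
#'   per-cell high-severity fraction.
#' @param footprint_size_dist function(n) returning n positive integers,
#'   the number of cells per fire footprint.
#' @param seed RNG seed.
#' @return data.frame with columns cell_id, fire_year, fraction (newly
#'   burned high-severity fraction of the cell in that fire year).
#' @export
gen_fire_history <- function(cells, years, fire_rate = 3,
                             severity_beta_params = c(1.2, 1.8),
                             footprint_size_dist = function(n)
                               1L + stats::rpois(n, 5),
                             seed) {
  if (nrow(cells) == 0) stop("empty cell table")
  if (fire_rate < 0) stop("fire_rate must be >= 0")
  years <- as.integer(years)
  if (length(years) && !all(diff(sort(years)) == 1L)) {
    stop("years must be a contiguous range")
  }
  set.seed(seed)
  n_cells <- nrow(cells)
  out <- list()
  for (yr in years) {
    n_fires <- stats::rpois(1, fire_rate)
    if (n_fires == 0) next
    sizes <- pmin(footprint_size_dist(n_fires), n_cells)
    for (f in seq_len(n_fires)) {
      start <- sample.int(n_cells - sizes[f] + 1L, 1L)
      idx <- start:(start + sizes[f] - 1L)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cells$cell_id[idx],
        fire_year = yr,
        fraction = stats::rbeta(sizes[f], severity_beta_params[1],
                                severity_beta_params[2]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(cell_id = character(), fire_year = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Generate a synthetic ARU deployment log
#'
#' Emulates a PAM field season: each surveyed cell gets `arus_per_cell`
#' recorders, each deployed for `duration_nights` consecutive nights
#' starting at a random point early in the 18-week season, recording
#' `nightly_hours` per survey night (the 20:00-06:00 analysis window holds
#' at most 10 h). A fraction of cell-years can be skipped entirely to mimic
#' access failures, producing missing years.
#'
#' @param cells landscape table.
#' @param years monitored calendar years.
#' @param arus_per_cell recorders per cell.
#' @param duration_nights nights each recorder stays out.
#' @param nightly_hours hours recorded per survey night (0-10).
#' @param p_skip probability a cell-year is not surveyed at all.
#' @param season_start month-day string; week 1 starts here each year.
#' @param seed RNG seed.
#' @return data.frame with columns aru_id, cell_id, x, y, start_night,
#'   end_night (Date), nightly_hours.
#' @export
gen_deployments <- function(cells, years, arus_per_cell = 2,
                            duration_nights = 35, nightly_hours = 10,
                            p_skip = 0.1, season_start = "04-01", seed) {
  if (nightly_hours < 0 || nightly_hours > 10) {
    stop("nightly_hours must be in [0, 10]")
  }
  set.seed(seed)
  out <- list()
  for (yr in years) {
    anchor <- as.Date(sprintf("%d-%s", yr, season_start))
    for (i in seq_len(nrow(cells))) {
      if (stats::runif(1) < p_skip) next
      for (a in seq_len(arus_per_cell)) {
        # start somewhere in the first ~13 weeks so the unit fits the season
        offset <- sample.int(18L * 7L - duration_nights + 1L, 1L) - 1L
        start <- anchor + offset
        out[[length(out) + 1L]] <- data.frame(
          aru_id = sprintf("%s_A%d_%d", cells$cell_id[i], a, yr),
          cell_id = cells$cell_id[i],
          x = stats::runif(1, 0, 50e3),
          y = cells$northing[i] + stats::runif(1, -1000, 1000),
          start_night = start,
          end_night = start + duration_nights - 1L,
          nightly_hours = nightly_hours,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic call-back survey locations
#'
#' Places `n` call-back survey events on nights and locations drawn from the
#' deployment log, each within `max_dist` of a recorder so the 1.5-km
#' exclusion filter has something to exclude.
#'
#' @param deployments deployment log from [gen_deployments()].
#' @param n number of call-back survey events.
#' @param max_dist maximum distance (m) from the chosen recorder.
#' @param seed RNG seed.
#' @return data.frame with columns x, y, night.
#' @export
gen_callback_surveys <- function(deployments, n, max_dist = 1200, seed) {
  set.seed(seed)
  rows <- sample.int(nrow(deployments), n, replace = TRUE)
  nights <- deployments$start_night[rows] +
    vapply(deployments$end_night[rows] - deployments$start_night[rows] + 1,
           function(k) sample.int(k, 1L) - 1L, numeric(1))
  ang <- stats::runif(n, 0, 2 * pi)
  r <- stats::runif(n, 0, max_dist)
  data.frame(
    x = deployments$x[rows] + r * cos(ang),
    y = deployments$y[rows] + r * sin(ang),
    night = as.Date(nights, origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
}
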