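#' Residualize elevation on latitude
#'
#' The elevational range a species occupies shifts with latitudinal position
#' along a mountain range, so elevation is corrected for geographic position
#' by taking the residuals of an ordinary least-squares regression of cell
#' elevation on cell northing.
#'
#' @param cells landscape table with `elevation` and `northing`.
#' @return numeric vector of residuals (same order as `cells`).
#' @export
residualize_elevation <- function(cells) {
  if (nrow(cells) < 3) stop("need at least 3 cells to residualize elevation")
  if (stats::sd(cells$northing) == 0) {
    stop("constant latitude across cells: elevation~latitude fit is singular")
  }
  fit <- stats::lm(elevation ~ northing, data = cells)
  unname(stats::residuals(fit))
}

#' Classify composite burn index values as high severity
#'
#' CBI is a 0-3 field-calibrated burn-severity scale; values at or above
#' the threshold (default 2.25) are classed as high-severity fire. Values
#' outside [0, 3] are clamped with a warning.
#'
#' @param cbi_values numeric CBI values.
#' @param threshold high-severity cutoff (inclusive).
#' @return logical vector.
#' @export
classify_high_severity <- function(cbi_values, threshold = 2.25) {
  if (any(cbi_values < 0 | cbi_values > 3, na.rm = TRUE)) {
    warning("CBI values outside [0, 3] clamped")
    cbi_values <- pmin(pmax(cbi_values, 0), 3)
  }
  cbi_values >= threshold
}

#' Cumulative proportion of a cell burned at high severity
#'
#' Proportion of a cell burned at high severity from `start_year` through
#' the fire season *preceding* the monitoring year (fires in the monitoring
#' year itself are excluded). Two input forms are supported:
#'
#' * scalar per-fire fractions (columns cell_id, fire_year, fraction): the
#'   union across fires is approximated as `1 - prod(1 - fraction)`, i.e.
#'   fires are assumed to land independently within the cell;
#' * pixel masks (a list per fire year of logical grids for the cell): the
#'   union is computed exactly over pixels.
#'
#' The two paths agree exactly when fires do not overlap.
#'
#' @param burn_layers data.frame of scalar fractions, or a named list
#'   (names = fire years) of logical pixel matrices for this cell.
#' @param cell cell_id to evaluate (ignored for the pixel-mask form).
#' @param monitoring_year year whose survey season is being modelled.
#' @param start_year earliest fire year considered.
#' @return proportion in [0, 1].
#' @export
cumulative_high_severity <- function(burn_layers, cell, monitoring_year,
                                     start_year = 1985) {
  if (monitoring_year <= start_year) {
    stop("monitoring_year must be after start_year")
  }
  if (is.data.frame(burn_layers)) {
    keep <- burn_layers$cell_id == cell &
      burn_layers$fire_year >= start_year &
      burn_layers$fire_year < monitoring_year
    fr <- burn_layers$fraction[keep]
    if (any(fr < 0)) stop("negative burn fractions")
    if (any(fr > 1)) stop("burn fractions must be in [0, 1]")
    return(1 - prod(1 - fr))
  }
  # pixel-mask path: named list of logical matrices, names are fire years
  yrs <- as.integer(names(burn_layers))
  keep <- yrs >= start_year & yrs < monitoring_year
  if (!any(keep)) return(0)
  masks <- burn_layers[keep]
  acc <- Reduce(`|`, masks)
  mean(acc)
}

# cumulative propHS for every cell at each requested year; scalar path,
# vectorized over the burn table
prop_hs_matrix <- function(cells, burns, monitoring_years,
                           start_year = 1985) {
  n <- nrow(cells)
  out <- matrix(0, n, length(monitoring_years),
                dimnames = list(cells$cell_id, monitoring_years))
  if (is.null(burns) || nrow(burns) == 0) return(out)
  if (any(burns$fraction < 0)) stop("negative burn fractions")
  for (k in seq_along(monitoring_years)) {
    keep <- burns$fire_year >= start_year &
      burns$fire_year < monitoring_years[k]
    if (!any(keep)) next
    b <- burns[keep, ]
    lp <- tapply(log1p(-b$fraction), b$cell_id, sum)
    m <- match(names(lp), cells$cell_id)
    ok <- !is.na(m)
    out[m[ok], k] <- 1 - exp(lp[ok])
  }
  out
}

standardize_col <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x, na.rm = TRUE)
  if (is.null(scale)) scale <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1
  list(values = (x - center) / scale, center = center, scale = scale)
}

#' Build the standardized design set for the four submodels
#'
#' Produces the covariate structures the model consumes:
#'
#' * initial occupancy: canopy height, latitude-residualized elevation
#'   (linear + quadratic), latitude (linear + quadratic), and the proportion
#'   of the cell burned at high severity before the first survey year;
#' * colonization / extinction: proportion high severity up to the start
#'   year of each transition, plus transition-start-year dummies (first
#'   transition year is the reference level);
#' * detection: natural log of weekly recording hours, day-of-year of the
#'   week midpoint (linear + quadratic), plus survey-year dummies (first
#'   year is the reference level).
#'
#' All continuous columns are centred and scaled over the estimation set;
#' quadratic columns are squares of the standardized linear column (not
#' re-standardized). The per-column centre/scale is recorded so new data can
#' be projected onto the same scale.
#'
#' @param cells landscape table.
#' @param burns burn-fraction table (cell_id, fire_year, fraction), possibly
#'   empty.
#' @param history an [encounter_history()] (needed for the detection design;
#'   may be `NULL` when only the state submodels are required).
#' @param years monitored years; defaults to the history's years.
#' @param season_start month-day string anchoring week 1.
#' @param fire_start_year earliest fire year entering the cumulative burn
#'   proportion.
#' @param scaling optional scaling list from a previous design, to project
#'   new data onto an existing standardization.
#' @return an object of class `occ_design`.
#' @export
build_design <- function(cells, burns, history = NULL, years = NULL,
                         season_start = "04-01", fire_start_year = 1985,
                         scaling = NULL) {
  if (is.null(years)) {
    if (is.null(history)) stop("supply `years` when history is NULL")
    years <- history$years
  }
  years <- as.integer(years)
  n <- nrow(cells)
  T <- length(years)
  sc <- list()
  std <- function(name, x) {
    s <- standardize_col(x, scaling[[name]]$center, scaling[[name]]$scale)
    sc[[name]] <<- list(center = s$center, scale = s$scale)
    s$values
  }

  elev_res <- residualize_elevation(cells)
  canopy_s <- std("canopy", cells$canopy_height)
  elev_s <- std("elev", elev_res)
  lat_s <- std("lat", cells$northing)
  phs <- prop_hs_matrix(cells, burns, years, fire_start_year)
  # transitions t -> t+1 additionally see fires in year t itself
  phs_trans <- if (T > 1) {
    prop_hs_matrix(cells, burns, years[-1], fire_start_year)
  } else NULL
  phs_all <- cbind(phs[, 1], phs_trans)
  phs_s_all <- std("propHS", as.vector(phs_all))
  phs_s <- matrix(phs_s_all, n)

  X_psi <- cbind(canopy = canopy_s, elev = elev_s, elev2 = elev_s^2,
                 lat = lat_s, lat2 = lat_s^2, propHS = phs_s[, 1])

  X_gamma <- X_eps <- NULL
  if (T > 1) {
    k_tr <- 1L + (T - 2L)
    X_gamma <- array(0, c(n, T - 1L, k_tr),
                     dimnames = list(cells$cell_id, years[-T],
                                     c("propHS", if (T > 2)
                                       paste0("yr", years[2:(T - 1)]))))
    for (t in seq_len(T - 1L)) {
      X_gamma[, t, 1] <- phs_s[, t + 1L]
      if (t > 1) X_gamma[, t, t] <- 1  # dummy for start year t (ref = year 1)
    }
    X_eps <- X_gamma
  }

  X_p <- NULL
  effort <- NULL
  if (!is.null(history)) {
    effort <- history$effort
    J <- length(history$weeks)
    obs <- effort > 0 & !is.na(effort)
    log_h <- ifelse(obs, log(pmax(effort, 1e-12)), NA_real_)
    # day-of-year at the midpoint of each week
    doy0 <- vapply(years, function(yr)
      as.integer(format(as.Date(sprintf("%d-%s", yr, season_start)), "%j")),
      integer(1))
    date_mid <- outer(rep(1, n),
                      outer(doy0, (seq_len(J) - 1L) * 7L + 3L, `+`))
    lh_s <- std("log_hours", as.vector(log_h))
    dt_s <- std("date", as.vector(date_mid)[as.vector(obs)])
    date_s <- array(NA_real_, dim(effort))
    date_s[obs] <- dt_s
    lh_arr <- array(lh_s, dim(effort))
    k_p <- 3L + (T - 1L)
    X_p <- array(NA_real_, c(n, T, J, k_p),
                 dimnames = list(cells$cell_id, years, NULL,
                                 c("log_hours", "date", "date2",
                                   if (T > 1) paste0("yr", years[-1]))))
    X_p[, , , 1] <- lh_arr
    X_p[, , , 2] <- date_s
    X_p[, , , 3] <- date_s^2
    if (T > 1) {
      X_p[, , , 4:k_p] <- 0
      for (t in 2:T) X_p[, t, , 3L + (t - 1L)] <- 1
    }
  }

  structure(list(
    X_psi = X_psi, X_gamma = X_gamma, X_eps = X_eps, X_p = X_p,
    forest = as.integer(cells$forest_id),
    n_forests = max(as.integer(cells$forest_id)),
    prop_hs = phs,
    site_ids = cells$cell_id, years = years,
    weeks = if (!is.null(history)) history$weeks else NULL,
    effort = effort, scaling = sc, season_start = season_start
  ), class = "occ_design")
}

#' Undo the standardization of a design column
#'
#' @param design an `occ_design`.
#' @param name scaled column name (e.g. "canopy", "log_hours").
#' @param x standardized values.
#' @return values on the original scale.
#' @export
unstandardize <- function(design, name, x) {
  s <- design$scaling[[name]]
  if (is.null(s)) stop("no scaling recorded for column ", name)
  x * s$scale + s$center
}
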