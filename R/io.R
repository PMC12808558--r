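# schema-validated CSV reading: missing required columns are hard errors
# (named in the message), unknown columns only warn
read_csv_checked <- function(path, required, date_cols = character(0),
                             what = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), c(required, "validated"))
  if (length(extra)) {
    warning(what, ": unknown column(s) ignored: ",
            paste(extra, collapse = ", "))
  }
  for (cl in date_cols) df[[cl]] <- as.Date(df[[cl]])
  df
}

#' Read a classifier prediction table
#' @param path CSV with columns cell_id, aru_id, night, segment_start,
#'   call_type, confidence (optionally validated).
#' @return data.frame with `night` parsed as Date.
#' @export
read_predictions_csv <- function(path) {
  df <- read_csv_checked(path, c("cell_id", "aru_id", "night",
                                 "segment_start", "call_type",
                                 "confidence"), "night")
  if (any(!is.finite(df$confidence) | df$confidence < 0 |
            df$confidence > 1)) {
    stop("predictions: confidence must be in [0, 1]")
  }
  df
}

#' Read an ARU deployment log
#' @param path CSV with columns aru_id, cell_id, x, y, start_night,
#'   end_night, nightly_hours.
#' @return data.frame with dates parsed.
#' @export
read_deployments_csv <- function(path) {
  df <- read_csv_checked(path, c("aru_id", "cell_id", "x", "y",
                                 "start_night", "end_night",
                                 "nightly_hours"),
                         c("start_night", "end_night"))
  if (any(df$start_night > df$end_night)) {
    stop("deployments: start_night after end_night")
  }
  if (any(df$nightly_hours < 0 | df$nightly_hours > 10)) {
    stop("deployments: nightly_hours must be in [0, 10]")
  }
  df
}

#' Read a call-back survey log
#' @param path CSV with columns x, y, night.
#' @return data.frame with `night` parsed as Date.
#' @export
read_callbacks_csv <- function(path) {
  read_csv_checked(path, c("x", "y", "night"), "night")
}

#' Read a cell covariate table
#' @param path CSV with columns cell_id, forest_id, northing, elevation,
#'   canopy_height.
#' @return data.frame.
#' @export
read_cells_csv <- function(path) {
  df <- read_csv_checked(path, c("cell_id", "forest_id", "northing",
                                 "elevation", "canopy_height"))
  if (anyDuplicated(df$cell_id)) stop("cells: duplicated cell_id")
  if (any(df$elevation < 0) || any(df$canopy_height < 0)) {
    stop("cells: elevation and canopy_height must be >= 0")
  }
  df
}

#' Read a burn-fraction table
#' @param path CSV with columns cell_id, fire_year, fraction.
#' @return data.frame.
#' @export
read_burns_csv <- function(path) {
  df <- read_csv_checked(path, c("cell_id", "fire_year", "fraction"))
  if (any(df$fraction < 0 | df$fraction > 1)) {
    stop("burns: fraction must be in [0, 1]")
  }
  df
}

#' Write / read an encounter history as a tidy long CSV
#'
#' Long layout (site, year, week, y, effort_hours), lossless: unsurveyed
#' cell-weeks are rows with empty y and zero effort.
#'
#' @param history an [encounter_history()].
#' @param path output CSV path.
#' @export
write_history_long <- function(history, path) {
  d <- dim(history$Y)
  df <- data.frame(
    site = rep(history$site_ids, times = d[2] * d[3]),
    year = rep(rep(history$years, each = d[1]), times = d[3]),
    week = rep(history$weeks, each = d[1] * d[2]),
    y = as.vector(history$Y),
    effort_hours = as.vector(history$effort)
  )
  df <- df[order(df$site, df$year, df$week), ]
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' @rdname write_history_long
#' @param path CSV produced by [write_history_long()].
#' @return an [encounter_history()].
#' @export
read_history_long <- function(path) {
  df <- read_csv_checked(path, c("site", "year", "week", "y",
                                 "effort_hours"))
  sites <- sort(unique(df$site))
  years <- sort(unique(df$year))
  weeks <- sort(unique(df$week))
  Y <- array(NA_real_, c(length(sites), length(years), length(weeks)))
  E <- array(0, dim(Y))
  idx <- cbind(match(df$site, sites), match(df$year, years),
               match(df$week, weeks))
  Y[idx] <- df$y
  E[idx] <- df$effort_hours
  encounter_history(Y, E, sites, years, weeks)
}

#' Write an encounter history in wide (unmarked-style) layout
#'
#' One row per site; detection columns `y_<year>_w<week>` followed by
#' effort columns `hours_<year>_w<week>`.
#'
#' @param history an [encounter_history()].
#' @param path output CSV path.
#' @export
write_history_wide <- function(history, path) {
  d <- dim(history$Y)
  flat <- function(a, prefix) {
    m <- matrix(a, d[1])
    colnames(m) <- paste0(prefix, "_",
                          rep(history$years, times = d[3]), "_w",
                          rep(history$weeks, each = d[2]))
    m[, order(colnames(m)), drop = FALSE]
  }
  df <- data.frame(site = history$site_ids, flat(history$Y, "y"),
                   flat(history$effort, "hours"), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Write group trend summaries as a tidy CSV plus a JSON of trend stats
#'
#' @param trajectories result of [group_trajectory()].
#' @param csv_path output CSV (group, year, mean, lo95, hi95).
#' @param json_path optional JSON path for per-group lambda-bar and
#'   probability-of-direction summaries.
#' @return the tidy data.frame, invisibly.
#' @export
write_trend_summary <- function(trajectories, csv_path,
                                json_path = NULL) {
  tab <- do.call(rbind, lapply(names(trajectories), function(g) {
    cbind(group = g, trajectories[[g]]$summary)
  }))
  utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    stats_list <- lapply(trajectories, function(tr) {
      lb <- lambda_bar(tr$draws)
      list(lambda_bar = unname(lb$summary["mean"]),
           lo95 = unname(lb$summary["lo95"]),
           hi95 = unname(lb$summary["hi95"]),
           pd_decline = lb$pd_decline)
    })
    jsonlite::write_json(stats_list, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(tab)
}

#' Default run configuration
#'
#' Collects the pipeline constants: detection threshold 0.989 (inclusive),
#' minimum 2 detection nights per cell-year, 18 weekly occasions anchored
#' at April 1, CBI high-severity cutoff 2.25, the weakly informative prior
#' scales, and sampler settings of 3 chains x 1500 iterations with 750
#' warmup.
#'
#' @param ... overrides of any default entry.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    threshold = 0.989, min_nights = 2, n_weeks = 18,
    season_start = "04-01", callback_radius = 1500,
    cbi_threshold = 2.25, fire_start_year = 1985,
    prior = prior_config(),
    chains = 3, iter = 1500, warmup = 750,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ",
                        paste(bad, collapse = ", "))
  structure(utils::modifyList(cfg, over), class = "run_config")
}

#' Serialize / load a run configuration
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

#' @rdname write_run_config
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
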