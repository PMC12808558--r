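#' Simulate latent occupancy dynamics
#'
#' Draws the latent occupancy state `z` over sites and years from the same
#' link-function code used in fitting: initial state from the initial
#' occupancy submodel, then Markov transitions
#' `z[i,t+1] ~ Bern(z[i,t](1 - eps) + (1 - z[i,t]) gamma)`.
#'
#' @param cells landscape table.
#' @param burns burn-fraction table.
#' @param params an [occ_params()].
#' @param years monitored years.
#' @param seed RNG seed.
#' @param design optional pre-built state design (must cover `years`).
#' @return list of class `sim_truth`: z (sites x years 0/1 matrix), params,
#'   design, seed.
#' @export
simulate_occupancy <- function(cells, burns, params, years, seed,
                               design = NULL) {
  if (is.null(design)) {
    design <- build_design(cells, burns, history = NULL, years = years)
  }
  pr <- link_probs(params, design)
  n <- nrow(cells); T <- length(design$years)
  set.seed(seed)
  z <- matrix(0L, n, T, dimnames = list(design$site_ids, design$years))
  z[, 1] <- stats::rbinom(n, 1, pr$psi)
  if (T > 1) for (t in 2:T) {
    pt <- z[, t - 1] * (1 - pr$eps[, t - 1]) +
      (1 - z[, t - 1]) * pr$gamma[, t - 1]
    z[, t] <- stats::rbinom(n, 1, pt)
  }
  structure(list(z = z, params = params, design = design, cells = cells,
                 burns = burns, seed = seed),
            class = "sim_truth")
}

#' Simulate nightly detections from a latent occupancy truth
#'
#' For every occupied cell-year, each surveyed night yields a detection
#' event independently with a per-night probability chosen so that the
#' probability of at least one detection night in a week equals the weekly
#' detection probability from the detection submodel:
#' `p_night = 1 - (1 - p_week)^(1/n_nights)`. Unoccupied cell-years yield
#' no events (false positives are injected later, by
#' [gen_prediction_table()]).
#'
#' @param sim_truth result of [simulate_occupancy()].
#' @param deployments deployment log defining per-cell surveyed nights.
#' @param params an [occ_params()] (detection submodel is used).
#' @param seed RNG seed.
#' @param season_start month-day anchor of week 1.
#' @param n_weeks weekly occasions per season.
#' @return list: `events` (data.frame cell_id, aru_id, night), `truth` (the
#'   directly aggregated [encounter_history()]: 1 iff any event in the
#'   cell-week), `p_weekly` (sites x years x weeks array), `design` (full
#'   design including the detection submodel).
#' @export
simulate_detections <- function(sim_truth, deployments, params, seed,
                                season_start = "04-01", n_weeks = 18) {
  years <- sim_truth$design$years
  dep_week_start <- night_to_week(deployments$start_night,
                                  as.integer(format(deployments$start_night,
                                                    "%Y")), season_start)
  dep_week_end <- night_to_week(deployments$end_night,
                                as.integer(format(deployments$end_night,
                                                  "%Y")), season_start)
  if (any(dep_week_start < 1 | dep_week_end > n_weeks)) {
    stop("deployment nights fall outside the ", n_weeks, "-week season")
  }
  # effort/missingness template from deployments, no events yet
  blank <- build_encounter_history(NULL, deployments,
                                   season_start = season_start,
                                   years = years, n_weeks = n_weeks)
  cells_order <- match(blank$site_ids, rownames(sim_truth$z))
  if (anyNA(cells_order)) stop("deployments reference cells missing from z")
  # full design over the surveyed cells, on the same covariate scale as the
  # state design that generated z
  design <- build_design(
    cells = sim_truth$cells[cells_order, , drop = FALSE],
    burns = sim_truth$burns, history = blank, years = years,
    season_start = season_start, scaling = sim_truth$design$scaling
  )
  pr <- link_probs(params, design)
  p_weekly <- pr$p
  z <- sim_truth$z[cells_order, , drop = FALSE]

  set.seed(seed)
  # long table of surveyed (cell, night, recorder); nights covered by more
  # than one recorder count once toward the weekly detection model
  dep <- deployments
  nights_list <- lapply(seq_len(nrow(dep)), function(r)
    seq(dep$start_night[r], dep$end_night[r], by = "day"))
  long <- data.frame(
    cell_id = rep(dep$cell_id, lengths(nights_list)),
    aru_id = rep(dep$aru_id, lengths(nights_list)),
    night = as.Date(unlist(nights_list), origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  long$year <- as.integer(format(long$night, "%Y"))
  long$week <- mapply(night_to_week, long$night, long$year,
                      MoreArgs = list(season_start = season_start))
  long <- long[long$year %in% years, , drop = FALSE]
  # one row per distinct surveyed cell-night (recorder chosen at random
  # among those active that night, for event attribution)
  long <- long[sample.int(nrow(long)), , drop = FALSE]
  nights_u <- long[!duplicated(long[c("cell_id", "night")]), , drop = FALSE]
  i <- match(nights_u$cell_id, blank$site_ids)
  t <- match(nights_u$year, years)
  occupied <- z[cbind(i, t)] == 1
  pw <- p_weekly[cbind(i, t, nights_u$week)]
  # distinct surveyed nights in each cell-week
  key <- paste(nights_u$cell_id, nights_u$year, nights_u$week)
  n_nights <- ave(rep(1, nrow(nights_u)), key, FUN = sum)
  p_night <- 1 - (1 - pw)^(1 / n_nights)
  hit <- occupied & !is.na(p_night) &
    stats::runif(nrow(nights_u)) < p_night
  events <- nights_u[hit, c("cell_id", "aru_id", "night"), drop = FALSE]
  events <- events[order(events$cell_id, events$night), , drop = FALSE]
  rownames(events) <- NULL
  # de-duplicate nights detected by >1 recorder when aggregating truth
  Y <- blank$Y
  if (nrow(events)) {
    eyr <- as.integer(format(events$night, "%Y"))
    ew <- mapply(night_to_week, events$night, eyr,
                 MoreArgs = list(season_start = season_start))
    idx <- unique(cbind(match(events$cell_id, blank$site_ids),
                        match(eyr, years), ew))
    Y[idx] <- 1
  }
  truth <- encounter_history(Y, blank$effort, blank$site_ids, years,
                             seq_len(n_weeks))
  list(events = events, truth = truth, p_weekly = p_weekly,
       design = design, z = z)
}


#' Generate a classifier-style prediction table from true events
#'
#' True detection events become prediction rows (random call type, segment
#' time and a confidence score drawn from `tp_confidence_dist`), flagged
#' "true-positive". Spurious predictions are injected at `fp_rate` per
#' surveyed cell-night with confidences from `fp_confidence_dist`, flagged
#' "false-positive". When call-back surveys are supplied, a fraction
#' `callback_frac` of the injected false positives is placed at recorders
#' within 1.5 km of a same-night call-back survey, so the exclusion filter
#' has realistic work to do.
#'
#' @param events true events from [simulate_detections()].
#' @param deployments deployment log (defines surveyed cell-nights and
#'   recorder coordinates).
#' @param fp_rate expected spurious predictions per surveyed cell-night.
#' @param tp_confidence_dist,fp_confidence_dist function(n) drawing n
#'   confidence scores in [0, 1].
#' @param callback_surveys optional call-back survey table (x, y, night).
#' @param callback_frac fraction of false positives co-located with
#'   call-back surveys.
#' @param seed RNG seed.
#' @return prediction table: cell_id, aru_id, night, segment_start,
#'   call_type, confidence, validated.
#' @export
gen_prediction_table <- function(events, deployments, fp_rate = 0.05,
                                 tp_confidence_dist = function(n)
                                   0.989 + 0.011 * stats::rbeta(n, 2, 1),
                                 fp_confidence_dist = function(n)
                                   stats::rbeta(n, 8, 1),
                                 callback_surveys = NULL,
                                 callback_frac = 0.3, seed) {
  if (fp_rate < 0) stop("fp_rate must be >= 0")
  set.seed(seed)
  mk <- function(cell, aru, night, conf, flag) {
    n <- length(night)
    if (any(conf < 0 | conf > 1)) stop("confidence distribution must be ",
                                       "supported on [0, 1]")
    data.frame(cell_id = cell, aru_id = aru, night = night,
               segment_start = sample.int(36000L, n, replace = TRUE),
               call_type = sample(CALL_TYPES, n, replace = TRUE,
                                  prob = c(0.5, 0.2, 0.12, 0.12, 0.06)),
               confidence = conf, validated = flag,
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (nrow(events)) {
    out$tp <- mk(events$cell_id, events$aru_id, events$night,
                 tp_confidence_dist(nrow(events)), "true-positive")
  }
  # spurious predictions over surveyed ARU-nights
  dep <- deployments
  nights_per_dep <- as.integer(dep$end_night - dep$start_night + 1L)
  n_fp <- stats::rpois(1, fp_rate * sum(nights_per_dep))
  if (n_fp > 0) {
    r <- sample.int(nrow(dep), n_fp, replace = TRUE,
                    prob = nights_per_dep)
    night <- dep$start_night[r] + vapply(nights_per_dep[r], function(k)
      sample.int(k, 1L) - 1L, numeric(1))
    fp <- mk(dep$cell_id[r], dep$aru_id[r],
             as.Date(night, origin = "1970-01-01"),
             fp_confidence_dist(n_fp), "false-positive")
    if (!is.null(callback_surveys) && nrow(callback_surveys) &&
        callback_frac > 0) {
      # move a subset of FPs onto (recorder, night) pairs near call-backs
      n_move <- round(callback_frac * n_fp)
      if (n_move > 0) {
        elig <- list()
        for (s in seq_len(nrow(callback_surveys))) {
          d <- sqrt((dep$x - callback_surveys$x[s])^2 +
                      (dep$y - callback_surveys$y[s])^2)
          active <- dep$start_night <= callback_surveys$night[s] &
            dep$end_night >= callback_surveys$night[s]
          hit <- which(d <= 1500 & active)
          if (length(hit)) {
            elig[[length(elig) + 1L]] <- data.frame(
              row = hit, night = callback_surveys$night[s])
          }
        }
        if (length(elig)) {
          elig <- do.call(rbind, elig)
          pick <- elig[sample.int(nrow(elig), n_move, replace = TRUE), ]
          mv <- seq_len(n_move)
          fp$cell_id[mv] <- dep$cell_id[pick$row]
          fp$aru_id[mv] <- dep$aru_id[pick$row]
          fp$night[mv] <- pick$night
        }
      }
    }
    out$fp <- fp
  }
  if (!length(out)) {
    return(data.frame(cell_id = character(), aru_id = character(),
                      night = as.Date(character()),
                      segment_start = integer(), call_type = character(),
                      confidence = numeric(), validated = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cell_id, res$night, res$segment_start), ]
}
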