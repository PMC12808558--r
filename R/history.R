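#' Weekly encounter history container
#'
#' Sites x years x weeks array of weekly detections (0/1/NA) with a
#' matching effort array (recording hours summed across recorders in the
#' cell-week). `NA` marks weeks without acoustic monitoring; a week can be
#' 1 only where effort is positive.
#'
#' @param Y sites x years x weeks array in {0, 1, NA}.
#' @param effort array of the same shape, hours >= 0.
#' @param site_ids,years,weeks dimension labels.
#' @return object of class `encounter_history`.
#' @export
encounter_history <- function(Y, effort, site_ids, years,
                              weeks = seq_len(dim(Y)[3])) {
  stopifnot(length(dim(Y)) == 3, all(dim(Y) == dim(effort)))
  if (!all(Y %in% c(0, 1, NA))) stop("Y must contain only 0, 1, NA")
  if (any(effort < 0, na.rm = TRUE)) stop("effort must be >= 0")
  effort[is.na(effort)] <- 0
  surveyed <- effort > 0
  if (any(is.na(Y) & surveyed)) stop("Y is NA where effort > 0")
  if (any(!is.na(Y) & !surveyed)) stop("Y must be NA where effort is 0")
  if (any(Y == 1 & !surveyed, na.rm = TRUE)) stop("detection with no effort")
  dimnames(Y) <- dimnames(effort) <- list(site_ids, years, weeks)
  structure(list(Y = Y, effort = effort, site_ids = site_ids,
                 years = as.integer(years), weeks = weeks),
            class = "encounter_history")
}

#' @export
print.encounter_history <- function(x, ...) {
  d <- dim(x$Y)
  cat(sprintf("Encounter history: %d sites x %d years x %d weeks\n",
              d[1], d[2], d[3]))
  cat(sprintf("  surveyed cell-weeks: %d (%.1f%%); detections: %d\n",
              sum(!is.na(x$Y)), 100 * mean(!is.na(x$Y)),
              sum(x$Y == 1, na.rm = TRUE)))
  invisible(x)
}

# fixed tie-break precedence for equal-confidence calls in one segment
CALL_TYPES <- c("four-note", "contact", "crow bark", "monkey hoot",
                "juvenile begging")

#' Filter classifier predictions into validated detection events
#'
#' Applies, in order: (1) the confidence-score threshold (inclusive, default
#' 0.989); (2) the best-call-per-segment rule - when several call types in
#' the same 3-s segment pass the threshold, only the highest-confidence one
#' is kept (ties broken by a fixed call-type precedence: four-note >
#' contact > crow bark > monkey hoot > juvenile begging); (3) the call-back
#' exclusion - predictions from a recorder within 1.5 km (inclusive,
#' planar Euclidean distance) of a call-back survey on the same night are
#' discarded, because broadcast calls are indistinguishable from real owls;
#' (4) removal of records flagged false-positive by manual validation.
#'
#' @param preds prediction table with columns cell_id, aru_id, night,
#'   segment_start, call_type, confidence and optionally validated.
#' @param threshold confidence threshold (inclusive).
#' @param callback_surveys optional data.frame (x, y, night).
#' @param aru_locations data.frame (aru_id, x, y); required when
#'   `callback_surveys` is non-empty.
#' @param callback_radius exclusion radius in metres (inclusive).
#' @return the retained events, sorted by (cell_id, night), with an
#'   attribute `filter_counts` recording rows dropped at each stage.
#' @export
filter_predictions <- function(preds, threshold = 0.989,
                               callback_surveys = NULL,
                               aru_locations = NULL,
                               callback_radius = 1500) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (any(!is.finite(preds$confidence)) ||
      any(preds$confidence < 0 | preds$confidence > 1)) {
    stop("malformed confidence scores (must be finite, in [0, 1])")
  }
  counts <- c(input = nrow(preds))
  keep <- preds$confidence >= threshold
  counts["below_threshold"] <- sum(!keep)
  preds <- preds[keep, , drop = FALSE]

  # best call per 3-s segment
  if (nrow(preds)) {
    prec <- match(preds$call_type, CALL_TYPES)
    ord <- order(preds$aru_id, preds$night, preds$segment_start,
                 -preds$confidence, prec)
    preds <- preds[ord, , drop = FALSE]
    seg <- paste(preds$aru_id, preds$night, preds$segment_start)
    dup <- duplicated(seg)
    counts["segment_duplicates"] <- sum(dup)
    preds <- preds[!dup, , drop = FALSE]
  } else counts["segment_duplicates"] <- 0L

  if (!is.null(callback_surveys) && nrow(callback_surveys)) {
    if (is.null(aru_locations)) {
      stop("aru_locations required when call-back surveys are supplied")
    }
    m <- match(preds$aru_id, aru_locations$aru_id)
    if (anyNA(m)) stop("missing ARU coordinates for: ",
                       paste(unique(preds$aru_id[is.na(m)]), collapse = ", "))
    ax <- aru_locations$x[m]; ay <- aru_locations$y[m]
    near <- rep(FALSE, nrow(preds))
    for (s in seq_len(nrow(callback_surveys))) {
      same <- preds$night == callback_surveys$night[s]
      if (!any(same)) next
      d <- sqrt((ax[same] - callback_surveys$x[s])^2 +
                  (ay[same] - callback_surveys$y[s])^2)
      near[same] <- near[same] | d <= callback_radius
    }
    counts["near_callback"] <- sum(near)
    preds <- preds[!near, , drop = FALSE]
  } else counts["near_callback"] <- 0L

  if (!is.null(preds$validated)) {
    fp <- !is.na(preds$validated) & preds$validated == "false-positive"
    counts["validated_fp"] <- sum(fp)
    preds <- preds[!fp, , drop = FALSE]
  } else counts["validated_fp"] <- 0L

  preds <- preds[order(preds$cell_id, preds$night), , drop = FALSE]
  rownames(preds) <- NULL
  counts["retained"] <- nrow(preds)
  attr(preds, "filter_counts") <- counts
  preds
}

# assign nights to season weeks; week 1 begins season_start (April 1)
night_to_week <- function(night, year, season_start = "04-01") {
  anchor <- as.Date(sprintf("%d-%s", year, season_start))
  as.integer(floor(as.numeric(night - anchor) / 7)) + 1L
}

#' Build a weekly encounter history from detection events and deployments
#'
#' Weeks are anchored to `season_start` (week 1 begins April 1 of each
#' year); nights outside weeks 1..`n_weeks` are discarded with a warning.
#' Effort for a cell-week is the sum of nightly recording hours across all
#' recorders surveying that cell that week. A surveyed cell-week is coded 1
#' only when (a) it contains at least one detection night and (b) the cell
#' accumulated at least `min_nights` distinct detection nights across the
#' whole season of that year (pooling recorders and weeks) - a stringent
#' occupancy definition that separates site occupancy from transient use.
#' Unsurveyed cell-weeks are `NA`.
#'
#' @param events filtered detection events (cell_id, aru_id, night).
#' @param deployments deployment log (aru_id, cell_id, start_night,
#'   end_night, nightly_hours).
#' @param season_start month-day string, anchor of week 1.
#' @param years years to include; defaults to the years present in the
#'   deployment log.
#' @param n_weeks number of weekly secondary occasions per year.
#' @param min_nights minimum distinct detection nights per cell-year.
#' @return an [encounter_history()].
#' @export
build_encounter_history <- function(events, deployments,
                                    season_start = "04-01", years = NULL,
                                    n_weeks = 18, min_nights = 2) {
  dep <- deployments
  dep_year <- as.integer(format(dep$start_night, "%Y"))
  if (is.null(years)) years <- sort(unique(dep_year))
  years <- as.integer(years)
  sites <- sort(unique(dep$cell_id))
  n <- length(sites); T <- length(years); J <- as.integer(n_weeks)

  effort <- array(0, c(n, T, J))
  surveyed_nights <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(dep))) {
    nights <- seq(dep$start_night[r], dep$end_night[r], by = "day")
    yr <- as.integer(format(nights[1], "%Y"))
    t <- match(yr, years)
    if (is.na(t)) next
    wk <- night_to_week(nights, yr, season_start)
    ok <- wk >= 1L & wk <= J
    if (any(!ok)) {
      warning(sum(!ok), " deployment night(s) outside the ", J,
              "-week season discarded")
    }
    i <- match(dep$cell_id[r], sites)
    for (w in unique(wk[ok])) {
      effort[i, t, w] <- effort[i, t, w] +
        dep$nightly_hours[r] * sum(wk[ok] == w)
    }
  }

  Y <- array(NA_real_, c(n, T, J))
  Y[effort > 0] <- 0
  if (!is.null(events) && nrow(events)) {
    ev_year <- as.integer(format(events$night, "%Y"))
    ev_week <- mapply(night_to_week, events$night, ev_year,
                      MoreArgs = list(season_start = season_start))
    in_season <- ev_week >= 1L & ev_week <= J & ev_year %in% years
    if (any(!in_season)) {
      warning(sum(!in_season), " event(s) outside the survey season ",
              "discarded")
    }
    ev <- events[in_season, , drop = FALSE]
    ev_year <- ev_year[in_season]; ev_week <- ev_week[in_season]
    i <- match(ev$cell_id, sites)
    t <- match(ev_year, years)
    if (anyNA(i)) stop("events in cells with no deployments")
    bad <- effort[cbind(i, t, ev_week)] <= 0
    if (any(bad)) {
      stop("detection event in a cell-week with zero recorded effort: ",
           paste(unique(paste(ev$cell_id[bad], ev$night[bad])),
                 collapse = "; "))
    }
    # >= min_nights distinct detection nights per cell-year
    key_cy <- paste(i, t)
    nights_per_cy <- tapply(as.character(ev$night), key_cy,
                            function(x) length(unique(x)))
    qualified <- names(nights_per_cy)[nights_per_cy >= min_nights]
    hit <- key_cy %in% qualified
    if (any(hit)) {
      idx <- unique(cbind(i, t, ev_week)[hit, , drop = FALSE])
      Y[idx] <- 1
    }
  }
  encounter_history(Y, effort, sites, years, seq_len(J))
}

#' Summarize manual validation of thresholded predictions
#'
#' Counts predictions at or above the confidence threshold and how many of
#' them were marked true-positive / false-positive during manual review.
#'
#' @param preds prediction table with a `validated` column
#'   ("true-positive", "false-positive" or "unreviewed").
#' @param threshold confidence threshold (inclusive).
#' @return list with reviewed (all records at/above threshold),
#'   true_positive, false_positive and unreviewed counts.
#' @export
validation_summary <- function(preds, threshold = 0.989) {
  if (is.null(preds$validated)) stop("predictions carry no validated flags")
  keep <- preds$confidence >= threshold
  v <- preds$validated[keep]
  list(reviewed = sum(keep),
       true_positive = sum(v == "true-positive"),
       false_positive = sum(v == "false-positive"),
       unreviewed = sum(v == "unreviewed"))
}
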