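# Race-level processing: same-day averaging, exclusion chaining,
# GPS-distance imputation, race velocity, week numbering.

VALID_FLAGS <- c("unwell", "injured_during_race", "imu_attachment_fault",
                 "gps_fail")

split_flags <- function(flags) {
  lapply(strsplit(ifelse(is.na(flags), "", as.character(flags)), ";"),
         function(x) x[nzchar(x)])
}

join_flags <- function(flag_list) {
  vapply(flag_list, function(x) paste(sort(unique(x)), collapse = ";"), "")
}

#' Average same-day races to a single observation
#'
#' When a participant races the same discipline more than once on one day,
#' the races are averaged to a single result: cadence, distance, duration
#' and velocity are each replaced by the arithmetic mean of the group;
#' exclusion flags are pooled (union).
#'
#' @param observations Data frame of race observations with columns
#'   `participant_id`, `date`, `discipline`, `cadence`, and optionally
#'   `season`, `week`, `distance_m`, `duration_s`, `flags`.
#' @return Data frame with one row per (participant, date, discipline).
#' @export
merge_same_day <- function(observations) {
  obs <- observations
  if (nrow(obs) == 0L) return(obs)
  key <- interaction(obs$participant_id, obs$date, obs$discipline,
                     drop = TRUE)
  pieces <- split(obs, key)
  merged <- lapply(pieces, function(g) {
    if (!is.null(g$season) && length(unique(g$season)) > 1L) {
      tri_abort("conflicting season labels within a same-day group",
                "inconsistent_record")
    }
    out <- g[1L, , drop = FALSE]
    for (col in intersect(c("cadence", "distance_m", "duration_s"),
                          names(g))) {
      out[[col]] <- mean(g[[col]])
    }
    if (!is.null(g$flags)) {
      out$flags <- join_flags(list(unlist(split_flags(g$flags))))
    }
    out
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Apply race exclusion and discipline-chaining rules
#'
#' Observations carrying any exclusion flag (`unwell`,
#' `injured_during_race`, `imu_attachment_fault`, `gps_fail`) are removed.
#' Because each discipline's performance is affected by the preceding leg,
#' a discipline is then only retained if the preceding legs survive: per
#' participant-date, a cycle observation is kept only if the same-day swim
#' survives, and a run observation only if both swim and cycle survive.
#'
#' @param observations Data frame of race observations (see
#'   [merge_same_day()]); a `flags` column holds semicolon-joined tokens.
#' @param chain_disciplines Apply the preceding-leg chaining rule (default
#'   TRUE). Set to FALSE for datasets holding a single discipline in
#'   isolation, where no preceding leg exists by construction.
#' @return Filtered data frame (possibly empty). Idempotent.
#' @export
apply_exclusions <- function(observations, chain_disciplines = TRUE) {
  obs <- observations
  if (nrow(obs) == 0L) return(obs)
  fl <- split_flags(obs$flags %||% rep("", nrow(obs)))
  flagged <- vapply(fl, function(x) length(intersect(x, VALID_FLAGS)) > 0,
                    logical(1))
  obs <- obs[!flagged, , drop = FALSE]
  if (nrow(obs) == 0L || !chain_disciplines) {
    rownames(obs) <- NULL
    return(obs)
  }
  key <- paste(obs$participant_id, obs$date, sep = "\r")
  has <- function(disc) {
    key %in% key[obs$discipline == disc]
  }
  keep <- rep(TRUE, nrow(obs))
  keep[obs$discipline == "cycle"] <- has("swim")[obs$discipline == "cycle"]
  keep[obs$discipline == "run"] <-
    (has("swim") & has("cycle"))[obs$discipline == "run"]
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute a race distance from peers in the same race
#'
#' When a participant's GPS failed, the race distance is approximated by
#' the arithmetic mean of the distances recorded by the functioning GPS
#' sensors of the other participants in the same race.
#'
#' @param peer_distances_m Numeric vector of peer distances (>= 1 value).
#' @return The imputed distance in metres, with attribute `imputed = TRUE`.
#' @export
impute_distance <- function(peer_distances_m) {
  peer_distances_m <- peer_distances_m[is.finite(peer_distances_m)]
  if (length(peer_distances_m) == 0L) {
    tri_abort("no peer distances available; observation stays excluded",
              "imputation_impossible")
  }
  structure(mean(peer_distances_m), imputed = TRUE)
}

#' Average race velocity
#'
#' @param distance_m Race distance in metres.
#' @param duration_s Race duration in seconds (> 0).
#' @return Velocity in m/s.
#' @export
race_velocity <- function(distance_m, duration_s) {
  if (any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    tri_abort("duration_s must be > 0", "invalid_parameter")
  }
  distance_m / duration_s
}

#' Assign week numbers from race dates
#'
#' Week 0 is the first race week; under the default `"season"` convention
#' it is the week of the earliest race of each season across the whole
#' cohort, under `"participant"` each athlete's own first race of the
#' season starts their week count.
#'
#' @param observations Data frame with `date` (Date or parseable string)
#'   and `season` columns; `"participant"` additionally uses
#'   `participant_id`.
#' @param convention `"season"` (default) or `"participant"`.
#' @return The data frame with an integer `week` column added/replaced.
#' @export
assign_weeks <- function(observations, convention = c("season",
                                                      "participant")) {
  convention <- match.arg(convention)
  obs <- observations
  d <- as.Date(obs$date)
  grp <- if (convention == "season") as.character(obs$season) else {
    paste(obs$participant_id, obs$season)
  }
  origin <- ave(as.numeric(d), grp, FUN = min)
  obs$week <- as.integer(floor((as.numeric(d) - origin) / 7))
  obs
}

#' Assemble the analysable longitudinal dataset
#'
#' Runs the race-processing pipeline in the documented order: same-day
#' races are first averaged to a single result (exclusions apply to races
#' as units), then flag- and chaining-based exclusions are applied, then
#' week numbers are assigned when race dates are available.
#'
#' @param observations Data frame of raw race observations.
#' @param week_convention Passed to [assign_weeks()]; ignored when the
#'   data carry no `date` column.
#' @return Filtered, merged data frame ready for [fit_model()].
#' @export
assemble_dataset <- function(observations, week_convention = "season") {
  obs <- merge_same_day(observations)
  obs <- apply_exclusions(obs)
  if (!is.null(obs$date) && nrow(obs) > 0L) {
    obs <- assign_weeks(obs, week_convention)
  }
  obs
}
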