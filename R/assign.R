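# State assignment: raw detection records -> annual observed states ->
# encounter histories, with the ground-reader breeder rule and the study's
# exclusion filters.

#' Ground-reader breeder rule
#'
#' A bird never confirmed breeding on nest inspections is still classified as
#' a breeder for a season if it was logged by the ground readers on at least
#' `min_detections` distinct days within the season window, and the span from
#' first to last such day is between `min_span` and `max_span` days
#' (inclusive). Pings outside the season window are discarded first; repeated
#' pings on one day count once.
#'
#' @param ping_dates `Date` vector of reader detections within one season.
#' @param season_window length-2 `Date` vector, default March 1 - October 31
#'   (taken from the year of the first ping when `NULL`).
#' @param min_detections minimum number of distinct detection days (6).
#' @param min_span,max_span inclusive bounds on the day span (12, 120).
#' @return single logical; `FALSE` for empty input.
#' @export
ground_reader_breeder_rule <- function(ping_dates, season_window = NULL,
                                       min_detections = 6L, min_span = 12L,
                                       max_span = 120L) {
  if (length(ping_dates) == 0L) return(FALSE)
  ping_dates <- as.Date(ping_dates)
  if (is.null(season_window)) {
    season_window <- .season_window(as.integer(format(min(ping_dates), "%Y")))
  }
  d <- unique(ping_dates[ping_dates >= season_window[1] &
    ping_dates <= season_window[2]])
  if (length(d) < min_detections) return(FALSE)
  span <- as.integer(max(d) - min(d))
  span >= min_span && span <= max_span
}

#' @noRd
.record_season <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  y <- as.integer(format(dates, "%Y"))
  y[m < 3L | m > 10L] <- NA_integer_
  y
}

#' Classify the observed state of one individual-season
#'
#' Returns 1 (breeder) if any nest record carries breeding evidence or the
#' ground-reader rule passes on the reader detections; otherwise 2
#' (nonbreeder) if the individual was encountered at all and has previously
#' been observed breeding, 3 (prebreeder) if encountered but never yet
#' observed breeding, and 0 if there are no records.
#'
#' @param records detection records (`data.frame` as written by
#'   [emit_detections()]) for a single individual and season.
#' @param prior_breeder logical: has this individual been observed breeding in
#'   an earlier season?
#' @param season_window,min_detections,min_span,max_span passed to
#'   [ground_reader_breeder_rule()].
#' @return integer state code in 0:3.
#' @export
classify_annual_state <- function(records, prior_breeder,
                                  season_window = NULL, min_detections = 6L,
                                  min_span = 12L, max_span = 120L) {
  if (nrow(records) == 0L) return(0L)
  .assert(length(unique(records$colony)) == 1L,
    "records for one individual-season span multiple colonies (%s); filter upstream",
    paste(unique(records$colony), collapse = ", "))
  nest_breeding <- any(records$method == "nest" & records$breeding_evidence == 1)
  reader_dates <- records$date[records$method == "reader"]
  if (nest_breeding ||
      ground_reader_breeder_rule(reader_dates, season_window,
        min_detections, min_span, max_span)) {
    return(1L)
  }
  if (isTRUE(prior_breeder)) 2L else 3L
}

#' Exclusion filters
#'
#' Removes (a) all records of individuals flagged as double-marked (the flag
#' list is an input: band histories predate the detection pipeline) and (b)
#' any individual observed breeding at more than one colony. With
#' `multi_colony = "any"` an individual with records at more than one colony
#' is removed regardless of breeding status; the default `"breeding"` policy
#' removes only multi-colony breeders and assigns the remaining multi-colony
#' individuals to their modal colony.
#'
#' @param records full detection-record `data.frame`.
#' @param double_marked_ids character vector of ids to drop.
#' @param multi_colony `"breeding"` (default) or `"any"`.
#' @return list with `records` (filtered; every kept individual reduced to a
#'   single colony) and `report` (`data.frame` of `individual_id`, `reason`).
#' @export
apply_exclusion_filters <- function(records, double_marked_ids = character(),
                                    multi_colony = c("breeding", "any")) {
  multi_colony <- match.arg(multi_colony)
  report <- data.frame(individual_id = character(), reason = character())
  dm <- intersect(unique(records$individual_id), double_marked_ids)
  if (length(dm)) {
    report <- rbind(report,
      data.frame(individual_id = dm, reason = "double_marked"))
    records <- records[!records$individual_id %in% dm, , drop = FALSE]
  }
  ncol_by_id <- tapply(records$colony, records$individual_id,
    function(z) length(unique(z)))
  multi <- names(ncol_by_id)[ncol_by_id > 1L]
  if (length(multi)) {
    if (multi_colony == "any") {
      report <- rbind(report,
        data.frame(individual_id = multi, reason = "multi_colony"))
      records <- records[!records$individual_id %in% multi, , drop = FALSE]
    } else {
      br <- records[records$breeding_evidence == 1, , drop = FALSE]
      nbrc <- tapply(br$colony, br$individual_id, function(z) length(unique(z)))
      drop <- names(nbrc)[nbrc > 1L]
      if (length(drop)) {
        report <- rbind(report,
          data.frame(individual_id = drop, reason = "breeding_multi_colony"))
        records <- records[!records$individual_id %in% drop, , drop = FALSE]
      }
      # remaining multi-colony, non-breeding-conflict birds: modal colony
      rest <- setdiff(multi, drop)
      for (ind in rest) {
        sel <- records$individual_id == ind
        modal <- names(which.max(table(records$colony[sel])))
        records <- records[!(sel & records$colony != modal), , drop = FALSE]
      }
    }
  }
  rownames(records) <- NULL
  list(records = records, report = report)
}

#' Build encounter histories from filtered detection records
#'
#' Classifies each individual-season with [classify_annual_state()], carrying
#' a has-ever-bred flag forward so that prebreeder coding flips permanently to
#' nonbreeder coding after the first observed breeding season. Seasons with no
#' records are coded 0 (not encountered); detection probability absorbs them
#' in the model. Also tallies newly marked individuals (first encounter) per
#' season, colony and state.
#'
#' @param records filtered detection records.
#' @param years calendar seasons spanned by the study (default 2013-2020).
#' @param min_detections,min_span,max_span rule thresholds, see
#'   [ground_reader_breeder_rule()].
#' @return list with `histories` (an [msmr_histories]) and `marked_tally`
#'   (`data.frame` year x colony x state counts of first encounters).
#' @export
build_encounter_histories <- function(records, years = 2013:2020,
                                      min_detections = 6L, min_span = 12L,
                                      max_span = 120L) {
  season <- .record_season(records$date)
  out_of_study <- !is.na(season) & (season < min(years) | season > max(years))
  if (any(out_of_study)) {
    stop(sprintf("records outside the study seasons %d-%d for: %s",
      min(years), max(years),
      paste(unique(records$individual_id[out_of_study]), collapse = ", ")),
      call. = FALSE)
  }
  keep <- !is.na(season)
  records <- records[keep, , drop = FALSE]
  season <- season[keep]
  ids <- sort(unique(records$individual_id))
  T <- length(years)
  codes <- matrix(0L, length(ids), T)
  colony <- character(length(ids))
  for (i in seq_along(ids)) {
    sel <- records$individual_id == ids[i]
    cols <- unique(records$colony[sel])
    .assert(length(cols) == 1L,
      "individual %s has records at multiple colonies; run apply_exclusion_filters first",
      ids[i])
    colony[i] <- cols
    prior <- FALSE
    for (t in seq_len(T)) {
      rs <- records[sel & season == years[t], , drop = FALSE]
      code <- classify_annual_state(rs, prior_breeder = prior,
        season_window = .season_window(years[t]),
        min_detections = min_detections, min_span = min_span,
        max_span = max_span)
      if (code == 1L) prior <- TRUE
      codes[i, t] <- code
    }
  }
  histories <- new_histories(ids, colony, codes, years)
  first_state <- codes[cbind(seq_along(ids), histories$first_occasion)]
  marked_tally <- as.data.frame(table(
    year = factor(years[histories$first_occasion], levels = years),
    colony = factor(colony),
    state = factor(.state_labels[first_state], levels = .state_labels)),
    responseName = "n_marked")
  list(histories = histories, marked_tally = marked_tally)
}
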