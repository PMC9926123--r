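#' @keywords internal
event_columns <- c("group", "day", "phase", "time", "actor", "receiver",
                   "behavior", "duration", "zone")

#' Validate a table of scan-sampled behavior events
#'
#' Checks the event table against the ethogram and its structural
#' invariants: known behavior labels, non-negative durations, actor distinct
#' from receiver, receivers present for dyadic behavior categories
#' (affiliative except the solitary behaviors, aggressive, sexual), and
#' phases restricted to dark/light. Only the first 4 h of each phase are
#' scored, so event times must lie in [0, 14400) seconds from phase start.
#'
#' @param events data.frame with columns `group`, `day`, `phase`, `time`,
#'   `actor`, `receiver` (NA for solitary behaviors), `behavior`,
#'   `duration`, `zone`.
#' @return the validated data.frame (invisibly the same object), with
#'   `category` and `grouped` columns appended.
#' @export
validate_events <- function(events) {
  missing_cols <- setdiff(event_columns, names(events))
  if (length(missing_cols))
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "))
  e <- vbs_ethogram()
  idx <- match(events$behavior, e$behavior)
  if (anyNA(idx)) {
    rows <- which(is.na(idx))
    stop("unknown behavior label(s) at row(s) ",
         paste(utils::head(rows, 10), collapse = ", "), ": ",
         paste(unique(events$behavior[rows]), collapse = ", "))
  }
  bad_phase <- which(!events$phase %in% c("dark", "light"))
  if (length(bad_phase))
    stop("invalid phase at row(s) ", paste(utils::head(bad_phase, 10), collapse = ", "))
  bad_dur <- which(events$duration < 0)
  if (length(bad_dur))
    stop("negative duration at row(s) ", paste(utils::head(bad_dur, 10), collapse = ", "))
  self <- which(!is.na(events$receiver) & events$receiver == events$actor)
  if (length(self))
    stop("actor equals receiver at row(s) ", paste(utils::head(self, 10), collapse = ", "))
  events$category <- e$category[idx]
  events$grouped  <- e$grouped[idx]
  need_recv <- which(e$dyadic[idx] & is.na(events$receiver))
  if (length(need_recv))
    stop("missing receiver for dyadic behavior at row(s) ",
         paste(utils::head(need_recv, 10), collapse = ", "))
  bad_time <- which(events$time < 0 | events$time >= 14400)
  if (length(bad_time))
    stop("event time outside the scored 4 h window at row(s) ",
         paste(utils::head(bad_time, 10), collapse = ", "))
  events
}

#' Read scan-sampled behavior events from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `group,day,phase,time,actor,receiver,behavior,duration,zone`; `receiver`
#' may be empty for solitary behaviors. Rows are validated against the
#' ethogram ([vbs_ethogram()]); unknown labels and invariant violations are
#' rejected with the offending row numbers.
#'
#' @param path path to the CSV file.
#' @return validated event data.frame (see [validate_events()]).
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(actor = "character",
                                          receiver = "character",
                                          group = "character"))
  if (nrow(ev) == 0) {
    ev <- ev[, event_columns, drop = FALSE]
    ev$category <- character(0)
    ev$grouped <- character(0)
    return(ev)
  }
  ev$receiver[!is.na(ev$receiver) & ev$receiver == ""] <- NA
  validate_events(ev)
}

#' Write behavior events to CSV
#'
#' @param events validated event data.frame.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, event_columns], path, row.names = FALSE, na = "")
}

#' Per-animal behavior occurrence counts
#'
#' Tallies occurrences (not durations; durations are scored but Results are
#' reported as numbers of occurrences) per animal and behavior grouping over
#' a day window, pooling the scored dark and light phases.
#'
#' @param events validated event data.frame.
#' @param grouping `"grouped"` (ethogram grouped labels) or `"category"`
#'   (five top-level categories).
#' @param days integer vector of days to include (default 1:4, the analyzed
#'   window).
#' @param animals optional character vector fixing the animal set (animals
#'   with no events get zero rows).
#' @param most_expressed if TRUE, keep only groupings whose cohort median
#'   count is strictly greater than 5.
#' @return data.frame, one row per animal, one column per behavior grouping.
#' @export
count_behaviors <- function(events, grouping = c("grouped", "category"),
                            days = 1:4, animals = NULL,
                            most_expressed = FALSE) {
  grouping <- match.arg(grouping)
  if (!"grouped" %in% names(events)) events <- validate_events(events)
  ev <- events[events$day %in% days, , drop = FALSE]
  if (is.null(animals)) animals <- sort(unique(events$actor))
  groups <- sort(unique(vbs_ethogram()[[grouping]]))
  counts <- matrix(0L, nrow = length(animals), ncol = length(groups),
                   dimnames = list(animals, groups))
  if (nrow(ev)) {
    tab <- table(factor(ev$actor, levels = animals),
                 factor(ev[[grouping]], levels = groups))
    counts <- counts + unclass(tab)
  }
  out <- as.data.frame.matrix(counts)
  if (most_expressed) {
    keep <- vapply(out, function(x) stats::median(x) > 5, logical(1))
    out <- out[, keep, drop = FALSE]
  }
  out
}

#' Build a directed weighted dyadic interaction matrix
#'
#' Counts of events initiated by each animal toward each other animal for
#' one behavior category over a day/phase window; the raw material of the
#' social-network analysis.
#'
#' @param events validated event data.frame (one housing group).
#' @param category a grouped label (e.g. `"general_aggression"`,
#'   `"huddling"`) or top-level category (e.g. `"aggressive"`); must be a
#'   dyadic category.
#' @param animals ordered animal ids defining rows/columns; defaults to all
#'   actors/receivers seen.
#' @param days,phases window restriction (defaults: days 1:4, both scored
#'   phases).
#' @return square integer matrix with zero diagonal,
#'   `counts[i, j]` = events `i` initiated toward `j`; attributes
#'   `category` and `days`.
#' @export
build_dyad_matrix <- function(events, category, animals = NULL,
                              days = 1:4, phases = c("dark", "light")) {
  if (!"grouped" %in% names(events)) events <- validate_events(events)
  e <- vbs_ethogram()
  if (category %in% e$grouped) {
    sel <- events$grouped == category
    dyadic <- any(e$dyadic[e$grouped == category])
  } else if (category %in% e$category) {
    sel <- events$category == category
    dyadic <- any(e$dyadic[e$category == category])
  } else stop("unknown behavior category: ", category)
  if (!dyadic)
    stop("category '", category, "' is solitary; no dyadic matrix can be built")
  ev <- events[sel & events$day %in% days & events$phase %in% phases, ,
               drop = FALSE]
  ev <- ev[!is.na(ev$receiver), , drop = FALSE]
  if (is.null(animals))
    animals <- sort(unique(c(events$actor, stats::na.omit(events$receiver))))
  m <- table(factor(ev$actor, levels = animals),
             factor(ev$receiver, levels = animals))
  m <- matrix(as.integer(m), nrow = length(animals),
              dimnames = list(animals, animals))
  diag(m) <- 0L
  structure(m, category = category, days = days)
}
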