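#' Rat gambling task decision profile
#'
#' Scores a 60-min gambling session: percentage of advantageous choices per
#' wall-clock 10-min bin, the last-20-min percentage used for
#' classification, the decision-maker class (good decision-makers GDM
#' strictly above 70% of advantageous choices in the last 20 min, poor
#' decision-makers PDM strictly below 30%, intermediates INT otherwise),
#' and the mean latency to visit the feeder after a choice.
#'
#' @param trials data.frame with columns `time` (s from session start),
#'   `advantageous` (logical) and `latency` (s, choice-to-magazine).
#' @param session_min session length in minutes (default 60).
#' @return list of class `rgt_profile`: `bin_pct` (per-10-min %),
#'   `last20_pct`, `dm_class`, `mean_latency`, `n_trials`.
#' @export
rgt_profile <- function(trials, session_min = 60) {
  if (nrow(trials) == 0) stop("insufficient data: empty session log")
  if (any(trials$latency < 0)) stop("latencies must be >= 0")
  bins <- seq(0, session_min * 60, by = 600)
  bin_idx <- cut(trials$time, bins, right = FALSE, labels = FALSE)
  bin_pct <- vapply(seq_len(length(bins) - 1), function(b) {
    sel <- which(bin_idx == b)
    if (!length(sel)) return(NA_real_)
    100 * mean(trials$advantageous[sel])
  }, numeric(1))
  last20 <- trials$time >= (session_min - 20) * 60 &
    trials$time < session_min * 60
  if (!any(last20)) stop("insufficient data: no trials in the last 20 min")
  last20_pct <- 100 * mean(trials$advantageous[last20])
  cls <- if (last20_pct > 70) "GDM" else if (last20_pct < 30) "PDM" else "INT"
  structure(list(bin_pct = bin_pct, last20_pct = last20_pct, dm_class = cls,
                 mean_latency = mean(trials$latency),
                 n_trials = nrow(trials)),
            class = "rgt_profile")
}

#' @export
print.rgt_profile <- function(x, ...) {
  cat(sprintf("RGT profile: %s (last 20 min %.1f%% advantageous, %d trials, mean latency %.2f s)\n",
              x$dm_class, x$last20_pct, x$n_trials, x$mean_latency))
  invisible(x)
}

#' Cognitive flexibility score from the reversed gambling task
#'
#' After the advantageous/disadvantageous sides are switched, the
#' flexibility score is the percentage of last-20-min choices made at the
#' side that held the non-preferred options during the original session.
#' Flexible animals score strictly above 60%, inflexible strictly below
#' 40%, undecided otherwise.
#'
#' @param rgt_trials original-session trials with columns `time`, `side`.
#' @param reversed_trials reversed-session trials with the same columns.
#' @param session_min session length in minutes (default 60).
#' @return list: `score` (%), `class`
#'   (`"flexible"`/`"undecided"`/`"inflexible"`), `rgt_preferred_side`.
#' @export
flexibility_score <- function(rgt_trials, reversed_trials, session_min = 60) {
  if (nrow(rgt_trials) == 0 || nrow(reversed_trials) == 0)
    stop("insufficient data: empty session log")
  sides <- table(rgt_trials$side)
  preferred <- names(sides)[which.max(sides)]
  last20 <- reversed_trials$time >= (session_min - 20) * 60 &
    reversed_trials$time < session_min * 60
  if (!any(last20)) stop("insufficient data: no trials in the last 20 min")
  score <- 100 * mean(reversed_trials$side[last20] != preferred)
  cls <- if (score > 60) "flexible" else if (score < 40) "inflexible"
         else "undecided"
  list(score = score, class = cls, rgt_preferred_side = preferred)
}

#' Odds transform for probability discounting
#'
#' @param p probability of reward delivery.
#' @return odds against delivery, `1/p - 1`.
#' @export
#' @examples
#' odds_transform(c(1, 0.2, 0.09))  # 0, 4, 10.11
odds_transform <- function(p) {
  if (any(p <= 0 | p > 1)) stop("probabilities must be in (0, 1]")
  1 / p - 1
}

#' Area under the discounting curve
#'
#' Preference for the large reward at each level is normalized to the
#' training preference; the x-axis is delay as a proportion of the maximum
#' delay, or odds (1/P - 1) as a proportion of the maximum odds. The AUC is
#' the trapezoidal area over sorted x, anchored at x = 0 at the training
#' level (y = 1) when the data include no x = 0 level. A flat curve at the
#' training level gives AUC = 1; steeper discounting gives smaller AUC.
#'
#' @param levels delays (s) or reward probabilities.
#' @param preference percentage (or proportion) of large-reward choices at
#'   each level, from the two stable sessions.
#' @param training_preference percentage (same scale) during training; must
#'   be > 0.
#' @param kind `"delay"` or `"probability"`.
#' @return AUC (>= 0; 1 for no discounting).
#' @export
discounting_auc <- function(levels, preference, training_preference,
                            kind = c("delay", "probability")) {
  kind <- match.arg(kind)
  if (anyNA(levels) || anyNA(preference))
    stop("missing levels or preferences: ",
         paste(levels[is.na(levels) | is.na(preference)], collapse = ", "))
  if (length(levels) != length(preference))
    stop("levels and preference lengths differ")
  if (training_preference <= 0) stop("training preference must be > 0")
  x <- if (kind == "delay") levels else odds_transform(levels)
  if (max(x) <= 0) stop("need at least one nonzero level")
  x <- x / max(x)
  y <- preference / training_preference
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (x[1] > 0) { x <- c(0, x); y <- c(1, y) }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Fixed-interval / extinction response profile
#'
#' Scores a session of two blocks of seven fixed intervals (FI) each
#' followed by a 5-min extinction (EXT) period. As per standard practice
#' the first FI of the session and the first FI after the first EXT are
#' excluded, leaving 12 analyzed FIs. Anticipatory activity is the nose
#' pokes summed over 10-s bins within FI; perseverative activity the pokes
#' summed over 1-min bins within EXT.
#'
#' @param pokes data.frame with columns `period_type` (`"FI"`/`"EXT"`),
#'   `period_number` (FI 1-14, EXT 1-2) and `time` (s within the period);
#'   periods with zero pokes need no rows.
#' @param fi_duration FI length in seconds (default 60, the test FI).
#' @param ext_duration EXT length in seconds (default 300).
#' @return list: `fi_totals` (length 14), `analyzed_fi` (indices),
#'   `fi_mean`, `fi_bins` (10-s bin sums over analyzed FIs), `ext_totals`
#'   (length 2), `ext_mean`, `ext_bins` (five 1-min bin sums).
#' @export
fiext_profile <- function(pokes, fi_duration = 60, ext_duration = 300) {
  fi <- pokes[pokes$period_type == "FI", , drop = FALSE]
  ext <- pokes[pokes$period_type == "EXT", , drop = FALSE]
  fi_totals <- vapply(1:14, function(i) sum(fi$period_number == i), numeric(1))
  analyzed <- setdiff(1:14, c(1, 8))
  fa <- fi[fi$period_number %in% analyzed, , drop = FALSE]
  fi_breaks <- seq(0, fi_duration, by = 10)
  fi_bins <- if (nrow(fa)) {
    table(cut(fa$time, fi_breaks, right = FALSE))
  } else table(cut(numeric(0), fi_breaks, right = FALSE))
  ext_totals <- vapply(1:2, function(i) sum(ext$period_number == i), numeric(1))
  ext_breaks <- seq(0, ext_duration, by = 60)
  ext_bins <- if (nrow(ext)) {
    table(cut(ext$time, ext_breaks, right = FALSE))
  } else table(cut(numeric(0), ext_breaks, right = FALSE))
  list(fi_totals = fi_totals, analyzed_fi = analyzed,
       fi_mean = mean(fi_totals[analyzed]),
       fi_bins = as.numeric(fi_bins),
       ext_totals = ext_totals, ext_mean = mean(ext_totals),
       ext_bins = as.numeric(ext_bins))
}

#' Social recognition task ratios
#'
#' Social preference = interaction time in the first encounter over the
#' habituation (empty cage) time; short-term recognition = first over third
#' encounter; long-term recognition = fourth encounter over the encounter
#' with a new conspecific.
#'
#' @param durations named numeric vector or list with elements `Hab`,
#'   `E1`, `E3`, `E4`, `Enew` (seconds, >= 0).
#' @return list: `social_preference` (E1/Hab), `short_term` (E1/E3),
#'   `long_term` (E4/Enew); a zero denominator yields NA.
#' @export
srt_scores <- function(durations) {
  d <- as.list(durations)
  need <- c("Hab", "E1", "E3", "E4", "Enew")
  if (!all(need %in% names(d)))
    stop("missing durations: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (any(unlist(d[need]) < 0)) stop("durations must be >= 0")
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  list(social_preference = ratio(d$E1, d$Hab),
       short_term = ratio(d$E1, d$E3),
       long_term = ratio(d$E4, d$Enew))
}

#' Dark-light box composite score
#'
#' Sum of the duration of the first visit to the dark compartment, the
#' number of risk assessments into the light compartment, and the total
#' time spent in the dark compartment (units as printed: seconds plus
#' counts, no rescaling).
#'
#' @param log data.frame with columns `time` (s) and `event`
#'   (`"enter_dark"`, `"exit_dark"`, `"risk_assessment"`).
#' @param session session length in seconds (default 600); an unclosed
#'   dark visit runs to session end.
#' @return composite score (numeric scalar).
#' @export
dlbox_composite <- function(log, session = 600) {
  if (nrow(log) && (any(log$time < 0) | any(log$time > session)))
    stop("event times must lie within the session")
  ent <- log$time[log$event == "enter_dark"]
  ext <- log$time[log$event == "exit_dark"]
  if (length(ext) > length(ent) || (length(ent) && length(ext) &&
      any(ext[seq_along(ext)] < ent[seq_along(ext)])))
    stop("dark-compartment exits must pair with prior entries")
  if (length(ext) < length(ent)) ext <- c(ext, session)
  dark_time <- sum(ext - ent)
  first_visit <- if (length(ent)) ext[1] - ent[1] else 0
  n_risk <- sum(log$event == "risk_assessment")
  first_visit + n_risk + dark_time
}

#' Risk-taking index for the dark-light box
#'
#' The composite scores of the analyzed cohort are subtracted from the
#' cohort maximum so that higher values mean more risk taking; the animal
#' with the maximal composite scores 0.
#'
#' @param composites per-animal composite scores ([dlbox_composite()]).
#' @param reference reference maximum; defaults to `max(composites)`.
#' @return named vector of indices (>= 0).
#' @export
dlbox_risk_index <- function(composites, reference = max(composites)) {
  reference - composites
}

#' Body-weight and corticosterone changes across VBS housing
#'
#' Weight change is reported both in grams lost (before - after, loss
#' positive) and as percent variation 100 (after - before) / before; the
#' corticosterone metabolite variation uses the same percent convention.
#'
#' @param before,after paired positive measurements.
#' @return data.frame with columns `delta` (before - after) and `pct`
#'   (percent variation).
#' @export
#' @examples
#' physiology_changes(250, 240)  # loss 10 g, -4 %
physiology_changes <- function(before, after) {
  if (any(before <= 0) || any(after <= 0))
    stop("paired measurements must be > 0")
  if (length(before) != length(after)) stop("unpaired measurements")
  data.frame(delta = before - after, pct = 100 * (after - before) / before)
}
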