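#' Win/loss outcomes from aggressive and sexual interactions
#'
#' All aggressive and sexual dyadic events of the dark phases of the
#' analyzed days, in time order; the initiator is the winner and the
#' receiver the loser.
#'
#' @param events validated event table (one housing group).
#' @param days analyzed days (default 1:4).
#' @param phases phases considered (default `"dark"`).
#' @return data.frame `winner`, `loser` ordered by (day, time).
#' @export
interaction_outcomes <- function(events, days = 1:4, phases = "dark") {
  if (!"category" %in% names(events)) events <- validate_events(events)
  ev <- events[events$category %in% c("aggressive", "sexual") &
                 events$day %in% days & events$phase %in% phases &
                 !is.na(events$receiver), , drop = FALSE]
  ev <- ev[order(ev$day, ev$time), ]
  data.frame(winner = ev$actor, loser = ev$receiver)
}

#' Hierarchy metrics for every housed group of a study
#'
#' Runs the Glicko rating, change-point detection and dominance rule on
#' each group's aggressive + sexual dark-phase interaction sequence.
#'
#' @param study a [simulate_colony()] study (or any list with `animals`
#'   and validated `events`).
#' @param ... passed to [hierarchy_metrics()].
#' @return named list of `hierarchy_metrics`, one per group.
#' @export
group_hierarchies <- function(study, ...) {
  groups <- unique(study$animals$group)
  out <- lapply(groups, function(g) {
    ga <- study$animals$animal[study$animals$group == g]
    oc <- interaction_outcomes(study$events[study$events$group == g, ])
    hierarchy_metrics(glicko_trajectory(oc, animals = ga), ...)
  })
  stats::setNames(out, groups)
}

#' Compute the per-animal feature table of a synthetic study
#'
#' Runs the full scoring pipeline: behavior category counts, weight and
#' corticosterone percent variations, total distance, total roaming
#' entropy, open-area preference, delay-discounting AUC, hub centrality in
#' each group's aggression network, flexibility score, gambling-task
#' preference and latency, and the Blanchard dominance score — then
#' assembles and validates the canonical 16-column feature table.
#'
#' @param study a [simulate_colony()] study.
#' @return a [build_feature_table()] table (rows = animals).
#' @export
study_features <- function(study) {
  an <- study$animals
  ids <- an$animal
  grid <- study$config$grid
  sliced <- slice_detections(study$detections)

  cats <- count_behaviors(study$events, "category", animals = ids)
  phys_w <- physiology_changes(study$physiology$weight_before,
                               study$physiology$weight_after)
  phys_c <- physiology_changes(study$physiology$cort_before,
                               study$physiology$cort_after)
  rownames(phys_w) <- rownames(phys_c) <- study$physiology$animal
  dist <- distance_index(study$detections, grid)$total
  occ <- occupancy_profile(sliced, grid$k, phases = "dark")
  entropy <- apply(occ, 1, roaming_entropy, k = grid$k)
  pref_open <- open_area_preference(sliced, grid)

  auc <- vapply(ids, function(a) {
    d <- study$ddt[study$ddt$animal == a, ]
    train <- 100 * sum(d$n_large[is.na(d$level)]) /
      sum(d$n_trials[is.na(d$level)])
    lv <- sort(unique(d$level[!is.na(d$level)]))
    pref <- vapply(lv, function(x) {
      s <- d[!is.na(d$level) & d$level == x, ]
      100 * sum(s$n_large) / sum(s$n_trials)
    }, numeric(1))
    discounting_auc(lv, pref, train, kind = "delay")
  }, numeric(1))

  hub <- unlist(lapply(unique(an$group), function(g) {
    ga <- an$animal[an$group == g]
    m <- build_dyad_matrix(study$events[study$events$group == g, ],
                           "general_aggression", animals = ga)
    stats::setNames(node_metrics(m)$hub_centrality, ga)
  }))

  rgt_stats <- t(vapply(ids, function(a) {
    pr <- rgt_profile(study$rgt[study$rgt$animal == a, ])
    fx <- flexibility_score(study$rgt[study$rgt$animal == a, ],
                            study$reversed_rgt[study$reversed_rgt$animal == a, ])
    c(rgt = pr$last20_pct, latency = pr$mean_latency, flex = fx$score)
  }, numeric(3)))

  blanchard <- unlist(lapply(unique(an$group), function(g) {
    ga <- an$animal[an$group == g]
    loss <- study$physiology$weight_before - study$physiology$weight_after
    names(loss) <- study$physiology$animal
    blanchard_score(pref_open[ga], loss[ga])
  }))

  build_feature_table(data.frame(
    row.names = ids,
    Sexual = cats[ids, "sexual"],
    Weight = phys_w[ids, "pct"],
    Corticosterone = phys_c[ids, "pct"],
    Distance = dist[ids],
    Entropy = entropy[ids],
    Defensive = cats[ids, "defensive"],
    Maintenance = cats[ids, "maintenance"],
    Aggressive = cats[ids, "aggressive"],
    Pref.open.area = pref_open[ids],
    Affiliative = cats[ids, "affiliative"],
    AUC.DDT = auc[ids],
    HUB.agg = hub[ids],
    Flexibility = rgt_stats[ids, "flex"],
    RGT = rgt_stats[ids, "rgt"],
    Latency.RGT = rgt_stats[ids, "latency"],
    Blanchard = blanchard[ids],
    genotype = an$genotype
  ))
}

#' Run the full phenotyping study
#'
#' Simulates a colony (unless a study is supplied), computes the feature
#' table and runs the unsupervised discrimination stage.
#'
#' @param config a [sim_config()] (ignored when `study` is given).
#' @param study optionally an existing [simulate_colony()] study.
#' @param n_runs random-forest runs (default 100).
#' @param ntree trees per forest.
#' @return list of class `vbs_study_result`: `study`, `features`, `rf`
#'   ([rf_discriminate()]), `pca` ([pca_profile()]), `hierarchy`
#'   ([group_hierarchies()]).
#' @export
run_study <- function(config = sim_config(), study = NULL, n_runs = 100,
                      ntree = 500) {
  if (is.null(study)) study <- simulate_colony(config)
  features <- study_features(study)
  rf <- rf_discriminate(features, n_runs = n_runs, ntree = ntree,
                        seed = study$config$seed)
  pca <- pca_profile(features)
  hier <- group_hierarchies(study)
  structure(list(study = study, features = features, rf = rf, pca = pca,
                 hierarchy = hier),
            class = "vbs_study_result")
}

#' @export
print.vbs_study_result <- function(x, ...) {
  print(x$study)
  print(x$rf)
  print(x$pca)
  invisible(x)
}
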