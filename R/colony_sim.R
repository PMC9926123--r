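#' Derive a child seed from the master seed
#'
#' Components of the simulation draw their seeds from the master seed by a
#' fixed counter scheme (multiplicative congruential step modulo 2^31 - 1),
#' so that streams are reproducible and independent across components.
#'
#' @param seed master seed (integer).
#' @param offset component counter.
#' @return integer seed.
#' @export
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(offset)) %% 2147483647)
}

#' Per-genotype generating parameters
#'
#' Rates and effect parameters for one genotype of the synthetic colony.
#' The defaults describe the control phenotype; [sim_config()] supplies a
#' second parameter set with the serotonin-depleted home-cage phenotype
#' (more aggression, sexual and defensive behavior, less affiliation and
#' maintenance, burrow-biased restricted roaming, larger weight loss and
#' corticosterone rise) while all operant/cognitive parameters stay at the
#' control values (null cognitive effects).
#'
#' @param event_rates named vector of dyadic/solitary event rates
#'   (events per animal per scored 4-h phase) over the grouped ethogram
#'   categories.
#' @param despotism initiation-propensity weight of the group's top animal
#'   for aggressive and sexual interactions (other animals weigh 1).
#' @param zone_weights named preference weights over zone labels
#'   (`open_area`, `feeder`, `water`, `tunnel`, `burrow`).
#' @param move_prob per-second probability of leaving the current zone.
#' @param weight_before_mean,weight_before_sd pre-housing body weight (g).
#' @param weight_loss_mean,weight_loss_sd weight loss across housing (g).
#' @param cort_before_mean,cort_before_sd baseline fecal corticosterone
#'   metabolites (ug/g).
#' @param cort_multiplier,cort_multiplier_sd post/pre multiplier.
#' @param dm_mix decision-maker mixture proportions (GDM, INT, PDM); must
#'   sum to 1.
#' @param k_meanlog,k_sdlog log-normal parameters of the hyperbolic
#'   discounting steepness k (1/s).
#' @param choice_temp logistic choice temperature (> 0).
#' @param flex_mix mixture of flexible/undecided/inflexible types.
#' @param srt_means mean interaction durations (s) for Hab, E1-E4, Enew.
#' @return list of class `genotype_params`.
#' @export
genotype_params <- function(
    event_rates = c(huddling = 15, sniffing = 10, attending = 4,
                    allogrooming = 3, struggling_at_feeder = 6,
                    general_aggression = 3, sexual = 1, defensive = 2,
                    eating = 10, drinking = 5, grooming = 8),
    despotism = 4,
    zone_weights = c(open_area = 1, feeder = 1.8, water = 1.3,
                     tunnel = 0.7, burrow = 1),
    move_prob = 0.15,
    weight_before_mean = 270, weight_before_sd = 15,
    weight_loss_mean = 5, weight_loss_sd = 3,
    cort_before_mean = 2, cort_before_sd = 0.4,
    cort_multiplier = 1.1, cort_multiplier_sd = 0.25,
    dm_mix = c(GDM = 0.74, INT = 0.09, PDM = 0.17),
    k_meanlog = log(0.2), k_sdlog = 0.4,
    choice_temp = 0.8,
    flex_mix = c(flexible = 0.4, undecided = 0.2, inflexible = 0.4),
    srt_means = c(Hab = 20, E1 = 60, E2 = 40, E3 = 25, E4 = 30, Enew = 55)) {
  if (any(event_rates < 0)) stop("event rates must be >= 0")
  if (abs(sum(dm_mix) - 1) > 1e-8)
    stop("decision-maker mixture proportions must sum to 1")
  if (abs(sum(flex_mix) - 1) > 1e-8)
    stop("flexibility mixture proportions must sum to 1")
  if (any(zone_weights <= 0)) stop("zone weights must be > 0")
  if (move_prob <= 0 || move_prob > 1) stop("move_prob must be in (0, 1]")
  if (choice_temp <= 0) stop("choice temperature must be > 0")
  if (despotism < 1) stop("despotism weight must be >= 1")
  if (any(srt_means < 0)) stop("negative duration requested")
  structure(as.list(environment()), class = "genotype_params")
}

#' Depleted-genotype defaults
#'
#' The home-cage phenotype of the serotonin-depleted genotype: compulsive
#' aggression and sexual behavior, hypervigilant defensive profile, reduced
#' affiliation and self-maintenance, restricted burrow-biased territory
#' with higher locomotion, larger weight loss and a strong corticosterone
#' rise. Operant/cognitive parameters equal the control defaults, so the
#' cognitive variables carry no genotype signal.
#'
#' @param ... overrides passed to [genotype_params()].
#' @return list of class `genotype_params`.
#' @export
genotype_params_depleted <- function(...) {
  defaults <- list(
    event_rates = c(huddling = 7, sniffing = 15, attending = 4,
                    allogrooming = 1.5, struggling_at_feeder = 2,
                    general_aggression = 12, sexual = 6, defensive = 8,
                    eating = 5, drinking = 3, grooming = 4),
    zone_weights = c(open_area = 0.15, feeder = 0.3, water = 0.3,
                     tunnel = 3, burrow = 4),
    move_prob = 0.3,
    despotism = 8,
    weight_loss_mean = 15, weight_loss_sd = 4,
    cort_multiplier = 3, cort_multiplier_sd = 0.6)
  args <- utils::modifyList(defaults, list(...))
  do.call(genotype_params, args)
}

#' Configuration of a synthetic colony study
#'
#' Defines the study layout (groups of 6 animals per genotype housed 4
#' days in the instrumented burrow system) and the per-genotype generating
#' parameters. The defaults mirror the reference study design: 8 control
#' and 5 depleted groups of 6 (48 + 30 animals), 4 analyzed days, a 32-
#' detector grid, large genotype effects on home-cage/physiology variables
#' and null effects on cognitive variables.
#'
#' @param n_groups named integer vector: groups per genotype.
#' @param group_size animals per group (>= 2, default 6).
#' @param n_days housed days (default 4).
#' @param phase_seconds movement-sampling span per scored phase (s at 1 Hz,
#'   default 3600).
#' @param grid a [zone_grid()].
#' @param genotypes named list of [genotype_params()], same names as
#'   `n_groups`.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_groups = c(wildtype = 8, knockout = 5),
                       group_size = 6, n_days = 4, phase_seconds = 3600,
                       grid = zone_grid(),
                       genotypes = list(wildtype = genotype_params(),
                                        knockout = genotype_params_depleted()),
                       seed = 1) {
  if (group_size < 2) stop("group_size must be >= 2")
  if (is.null(names(n_groups)) || !setequal(names(n_groups), names(genotypes)))
    stop("n_groups and genotypes must share the same genotype names")
  if (!inherits(grid, "zone_grid")) stop("grid must be a zone_grid")
  if (any(rowSums(grid$adjacency) == 0))
    stop("invalid grid spec: zones without adjacency")
  for (g in genotypes) stopifnot(inherits(g, "genotype_params"))
  structure(list(n_groups = n_groups, group_size = group_size,
                 n_days = n_days, phase_seconds = phase_seconds,
                 grid = grid, genotypes = genotypes, seed = seed),
            class = "sim_config")
}

#' @keywords internal
animal_frame <- function(config) {
  out <- do.call(rbind, lapply(names(config$n_groups), function(g) {
    do.call(rbind, lapply(seq_len(config$n_groups[[g]]), function(i) {
      grp <- paste0(g, i)
      data.frame(animal = paste0(grp, "_", seq_len(config$group_size)),
                 genotype = g, group = grp)
    }))
  }))
  out$despot <- !duplicated(out$group)  # first animal of each group
  out
}

# One animal's movement as a zone jump chain: dwell ~ 1 + geometric
# (per-second leave probability), next zone drawn among grid neighbors
# proportionally to the genotype zone-preference weights.
#' @keywords internal
sim_stream_animal <- function(animal, gp, grid, n_days, phase_seconds) {
  wz <- gp$zone_weights[grid$zones$label]
  nbrs <- apply(grid$adjacency, 1, function(a) which(a > 0))
  rows <- vector("list", n_days * 2)
  z <- sample.int(grid$k, 1, prob = wz)
  ri <- 0
  for (day in seq_len(n_days)) for (phase in c("dark", "light")) {
    tt <- 0
    zs <- integer(0); ts <- numeric(0); ds <- numeric(0)
    while (tt < phase_seconds) {
      dwell <- 1 + stats::rgeom(1, gp$move_prob)
      dur <- min(dwell, phase_seconds - tt)
      zs <- c(zs, z); ts <- c(ts, tt); ds <- c(ds, dur)
      tt <- tt + dur
      nb <- nbrs[[z]]
      z <- if (length(nb) == 1) nb else sample(nb, 1, prob = wz[nb])
    }
    ri <- ri + 1
    rows[[ri]] <- data.frame(animal = animal, day = day, phase = phase,
                             time = ts, detector = zs, duration = ds)
  }
  do.call(rbind, rows)
}

#' @keywords internal
sim_events_group <- function(animals, gp, grid, n_days) {
  e <- vbs_ethogram()
  weights_despotic <- c(gp$despotism, rep(1, length(animals) - 1))
  zone_w <- gp$zone_weights[grid$zones$label]
  feeder <- grid$zones$detector[grid$zones$label == "feeder"][1]
  water <- grid$zones$detector[grid$zones$label == "water"][1]
  out <- list()
  for (day in seq_len(n_days)) for (phase in c("dark", "light")) {
    for (cat in names(gp$event_rates)) {
      n <- stats::rpois(1, length(animals) * gp$event_rates[[cat]])
      if (n == 0) next
      despotic <- cat %in% c("general_aggression", "struggling_at_feeder",
                             "sexual")
      actor <- sample(animals, n, replace = TRUE,
                      prob = if (despotic) weights_despotic else NULL)
      top_cat <- e$category[match(cat, e$grouped)]
      dyadic <- e$dyadic[match(cat, e$grouped)]
      receiver <- if (dyadic) {
        vapply(actor, function(a) sample(setdiff(animals, a), 1),
               character(1))
      } else rep(NA_character_, n)
      beh_pool <- e$behavior[e$grouped == cat]
      zone <- switch(cat,
        struggling_at_feeder = , eating = rep(feeder, n),
        drinking = rep(water, n),
        sample.int(grid$k, n, replace = TRUE, prob = zone_w))
      out[[length(out) + 1]] <- data.frame(
        group = sub("_.*", "", animals[1]), day = day, phase = phase,
        time = round(stats::runif(n, 0, 14400 - 1), 1),
        actor = actor, receiver = receiver,
        behavior = sample(beh_pool, n, replace = TRUE),
        duration = round(stats::rgamma(n, shape = 2, scale = 3), 1),
        zone = zone)
    }
  }
  ev <- do.call(rbind, out)
  ev[order(ev$day, ev$phase, ev$time), ]
}

#' Simulate gambling-task sessions for a cohort
#'
#' Per-animal latent decision-maker type drawn from the configured mixture;
#' advantageous-choice probability ramps from chance toward the latent
#' asymptote with a 15-min time constant, so the last-20-min preference
#' concentrates around the type. Disadvantageous choices draw the long
#' penalties (222 s / 444 s with probabilities 1/2 and 1/4), advantageous
#' choices the short ones (6 s / 12 s), which shapes trial throughput.
#' Poor decision-makers collect rewards faster (shorter latencies).
#' A reversed session is generated per animal from a latent flexibility
#' type (preference for the formerly non-preferred side of 0.75 / 0.5 /
#' 0.25 plus noise).
#'
#' @param config a [sim_config()].
#' @param session_min session length (minutes; 0 gives empty logs).
#' @return list: `trials` (columns `animal`, `time`, `side`,
#'   `advantageous`, `latency`), `reversed` (columns `animal`, `time`,
#'   `side`), `truth` (per-animal latent type, asymptote, sides,
#'   flexibility type).
#' @export
simulate_rgt_cohort <- function(config, session_min = 60) {
  set.seed(child_seed(config$seed, 201))
  animals <- animal_frame(config)
  trials <- list(); reversed <- list(); truth <- list()
  lat_mean <- c(GDM = 2.4, INT = 1.8, PDM = 1.2)
  for (i in seq_len(nrow(animals))) {
    gp <- config$genotypes[[animals$genotype[i]]]
    cls <- sample(names(gp$dm_mix), 1, prob = gp$dm_mix)
    asym <- switch(cls, GDM = stats::runif(1, 0.85, 0.98),
                   INT = stats::runif(1, 0.35, 0.65),
                   PDM = stats::runif(1, 0.02, 0.15))
    adv_side <- sample(c("left", "right"), 1)
    tt <- 0; tms <- c(); adv <- c(); lat <- c()
    while (tt < session_min * 60) {
      p <- 0.5 + (asym - 0.5) * (1 - exp(-tt / 900))
      a <- stats::runif(1) < p
      l <- stats::rgamma(1, shape = 4, scale = lat_mean[[cls]] / 4)
      u <- stats::runif(1)
      timeout <- if (a) c(6, 12, 0)[findInterval(u, c(0.5, 0.75)) + 1]
                 else c(222, 444, 0)[findInterval(u, c(0.5, 0.75)) + 1]
      tms <- c(tms, tt); adv <- c(adv, a); lat <- c(lat, l)
      tt <- tt + l + 8 + timeout
    }
    if (length(tms))
      trials[[i]] <- data.frame(animal = animals$animal[i], time = tms,
                                side = ifelse(adv, adv_side,
                                              setdiff(c("left", "right"),
                                                      adv_side)),
                                advantageous = adv, latency = lat)
    flex <- sample(names(gp$flex_mix), 1, prob = gp$flex_mix)
    p_flex <- switch(flex, flexible = 0.75, undecided = 0.5,
                     inflexible = 0.25) + stats::rnorm(1, 0, 0.05)
    p_flex <- min(max(p_flex, 0.02), 0.98)
    pref_side <- if (length(tms) && mean(adv) < 0.5)
      setdiff(c("left", "right"), adv_side) else adv_side
    n_rev <- max(1, stats::rpois(1, 100 * session_min / 60))
    if (session_min > 0)
      reversed[[i]] <- data.frame(
        animal = animals$animal[i],
        time = sort(stats::runif(n_rev, 0, session_min * 60)),
        side = ifelse(stats::runif(n_rev) < p_flex,
                      setdiff(c("left", "right"), pref_side), pref_side))
    truth[[i]] <- data.frame(animal = animals$animal[i], dm_class = cls,
                             asymptote = asym, adv_side = adv_side,
                             flex_class = flex)
  }
  empty_trials <- data.frame(animal = character(0), time = numeric(0),
                             side = character(0), advantageous = logical(0),
                             latency = numeric(0))
  list(trials = if (length(trials)) do.call(rbind, trials) else empty_trials,
       reversed = if (length(reversed)) do.call(rbind, reversed) else
         empty_trials[, c("animal", "time", "side")],
       truth = do.call(rbind, truth))
}

#' Simulate delay- and probability-discounting session logs
#'
#' Choices follow a hyperbolic value rule V = A / (1 + k D) for delays and
#' expected value for probabilities, passed through a logistic choice rule
#' with the configured temperature; per-animal steepness k is log-normal.
#' Two stable sessions of 40 trials are emitted per level plus two
#' training sessions (delay 0 / probability 1).
#'
#' @param config a [sim_config()].
#' @param delays delay levels in seconds (default 0-40 s by 10).
#' @param probabilities probability levels (default 0.66, 0.33, 0.20,
#'   0.14, 0.09).
#' @param trials_per_session trials per session (default 40).
#' @return list with data.frames `ddt` and `pdt` (columns `animal`,
#'   `level` (NA = training), `session`, `n_trials`, `n_large`) and
#'   `truth` (per-animal k).
#' @export
simulate_discounting <- function(config, delays = seq(0, 40, by = 10),
                                 probabilities = c(0.66, 0.33, 0.20, 0.14,
                                                   0.09),
                                 trials_per_session = 40) {
  set.seed(child_seed(config$seed, 301))
  animals <- animal_frame(config)
  ddt <- list(); pdt <- list(); truth <- list()
  for (i in seq_len(nrow(animals))) {
    gp <- config$genotypes[[animals$genotype[i]]]
    k <- stats::rlnorm(1, gp$k_meanlog, gp$k_sdlog)
    temp <- gp$choice_temp
    p_choice_delay <- function(D) stats::plogis((5 / (1 + k * D) - 1) / temp)
    p_choice_prob <- function(p) stats::plogis((5 * p - 1) / temp)
    mk <- function(levels, pfun) {
      do.call(rbind, lapply(c(NA, levels), function(lv) {
        p <- if (is.na(lv)) pfun(if (identical(pfun, p_choice_prob)) 1 else 0)
             else pfun(lv)
        data.frame(animal = animals$animal[i], level = lv, session = 1:2,
                   n_trials = trials_per_session,
                   n_large = stats::rbinom(2, trials_per_session, p))
      }))
    }
    ddt[[i]] <- mk(delays, p_choice_delay)
    pdt[[i]] <- mk(probabilities, p_choice_prob)
    truth[[i]] <- data.frame(animal = animals$animal[i], k = k)
  }
  list(ddt = do.call(rbind, ddt), pdt = do.call(rbind, pdt),
       truth = do.call(rbind, truth))
}

#' Simulate classical-test and physiology records
#'
#' Social-recognition interaction durations, odor-discrimination
#' preference, dark-light box visit logs, motor-impulsivity (FIEXT) poke
#' logs, and paired body weights and fecal corticosterone metabolite
#' levels with the configured genotype shifts.
#'
#' @param config a [sim_config()].
#' @return list: `srt` (durations per animal), `odor`, `dlbox` (event
#'   log), `fiext` (poke log), `physiology` (paired weights and
#'   corticosterone).
#' @export
simulate_classical <- function(config) {
  set.seed(child_seed(config$seed, 401))
  animals <- animal_frame(config)
  srt <- list(); dlbox <- list(); fiext <- list(); phys <- list()
  odor <- list()
  for (i in seq_len(nrow(animals))) {
    id <- animals$animal[i]
    gp <- config$genotypes[[animals$genotype[i]]]
    m <- gp$srt_means
    dur <- pmax(1, stats::rnorm(length(m), m, m * 0.2))
    srt[[i]] <- data.frame(animal = id, t(stats::setNames(dur, names(m))))
    odor[[i]] <- data.frame(animal = id,
                            spoiled_pref = stats::rbeta(1, 6, 3))
    # dark-light box: alternated light gaps and dark visits + risk events
    dark_total <- min(580, max(30, stats::rnorm(1, 350, 80)))
    n_visits <- 1 + stats::rpois(1, 1.5)
    dk <- stats::rgamma(n_visits, 2); dk <- dk / sum(dk) * dark_total
    lg <- stats::rgamma(n_visits + 1, 2)
    lg <- lg / sum(lg) * (600 - dark_total)
    tt <- 0; log_rows <- list()
    for (v in seq_len(n_visits)) {
      tt <- tt + lg[v]
      log_rows[[length(log_rows) + 1]] <-
        data.frame(animal = id, time = tt, event = "enter_dark")
      tt <- tt + dk[v]
      log_rows[[length(log_rows) + 1]] <-
        data.frame(animal = id, time = tt, event = "exit_dark")
    }
    n_risk <- stats::rpois(1, 8)
    if (n_risk > 0)
      log_rows[[length(log_rows) + 1]] <-
        data.frame(animal = id,
                   time = stats::runif(n_risk, 0, lg[1]),
                   event = "risk_assessment")
    dlbox[[i]] <- do.call(rbind, log_rows)
    # FIEXT pokes: anticipatory ramp within FI, perseverative decay in EXT
    fi_rows <- do.call(rbind, lapply(1:14, function(fi_n) {
      np <- stats::rpois(1, 5)
      if (np == 0) return(NULL)
      data.frame(animal = id, period_type = "FI", period_number = fi_n,
                 time = sort(60 * stats::rbeta(np, 2, 1)))
    }))
    ext_rows <- do.call(rbind, lapply(1:2, function(ex_n) {
      np <- stats::rpois(1, 15)
      if (np == 0) return(NULL)
      data.frame(animal = id, period_type = "EXT", period_number = ex_n,
                 time = sort(300 * stats::rbeta(np, 1, 2)))
    }))
    fiext[[i]] <- rbind(fi_rows, ext_rows)
    wb <- stats::rnorm(1, gp$weight_before_mean, gp$weight_before_sd)
    loss <- stats::rnorm(1, gp$weight_loss_mean, gp$weight_loss_sd)
    cb <- max(0.3, stats::rnorm(1, gp$cort_before_mean, gp$cort_before_sd))
    mult <- max(0.1, stats::rnorm(1, gp$cort_multiplier,
                                  gp$cort_multiplier_sd))
    phys[[i]] <- data.frame(animal = id, weight_before = wb,
                            weight_after = wb - loss,
                            cort_before = cb, cort_after = cb * mult)
  }
  list(srt = do.call(rbind, srt), odor = do.call(rbind, odor),
       dlbox = do.call(rbind, dlbox), fiext = do.call(rbind, fiext),
       physiology = do.call(rbind, phys))
}

#' Simulate a full synthetic colony study
#'
#' Generates, for every housed group, the RFID detection streams (Markov
#' walk over the detector grid with genotype-specific zone preferences),
#' the scan-sampled dyadic ethogram events (Poisson counts per behavior
#' category and scored 4-h phase, initiators of aggressive and sexual
#' interactions drawn with a despotic propensity), the operant task logs
#' and the classical-test/physiology records.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_study`: `animals`, `detections`,
#'   `events`, `rgt`, `reversed_rgt`, `ddt`, `pdt`, `fiext`, `srt`,
#'   `odor`, `dlbox`, `physiology`, `truth` (generating parameters and
#'   per-animal latents), `config`.
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  animals <- animal_frame(config)
  streams <- vector("list", nrow(animals))
  for (i in seq_len(nrow(animals))) {
    set.seed(child_seed(config$seed, 1000 + i))
    gp <- config$genotypes[[animals$genotype[i]]]
    streams[[i]] <- sim_stream_animal(animals$animal[i], gp, config$grid,
                                      config$n_days, config$phase_seconds)
  }
  groups <- unique(animals$group)
  events <- vector("list", length(groups))
  for (j in seq_along(groups)) {
    set.seed(child_seed(config$seed, 2000 + j))
    ga <- animals$animal[animals$group == groups[j]]
    gp <- config$genotypes[[animals$genotype[animals$group == groups[j]][1]]]
    events[[j]] <- sim_events_group(ga, gp, config$grid, config$n_days)
  }
  events <- validate_events(do.call(rbind, events))
  rgt <- simulate_rgt_cohort(config)
  disc <- simulate_discounting(config)
  classical <- simulate_classical(config)
  structure(list(animals = animals,
                 detections = do.call(rbind, streams),
                 events = events,
                 rgt = rgt$trials, reversed_rgt = rgt$reversed,
                 ddt = disc$ddt, pdt = disc$pdt,
                 fiext = classical$fiext, srt = classical$srt,
                 odor = classical$odor, dlbox = classical$dlbox,
                 physiology = classical$physiology,
                 truth = list(rgt = rgt$truth, discounting = disc$truth),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic colony study:", nrow(x$animals), "animals in",
      length(unique(x$animals$group)), "groups\n")
  cat(nrow(x$events), "ethogram events,", nrow(x$detections),
      "dwell intervals\n")
  invisible(x)
}
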