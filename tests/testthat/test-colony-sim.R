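test_that("configuration invariants are enforced", {
  expect_error(genotype_params(event_rates = c(huddling = -1)), ">= 0")
  expect_error(genotype_params(dm_mix = c(GDM = 0.5, INT = 0.5, PDM = 0.5)),
               "sum to 1")
  expect_error(sim_config(group_size = 1), "group_size")
  expect_error(genotype_params(srt_means = c(Hab = -5, E1 = 1, E2 = 1,
                                             E3 = 1, E4 = 1, Enew = 1)),
               "negative duration")
  expect_error(genotype_params(choice_temp = 0), "> 0")
  expect_error(sim_config(grid = list(zones = 1)), "zone_grid")
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- small_config(seed = 4)
  s1 <- simulate_colony(cfg)
  s2 <- simulate_colony(cfg)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$rgt, s2$rgt)
  expect_identical(s1$physiology, s2$physiology)
  # different seed differs
  s3 <- simulate_colony(small_config(seed = 5))
  expect_false(identical(s1$events, s3$events))
})

test_that("dyadic event counts follow the configured Poisson rates", {
  # one category at rate 10 events/animal/phase over 8 scored phases:
  # per-animal mean must land within 3 SE of 80 (SE = sqrt(80 / n))
  rate <- 10
  gp <- genotype_params(event_rates = c(general_aggression = rate),
                        despotism = 1)
  cfg <- sim_config(n_groups = c(wildtype = 4), group_size = 6, n_days = 4,
                    phase_seconds = 60,
                    genotypes = list(wildtype = gp), seed = 8)
  st <- simulate_colony(cfg)
  n_animals <- nrow(st$animals)
  per_animal <- as.numeric(table(factor(st$events$actor,
                                        levels = st$animals$animal)))
  se <- sqrt(rate * 8 / n_animals)
  expect_lt(abs(mean(per_animal) - 80), 3 * se)
})

test_that("movement is a walk over the grid adjacency", {
  cfg <- small_config(seed = 6)
  st <- simulate_colony(cfg)
  g <- cfg$grid
  one <- st$detections[st$detections$animal == st$animals$animal[1] &
                         st$detections$day == 1 &
                         st$detections$phase == "dark", ]
  moves <- cbind(head(one$detector, -1), tail(one$detector, -1))
  expect_true(all(g$adjacency[moves] == 1))
  # dwell intervals tile the phase exactly
  expect_equal(sum(one$duration), cfg$phase_seconds)
})

test_that("the depleted genotype is burrow-biased and the control is not", {
  cfg <- sim_config(n_groups = c(wildtype = 1, knockout = 1),
                    phase_seconds = 1500, seed = 10)
  st <- simulate_colony(cfg)
  pref <- open_area_preference(st$detections, cfg$grid)
  wt <- st$animals$animal[st$animals$genotype == "wildtype"]
  ko <- st$animals$animal[st$animals$genotype == "knockout"]
  expect_gt(min(pref[wt]), max(pref[ko]))
  re <- roaming_entropy_stream(st$detections, cfg$grid)$total
  expect_gt(mean(re[wt]), mean(re[ko]))
})

test_that("gambling cohort mixture proportions are recovered", {
  cfg <- sim_config(n_groups = c(wildtype = 8), phase_seconds = 60,
                    genotypes = list(wildtype = genotype_params()), seed = 12)
  rgt <- simulate_rgt_cohort(cfg)
  classes <- vapply(unique(rgt$trials$animal), function(a)
    rgt_profile(rgt$trials[rgt$trials$animal == a, ])$dm_class, character(1))
  n <- length(classes)
  expect_equal(n, 48)
  # observed GDM count within the binomial 95% interval around 0.74
  ci <- qbinom(c(0.025, 0.975), n, 0.74)
  expect_gte(sum(classes == "GDM"), ci[1])
  expect_lte(sum(classes == "GDM"), ci[2])
  # a latent near-ceiling decision-maker classifies as GDM
  hi <- rgt$truth$animal[which.max(rgt$truth$asymptote)]
  expect_equal(
    rgt_profile(rgt$trials[rgt$trials$animal == hi, ])$dm_class, "GDM")
  # zero-length session: empty log, scorer raises insufficient-data error
  empty <- simulate_rgt_cohort(small_config(seed = 1), session_min = 0)
  expect_equal(nrow(empty$trials), 0)
  expect_error(rgt_profile(empty$trials), "insufficient")
})

test_that("discounting curves cross indifference near the configured delay", {
  # k concentrated near 0.2 puts large-vs-small indifference at delay 20 s
  gp <- genotype_params(k_meanlog = log(0.2), k_sdlog = 0.05)
  cfg <- sim_config(n_groups = c(wildtype = 4), phase_seconds = 60,
                    genotypes = list(wildtype = gp), seed = 14)
  disc <- simulate_discounting(cfg)
  pref <- sapply(seq(0, 40, 10), function(lv) {
    d <- disc$ddt[!is.na(disc$ddt$level) & disc$ddt$level == lv, ]
    100 * sum(d$n_large) / sum(d$n_trials)
  })
  expect_gt(pref[2], 50)   # 10 s: still prefers large
  expect_lt(pref[4], 50)   # 30 s: switched to small
  # AUC limit cases
  lo_k <- genotype_params(k_meanlog = log(1e-6), k_sdlog = 0.01)
  cfg_lo <- sim_config(n_groups = c(wildtype = 1), phase_seconds = 60,
                       genotypes = list(wildtype = lo_k), seed = 15)
  d <- simulate_discounting(cfg_lo)$ddt
  auc <- vapply(unique(d$animal), function(a) {
    da <- d[d$animal == a, ]
    tr <- 100 * sum(da$n_large[is.na(da$level)]) /
      sum(da$n_trials[is.na(da$level)])
    lv <- sort(unique(da$level[!is.na(da$level)]))
    pf <- vapply(lv, function(x) 100 * sum(da$n_large[!is.na(da$level) &
                                                        da$level == x]) /
                   sum(da$n_trials[!is.na(da$level) & da$level == x]),
                 numeric(1))
    discounting_auc(lv, pf, tr, "delay")
  }, numeric(1))
  expect_gt(mean(auc), 0.9)
  hi_k <- genotype_params(k_meanlog = log(50), k_sdlog = 0.01)
  cfg_hi <- sim_config(n_groups = c(wildtype = 1), phase_seconds = 60,
                       genotypes = list(wildtype = hi_k), seed = 16)
  d2 <- simulate_discounting(cfg_hi)$ddt
  lv <- seq(10, 40, 10)
  pf2 <- sapply(lv, function(x) 100 * sum(d2$n_large[!is.na(d2$level) &
                                                       d2$level == x]) /
                  sum(d2$n_trials[!is.na(d2$level) & d2$level == x]))
  expect_lt(max(pf2), 25)  # switched to small at every nonzero delay
})

test_that("null physiology overlaps and contrasted physiology separates", {
  # corticosterone multiplier equal for both genotypes: rank-sum usually ns
  base <- genotype_params()
  cfg0 <- sim_config(n_groups = c(a = 2, b = 2), phase_seconds = 60,
                     genotypes = list(a = base, b = base), seed = 18)
  cls <- simulate_classical(cfg0)
  pct <- physiology_changes(cls$physiology$cort_before,
                            cls$physiology$cort_after)$pct
  gen <- rep(c("a", "b"), each = 12)
  set.seed(123)
  ps <- replicate(40, {
    cfg <- sim_config(n_groups = c(a = 2, b = 2), phase_seconds = 60,
                      genotypes = list(a = base, b = base),
                      seed = sample.int(1e6, 1))
    cc <- simulate_classical(cfg)
    p <- physiology_changes(cc$physiology$cort_before,
                            cc$physiology$cort_after)$pct
    rank_sum_W(p[gen == "a"], p[gen == "b"])$p
  })
  expect_gte(mean(ps > 0.05), 0.9)
  # well-separated weight-loss means: W near complete separation
  gpa <- genotype_params(weight_loss_mean = 2, weight_loss_sd = 2)
  gpb <- genotype_params(weight_loss_mean = 10, weight_loss_sd = 2)
  cfg2 <- sim_config(n_groups = c(a = 2, b = 2), phase_seconds = 60,
                     genotypes = list(a = gpa, b = gpb), seed = 19)
  cc2 <- simulate_classical(cfg2)
  loss <- cc2$physiology$weight_before - cc2$physiology$weight_after
  W <- rank_sum_W(loss[gen == "a"], loss[gen == "b"])$W
  expect_lte(W, 0.15 * 144)  # near 0 of the n1*n2 = 144 maximum
})
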