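rgt_log <- function(times, adv, latency = 2) {
  data.frame(time = times, advantageous = adv,
             latency = rep_len(latency, length(times)),
             side = ifelse(adv, "left", "right"))
}

test_that("gambling-task classification uses strict 70/30 thresholds", {
  # 80% advantageous in the last 20 min -> GDM; 50% -> INT; 20% -> PDM
  mk <- function(p) {
    t_last <- seq(2400, 3590, length.out = 20)
    rgt_log(c(seq(0, 2399, length.out = 20), t_last),
            c(rep(TRUE, 20), rep(c(TRUE, FALSE), round(c(p, 1 - p) * 20))))
  }
  expect_equal(rgt_profile(mk(0.8))$dm_class, "GDM")
  expect_equal(rgt_profile(mk(0.5))$dm_class, "INT")
  expect_equal(rgt_profile(mk(0.2))$dm_class, "PDM")
  # all advantageous
  all_adv <- rgt_profile(rgt_log(seq(0, 3599, length.out = 30), TRUE))
  expect_equal(all_adv$last20_pct, 100)
  expect_equal(all_adv$dm_class, "GDM")
  # exactly 70% is INT under the strict rule
  t10 <- seq(2410, 3590, length.out = 10)
  p70 <- rgt_profile(rgt_log(t10, c(rep(TRUE, 7), rep(FALSE, 3))))
  expect_equal(p70$last20_pct, 70)
  expect_equal(p70$dm_class, "INT")
  # insufficient data
  expect_error(rgt_profile(rgt_log(numeric(0), logical(0))), "insufficient")
  expect_error(rgt_profile(rgt_log(c(10, 20), c(TRUE, TRUE))),
               "last 20 min")
})

test_that("per-10-min bins track the preference trajectory", {
  tr <- rgt_log(c(100, 700, 1300, 1900, 2500, 3100),
                c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  p <- rgt_profile(tr)
  expect_equal(p$bin_pct, c(0, 0, 100, 100, 100, 100))
  expect_equal(p$mean_latency, 2)
})

test_that("flexibility scores classify by strict 60/40 thresholds", {
  rgt <- rgt_log(seq(0, 3599, length.out = 20), TRUE)  # all on "left"
  mk_rev <- function(p_right) {
    n <- 20
    data.frame(time = seq(2400, 3599, length.out = n),
               side = rep(c("right", "left"),
                          round(c(p_right, 1 - p_right) * n)))
  }
  expect_equal(flexibility_score(rgt, mk_rev(1))$class, "flexible")
  expect_equal(flexibility_score(rgt, mk_rev(0.5))$class, "undecided")
  expect_equal(flexibility_score(rgt, mk_rev(0.35))$class, "inflexible")
  expect_equal(flexibility_score(rgt, mk_rev(0.35))$score, 35)
})

test_that("odds transform and discounting AUC follow the stated forms", {
  expect_equal(odds_transform(1), 0)
  expect_equal(odds_transform(0.2), 4)
  expect_equal(odds_transform(0.09), 1 / 0.09 - 1, tolerance = 1e-12)
  expect_equal(round(odds_transform(0.09), 2), 10.11)
  # flat curve at training level
  expect_equal(discounting_auc(c(0, 10, 20, 40), rep(80, 4), 80, "delay"), 1)
  # two-point toy curve y = {1, 0} at x = {0, 1}
  expect_equal(discounting_auc(c(0, 40), c(70, 0), 70, "delay"), 0.5)
  # probability curves anchor at x = 0 at the training level
  expect_equal(discounting_auc(c(0.66, 0.33, 0.2, 0.14, 0.09),
                               rep(90, 5), 90, "probability"), 1)
  expect_error(discounting_auc(c(0, NA), c(1, 1), 1), "missing")
  expect_error(discounting_auc(c(0, 10), c(50, 40), 0), "training")
  # monotone under pointwise dominance
  lv <- c(0, 10, 20, 30, 40)
  hi <- c(100, 90, 80, 70, 60); lo <- hi - 20
  expect_gt(discounting_auc(lv, hi, 100, "delay"),
            discounting_auc(lv, lo, 100, "delay"))
})

test_that("FIEXT exclusions and bins follow the session structure", {
  pokes <- do.call(rbind, lapply(1:14, function(i)
    data.frame(period_type = "FI", period_number = i,
               time = c(5, 25, 55))))
  pokes <- rbind(pokes, data.frame(period_type = "EXT", period_number = 1:2,
                                   time = c(30, 250)))
  pr <- fiext_profile(pokes)
  expect_equal(pr$analyzed_fi, setdiff(1:14, c(1, 8)))
  expect_length(pr$analyzed_fi, 12)
  expect_equal(pr$fi_mean, 3)
  expect_length(pr$ext_bins, 5)
  expect_length(pr$fi_bins, 6)
  expect_equal(sum(pr$ext_bins), 2)
  # zero pokes -> all bins zero
  pr0 <- fiext_profile(pokes[0, ])
  expect_true(all(pr0$fi_bins == 0) && all(pr0$ext_bins == 0))
  expect_equal(pr0$fi_mean, 0)
})

test_that("social recognition ratios divide the stated encounters", {
  expect_equal(srt_scores(c(Hab = 30, E1 = 30, E3 = 10, E4 = 10,
                            Enew = 40))$social_preference, 1)
  s <- srt_scores(c(Hab = 20, E1 = 60, E3 = 20, E4 = 10, Enew = 40))
  expect_equal(s$short_term, 3)
  expect_equal(s$long_term, 0.25)
  # zero denominator flagged missing
  expect_true(is.na(srt_scores(c(Hab = 0, E1 = 60, E3 = 20, E4 = 10,
                                 Enew = 40))$social_preference))
  expect_error(srt_scores(c(Hab = -1, E1 = 1, E3 = 1, E4 = 1, Enew = 1)),
               ">= 0")
})

test_that("dark-light composite and risk index invert the cohort maximum", {
  log1 <- data.frame(time = c(50, 150, 20, 30, 300, 500),
                     event = c("enter_dark", "exit_dark", "risk_assessment",
                               "risk_assessment", "enter_dark", "exit_dark"))
  # first visit 100 s + 2 risk + 300 s dark total
  expect_equal(dlbox_composite(log1), 100 + 2 + 300)
  # never leaves the bright compartment
  none <- data.frame(time = numeric(0), event = character(0))
  expect_equal(dlbox_composite(none), 0)
  idx <- dlbox_risk_index(c(a = 300, b = 100))
  expect_equal(unname(idx), c(0, 200))
  expect_equal(unname(dlbox_risk_index(c(a = 402, b = 0))["b"]), 402)
  # unclosed visit runs to session end
  open_ended <- data.frame(time = 500, event = "enter_dark")
  expect_equal(dlbox_composite(open_ended), 100 + 100)
})

test_that("physiology changes use the loss and percent conventions", {
  pw <- physiology_changes(250, 240)
  expect_equal(pw$delta, 10)
  expect_equal(pw$pct, -4)
  pc <- physiology_changes(2, 6)
  expect_equal(pc$pct, 200)
  expect_equal(physiology_changes(5, 5)$pct, 0)
  expect_error(physiology_changes(0, 5), "> 0")
  expect_error(physiology_changes(c(1, 2), 1), "unpaired")
})
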