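test_that("every ethogram behavior maps to exactly one category and group", {
  e <- vbs_ethogram()
  expect_false(any(duplicated(e$behavior)))
  expect_setequal(unique(e$category),
                  c("affiliative", "aggressive", "sexual", "defensive",
                    "maintenance"))
  # all aggressive behaviors except struggling at feeder -> general_aggression
  agg <- e[e$category == "aggressive", ]
  expect_equal(agg$grouped[agg$behavior == "struggling_at_feeder"],
               "struggling_at_feeder")
  expect_true(all(agg$grouped[agg$behavior != "struggling_at_feeder"] ==
                    "general_aggression"))
  expect_setequal(e$behavior[e$grouped == "sexual"], c("mounting", "embracing"))
  expect_equal(sum(e$grouped == "sniffing"), 3)
  # self-grooming is maintenance, allogrooming affiliative
  expect_equal(e$category[e$behavior == "grooming"], "maintenance")
  expect_equal(e$category[e$behavior == "allogrooming"], "affiliative")
})

test_that("read_events validates rows and reports offenders", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("group,day,phase,time,actor,receiver,behavior,duration,zone", path)
  expect_equal(nrow(read_events(path)), 0)

  ev <- data.frame(group = "g1", day = 1, phase = "dark", time = 1:3 * 10,
                   actor = c("a", "b", "c"), receiver = c("b", "", ""),
                   behavior = c("attack", "huddle", "eating"),
                   duration = 1, zone = 2)
  ev$receiver[2] <- "c"
  utils::write.csv(ev, path, row.names = FALSE)
  got <- read_events(path)
  expect_setequal(got$grouped, c("general_aggression", "huddling", "eating"))

  ev_bad <- ev; ev_bad$receiver[1] <- "a"
  utils::write.csv(ev_bad, path, row.names = FALSE)
  expect_error(read_events(path), "actor equals receiver.*1")

  ev_bad <- ev; ev_bad$behavior[3] <- "levitating"
  utils::write.csv(ev_bad, path, row.names = FALSE)
  expect_error(read_events(path), "unknown behavior.*3")

  ev_bad <- ev; ev_bad$duration[2] <- -1
  utils::write.csv(ev_bad, path, row.names = FALSE)
  expect_error(read_events(path), "negative duration")
})

test_that("events round-trip through CSV", {
  ev <- make_events(c("a", "b"), c("b", NA), c("attack", "grooming"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$actor, ev$actor)
  expect_equal(back$grouped, ev$grouped)
})

test_that("count_behaviors sums occurrences and filters by cohort median", {
  ev <- make_events(actor = c(rep("a", 8), "b"),
                    receiver = c(rep("b", 8), "a"),
                    behavior = c(rep("mounting", 7), "embracing", "attack"))
  cnt <- count_behaviors(ev, "grouped")
  expect_equal(cnt["a", "sexual"], 8)
  expect_equal(cnt["b", "general_aggression"], 1)
  expect_equal(sum(cnt), 9)

  # no events at all: all zero, most_expressed empty
  empty <- count_behaviors(ev[0, ], "grouped", animals = c("a", "b"))
  expect_true(all(empty == 0))
  expect_equal(ncol(count_behaviors(ev[0, ], "grouped", animals = c("a", "b"),
                                    most_expressed = TRUE)), 0)

  # median exactly 5 is excluded (strict > 5)
  ev5 <- make_events(actor = rep(c("a", "b"), each = 5),
                     receiver = NA_character_,
                     behavior = rep("grooming", 10),
                     time = rep(seq(10, 50, by = 10), 2))
  cnt5 <- count_behaviors(ev5, "grouped", most_expressed = TRUE)
  expect_false("grooming" %in% names(cnt5))
  ev6 <- make_events(actor = rep(c("a", "b"), each = 6),
                     receiver = NA_character_,
                     behavior = rep("grooming", 12),
                     time = rep(seq(10, 60, by = 10), 2))
  expect_true("grooming" %in%
                names(count_behaviors(ev6, "grouped", most_expressed = TRUE)))
})

test_that("count_behaviors is additive over disjoint day windows", {
  set.seed(5)
  e <- vbs_ethogram()
  beh <- sample(e$behavior, 40, replace = TRUE)
  actor <- sample(c("a", "b", "c"), 40, replace = TRUE)
  recv <- ifelse(e$dyadic[match(beh, e$behavior)],
                 ifelse(actor == "a", "b", "a"), NA)
  ev <- validate_events(data.frame(group = "g1",
                                   day = sample(1:4, 40, replace = TRUE),
                                   phase = "dark", time = runif(40, 0, 14000),
                                   actor = actor, receiver = recv,
                                   behavior = beh, duration = 2, zone = 1))
  all4 <- count_behaviors(ev, "grouped", days = 1:4, animals = c("a", "b", "c"))
  d12 <- count_behaviors(ev, "grouped", days = 1:2, animals = c("a", "b", "c"))
  d34 <- count_behaviors(ev, "grouped", days = 3:4, animals = c("a", "b", "c"))
  expect_equal(as.matrix(all4), as.matrix(d12) + as.matrix(d34))
})

test_that("dyad matrices tally directed counts within the window", {
  ev <- make_events(actor = c("a", "a", "a", "b", "c"),
                    receiver = c("b", "b", "b", "a", "a"),
                    behavior = c(rep("attack", 4), "huddle"),
                    day = c(1, 1, 1, 1, 2))
  m <- build_dyad_matrix(ev, "general_aggression",
                         animals = c("a", "b", "c"))
  expect_equal(m["a", "b"], 3L)
  expect_equal(m["b", "a"], 1L)
  expect_equal(sum(m), 4L)
  expect_true(all(diag(m) == 0))
  # single event
  m1 <- build_dyad_matrix(ev[5, ], "huddling", animals = c("a", "b", "c"))
  expect_equal(m1["c", "a"], 1L)
  expect_equal(sum(m1), 1L)
  # window restriction excludes out-of-window events
  m2 <- build_dyad_matrix(ev, "huddling", animals = c("a", "b", "c"),
                          days = 1)
  expect_equal(sum(m2), 0L)
  # solitary category cannot form a matrix
  expect_error(build_dyad_matrix(ev, "grooming"), "solitary")
  # conservation: total over categories = number of dyadic events
  tot <- sum(build_dyad_matrix(ev, "general_aggression",
                               animals = c("a", "b", "c"))) +
    sum(build_dyad_matrix(ev, "huddling", animals = c("a", "b", "c")))
  expect_equal(tot, sum(!is.na(ev$receiver)))
})
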