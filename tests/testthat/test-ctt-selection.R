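test_that("coverage distance is 0 in range, gap-to-endpoint outside, 10 absent", {
  expect_equal(domain_distance(55, c(40, 70)), 0)
  expect_equal(domain_distance(55, NULL), 10)
  expect_equal(domain_distance(35, c(40, 70)), 0.5)  # 3.5 vs [4.0, 7.0]
  expect_equal(domain_distance(95, c(40, 70)), 2.5)
  expect_equal(domain_distance(0, c(40, 40)), 4)
  expect_error(domain_distance(55, c(70, 40)), "malformed")
})

test_that("coverage distance stays in [0, 10] and is 0 iff in range", {
  set.seed(3)
  for (i in 1:50) {
    cs <- round(stats::runif(1, 0, 100), 1)
    lo <- stats::runif(1, 0, 100)
    hi <- stats::runif(1, lo, 100)
    d <- domain_distance(cs, c(lo, hi))
    expect_gte(d, 0)
    expect_lte(d, 10)
    expect_identical(d == 0, cs >= lo && cs <= hi)
  }
})

make_repo <- function() {
  list(
    ctt_model("a_perfect", "search", "kitchen",
              coverage = list(attention = c(40, 70), memory = c(40, 70),
                              executive_functions = c(40, 70)),
              training_weights = list(attention = 0.4, memory = 0.3,
                                      executive_functions = 0.3),
              parameters = list(targets = c(1, 12))),
    ctt_model("b_nocover", "organize", "supermarket",
              coverage = list(language = c(0, 100)),
              training_weights = list(language = 1),
              parameters = list(steps = c(2, 12))),
    ctt_model("c_partial", "categorize", c("kitchen", "supermarket"),
              coverage = list(attention = c(40, 70), memory = c(0, 30)),
              training_weights = list(attention = 0.5, memory = 0.5),
              parameters = list(items = c(2, 60), containers = c(2, 4)))
  )
}

test_that("ranking scores priority-weighted distances, ascending, ties by id", {
  repo <- make_repo()
  cs <- c(attention = 55, memory = 55, executive_functions = 55)
  ob <- training_objective(c(attention = 1, memory = 1,
                             executive_functions = 1))
  rk <- rank_ctts(cs, ob, repo)
  expect_equal(rk$id[1], "a_perfect")
  expect_equal(rk$score[1], 0)
  # b covers none of the three target domains: 3 x 10
  expect_equal(rk$score[rk$id == "b_nocover"], 30)
  expect_equal(rk$id[nrow(rk)], "b_nocover")
  # c: attention 0, memory gap 5.5-3.0 = 2.5, executive uncovered 10
  expect_equal(rk$score[rk$id == "c_partial"], 12.5)

  # deterministic tie-break by lexicographic id
  twin1 <- ctt_model("zz_twin", "search", "kitchen",
                     coverage = list(attention = c(40, 70)),
                     training_weights = list(attention = 1))
  twin2 <- ctt_model("aa_twin", "search", "kitchen",
                     coverage = list(attention = c(40, 70)),
                     training_weights = list(attention = 1))
  rk2 <- rank_ctts(c(attention = 55), training_objective(c(attention = 1)),
                   list(twin1, twin2))
  expect_equal(rk2$id, c("aa_twin", "zz_twin"))
})

test_that("ranking is invariant under repository permutation", {
  repo <- make_repo()
  cs <- c(attention = 35, memory = 80, executive_functions = 20)
  ob <- training_objective(c(attention = 2, memory = 1,
                             executive_functions = 0.5))
  set.seed(9)
  base <- rank_ctts(cs, ob, repo)
  for (i in 1:5) {
    perm <- rank_ctts(cs, ob, sample(repo))
    expect_equal(perm$id, base$id)
    expect_equal(perm$score, base$score)
  }
})

test_that("widening coverage to include the CS value never worsens the score", {
  cs <- c(attention = 85)
  ob <- training_objective(c(attention = 1))
  narrow <- ctt_model("t", "search", "kitchen",
                      coverage = list(attention = c(40, 70)),
                      training_weights = list(attention = 1))
  wide <- ctt_model("t", "search", "kitchen",
                    coverage = list(attention = c(40, 90)),
                    training_weights = list(attention = 1))
  expect_lt(rank_ctts(cs, ob, list(wide))$score,
            rank_ctts(cs, ob, list(narrow))$score)
})

test_that("context filter keeps matching contexts and respects the budget", {
  repo <- make_repo()
  cs <- c(attention = 55, memory = 55, executive_functions = 55,
          language = 55)
  ob_all <- training_objective(c(attention = 1), contexts = "kitchen")
  rk <- rank_ctts(cs, training_objective(c(attention = 1)), repo)
  kept <- filter_by_context(rk, ob_all)
  expect_true(all(kept$id %in% c("a_perfect", "c_partial")))

  # 1 session x 30 min with 11-min tasks keeps at most 2
  ob_budget <- training_objective(c(attention = 1), sessions = 1,
                                  minutes_per_session = 30)
  kept2 <- filter_by_context(rk, ob_budget)
  expect_lte(nrow(kept2), 2)

  # empty preference set: the context filter is a no-op
  ob_free <- training_objective(c(attention = 1))
  expect_equal(nrow(filter_by_context(rk, ob_free)), nrow(rk))

  # zero budget empties the list -> explicit no-candidate error
  ob_zero <- training_objective(c(attention = 1), sessions = 1,
                                minutes_per_session = 0)
  expect_error(filter_by_context(rk, ob_zero), class = "no_candidate")
})

test_that("objectives validate their priorities and thresholds", {
  expect_error(training_objective(c(attention = 0)), "positive")
  expect_error(training_objective(c(1, 2)), "named")
  expect_error(training_objective(c(attention = 1), thresholds = c(80, 50)),
               "thresholds")
})

test_that("initial parameters interpolate bounds along the difficulty scale", {
  sch <- training_schema()
  task <- ctt_model("s", "search", "kitchen",
                    coverage = list(memory = c(0, 100),
                                    attention = c(0, 100)),
                    training_weights = list(memory = 0.5, attention = 0.5),
                    parameters = list(targets = c(1, 12),
                                      sections = c(1, 8)))
  top <- cog_profile(sch, c(10, 10, 10, 10))
  p_top <- initial_parameters(task, top)
  expect_equal(p_top$targets, 12)
  expect_equal(attr(p_top, "difficulty"), 10)

  bottom <- cog_profile(sch, c(1, 1, 1, 1))
  org <- ctt_model("o", "organize", "kitchen",
                   coverage = list(memory = c(0, 100)),
                   training_weights = list(memory = 1),
                   parameters = list(steps = c(2, 12)))
  expect_equal(initial_parameters(org, bottom)$steps, 2)

  # memory 7, attention 5, weights 0.5/0.5 -> difficulty 6, p in [2,12] -> 8
  mid <- cog_profile(sch, c(attention = 5, memory = 7,
                            executive_functions = 5, language = 5))
  mixed <- ctt_model("m", "organize", "kitchen",
                     coverage = list(memory = c(0, 100),
                                     attention = c(0, 100)),
                     training_weights = list(memory = 0.5, attention = 0.5),
                     parameters = list(steps = c(2, 12)))
  pm <- initial_parameters(mixed, mid)
  expect_equal(attr(pm, "difficulty"), 6)
  expect_equal(pm$steps, 8)

  expect_error(initial_parameters(task, cog_profile(
    profile_schema("language", min = 1, max = 10, step = 0.5), 5)),
    "lacks trained domain")
})

test_that("initial parameters always pass validation", {
  set.seed(21)
  repo <- read_ctt_repo()
  sch <- training_schema()
  for (i in 1:20) {
    prof <- random_profile(sch)
    for (task in repo) {
      pars <- initial_parameters(task, prof)
      expect_true(validate_task_parameters(task, pars))
    }
  }
})

test_that("parameter validation reports violations as data", {
  search <- ctt_model("s", "search", "kitchen",
                      coverage = list(attention = c(0, 100)),
                      training_weights = list(attention = 1),
                      parameters = list(targets = c(1, 12)))
  bad <- validate_task_parameters(search, list(targets = 13))
  expect_false(bad)
  v <- attr(bad, "violations")
  expect_equal(v$parameter, "targets")
  expect_match(v$bound, "max 12")

  cat_task <- ctt_model("c", "categorize", "kitchen",
                        coverage = list(attention = c(0, 100)),
                        training_weights = list(attention = 1),
                        parameters = list(containers = c(2, 4)))
  expect_false(validate_task_parameters(cat_task, list(containers = 5)))

  org <- ctt_model("o", "organize", "kitchen",
                   coverage = list(attention = c(0, 100)),
                   training_weights = list(attention = 1),
                   parameters = list(steps = c(2, 12)))
  expect_true(validate_task_parameters(org, list(steps = 6)))
})

test_that("task models reject bounds beyond their kind limits", {
  expect_error(ctt_model("bad", "search", "kitchen",
                         coverage = list(attention = c(0, 100)),
                         training_weights = list(attention = 1),
                         parameters = list(targets = c(1, 13))),
               "exceed the search limits")
  expect_error(ctt_model("bad", "categorize", "kitchen",
                         coverage = list(attention = c(0, 100)),
                         training_weights = list(attention = 1),
                         parameters = list(containers = c(1, 5))),
               "exceed the categorize limits")
  expect_error(ctt_model("bad", "search", "kitchen",
                         coverage = list(attention = c(0, 100)),
                         training_weights = list(attention = 0.5)),
               "sum to 1")
})

test_that("the shipped repository loads and validates", {
  repo <- read_ctt_repo()
  expect_gte(length(repo), 5)
  kinds <- vapply(repo, `[[`, "", "kind")
  expect_setequal(unique(kinds),
                  c("search", "organize", "categorize", "pay", "drive"))
  for (m in repo) expect_equal(sum(m$training_weights), 1)
})
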