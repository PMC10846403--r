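test_that("min-max normalization maps bounds to 0 and 100", {
  expect_equal(normalize_score(30, 0, 30), 100)
  expect_equal(normalize_score(0, 0, 30), 0)
  expect_equal(normalize_score(15, 0, 30), 50)
  # reverse-scored instruments flip the axis
  expect_equal(normalize_score(0, 0, 30, higher_is_better = FALSE), 100)
  expect_equal(normalize_score(30, 0, 30, higher_is_better = FALSE), 0)
  expect_error(normalize_score(31, 0, 30), "outside")
  expect_error(normalize_score(5, 10, 10), "degenerate")
})

test_that("weight renormalization reproduces the published row fractions", {
  wm <- renormalize_weights(c(50, 12.5, 6.25, 4.2))
  expect_equal(unname(wm), c(0.6854, 0.1713, 0.0857, 0.0576), tolerance = 5e-4)
  expect_equal(sum(wm), 1)
  expect_equal(unname(renormalize_weights(50)), 1)
  expect_equal(unname(renormalize_weights(c(33.33, 12.5))),
               c(0.7273, 0.2727), tolerance = 1e-4)
  expect_error(renormalize_weights(numeric()), "empty")
  expect_error(renormalize_weights(c(10, -1)), "positive")
})

test_that("the shipped weight table renormalizes to 1 within every domain", {
  wt <- read_weight_table()
  sums <- tapply(wt$weight, wt$domain, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(wt$raw_pct > 0))
})

test_that("ACP aggregation matches the hand-computed weighted sum", {
  wt <- read_weight_table()
  ins <- read_instruments()
  # working-memory normalized scores {DSC:80, digit:60, calculus:40, target:100}
  sc <- npa_scores("p1", data.frame(
    instrument = c("WAIS_III", "MoCA", "MoCA", "MoCA"),
    subscore = c("digit_symbol_coding", "digit_reverse", "calculus",
                 "target_detection"),
    raw = c(0.8 * 133, 0.6 * 1, 0.4 * 3, 1)), instruments = ins)
  acp <- compute_acp(sc, wt, ins)
  expect_equal(acp$values[["executive.working_memory"]], 74.30,
               tolerance = 0.05 / 74.30)
  # unscored domains are absent, not zero
  expect_true("memory.delayed_verbal" %in% acp$absent)
  expect_true(is.na(acp$values[["memory.delayed_verbal"]]))
})

test_that("missing subscores renormalize over what is present", {
  wt <- read_weight_table()
  ins <- read_instruments()
  sc <- npa_scores("p2", data.frame(
    instrument = "WAIS_III", subscore = "digit_symbol_coding",
    raw = 0.8 * 133))
  acp <- compute_acp(sc, wt, ins)
  # DSC weight renormalizes to 1, so the domain equals Norm(DSC)
  expect_equal(acp$values[["executive.working_memory"]], 80)
})

test_that("ACP at all maxima is 100 and aggregation is monotone and convex", {
  wt <- read_weight_table()
  ins <- read_instruments()
  wm_rows <- wt[wt$domain == "executive.working_memory", ]
  maxima <- vapply(seq_len(nrow(wm_rows)), function(r)
    cogrehab:::lookup_subscore(ins, wm_rows$instrument[r],
                               wm_rows$subscore[r])$max, numeric(1))
  full <- npa_scores("p3", data.frame(
    instrument = wm_rows$instrument, subscore = wm_rows$subscore,
    raw = maxima))
  expect_equal(compute_acp(full, wt, ins)$values[["executive.working_memory"]],
               100)

  set.seed(5)
  base_raw <- maxima * stats::runif(length(maxima), 0.2, 0.8)
  base <- compute_acp(npa_scores("p", data.frame(
    instrument = wm_rows$instrument, subscore = wm_rows$subscore,
    raw = base_raw)), wt, ins)$values[["executive.working_memory"]]
  for (j in seq_along(base_raw)) {
    bumped_raw <- base_raw
    bumped_raw[j] <- min(maxima[j], bumped_raw[j] * 1.25)
    bumped <- compute_acp(npa_scores("p", data.frame(
      instrument = wm_rows$instrument, subscore = wm_rows$subscore,
      raw = bumped_raw)), wt, ins)$values[["executive.working_memory"]]
    expect_gte(bumped, base)  # monotone in every raw subscore
  }
  norm <- 100 * base_raw / maxima
  expect_gte(base, min(norm) - 1e-9)  # convex-combination bounds
  expect_lte(base, max(norm) + 1e-9)
})

test_that("cognitive status anchors the group average at the 50th percentile", {
  wt <- read_weight_table()
  ins <- read_instruments()
  nt <- read_normative_table()
  sdi <- list(age_band = "65-80", education_band = "5-12")
  # language.comprehension has one instrument (vocabulary, 0-66);
  # its synthetic stratum mean is 33 -> expected normalized score 50
  at_mean <- npa_scores("p4", data.frame(
    instrument = "WAIS_III", subscore = "vocabulary", raw = 33), sdi = sdi)
  cs <- compute_cs(compute_acp(at_mean, wt, ins), nt, sdi, wt, ins)
  expect_equal(cs$values[["language.comprehension"]], 50)

  # ACP 0 floors at 0
  at_floor <- npa_scores("p5", data.frame(
    instrument = "WAIS_III", subscore = "vocabulary", raw = 0), sdi = sdi)
  cs0 <- compute_cs(compute_acp(at_floor, wt, ins), nt, sdi, wt, ins)
  expect_equal(cs0$values[["language.comprehension"]], 0)

  # cross-multiplication: expected 50, ACP 90 -> CS 90 * 100 / (2*50) = 90...
  # use raw 59.4 (ACP 90): CS = 100 * 90 / (2 * 50) = 90
  hi <- npa_scores("p6", data.frame(
    instrument = "WAIS_III", subscore = "vocabulary", raw = 0.9 * 66),
    sdi = sdi)
  cs_hi <- compute_cs(compute_acp(hi, wt, ins), nt, sdi, wt, ins)
  expect_equal(cs_hi$values[["language.comprehension"]], 90)
})

test_that("cross-multiplication scales linearly below the clip", {
  wt <- read_weight_table()
  ins <- read_instruments()
  nt <- read_normative_table()
  sdi <- list(age_band = "50-64", education_band = "5-12")
  # expected_k for comprehension in this stratum: mean 35 -> 53.03
  cs_at <- function(raw) {
    sc <- npa_scores("p", data.frame(instrument = "WAIS_III",
                                     subscore = "vocabulary", raw = raw),
                     sdi = sdi)
    compute_cs(compute_acp(sc, wt, ins), nt, sdi, wt, ins)$values[[
      "language.comprehension"]]
  }
  expect_equal(cs_at(40) / cs_at(20), 2, tolerance = 1e-9)
  # expected 60, ACP 90 -> 75 by the cross-multiplication rule
  expect_equal(100 * 90 / (2 * 60), 75)
})

test_that("missing normative strata raise an unstratified-SDI error", {
  wt <- read_weight_table()
  ins <- read_instruments()
  nt <- read_normative_table()
  sdi <- list(age_band = "18-49", education_band = "5-12")
  sc <- npa_scores("p7", data.frame(
    instrument = "WAIS_III", subscore = "vocabulary", raw = 33), sdi = sdi)
  expect_error(compute_cs(compute_acp(sc, wt, ins), nt, sdi, wt, ins),
               "unstratified SDI")
})

test_that("the zscore backend reports normal percentiles", {
  wt <- read_weight_table()
  ins <- read_instruments()
  nt <- read_normative_table()
  sdi <- list(age_band = "65-80", education_band = "5-12")
  at_mean <- npa_scores("p8", data.frame(
    instrument = "WAIS_III", subscore = "vocabulary", raw = 33), sdi = sdi)
  cs <- compute_cs(compute_acp(at_mean, wt, ins), nt, sdi, wt, ins,
                   method = "zscore")
  expect_equal(cs$values[["language.comprehension"]], 50)
})

test_that("the simplified scheme averages 0-10 normalized scores per macro-domain", {
  t3 <- read_table3_scheme()
  # screening total at ceiling -> general cognition 10
  sc <- npa_scores("p9", data.frame(
    instrument = "MoCA", subscore = "total", raw = 30))
  sp <- compute_simple_profile(sc, t3)
  expect_equal(sp$values[["general_cognition"]], 10)
  expect_true("language" %in% sp$absent)

  # memory: 24/48, 18/36 and 8/16 all normalize to 5.0
  mem <- npa_scores("p10", data.frame(
    instrument = c("FCSRT", "ROCFT", "FCSRT"),
    subscore = c("immediate_memory", "recall_3min", "delayed_recall"),
    raw = c(24, 18, 8)))
  expect_equal(compute_simple_profile(mem, t3)$values[["memory"]], 5.0)

  # every raw score at its minimum -> every scored macro-domain 0
  entries <- do.call(rbind, lapply(t3$macro_domains, function(m)
    do.call(rbind, lapply(m$subdomains, function(s)
      do.call(rbind, lapply(s$entries, function(e)
        data.frame(instrument = e$instrument, subscore = e$subscore,
                   raw = e$min)))))))
  floor_sc <- npa_scores("p11", unique(entries))
  floor_sp <- compute_simple_profile(floor_sc, t3)
  expect_true(all(floor_sp$values[!is.na(floor_sp$values)] == 0))
})

test_that("training profiles snap continuous values to the half-step grid", {
  sp <- structure(list(values = c(memory = 6.23, attention = 0.2),
                       absent = character(), patient_id = "p"),
                  class = "simple_profile")
  tp <- as_training_profile(sp)
  expect_equal(unname(tp$values), c(6.0, 1))  # snapped and clamped to >= 1
  expect_equal(tp$schema$step, c(0.5, 0.5))
})

test_that("NPA score documents round-trip and validate ranges", {
  ins <- read_instruments()
  sc <- npa_scores("rt", data.frame(
    instrument = "MoCA", subscore = "total", raw = 22),
    sdi = list(age_band = "65-80", education_band = "5-12"),
    instruments = ins)
  f <- tempfile(fileext = ".json")
  write_npa_scores(sc, f)
  back <- read_npa_scores(f)
  expect_equal(back$patient_id, "rt")
  expect_equal(back$scores$raw, 22)
  expect_equal(back$sdi$age_band, "65-80")
  expect_error(npa_scores("bad", data.frame(
    instrument = "MoCA", subscore = "total", raw = 31), instruments = ins),
    "outside")
})
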