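#' Generate a synthetic patient
#'
#' A synthetic patient carries one latent ability per domain on the 0-100
#' axis, a performance-noise standard deviation, a per-play learning rate,
#' and the slope of its difficulty-performance curve. Severity presets draw
#' abilities uniformly from mild (50-85), moderate (30-65) or severe (10-45)
#' ranges.
#'
#' @param seed integer seed; the same seed always yields the same patient.
#' @param domains character vector of domain names.
#' @param severity one of `"mild"`, `"moderate"`, `"severe"`; ignored when
#'   `abilities` is given.
#' @param abilities optional named numeric of explicit latent abilities in
#'   `[0, 100]`, passed through unchanged.
#' @param noise_sd Gaussian performance noise sd in percent (default 5).
#' @param learning_rate latent ability gained per play training a domain
#'   (default 0: stationary patient).
#' @param slope logistic slope of the difficulty-performance curve on the
#'   1-10 difficulty axis (default 1).
#' @return An object of class `synthetic_patient`.
#' @export
generate_patient <- function(seed, domains,
                             severity = c("moderate", "mild", "severe"),
                             abilities = NULL, noise_sd = 5,
                             learning_rate = 0, slope = 1) {
  stopifnot(noise_sd >= 0, learning_rate >= 0, slope > 0)
  if (is.null(abilities)) {
    severity <- match.arg(severity)
    rng <- switch(severity, mild = c(50, 85), moderate = c(30, 65),
                  severe = c(10, 45))
    ab <- withr_seed(seed, function()
      stats::runif(length(domains), rng[1], rng[2]))
    abilities <- stats::setNames(ab, domains)
  } else {
    abilities <- unlist(abilities)
    if (is.null(names(abilities))) names(abilities) <- domains
    if (any(abilities < 0 | abilities > 100))
      stop("abilities must lie in [0, 100]")
  }
  structure(list(abilities = abilities, noise_sd = noise_sd,
                 learning_rate = learning_rate, slope = slope, seed = seed),
            class = "synthetic_patient")
}

## run f() under a local RNG state seeded with `seed`
withr_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("<synthetic_patient> noise sd ", x$noise_sd, ", learning rate ",
      x$learning_rate, ", slope ", x$slope, "\n", sep = "")
  for (d in names(x$abilities))
    cat(sprintf("  %-24s %5.1f\n", d, x$abilities[[d]]))
  invisible(x)
}

#' Effective ability of a patient on one task, on the 1-10 axis
#'
#' Training-weight-weighted mean of the latent abilities over the task's
#' trained domains, rescaled from 0-100 to the difficulty axis (divided by
#' 10, clamped to `[1, 10]`).
#'
#' @param patient a [generate_patient()] patient.
#' @param ctt a [ctt_model()].
#' @return A scalar in `[1, 10]`.
#' @export
effective_ability <- function(patient, ctt) {
  tw <- ctt$training_weights
  tw <- tw[tw > 0]
  if (length(tw) == 0L) stop("task trains no domain")
  miss <- setdiff(names(tw), names(patient$abilities))
  if (length(miss))
    stop("patient lacks ability for domain(s): ", paste(miss, collapse = ", "))
  a <- sum(tw * patient$abilities[names(tw)]) / sum(tw)
  min(10, max(1, a / 10))
}

#' Simulate one task play
#'
#' Expected performance follows a logistic curve in the gap between the
#' patient's effective ability (on the 1-10 axis) and the task difficulty:
#' `100 * plogis(slope * (ability - difficulty))`, so performance is 50% when
#' difficulty matches ability and decreases as difficulty grows. Gaussian
#' noise is added and the result clipped to `[0, 100]`.
#'
#' @param patient a [generate_patient()] patient.
#' @param ctt a [ctt_model()].
#' @param difficulty difficulty on the 1-10 grid.
#' @return A performance percentage in `[0, 100]`. Randomness comes from the
#'   caller's RNG state; seed it (or wrap the call) for reproducibility.
#' @export
simulate_task_performance <- function(patient, ctt, difficulty) {
  a <- effective_ability(patient, ctt)
  expected <- 100 * stats::plogis(patient$slope * (a - difficulty))
  perf <- expected + stats::rnorm(1, 0, patient$noise_sd)
  max(0, min(100, perf))
}

#' Apply a session's training effect to a patient
#'
#' Each domain gains `learning_rate` latent ability points per play of a
#' task that trains it, capped at 100. Untrained domains are unchanged.
#'
#' @param patient a [generate_patient()] patient.
#' @param record a [run_session()] record (or session log data.frame).
#' @param ctt_models task models for the plays.
#' @return The updated `synthetic_patient`.
#' @export
apply_training_effect <- function(patient, record, ctt_models) {
  log <- if (inherits(record, "session_record")) record$log else
    as.data.frame(record)
  stopifnot(nrow(log) > 0)
  ids <- vapply(ctt_models, `[[`, "", "id")
  for (r in seq_len(nrow(log))) {
    m <- ctt_models[[match(log$task_id[r], ids)]]
    for (d in names(m$training_weights)) {
      if (m$training_weights[[d]] <= 0) next
      patient$abilities[d] <- min(100, patient$abilities[[d]] +
                                    patient$learning_rate)
    }
  }
  patient
}

#' Run a full closed-loop training program against a synthetic patient
#'
#' Repeats, for `sessions` sessions: play the plan (difficulty of each task
#' initialized from the current training profile via the task's training
#' weights), adapt difficulty in-session, summarize the session into a
#' sentence of the profile language, revise the profile by minimal change,
#' and apply the patient's training effect. This is the
#' profiling-selection-adaptation-revision loop run end to end.
#'
#' @param patient a [generate_patient()] patient.
#' @param ctt_models tasks played each session (one play per model per
#'   session repeated `plays_per_task` times).
#' @param initial_profile starting [cog_profile()] on the half-step 1-10
#'   training schema; labels must cover the tasks' trained domains.
#' @param sessions number of sessions (default 12).
#' @param plays_per_task plays of each task per session (default 1).
#' @param config an [adaptation_config()].
#' @param seed integer; all randomness in the program flows from it.
#' @return List with `profile` (final predicted profile), `profiles`
#'   (after each session), `records` (session records), `patient` (final
#'   state), `sentences`.
#' @export
run_program <- function(patient, ctt_models, initial_profile,
                        sessions = 12, plays_per_task = 1,
                        config = adaptation_config(), seed = 1) {
  stopifnot(is_cog_profile(initial_profile))
  profile <- initial_profile
  profiles <- list()
  records <- list()
  sentences <- character()
  withr_seed(seed, function() {
    for (s in seq_len(sessions)) {
      plan <- do.call(rbind, lapply(ctt_models, function(m) {
        d <- attr(initial_parameters(m, profile), "difficulty")
        data.frame(task_id = rep(m$id, plays_per_task), difficulty = d,
                   stringsAsFactors = FALSE)
      }))
      perf_src <- function(task_id, difficulty, play) {
        ids <- vapply(ctt_models, `[[`, "", "id")
        simulate_task_performance(patient,
                                  ctt_models[[match(task_id, ids)]],
                                  difficulty)
      }
      rec <- run_session(plan, perf_src, config,
                         session_id = sprintf("s%02d", s))
      sent <- summarize_to_sentence(rec, ctt_models, profile, config)
      tiebreak <- combined_training_weights(ctt_models)
      pred <- revise_profile(profile, sent, tiebreak_weights = tiebreak,
                             source = rec$session_id)
      profile <<- pred$profile
      profiles[[s]] <<- profile
      records[[s]] <<- rec
      sentences[s] <<- pred$sentence
      patient <<- apply_training_effect(patient, rec, ctt_models)
    }
  })
  list(profile = profile, profiles = profiles, records = records,
       patient = patient, sentences = sentences)
}

combined_training_weights <- function(ctt_models) {
  acc <- numeric(0)
  for (m in ctt_models) {
    for (d in names(m$training_weights)) {
      cur <- if (d %in% names(acc)) acc[[d]] else 0
      acc[d] <- cur + m$training_weights[[d]]
    }
  }
  acc / sum(acc)
}

#' Read / write synthetic patient fixtures
#' @param patient a `synthetic_patient` (writer) or file path (reader).
#' @param path JSON path.
#' @return Writer: `path` invisibly. Reader: the patient.
#' @export
write_patient_json <- function(patient, path) {
  stopifnot(inherits(patient, "synthetic_patient"))
  jsonlite::write_json(
    list(abilities = as.list(patient$abilities), noise_sd = patient$noise_sd,
         learning_rate = patient$learning_rate, slope = patient$slope,
         seed = patient$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_patient_json
#' @export
read_patient_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  generate_patient(seed = if (is.null(doc$seed)) 0 else doc$seed,
                   domains = names(doc$abilities),
                   abilities = unlist(doc$abilities),
                   noise_sd = doc$noise_sd,
                   learning_rate = doc$learning_rate, slope = doc$slope)
}
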