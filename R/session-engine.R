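#' Difficulty adaptation configuration
#'
#' The controller keeps per-task performance inside a challenge band: below
#' the low threshold the difficulty drops by one step, above the high
#' threshold it rises by one step, in between it holds. Defaults are the
#' low = 50% / high = 71% thresholds with 0.5-point steps on the 1-10
#' half-step difficulty grid.
#'
#' @param low,high thresholds in percent, `0 <= low < high <= 100`.
#' @param step difficulty step size; must lie on the grid.
#' @param grid_min,grid_max,grid_step the difficulty grid.
#' @return An object of class `adaptation_config`.
#' @export
adaptation_config <- function(low = 50, high = 71, step = 0.5,
                              grid_min = 1, grid_max = 10, grid_step = 0.5) {
  if (low < 0 || low >= high || high > 100)
    stop("thresholds must satisfy 0 <= low < high <= 100")
  if (step <= 0) stop("step must be positive")
  k <- step / grid_step
  if (abs(k - round(k)) > 1e-8) stop("step must be a multiple of the grid step")
  structure(list(low = low, high = high, step = step,
                 grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step),
            class = "adaptation_config")
}

#' Initial 1-10 training profile and difficulty from screening subscores
#'
#' Screening domain raw scores (attention, memory, executive, language, with
#' maxima 6, 11, 7 and 6 on the 0-30 screening total) are rescaled to the
#' half-step 1-10 training scale as `clamp(round_half(10 * raw / max), 1, 10)`;
#' the initial session difficulty applies the same mapping to the screening
#' total out of 30.
#'
#' @param attention,memory,executive,language raw domain scores.
#' @param total raw screening total; default the sum of the four domains.
#' @return List with `profile` (a [cog_profile()] on the half-step 1-10 grid)
#'   and `difficulty` (a scalar on the same grid).
#' @export
init_difficulty_from_moca <- function(attention, memory, executive, language,
                                      total = attention + memory +
                                        executive + language) {
  maxima <- c(attention = 6, memory = 11, executive = 7, language = 6)
  raw <- c(attention = attention, memory = memory, executive = executive,
           language = language)
  for (d in names(raw)) {
    if (raw[[d]] < 0 || raw[[d]] > maxima[[d]])
      stop("raw ", d, " score ", raw[[d]], " outside [0, ", maxima[[d]], "]")
  }
  if (total < 0 || total > 30) stop("screening total outside [0, 30]")
  to_scale <- function(x, mx) min(10, max(1, snap_half(10 * x / mx)))
  vals <- mapply(to_scale, raw, maxima)
  schema <- profile_schema(names(raw), min = 1, max = 10, step = 0.5)
  list(profile = cog_profile(schema, vals),
       difficulty = to_scale(total, 30))
}

#' One step of the threshold difficulty controller
#'
#' @param current current difficulty, on the grid.
#' @param performance performance percentage in `[0, 100]`.
#' @param config an [adaptation_config()].
#' @return The next difficulty: `current - step` below the low threshold,
#'   `current + step` above the high threshold, unchanged in between;
#'   clamped to the grid bounds.
#' @examples
#' cfg <- adaptation_config()
#' adapt_difficulty(5, 40, cfg)  # 4.5
#' adapt_difficulty(5, 80, cfg)  # 5.5
#' adapt_difficulty(5, 60, cfg)  # 5
#' @export
adapt_difficulty <- function(current, performance, config = adaptation_config()) {
  stopifnot(inherits(config, "adaptation_config"))
  if (performance < 0 || performance > 100)
    stop("performance must be a percentage in [0, 100]")
  nxt <- current
  if (performance < config$low) nxt <- current - config$step
  else if (performance > config$high) nxt <- current + config$step
  min(config$grid_max, max(config$grid_min, nxt))
}

#' Medal awarded for a task performance
#'
#' Band lookup: below 50% no medal, 50-70% copper, above 70 up to 90% silver,
#' above 90% gold. The bands partition `[0, 100]`.
#'
#' @param performance percentage in `[0, 100]`.
#' @return One of `"none"`, `"copper"`, `"silver"`, `"gold"`.
#' @export
award_medal <- function(performance) {
  if (performance < 0 || performance > 100)
    stop("performance must be a percentage in [0, 100]")
  if (performance < 50) "none"
  else if (performance <= 70) "copper"
  else if (performance <= 90) "silver"
  else "gold"
}

#' Points scored for a task
#'
#' Correct actions earn points, errors are never scored negatively, and
#' completing a task with a hint halves the points.
#'
#' @param base_points non-negative points earned.
#' @param hint_used logical.
#' @return Final points (never negative).
#' @export
score_task <- function(base_points, hint_used = FALSE) {
  if (base_points < 0) stop("base points must be non-negative")
  if (isTRUE(hint_used)) base_points / 2 else base_points
}

#' Run one training session's adaptation loop
#'
#' Executes an ordered plan of task plays. Each play asks the performance
#' source for a performance percentage at the task's current difficulty,
#' logs the result, and adapts that task's difficulty (adaptation is
#' per-task, not session-global; set `per_task = FALSE` for the legacy
#' session-mean mode in which every task shares one difficulty updated from
#' the running mean performance).
#'
#' @param plan data.frame with columns `task_id` and `difficulty` (initial
#'   difficulty per task; repeated task ids continue from the adapted
#'   value).
#' @param performance_source function `(task_id, difficulty, play_index)`
#'   returning a performance percentage; typically a simulator closure or a
#'   replay of recorded scores.
#' @param config an [adaptation_config()].
#' @param session_id identifier recorded in the log.
#' @param base_points points available per play.
#' @param per_task adapt each task independently (default) or session-wide.
#' @return A `session_record`: list with the per-play `log` data.frame
#'   (columns `session_id`, `play`, `task_id`, `difficulty`, `performance`,
#'   `medal`, `points`, `hint`), per-task difficulty trajectories and final
#'   difficulties. If the performance source fails, the partial record is
#'   attached to the error condition.
#' @export
run_session <- function(plan, performance_source,
                        config = adaptation_config(),
                        session_id = "s1", base_points = 100,
                        per_task = TRUE) {
  plan <- as.data.frame(plan)
  stopifnot(all(c("task_id", "difficulty") %in% names(plan)),
            nrow(plan) > 0)
  current <- c()
  for (r in seq_len(nrow(plan))) {
    tid <- plan$task_id[r]
    if (is.null(current[tid]) || is.na(current[tid]))
      current[tid] <- plan$difficulty[r]
  }
  log <- data.frame(session_id = character(), play = integer(),
                    task_id = character(), difficulty = numeric(),
                    performance = numeric(), medal = character(),
                    points = numeric(), hint = logical(),
                    stringsAsFactors = FALSE)
  traj <- lapply(stats::setNames(nm = unique(plan$task_id)),
                 function(t) numeric())
  session_mean_d <- plan$difficulty[1]
  for (r in seq_len(nrow(plan))) {
    tid <- plan$task_id[r]
    d <- if (per_task) current[[tid]] else session_mean_d
    perf <- tryCatch(performance_source(tid, d, r), error = function(e) e)
    if (inherits(perf, "error")) {
      cond <- simpleError(paste0("performance source failed at play ", r,
                                 ": ", conditionMessage(perf)))
      cond$partial_record <- structure(
        list(session_id = session_id, log = log, trajectories = traj,
             final = current), class = "session_record")
      stop(cond)
    }
    hint <- isTRUE(attr(perf, "hint"))
    perf <- max(0, min(100, as.numeric(perf)))
    log[nrow(log) + 1L, ] <- list(session_id, r, tid, d, perf,
                                  award_medal(perf),
                                  score_task(base_points, hint), hint)
    traj[[tid]] <- c(traj[[tid]], d)
    if (per_task) current[[tid]] <- adapt_difficulty(d, perf, config)
    else session_mean_d <- adapt_difficulty(d, mean(log$performance), config)
  }
  structure(list(session_id = session_id, log = log, trajectories = traj,
                 final = current, config = config,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat("<session_record> ", x$session_id, ": ", nrow(x$log), " plays, ",
      length(x$trajectories), " tasks\n", sep = "")
  invisible(x)
}

#' Write / read a session log as CSV
#'
#' Stable column order (`session_id`, `play`, `task_id`, `difficulty`,
#' `performance`, `medal`, `points`, `hint`) so downstream profile revision
#' can consume logs from live or simulated sessions alike.
#'
#' @param record a `session_record` (writer) or file path (reader).
#' @param path CSV path.
#' @return Writer: `path` invisibly. Reader: the log data.frame.
#' @export
write_session_csv <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  cols <- c("session_id", "play", "task_id", "difficulty", "performance",
            "medal", "points", "hint")
  utils::write.csv(record$log[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("session_id", "play", "task_id", "difficulty", "performance",
            "medal", "points", "hint")
  if (!all(cols %in% names(log)))
    stop("session CSV must have columns: ", paste(cols, collapse = ", "))
  log[, cols]
}
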