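## Per-kind hard parameter limits for the training task families:
## search (cancellation), organize (action sequencing), categorize, pay
## (calculation), drive (alternating attention). Kinds without published
## limits are unconstrained beyond their own declared bounds.
kind_limits <- list(
  search = list(targets = c(1, 12), elements_per_section = c(1, 20),
                sections = c(1, 8)),
  organize = list(steps = c(2, 12)),
  categorize = list(items = c(2, 60), containers = c(1, 4))
)

#' Construct a cognitive training task model
#'
#' A CTT model records which domains a task trains (coverage ranges on the
#' 0-100 cognitive-status axis and training weights summing to 1), the ADL
#' contexts it is embedded in, its difficulty-parameter bounds, and its
#' nominal play duration.
#'
#' @param id unique task id.
#' @param kind one of `search`, `organize`, `categorize`, `pay`, `drive`.
#' @param contexts character vector of ADL contexts (e.g. `kitchen`).
#' @param coverage named list: domain -> `c(lo, hi)` on `[0, 100]`.
#' @param training_weights named numeric: domain -> fraction; must sum to 1
#'   and name a subset of the coverage domains.
#' @param parameters named list: parameter -> `c(min, max)`; bounds must
#'   respect the task kind's hard limits.
#' @param nominal_minutes nominal duration of one play (default 11).
#' @return An object of class `ctt_model`.
#' @export
ctt_model <- function(id, kind, contexts, coverage, training_weights,
                      parameters = list(), nominal_minutes = 11) {
  kind <- match.arg(kind, c("search", "organize", "categorize", "pay", "drive"))
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  coverage <- lapply(coverage, as.numeric)
  for (d in names(coverage)) {
    r <- coverage[[d]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 100)
      stop("malformed coverage range for domain ", d)
  }
  tw <- unlist(training_weights)
  if (abs(sum(tw) - 1) > 1e-6) stop("training weights must sum to 1")
  if (!all(names(tw) %in% names(coverage)))
    stop("training weights name domains without coverage")
  parameters <- lapply(parameters, as.numeric)
  lim <- kind_limits[[kind]]
  for (p in names(parameters)) {
    b <- parameters[[p]]
    if (length(b) != 2L || b[1] > b[2]) stop("malformed bounds for ", p)
    if (!is.null(lim[[p]]) && (b[1] < lim[[p]][1] || b[2] > lim[[p]][2]))
      stop("bounds for ", p, " exceed the ", kind, " limits [",
           lim[[p]][1], ", ", lim[[p]][2], "]")
  }
  structure(list(id = id, kind = kind, contexts = as.character(contexts),
                 coverage = coverage, training_weights = tw,
                 parameters = parameters,
                 nominal_minutes = as.numeric(nominal_minutes)),
            class = "ctt_model")
}

#' @export
print.ctt_model <- function(x, ...) {
  cat("<ctt_model> ", x$id, " (", x$kind, "; ",
      paste(x$contexts, collapse = ", "), "; ~", x$nominal_minutes,
      " min)\n", sep = "")
  invisible(x)
}

#' Load a CTT repository from JSON
#' @param path JSON file; default is the example repository shipped with the
#'   package.
#' @return A list of [ctt_model()] objects, validated at load.
#' @export
read_ctt_repo <- function(path = system.file("extdata", "ctts.json",
                                             package = "cogrehab")) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  repo <- lapply(doc$tasks, function(t) {
    ctt_model(t$id, t$kind, unlist(t$contexts),
              coverage = lapply(t$coverage, unlist),
              training_weights = t$training_weights,
              parameters = lapply(t$parameters, unlist),
              nominal_minutes = if (is.null(t$nominal_minutes)) 11
                                else t$nominal_minutes)
  })
  ids <- vapply(repo, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate task ids in repository")
  repo
}

#' Define a training objective
#'
#' @param priorities named non-negative numeric: target domain -> priority
#'   weight; at least one must be positive.
#' @param contexts preferred ADL contexts (empty = no context preference).
#' @param sessions,minutes_per_session session budget.
#' @param thresholds `c(low, high)` challenge thresholds in percent,
#'   `0 <= low < high <= 100`.
#' @return An object of class `training_objective`.
#' @export
training_objective <- function(priorities, contexts = character(),
                               sessions = 12, minutes_per_session = 30,
                               thresholds = c(50, 71)) {
  pr <- unlist(priorities)
  if (is.null(names(pr)) || any(!nzchar(names(pr))))
    stop("priorities must be named by domain")
  if (any(pr < 0) || !any(pr > 0))
    stop("priorities must be non-negative with at least one positive")
  if (length(thresholds) != 2L || thresholds[1] < 0 ||
      thresholds[1] >= thresholds[2] || thresholds[2] > 100)
    stop("thresholds must satisfy 0 <= low < high <= 100")
  structure(list(priorities = pr, contexts = as.character(contexts),
                 sessions = sessions,
                 minutes_per_session = minutes_per_session,
                 thresholds = thresholds),
            class = "training_objective")
}

#' Coverage distance between a cognitive-status value and a task's range
#'
#' A per-domain variant of the Hamming distance on a 0-10 axis: 0 when the
#' CS value falls inside the task's covered range; otherwise the gap to the
#' nearest range endpoint after rescaling CS/10, capped at the maximal
#' distance 10; exactly 10 when the task does not cover the domain at all.
#'
#' @param cs_value cognitive-status value in `[0, 100]`.
#' @param coverage_range `c(lo, hi)` on `[0, 100]`, or `NULL` when the
#'   domain is not covered.
#' @return A number in `[0, 10]`.
#' @export
domain_distance <- function(cs_value, coverage_range = NULL) {
  stopifnot(is.numeric(cs_value), cs_value >= 0, cs_value <= 100)
  if (is.null(coverage_range)) return(10)
  r <- as.numeric(coverage_range)
  if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 100)
    stop("malformed coverage range")
  v <- cs_value / 10
  lo <- r[1] / 10
  hi <- r[2] / 10
  if (v >= lo && v <= hi) return(0)
  min(10, if (v < lo) lo - v else v - hi)
}

cs_values <- function(cs) {
  if (inherits(cs, "cognitive_status")) cs$values else unlist(cs)
}

#' Rank training tasks by fit to a patient's cognitive status
#'
#' Each task scores the priority-weighted sum of [domain_distance()] over the
#' objective's target domains; lower is a better match. Ties are broken by
#' lexicographic task id, so the ranking is deterministic.
#'
#' @param cs a `cognitive_status` or named numeric of CS values (0-100).
#' @param objective a [training_objective()].
#' @param repo list of [ctt_model()] objects.
#' @return A data.frame `id`, `score`, ascending by score, with the matched
#'   models in `attr(, "models")` (same order).
#' @export
rank_ctts <- function(cs, objective, repo) {
  stopifnot(inherits(objective, "training_objective"), length(repo) > 0)
  vals <- cs_values(cs)
  pr <- objective$priorities
  miss <- setdiff(names(pr), names(vals))
  if (length(miss))
    stop("cognitive status lacks objective domain(s): ",
         paste(miss, collapse = ", "))
  score_one <- function(m) {
    s <- 0
    for (d in names(pr)) {
      if (pr[[d]] == 0) next
      s <- s + pr[[d]] * domain_distance(vals[[d]], m$coverage[[d]])
    }
    s
  }
  scores <- vapply(repo, score_one, numeric(1))
  ids <- vapply(repo, `[[`, "", "id")
  ord <- order(scores, ids)
  out <- data.frame(id = ids[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "models") <- repo[ord]
  class(out) <- c("ctt_ranking", "data.frame")
  out
}

#' Filter a ranked task list by ADL context and session budget
#'
#' Keeps tasks whose contexts intersect the objective's preferred ADLs (a
#' no-op when no preference is set), then truncates the list so the summed
#' nominal task durations fit within `sessions * minutes_per_session`,
#' preserving rank order.
#'
#' @param ranked a [rank_ctts()] result.
#' @param objective a [training_objective()].
#' @return A filtered `ctt_ranking`; raises a `no_candidate` error when the
#'   filter empties the list.
#' @export
filter_by_context <- function(ranked, objective) {
  models <- attr(ranked, "models")
  keep <- rep(TRUE, length(models))
  if (length(objective$contexts) > 0) {
    keep <- vapply(models, function(m)
      length(intersect(m$contexts, objective$contexts)) > 0, logical(1))
  }
  models <- models[keep]
  out <- ranked[keep, , drop = FALSE]
  budget <- objective$sessions * objective$minutes_per_session
  if (length(models)) {
    mins <- cumsum(vapply(models, `[[`, numeric(1), "nominal_minutes"))
    fit <- mins <= budget
    models <- models[fit]
    out <- out[fit, , drop = FALSE]
  }
  if (length(models) == 0L)
    stop(structure(class = c("no_candidate", "error", "condition"),
                   list(message = "no candidate task survives the context/budget filter",
                        call = sys.call(-1))))
  rownames(out) <- NULL
  attr(out, "models") <- models
  class(out) <- c("ctt_ranking", "data.frame")
  out
}

snap_half <- function(x) round(x * 2) / 2

#' Initial task parameters from a training profile
#'
#' The task difficulty is the training-weight-weighted mean of the profile
#' values over the task's trained domains, snapped to the half-step 1-10
#' grid. Each parameter is then set by linear interpolation of its bounds at
#' `(d - 1) / 9`, so the grid minimum maps to the parameter minimum and 10 to
#' the maximum; count-valued bounds are rounded to integers.
#'
#' @param ctt a [ctt_model()].
#' @param profile a [cog_profile()] on the 1-10 scale covering the task's
#'   trained domains.
#' @return Named list of parameter values, with the chosen difficulty in
#'   `attr(, "difficulty")`; always within bounds.
#' @export
initial_parameters <- function(ctt, profile) {
  stopifnot(inherits(ctt, "ctt_model"), is_cog_profile(profile))
  tw <- ctt$training_weights
  miss <- setdiff(names(tw), profile$schema$labels)
  if (length(miss))
    stop("profile lacks trained domain(s): ", paste(miss, collapse = ", "))
  d <- snap_half(sum(tw * profile$values[names(tw)]) / sum(tw))
  d <- min(10, max(1, d))
  t <- (d - 1) / 9
  params <- lapply(ctt$parameters, function(b) {
    v <- b[1] + t * (b[2] - b[1])
    if (all(b == round(b))) v <- round(v)
    min(b[2], max(b[1], v))
  })
  attr(params, "difficulty") <- d
  params
}

#' Validate a parameter assignment against a task's bounds
#'
#' Violations are returned as data, not raised: each names the parameter,
#' the offending value and the bound.
#'
#' @param ctt a [ctt_model()].
#' @param params named list/vector of parameter values.
#' @return `TRUE` (with zero rows in `attr(, "violations")`) when all bounds
#'   hold, otherwise `FALSE` with a violations data.frame.
#' @export
validate_task_parameters <- function(ctt, params) {
  stopifnot(inherits(ctt, "ctt_model"))
  params <- as.list(params)
  unknown <- setdiff(names(params), names(ctt$parameters))
  if (length(unknown))
    stop("unknown parameter(s) for task ", ctt$id, ": ",
         paste(unknown, collapse = ", "))
  viol <- data.frame(parameter = character(), value = numeric(),
                     bound = character(), stringsAsFactors = FALSE)
  lim <- kind_limits[[ctt$kind]]
  for (p in names(params)) {
    v <- as.numeric(params[[p]])
    b <- ctt$parameters[[p]]
    hard <- lim[[p]]
    lo <- if (is.null(hard)) b[1] else max(b[1], hard[1])
    hi <- if (is.null(hard)) b[2] else min(b[2], hard[2])
    if (v < lo) viol[nrow(viol) + 1L, ] <- list(p, v, paste("min", lo))
    if (v > hi) viol[nrow(viol) + 1L, ] <- list(p, v, paste("max", hi))
  }
  ok <- nrow(viol) == 0L
  attr(ok, "violations") <- viol
  ok
}
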