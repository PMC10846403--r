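#' Summarize a session into per-domain performance means
#'
#' For each domain trained in the session, the training-weight-weighted mean
#' performance across the plays of tasks that train it, together with the
#' play counts. Domains no played task trains are omitted.
#'
#' @param record a [run_session()] record (or a bare session log data.frame).
#' @param ctt_models list of [ctt_model()] objects covering every task id in
#'   the log.
#' @return A data.frame `domain`, `mean_performance`, `plays`, of class
#'   `performance_summary`.
#' @export
summarize_performance <- function(record, ctt_models) {
  log <- if (inherits(record, "session_record")) record$log else
    as.data.frame(record)
  stopifnot(nrow(log) > 0)
  ids <- vapply(ctt_models, `[[`, "", "id")
  acc <- list()
  for (r in seq_len(nrow(log))) {
    m <- ctt_models[[match(log$task_id[r], ids)]]
    if (is.na(match(log$task_id[r], ids)) || is.null(m))
      stop("no model for task ", log$task_id[r])
    for (d in names(m$training_weights)) {
      w <- m$training_weights[[d]]
      if (w <= 0) next
      prev <- acc[[d]]
      if (is.null(prev)) prev <- c(num = 0, den = 0, n = 0)
      prev["num"] <- prev[["num"]] + w * log$performance[r]
      prev["den"] <- prev[["den"]] + w
      prev["n"] <- prev[["n"]] + 1
      acc[[d]] <- prev
    }
  }
  out <- data.frame(
    domain = names(acc),
    mean_performance = vapply(acc, function(a) a[["num"]] / a[["den"]],
                              numeric(1)),
    plays = vapply(acc, function(a) as.integer(a[["n"]]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("performance_summary", "data.frame")
  out
}

#' Translate session performance into a sentence of the profile language
#'
#' For every domain trained in the session, with weighted mean performance
#' `m`: above the high threshold the sentence asserts `domain > current`,
#' below the low threshold `domain < current`, inside the band
#' `domain = current`. The conjunction of these atoms is the input to the
#' minimal-change revision, which therefore moves each trained domain by
#' exactly one grid step (or not at all). Untrained domains are omitted.
#'
#' @param record a [run_session()] record or session log.
#' @param ctt_models task models (see [summarize_performance()]).
#' @param current the current [cog_profile()] on the training schema.
#' @param config an [adaptation_config()] providing the thresholds.
#' @return A `wff`, with the summary attached as `attr(, "summary")`.
#' @export
summarize_to_sentence <- function(record, ctt_models, current,
                                  config = adaptation_config()) {
  stopifnot(is_cog_profile(current))
  summ <- summarize_performance(record, ctt_models)
  unknown <- setdiff(summ$domain, current$schema$labels)
  if (length(unknown))
    stop("session trains domain(s) absent from the profile: ",
         paste(unknown, collapse = ", "))
  atoms <- character(nrow(summ))
  for (r in seq_len(nrow(summ))) {
    d <- summ$domain[r]
    m <- summ$mean_performance[r]
    cur <- current$values[[d]]
    i <- match(d, current$schema$labels)
    # saturate at the grid bounds: a domain already at the scale maximum
    # (minimum) cannot move further up (down), so assert equality there
    at_max <- cur >= current$schema$max[i] - 1e-9
    at_min <- cur <= current$schema$min[i] + 1e-9
    atoms[r] <- if (m > config$high && !at_max) sprintf("%s > %g", d, cur)
      else if (m < config$low && !at_min) sprintf("%s < %g", d, cur)
      else sprintf("%s = %g", d, cur)
  }
  wff <- parse_wff(paste(atoms, collapse = " & "), current$schema)
  attr(wff, "summary") <- summ
  wff
}

## collect the atoms of a pure conjunction-of-atoms sentence; NULL otherwise
conjunct_atoms <- function(wff) {
  if (wff$kind == "atom") {
    if (wff$term$kind != "label") return(NULL)
    return(list(wff))
  }
  if (wff$kind == "and") {
    l <- conjunct_atoms(wff$lhs)
    r <- conjunct_atoms(wff$rhs)
    if (is.null(l) || is.null(r)) return(NULL)
    return(c(l, r))
  }
  NULL
}

## feasible grid values for one label under a set of simple atoms
feasible_values <- function(grid, atoms_for_label) {
  keep <- rep(TRUE, length(grid))
  tol <- 1e-9
  for (a in atoms_for_label) {
    keep <- keep & switch(a$op,
      "="  = abs(grid - a$const) <= tol,
      "<"  = grid < a$const - tol,
      ">"  = grid > a$const + tol,
      "<=" = grid <= a$const + tol,
      ">=" = grid >= a$const - tol)
  }
  grid[keep]
}

#' Revise a profile by minimal change to satisfy a sentence
#'
#' Among the grid profiles satisfying the sentence, returns the one closest
#' to the current profile in unit-weighted L1 distance. Distance ties are
#' broken by preferring the candidate whose change concentrates on domains
#' with higher tiebreak weight (the training weights of the session's
#' tasks), compared lexicographically over domains in descending weight
#' order; remaining ties go to the lexicographically smallest value vector.
#'
#' Sentences that are pure conjunctions of single-label atoms are revised
#' coordinate-wise (each label moves to its nearest feasible grid value),
#' which is equivalent to the exhaustive search for that fragment and does
#' not touch the state-space cap.
#'
#' @param current the current [cog_profile()].
#' @param sentence a `wff` or a string parsed against the profile's schema.
#' @param tiebreak_weights named non-negative per-domain weights (missing
#'   domains count 0); default none.
#' @param cap state-space cap forwarded to [enumerate_models()].
#' @param source optional provenance (e.g. session ids) recorded on the
#'   result.
#' @return A `predicted_profile`: the revised [cog_profile()] plus
#'   provenance (`sentence`, `distance` moved, `source`).
#' @examples
#' s <- profile_schema(c("memory", "attention"), min = 1, max = 10, step = 0.5)
#' p <- cog_profile(s, c(7, 5))
#' revise_profile(p, "memory > 7")$profile
#' @export
revise_profile <- function(current, sentence, tiebreak_weights = NULL,
                           cap = 250000, source = NULL) {
  stopifnot(is_cog_profile(current))
  schema <- current$schema
  if (is.character(sentence)) sentence <- parse_wff(sentence, schema)
  atoms <- conjunct_atoms(sentence)
  if (!is.null(atoms)) {
    new_vals <- current$values
    for (lab in unique(vapply(atoms, function(a) a$term$name, ""))) {
      for_lab <- Filter(function(a) a$term$name == lab, atoms)
      feas <- feasible_values(schema_grid(schema, lab), for_lab)
      if (length(feas) == 0L)
        stop("inconsistent sentence: no grid value of '", lab,
             "' satisfies it")
      gap <- abs(feas - current$values[[lab]])
      # nearest feasible value; equidistant ties to the smaller value,
      # matching the exhaustive search's lexicographic final tiebreak
      new_vals[lab] <- feas[order(gap, feas)][1]
    }
    revised <- cog_profile(schema, new_vals)
  } else {
    models <- enumerate_models(sentence, schema, cap = cap)
    if (length(models) == 0L)
      stop("inconsistent sentence: no grid profile satisfies it")
    dists <- vapply(models, function(m) profile_distance(current, m),
                    numeric(1))
    best <- which(abs(dists - min(dists)) <= 1e-9)
    if (length(best) > 1L && !is.null(tiebreak_weights)) {
      tw <- stats::setNames(rep(0, length(schema$labels)), schema$labels)
      tw[names(tiebreak_weights)] <- unlist(tiebreak_weights)
      ord_lab <- order(-tw, schema$labels)
      keymat <- t(vapply(models[best], function(m) {
        ch <- abs(m$values - current$values)[ord_lab]
        c(-ch, m$values)  # bigger change on heavier domains first
      }, numeric(2 * length(schema$labels))))
      o <- do.call(order, as.data.frame(keymat))
      best <- best[o]
    } else if (length(best) > 1L) {
      valmat <- t(vapply(models[best], `[[`, numeric(length(schema$labels)),
                         "values"))
      best <- best[do.call(order, as.data.frame(valmat))]
    }
    revised <- models[[best[1]]]
  }
  structure(list(profile = revised,
                 sentence = deparse_wff(sentence),
                 distance = profile_distance(current, revised),
                 source = source),
            class = "predicted_profile")
}

#' @export
print.predicted_profile <- function(x, ...) {
  cat("<predicted_profile> moved ", format(x$distance),
      " under \"", x$sentence, "\"\n  ", format(x$profile), "\n", sep = "")
  invisible(x)
}

#' Compare a predicted with a newly assessed profile
#'
#' @param predicted,assessed profiles on the same schema (a
#'   `predicted_profile` is unwrapped).
#' @param weights per-label weights for the aggregate distance (default
#'   unit).
#' @param flag_threshold absolute per-domain divergence above which a domain
#'   is flagged (default 0.5, one half-step).
#' @return A `divergence_report`: per-domain signed differences
#'   (predicted - assessed), the aggregate weighted distance, and the
#'   flagged domains in descending divergence.
#' @export
compare_profiles <- function(predicted, assessed, weights = 1,
                             flag_threshold = 0.5) {
  if (inherits(predicted, "predicted_profile")) predicted <- predicted$profile
  stopifnot(is_cog_profile(predicted), is_cog_profile(assessed))
  if (!same_schema(predicted, assessed))
    stop("profiles are on different schemas")
  diff <- predicted$values - assessed$values
  agg <- profile_distance(predicted, assessed, weights)
  flagged <- names(diff)[abs(diff) >= flag_threshold - 1e-9]
  flagged <- flagged[order(-abs(diff[flagged]))]
  structure(list(differences = diff, aggregate = agg,
                 flagged = flagged, flag_threshold = flag_threshold),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("<divergence_report> aggregate distance ", format(x$aggregate), "\n",
      sep = "")
  for (d in names(x$differences)) {
    cat(sprintf("  %-24s %+5.2f%s\n", d, x$differences[[d]],
                if (d %in% x$flagged) "  *" else ""))
  }
  invisible(x)
}

#' Append a revision event to a JSON-lines audit log
#'
#' @param predicted a `predicted_profile`.
#' @param before the profile that was revised.
#' @param path audit file (created if missing).
#' @return `path`, invisibly.
#' @export
append_revision_audit <- function(predicted, before, path) {
  stopifnot(inherits(predicted, "predicted_profile"))
  line <- jsonlite::toJSON(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    sentence = predicted$sentence,
    before = as.numeric(before$values),
    after = as.numeric(predicted$profile$values),
    labels = before$schema$labels,
    distance = predicted$distance), auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
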