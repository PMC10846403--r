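#' Define a profile schema
#'
#' A profile schema fixes the ordered set of cognitive domain/subdomain labels
#' a profile carries and, for each label, the finite grid of values it may
#' take. Grids are arithmetic sequences `min, min+step, ..., max`; the default
#' is integer steps, while training profiles typically use the half-step
#' 1--10 scale (`min = 1, max = 10, step = 0.5`).
#'
#' @param labels character vector of unique, non-empty label names.
#' @param min,max,step numeric scalars or vectors (recycled to
#'   `length(labels)`) defining each label's value grid. `max - min` must be
#'   an integer multiple of `step`.
#' @param levels optional named list mapping a label to a character vector of
#'   category names; such labels use the integer grid `0..k-1` and values can
#'   be given by name.
#' @return An object of class `profile_schema`.
#' @examples
#' profile_schema(c("age", "weight", "height"), min = 0, max = 200)
#' profile_schema(c("memory", "attention"), min = 1, max = 10, step = 0.5)
#' @export
profile_schema <- function(labels, min = 0, max = 100, step = 1,
                           levels = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("schema needs at least one label")
  if (anyDuplicated(labels)) stop("schema labels must be unique")
  if (any(!nzchar(labels))) stop("schema labels must be non-empty")
  n <- length(labels)
  min <- rep_len(as.numeric(min), n)
  max <- rep_len(as.numeric(max), n)
  step <- rep_len(as.numeric(step), n)
  if (!is.null(levels)) {
    if (is.null(names(levels)) || !all(names(levels) %in% labels))
      stop("names of 'levels' must be schema labels")
    for (lab in names(levels)) {
      i <- match(lab, labels)
      min[i] <- 0
      max[i] <- length(levels[[lab]]) - 1
      step[i] <- 1
    }
  }
  if (any(min > max)) stop("grid min must not exceed max")
  if (any(step <= 0)) stop("grid step must be positive")
  k <- (max - min) / step
  if (any(abs(k - round(k)) > 1e-8))
    stop("(max - min) must be an integer multiple of step")
  structure(
    list(labels = labels, min = min, max = max, step = step,
         levels = levels),
    class = "profile_schema"
  )
}

#' @export
print.profile_schema <- function(x, ...) {
  cat("<profile_schema> ", length(x$labels), " labels\n", sep = "")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-28s [%g, %g] step %g\n",
                x$labels[i], x$min[i], x$max[i], x$step[i]))
  }
  invisible(x)
}

#' Grid values available for one schema label
#' @param schema a `profile_schema`.
#' @param label a label name present in the schema.
#' @return Numeric vector of admissible values, ascending.
#' @export
schema_grid <- function(schema, label) {
  stopifnot(inherits(schema, "profile_schema"))
  i <- match(label, schema$labels)
  if (is.na(i)) stop("unknown label: ", label)
  seq(schema$min[i], schema$max[i], by = schema$step[i])
}

grid_sizes <- function(schema) {
  round((schema$max - schema$min) / schema$step) + 1
}

on_grid <- function(value, min, max, step, tol = 1e-8) {
  if (value < min - tol || value > max + tol) return(FALSE)
  k <- (value - min) / step
  abs(k - round(k)) <= tol
}

#' Construct a profile
#'
#' A profile is an ordered tuple of values, one per schema label, each lying
#' on its label's grid. Categorical labels accept category names, which are
#' mapped to their grid integers.
#'
#' @param schema a [profile_schema()].
#' @param values numeric (or mixed, for categorical labels) vector of
#'   `length(schema$labels)` values; may be named, in which case names must
#'   match the schema labels and order is taken from the schema.
#' @return An object of class `cog_profile`.
#' @examples
#' s <- profile_schema(c("age", "weight", "height"), min = 0, max = 200)
#' john <- cog_profile(s, c(20, 80, 178))
#' @export
cog_profile <- function(schema, values) {
  stopifnot(inherits(schema, "profile_schema"))
  n <- length(schema$labels)
  if (!is.null(names(values))) {
    miss <- setdiff(schema$labels, names(values))
    if (length(miss))
      stop("values missing for label(s): ", paste(miss, collapse = ", "))
    values <- values[schema$labels]
  }
  if (length(values) != n)
    stop("profile needs exactly ", n, " values, got ", length(values))
  vals <- numeric(n)
  for (i in seq_len(n)) {
    v <- values[[i]]
    lab <- schema$labels[i]
    if (is.character(v) && !is.null(schema$levels[[lab]])) {
      j <- match(v, schema$levels[[lab]])
      if (is.na(j)) stop("unknown level '", v, "' for label ", lab)
      v <- j - 1
    }
    v <- as.numeric(v)
    if (!on_grid(v, schema$min[i], schema$max[i], schema$step[i]))
      stop("value ", v, " for label '", lab, "' is off the grid [",
           schema$min[i], ", ", schema$max[i], "] step ", schema$step[i])
    vals[i] <- v
  }
  structure(list(schema = schema, values = stats::setNames(vals, schema$labels)),
            class = "cog_profile")
}

#' @export
print.cog_profile <- function(x, ...) {
  cat("<cog_profile> ≪",
      paste(sprintf("%s=%g", x$schema$labels, x$values), collapse = ", "),
      "≫\n", sep = "")
  invisible(x)
}

#' @export
format.cog_profile <- function(x, ...) {
  paste0("≪", paste(sprintf("%g", x$values), collapse = ", "), "≫")
}

#' @rdname cog_profile
#' @param x object to test.
#' @export
is_cog_profile <- function(x) inherits(x, "cog_profile")

same_schema <- function(p, q) {
  identical(p$schema$labels, q$schema$labels) &&
    isTRUE(all.equal(p$schema$min, q$schema$min)) &&
    isTRUE(all.equal(p$schema$max, q$schema$max)) &&
    isTRUE(all.equal(p$schema$step, q$schema$step))
}

## ---- profile language: AST constructors -----------------------------------

wff_node <- function(kind, ...) structure(list(kind = kind, ...), class = "wff")
term_node <- function(kind, ...) structure(list(kind = kind, ...), class = "wff_term")

#' @export
print.wff <- function(x, ...) {
  cat("<wff> ", deparse_wff(x), "\n", sep = "")
  invisible(x)
}

#' Render a formula back to its surface syntax
#' @param wff a parsed formula.
#' @return A single string in the same ASCII syntax accepted by [parse_wff()].
#' @export
deparse_wff <- function(wff) {
  if (inherits(wff, "wff_term")) return(deparse_term(wff))
  switch(wff$kind,
    atom = paste(deparse_term(wff$term), wff$op, format(wff$const)),
    not  = paste0("!(", deparse_wff(wff$arg), ")"),
    and  = paste0("(", deparse_wff(wff$lhs), " & ", deparse_wff(wff$rhs), ")"),
    stop("unknown wff node: ", wff$kind)
  )
}

deparse_term <- function(t) {
  switch(t$kind,
    label = t$name,
    neg   = paste0("-", deparse_term(t$arg)),
    sum   = paste0("(", deparse_term(t$lhs), " + ", deparse_term(t$rhs), ")"),
    stop("unknown term node: ", t$kind)
  )
}

## ---- tokenizer + recursive-descent parser ---------------------------------

tokenize_wff <- function(text) {
  pats <- c(
    ws     = "^\\s+",
    num    = "^[0-9]+(\\.[0-9]+)?",
    iff    = "^<->",
    imp    = "^->",
    le     = "^<=",
    ge     = "^>=",
    lt     = "^<",
    gt     = "^>",
    eq     = "^=",
    and    = "^&",
    or     = "^\\|",
    not    = "^!",
    plus   = "^\\+",
    minus  = "^-",
    lpar   = "^\\(",
    rpar   = "^\\)",
    ident  = "^[A-Za-z_][A-Za-z0-9_.]*"
  )
  toks <- list()
  pos <- 1L
  rest <- text
  while (nchar(rest) > 0) {
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest))
      if (length(m) == 1L) {
        if (ty != "ws")
          toks[[length(toks) + 1L]] <- list(type = ty, text = m, pos = pos)
        pos <- pos + nchar(m)
        rest <- substring(rest, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop(sprintf("syntax error at position %d: unexpected '%s'",
                   pos, substring(rest, 1, 1)), call. = FALSE)
  }
  toks
}

#' Parse a sentence of the profile language
#'
#' The language has terms (labels, unary minus, sums), atoms comparing a term
#' to a numeric constant with `=`, `<`, `>`, `<=`, `>=`, and the connectives
#' `!` (negation), `&` (conjunction), `|`, `->`, `<->`. Derived connectives
#' are desugared to negation and conjunction at parse time; `<=`/`>=` are kept
#' as primitive comparators with their usual semantics.
#'
#' @param text a single non-empty string, e.g. `"weight >= 90 & height <= 180"`.
#' @param schema the [profile_schema()] the labels must belong to.
#' @return A `wff` AST.
#' @examples
#' s <- profile_schema(c("age", "weight", "height"), min = 0, max = 250)
#' parse_wff("weight >= 90 & height <= 180", s)
#' @export
parse_wff <- function(text, schema) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty formula")
  stopifnot(inherits(schema, "profile_schema"))
  toks <- tokenize_wff(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() {
    t <- peek()
    st$i <- st$i + 1L
    t
  }
  expect <- function(type) {
    t <- peek()
    if (is.null(t))
      stop("syntax error: unexpected end of input, expected ", type,
           call. = FALSE)
    if (t$type != type)
      stop(sprintf("syntax error at position %d: expected %s, got '%s'",
                   t$pos, type, t$text), call. = FALSE)
    advance()
  }

  parse_number <- function() {
    neg <- FALSE
    t <- peek()
    if (!is.null(t) && t$type == "minus") { advance(); neg <- TRUE }
    t <- expect("num")
    v <- as.numeric(t$text)
    if (neg) -v else v
  }

  # term := factor (('+'|'-') factor)*   with a-b read as a + (-b)
  parse_term <- function() {
    lhs <- parse_factor()
    repeat {
      t <- peek()
      if (!is.null(t) && t$type == "plus") {
        advance()
        lhs <- term_node("sum", lhs = lhs, rhs = parse_factor())
      } else if (!is.null(t) && t$type == "minus") {
        advance()
        lhs <- term_node("sum", lhs = lhs,
                         rhs = term_node("neg", arg = parse_factor()))
      } else break
    }
    lhs
  }

  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) stop("syntax error: unexpected end of input", call. = FALSE)
    if (t$type == "minus") {
      advance()
      return(term_node("neg", arg = parse_factor()))
    }
    if (t$type == "lpar") {
      advance()
      inner <- parse_term()
      expect("rpar")
      return(inner)
    }
    if (t$type == "ident") {
      advance()
      if (!(t$text %in% schema$labels))
        stop(sprintf("unknown label '%s' at position %d", t$text, t$pos),
             call. = FALSE)
      return(term_node("label", name = t$text))
    }
    stop(sprintf("syntax error at position %d: unexpected '%s'",
                 t$pos, t$text), call. = FALSE)
  }

  parse_atom_or_group <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "not") {
      advance()
      return(wff_node("not", arg = parse_atom_or_group()))
    }
    if (!is.null(t) && t$type == "lpar") {
      # could be a parenthesized wff or a parenthesized term inside an atom;
      # try wff first, fall back to atom on failure
      save <- st$i
      res <- tryCatch({
        advance()
        inner <- parse_iff()
        expect("rpar")
        inner
      }, error = function(e) NULL)
      if (!is.null(res)) return(res)
      st$i <- save
    }
    term <- parse_term()
    t <- peek()
    if (is.null(t) || !(t$type %in% c("eq", "lt", "gt", "le", "ge")))
      stop(sprintf("syntax error%s: expected comparator after term",
                   if (is.null(t)) "" else paste0(" at position ", t$pos)),
           call. = FALSE)
    advance()
    op <- switch(t$type, eq = "=", lt = "<", gt = ">", le = "<=", ge = ">=")
    wff_node("atom", term = term, op = op, const = parse_number())
  }

  parse_and <- function() {
    lhs <- parse_atom_or_group()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      lhs <- wff_node("and", lhs = lhs, rhs = parse_atom_or_group())
    }
    lhs
  }

  # a | b  ==  !(!a & !b)
  parse_or <- function() {
    lhs <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      rhs <- parse_and()
      lhs <- wff_node("not",
                      arg = wff_node("and",
                                     lhs = wff_node("not", arg = lhs),
                                     rhs = wff_node("not", arg = rhs)))
    }
    lhs
  }

  # a -> b  ==  !(a & !b); right-associative
  parse_imp <- function() {
    lhs <- parse_or()
    t <- peek()
    if (!is.null(t) && t$type == "imp") {
      advance()
      rhs <- parse_imp()
      lhs <- wff_node("not",
                      arg = wff_node("and", lhs = lhs,
                                     rhs = wff_node("not", arg = rhs)))
    }
    lhs
  }

  # a <-> b  ==  (a -> b) & (b -> a)
  parse_iff <- function() {
    lhs <- parse_imp()
    while (!is.null(peek()) && peek()$type == "iff") {
      advance()
      rhs <- parse_imp()
      fwd <- wff_node("not",
                      arg = wff_node("and", lhs = lhs,
                                     rhs = wff_node("not", arg = rhs)))
      bwd <- wff_node("not",
                      arg = wff_node("and", lhs = rhs,
                                     rhs = wff_node("not", arg = lhs)))
      lhs <- wff_node("and", lhs = fwd, rhs = bwd)
    }
    lhs
  }

  res <- parse_iff()
  t <- peek()
  if (!is.null(t))
    stop(sprintf("syntax error at position %d: unexpected trailing '%s'",
                 t$pos, t$text), call. = FALSE)
  res
}

## ---- semantics ------------------------------------------------------------

#' Evaluate a term against a profile
#' @param profile a [cog_profile()].
#' @param term a term AST (e.g. from a parsed atom), or a label name.
#' @return The numeric value of the term.
#' @export
eval_term <- function(profile, term) {
  stopifnot(is_cog_profile(profile))
  if (is.character(term)) term <- term_node("label", name = term)
  switch(term$kind,
    label = {
      v <- profile$values[[term$name]]
      if (is.null(v)) stop("unknown label: ", term$name)
      v
    },
    neg = -eval_term(profile, term$arg),
    sum = eval_term(profile, term$lhs) + eval_term(profile, term$rhs),
    stop("unknown term node: ", term$kind)
  )
}

#' Does a profile satisfy a formula?
#'
#' Classical propositional evaluation: atoms compare the term's value with the
#' constant, negation and conjunction are the usual connectives.
#'
#' @param profile a [cog_profile()].
#' @param wff a parsed formula, or a string parsed against the profile's schema.
#' @return `TRUE` or `FALSE`.
#' @export
satisfies <- function(profile, wff) {
  stopifnot(is_cog_profile(profile))
  if (is.character(wff)) wff <- parse_wff(wff, profile$schema)
  tol <- 1e-9
  switch(wff$kind,
    atom = {
      v <- eval_term(profile, wff$term)
      switch(wff$op,
        "="  = abs(v - wff$const) <= tol,
        "<"  = v < wff$const - tol,
        ">"  = v > wff$const + tol,
        "<=" = v <= wff$const + tol,
        ">=" = v >= wff$const - tol)
    },
    not = !satisfies(profile, wff$arg),
    and = satisfies(profile, wff$lhs) && satisfies(profile, wff$rhs),
    stop("unknown wff node: ", wff$kind)
  )
}

#' Enumerate the grid profiles satisfying a formula
#'
#' Walks the full Cartesian product of the schema's per-label grids and keeps
#' the profiles the formula holds on. The product size is guarded by `cap`.
#'
#' @param wff a parsed formula or a string.
#' @param schema the [profile_schema()] defining the grid.
#' @param cap maximum admissible product of grid sizes (default 250000).
#' @return A list of `cog_profile` models (possibly empty).
#' @export
enumerate_models <- function(wff, schema, cap = 250000) {
  stopifnot(inherits(schema, "profile_schema"))
  if (is.character(wff)) wff <- parse_wff(wff, schema)
  sizes <- grid_sizes(schema)
  total <- prod(sizes)
  if (total > cap)
    stop("state space too large: ", format(total),
         " grid profiles exceeds cap ", format(cap))
  grids <- lapply(schema$labels, function(l) schema_grid(schema, l))
  combos <- do.call(expand.grid,
                    c(stats::setNames(grids, schema$labels),
                      KEEP.OUT.ATTRS = FALSE))
  out <- list()
  for (r in seq_len(nrow(combos))) {
    p <- cog_profile(schema, as.numeric(combos[r, ]))
    if (satisfies(p, wff)) out[[length(out) + 1L]] <- p
  }
  out
}

#' Weighted L1 distance between two profiles
#'
#' `sum_i w_i * |p_i - q_i|` over the shared schema; the distance used both to
#' pick the minimal-change revision and to compare predicted with assessed
#' profiles.
#'
#' @param p,q profiles on the same schema.
#' @param weights non-negative per-label weights, recycled; default unit.
#' @return A non-negative number; 0 iff `p == q` when all weights are positive.
#' @export
profile_distance <- function(p, q, weights = 1) {
  stopifnot(is_cog_profile(p), is_cog_profile(q))
  if (!same_schema(p, q)) stop("profiles are on different schemas")
  w <- rep_len(as.numeric(weights), length(p$values))
  if (any(w < 0)) stop("weights must be non-negative")
  sum(w * abs(p$values - q$values))
}

## ---- JSON round-trip -------------------------------------------------------

#' Serialize / restore schemas and profiles as JSON
#'
#' @param x a `profile_schema` or `cog_profile`.
#' @param path file path; for readers, the file to load.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name profile_json
NULL

#' @rdname profile_json
#' @export
write_profile_json <- function(x, path) {
  if (inherits(x, "profile_schema")) {
    doc <- list(type = "profile_schema", labels = x$labels, min = x$min,
                max = x$max, step = x$step, levels = x$levels)
  } else if (is_cog_profile(x)) {
    doc <- list(type = "cog_profile",
                schema = list(labels = x$schema$labels, min = x$schema$min,
                              max = x$schema$max, step = x$schema$step,
                              levels = x$schema$levels),
                values = as.numeric(x$values))
  } else stop("unsupported object")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname profile_json
#' @export
read_profile_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema_doc <- if (identical(doc$type, "profile_schema")) doc else doc$schema
  lv <- schema_doc$levels
  if (!is.null(lv)) lv <- lapply(lv, as.character)
  schema <- profile_schema(schema_doc$labels, min = schema_doc$min,
                           max = schema_doc$max, step = schema_doc$step,
                           levels = lv)
  if (identical(doc$type, "profile_schema")) return(schema)
  cog_profile(schema, as.numeric(doc$values))
}
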