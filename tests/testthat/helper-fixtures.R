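# Shared fixtures, built in code at test time.

# half-step 1-10 training schema over the four trained domains
training_schema <- function(domains = c("attention", "memory",
                                        "executive_functions", "language")) {
  profile_schema(domains, min = 1, max = 10, step = 0.5)
}

# a task training exactly one domain, fully covering the CS axis
single_domain_task <- function(domain, id = paste0("t_", domain),
                               kind = "search") {
  cov <- list(c(0, 100))
  names(cov) <- domain
  tw <- list(1)
  names(tw) <- domain
  ctt_model(id, kind, contexts = "kitchen", coverage = cov,
            training_weights = tw,
            parameters = list(targets = c(1, 12)))
}

# random small schema for property tests: <= 3 labels, <= 21 grid points each
random_small_schema <- function() {
  n <- sample(1:3, 1)
  labels <- paste0("L", seq_len(n))
  mins <- sample(0:3, n, replace = TRUE)
  steps <- sample(c(0.5, 1), n, replace = TRUE)
  sizes <- sample(2:21, n, replace = TRUE)
  profile_schema(labels, min = mins, max = mins + steps * (sizes - 1),
                 step = steps)
}

random_profile <- function(schema) {
  vals <- vapply(schema$labels, function(l) sample(schema_grid(schema, l), 1),
                 numeric(1))
  cog_profile(schema, vals)
}

# random sentence over a schema: conjunctions of simple atoms, optionally
# wrapped in negation/disjunction so both revision code paths are exercised
random_sentence <- function(schema, n_atoms = sample(1:3, 1),
                            allow_nonconj = TRUE) {
  atom <- function() {
    lab <- sample(schema$labels, 1)
    g <- schema_grid(schema, lab)
    const <- sample(g, 1)
    op <- sample(c("=", "<", ">", "<=", ">="), 1)
    sprintf("%s %s %g", lab, op, const)
  }
  parts <- replicate(n_atoms, atom())
  if (allow_nonconj && stats::runif(1) < 0.3 && length(parts) >= 2) {
    paste0(parts[1], " | ", paste(parts[-1], collapse = " & "))
  } else {
    paste(parts, collapse = " & ")
  }
}

# independent exhaustive revision oracle: full grid scan, minimal L1
# distance, ties to the lexicographically smallest value vector
oracle_revise <- function(current, sentence_text) {
  schema <- current$schema
  wff <- parse_wff(sentence_text, schema)
  grids <- lapply(schema$labels, function(l) schema_grid(schema, l))
  combos <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  best <- NULL
  best_key <- NULL
  for (r in seq_len(nrow(combos))) {
    v <- as.numeric(combos[r, ])
    p <- cog_profile(schema, v)
    if (!satisfies(p, wff)) next
    key <- c(sum(abs(v - current$values)), v)
    if (is.null(best_key) || lex_less(key, best_key)) {
      best <- p
      best_key <- key
    }
  }
  best
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-9) return(TRUE)
    if (a[i] > b[i] + 1e-9) return(FALSE)
  }
  FALSE
}
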