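#' Min-max normalize a raw test score to the 0-100 axis
#'
#' Linear rescaling `100 * (raw - min) / (max - min)`. For reverse-scored
#' instruments (symptom/impairment scales where higher raw scores mean worse
#' functioning) set `higher_is_better = FALSE`, which flips the scale to
#' `100 * (max - raw) / (max - min)` so that 100 always means best observed
#' functioning.
#'
#' @param raw raw score(s), each within `[min, max]`.
#' @param min,max the subscore's published bounds, `min < max`.
#' @param higher_is_better logical; flip the scale when `FALSE`.
#' @return Normalized score(s) in `[0, 100]`.
#' @export
normalize_score <- function(raw, min, max, higher_is_better = TRUE) {
  if (!is.numeric(raw)) stop("raw score must be numeric")
  if (min >= max) stop("degenerate range: min must be below max")
  if (any(raw < min - 1e-9) || any(raw > max + 1e-9))
    stop("raw score ", raw[which(raw < min | raw > max)[1]],
         " outside [", min, ", ", max, "]")
  x <- 100 * (raw - min) / (max - min)
  if (!higher_is_better) x <- 100 - x
  x
}

#' Renormalize raw instrument weights within a domain
#'
#' Each domain/subdomain row of the weight table carries raw percentage
#' weights; for the row to sum to 100% they are renormalized as
#' `w_i / sum(w)`, preserving order.
#'
#' @param raw_weights positive raw weights (percent or fractions alike).
#' @return Fractions summing to 1, same order (names preserved).
#' @examples
#' round(100 * renormalize_weights(c(50, 12.5, 6.25, 4.2)), 2)
#' @export
renormalize_weights <- function(raw_weights) {
  w <- as.numeric(raw_weights)
  if (length(w) == 0L) stop("empty weight list")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite")
  out <- w / sum(w)
  names(out) <- names(raw_weights)
  out
}

## ---- registries and tables ------------------------------------------------

#' Load the NPA instrument registry
#'
#' @param path JSON file; default is the registry shipped with the package.
#' @return A data.frame with columns `instrument`, `subscore`, `min`, `max`,
#'   `higher_is_better`, of class `npa_instruments`.
#' @export
read_instruments <- function(path = system.file("extdata", "instruments.json",
                                                package = "cogrehab")) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(doc$subscores)
  need <- c("instrument", "subscore", "min", "max", "higher_is_better")
  if (!all(need %in% names(df)))
    stop("instruments file must provide columns: ", paste(need, collapse = ", "))
  if (any(df$min >= df$max)) stop("instrument registry: min must be < max")
  key <- paste(df$instrument, df$subscore, sep = "::")
  if (anyDuplicated(key)) stop("duplicate instrument/subscore entries")
  class(df) <- c("npa_instruments", "data.frame")
  df
}

lookup_subscore <- function(instruments, instrument, subscore) {
  i <- which(instruments$instrument == instrument &
               instruments$subscore == subscore)
  if (length(i) != 1L)
    stop("unknown instrument subscore: ", instrument, "/", subscore)
  instruments[i, ]
}

#' Load the domain weight table
#'
#' Reads the expert weight table mapping instrument subscores to cognitive
#' domains/subdomains. Raw percentages are stored verbatim; within-domain
#' renormalized fractions are derived at load time.
#'
#' @param path JSON file; default is the table shipped with the package.
#' @return A data.frame of class `weight_table` with columns `domain`,
#'   `instrument`, `subscore`, `raw_pct`, `printed_pct` (if shipped) and the
#'   derived `weight` (renormalized fraction; sums to 1 within each domain).
#' @export
read_weight_table <- function(path = system.file("extdata", "weights.json",
                                                 package = "cogrehab")) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(doc$entries)
  need <- c("domain", "instrument", "subscore", "raw_pct")
  if (!all(need %in% names(df)))
    stop("weight table must provide columns: ", paste(need, collapse = ", "))
  if (any(df$raw_pct <= 0)) stop("raw weights must be positive")
  df$weight <- stats::ave(df$raw_pct, df$domain,
                          FUN = function(w) w / sum(w))
  chk <- tapply(df$weight, df$domain, sum)
  stopifnot(all(abs(chk - 1) < 1e-9))
  class(df) <- c("weight_table", "data.frame")
  df
}

#' @export
print.weight_table <- function(x, ...) {
  cat("<weight_table> ", length(unique(x$domain)), " domains, ",
      nrow(x), " weighted subscores\n", sep = "")
  invisible(x)
}

#' Read/write a patient's raw NPA scores
#'
#' The scores document carries a patient id, a socio-demographic record (age
#' band, education band, plus free keys) and a flat list of
#' (instrument, subscore, raw) observations. Absent subscores are simply
#' omitted; aggregation renormalizes over what is present.
#'
#' @param path JSON file.
#' @param scores for the writer, an `npa_scores` object (see
#'   [npa_scores()]).
#' @return Reader: an `npa_scores` object. Writer: `path`, invisibly.
#' @name npa_scores_io
NULL

#' Construct an NPA score set
#' @param patient_id identifier string.
#' @param scores data.frame with columns `instrument`, `subscore`, `raw`.
#' @param sdi named list of socio-demographic keys; `age_band` and
#'   `education_band` select normative strata.
#' @param instruments registry used to range-check raw scores (optional).
#' @return An object of class `npa_scores`.
#' @export
npa_scores <- function(patient_id, scores, sdi = list(),
                       instruments = NULL) {
  scores <- as.data.frame(scores)
  need <- c("instrument", "subscore", "raw")
  if (!all(need %in% names(scores)))
    stop("scores need columns: ", paste(need, collapse = ", "))
  if (!is.null(instruments)) {
    for (r in seq_len(nrow(scores))) {
      reg <- lookup_subscore(instruments, scores$instrument[r],
                             scores$subscore[r])
      if (scores$raw[r] < reg$min - 1e-9 || scores$raw[r] > reg$max + 1e-9)
        stop("raw score ", scores$raw[r], " for ", scores$instrument[r], "/",
             scores$subscore[r], " outside [", reg$min, ", ", reg$max, "]")
    }
  }
  structure(list(patient_id = as.character(patient_id), scores = scores,
                 sdi = sdi),
            class = "npa_scores")
}

#' @rdname npa_scores_io
#' @export
read_npa_scores <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  npa_scores(doc$patient_id, as.data.frame(doc$scores),
             sdi = as.list(doc$sdi))
}

#' @rdname npa_scores_io
#' @export
write_npa_scores <- function(scores, path) {
  stopifnot(inherits(scores, "npa_scores"))
  jsonlite::write_json(
    list(patient_id = scores$patient_id, scores = scores$scores,
         sdi = scores$sdi),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a normative table
#'
#' @param path JSON file; the default is a clearly labelled synthetic table
#'   shipped for demonstration, with raw-scale means and standard deviations
#'   stratified by age band and education band.
#' @return A data.frame of class `normative_table`.
#' @export
read_normative_table <- function(path = system.file(
                                   "extdata", "normative_synthetic.json",
                                   package = "cogrehab")) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(doc$strata)
  need <- c("instrument", "subscore", "age_band", "education_band", "mean", "sd")
  if (!all(need %in% names(df)))
    stop("normative table must provide columns: ", paste(need, collapse = ", "))
  if (any(df$sd <= 0)) stop("normative sd must be positive")
  class(df) <- c("normative_table", "data.frame")
  df
}

normative_stratum <- function(normative, instrument, subscore, sdi) {
  i <- which(normative$instrument == instrument &
               normative$subscore == subscore &
               normative$age_band == sdi$age_band &
               normative$education_band == sdi$education_band)
  if (length(i) != 1L)
    stop("no normative stratum for ", instrument, "/", subscore,
         " at SDI (", sdi$age_band, ", ", sdi$education_band,
         "): unstratified SDI")
  normative[i, ]
}

## ---- ACP ------------------------------------------------------------------

#' Aggregate raw NPA scores into the Assessed Cognitive Profile
#'
#' For each domain/subdomain of the weight table, the ACP value is the
#' weighted sum of the min-max normalized available subscores, with the raw
#' weights renormalized over the entries that are actually present. Domains
#' with no available subscore are reported absent, never imputed.
#'
#' @param scores an [npa_scores()] object.
#' @param weights a [read_weight_table()] table.
#' @param instruments a [read_instruments()] registry.
#' @return An object of class `acp`: named values in `[0, 100]` (NA for
#'   absent domains) plus an `absent` character vector.
#' @export
compute_acp <- function(scores, weights, instruments) {
  stopifnot(inherits(scores, "npa_scores"), inherits(weights, "weight_table"))
  have <- paste(scores$scores$instrument, scores$scores$subscore, sep = "::")
  domains <- unique(weights$domain)
  values <- stats::setNames(rep(NA_real_, length(domains)), domains)
  used <- list()
  for (d in domains) {
    rows <- weights[weights$domain == d, ]
    key <- paste(rows$instrument, rows$subscore, sep = "::")
    avail <- key %in% have
    if (!any(avail)) next
    rows <- rows[avail, ]
    w <- renormalize_weights(rows$raw_pct)
    acc <- 0
    for (r in seq_len(nrow(rows))) {
      reg <- lookup_subscore(instruments, rows$instrument[r], rows$subscore[r])
      raw <- scores$scores$raw[match(paste(rows$instrument[r],
                                           rows$subscore[r], sep = "::"),
                                     have)]
      acc <- acc + w[r] * normalize_score(raw, reg$min, reg$max,
                                          reg$higher_is_better)
    }
    values[d] <- acc
    used[[d]] <- rows[, c("domain", "instrument", "subscore", "raw_pct")]
  }
  structure(list(values = values,
                 absent = domains[is.na(values)],
                 contributing = used,
                 patient_id = scores$patient_id),
            class = "acp")
}

#' @export
print.acp <- function(x, ...) {
  cat("<acp> patient ", x$patient_id, "\n", sep = "")
  pres <- x$values[!is.na(x$values)]
  for (d in names(pres)) cat(sprintf("  %-38s %6.2f\n", d, pres[[d]]))
  if (length(x$absent))
    cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

## ---- Cognitive Status -----------------------------------------------------

#' Contextualize an ACP against normative data: the Cognitive Status
#'
#' The SDI-expected normalized score for a domain is the weighted sum of the
#' normalized stratum means of the instruments contributing to it. The
#' default (`method = "mean"`) anchors the patient's relative standing by
#' cross-multiplication: `CS_k = 100 * ACP_k / (2 * expected_k)`, clipped to
#' `[0, 100]`, so an ACP equal to the group average scores 50 (the
#' 50th-percentile anchor). `method = "zscore"` instead reports the normal
#' percentile of the ACP within the stratum,
#' `100 * pnorm((ACP_k - expected_k) / sd_k)`, with the stratum sd pooled on
#' the normalized scale.
#'
#' @param acp a [compute_acp()] result.
#' @param normative a [read_normative_table()] table.
#' @param sdi the patient's socio-demographic record (list with `age_band`,
#'   `education_band`).
#' @param weights the [read_weight_table()] used for the ACP; supplies which
#'   instruments contribute to each domain and their relative weights.
#' @param instruments a [read_instruments()] registry.
#' @param method `"mean"` (default) or `"zscore"`.
#' @return An object of class `cognitive_status`: named values in `[0, 100]`
#'   (NA where the ACP was absent), plus the per-domain expected scores.
#' @export
compute_cs <- function(acp, normative, sdi, weights, instruments,
                       method = c("mean", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(acp, "acp"))
  domains <- names(acp$values)
  cs <- stats::setNames(rep(NA_real_, length(domains)), domains)
  expected <- cs
  for (d in domains) {
    if (is.na(acp$values[[d]])) next
    # normalize over the subscores that actually contributed to the ACP
    rows <- if (!is.null(acp$contributing[[d]])) acp$contributing[[d]]
            else weights[weights$domain == d, ]
    w <- renormalize_weights(rows$raw_pct)
    exp_k <- 0
    var_k <- 0
    for (r in seq_len(nrow(rows))) {
      reg <- lookup_subscore(instruments, rows$instrument[r], rows$subscore[r])
      st <- normative_stratum(normative, rows$instrument[r],
                              rows$subscore[r], sdi)
      norm_mean <- normalize_score(st$mean, reg$min, reg$max,
                                   reg$higher_is_better)
      norm_sd <- 100 * st$sd / (reg$max - reg$min)
      exp_k <- exp_k + w[r] * norm_mean
      var_k <- var_k + (w[r] * norm_sd)^2
    }
    expected[d] <- exp_k
    cs[d] <- switch(method,
      mean = {
        if (exp_k <= 0) stop("degenerate expected score for domain ", d)
        max(0, min(100, 100 * acp$values[[d]] / (2 * exp_k)))
      },
      zscore = 100 * stats::pnorm((acp$values[[d]] - exp_k) / sqrt(var_k))
    )
  }
  structure(list(values = cs, expected = expected, method = method,
                 patient_id = acp$patient_id),
            class = "cognitive_status")
}

#' @export
print.cognitive_status <- function(x, ...) {
  cat("<cognitive_status> (", x$method, "-anchored) patient ",
      x$patient_id, "\n", sep = "")
  pres <- x$values[!is.na(x$values)]
  for (d in names(pres)) cat(sprintf("  %-38s %6.1f\n", d, pres[[d]]))
  invisible(x)
}

## ---- simplified (five macro-domain) profiling -----------------------------

#' Load the simplified profiling scheme
#' @param path JSON file; default is the scheme shipped with the package.
#' @return The parsed scheme (class `simple_scheme`).
#' @export
read_table3_scheme <- function(path = system.file(
                                 "extdata", "table3_scheme.json",
                                 package = "cogrehab")) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(doc, class = "simple_scheme")
}

#' Compute the simplified five macro-domain profile
#'
#' Each performance-based subscore is min-max normalized to the 0-10 scale;
#' subdomain scores are the mean of their available entries and macro-domain
#' scores the mean of their available subdomains. Macro-domains with no
#' scorable entry are reported absent.
#'
#' @param scores an [npa_scores()] object.
#' @param scheme a [read_table3_scheme()] scheme.
#' @return An object of class `simple_profile`: named values on `[0, 10]`
#'   (NA for absent macro-domains).
#' @export
compute_simple_profile <- function(scores, scheme = read_table3_scheme()) {
  stopifnot(inherits(scores, "npa_scores"))
  have <- paste(scores$scores$instrument, scores$scores$subscore, sep = "::")
  out <- c()
  for (macro in scheme$macro_domains) {
    sub_scores <- c()
    for (sub in macro$subdomains) {
      entry_scores <- c()
      for (e in sub$entries) {
        k <- match(paste(e$instrument, e$subscore, sep = "::"), have)
        if (is.na(k)) next
        raw <- scores$scores$raw[k]
        entry_scores <- c(entry_scores,
                          normalize_score(raw, e$min, e$max) / 10)
      }
      if (length(entry_scores)) sub_scores <- c(sub_scores, mean(entry_scores))
    }
    out[macro$name] <- if (length(sub_scores)) mean(sub_scores) else NA_real_
  }
  structure(list(values = out, absent = names(out)[is.na(out)],
                 patient_id = scores$patient_id),
            class = "simple_profile")
}

#' @export
print.simple_profile <- function(x, ...) {
  cat("<simple_profile> patient ", x$patient_id, " (0-10 scale)\n", sep = "")
  pres <- x$values[!is.na(x$values)]
  for (d in names(pres)) cat(sprintf("  %-24s %5.2f\n", d, pres[[d]]))
  if (length(x$absent))
    cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Snap a continuous profile onto the half-step 1-10 training grid
#'
#' @param x a `simple_profile`, or a named numeric vector of per-domain
#'   values on a 0-10 (or 0-100, see `from100`) axis.
#' @param from100 divide values by 10 first (for cognitive-status inputs).
#' @return A [cog_profile()] on the half-step 1-10 grid over the present
#'   domains.
#' @export
as_training_profile <- function(x, from100 = FALSE) {
  vals <- if (inherits(x, c("simple_profile", "acp", "cognitive_status")))
    x$values else x
  vals <- vals[!is.na(vals)]
  if (from100) vals <- vals / 10
  snapped <- pmin(10, pmax(1, round(vals * 2) / 2))
  schema <- profile_schema(names(vals), min = 1, max = 10, step = 0.5)
  cog_profile(schema, snapped)
}
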