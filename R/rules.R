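# Expert knowledge-based decision model: banded rules scoring the derived
# workload ratios into {0, 3, 7, 10}, mean aggregation, 6.5 injury cutoff.

.rule_scores <- c(0, 3, 7, 10)

#' Construct a banded expert rule
#'
#' A rule maps one derived variable onto a score in \{0, 3, 7, 10\} through
#' an ordered list of bands that must partition the whole real line with no
#' overlap and no gap (adjacent bands share an endpoint that is closed on
#' exactly one side).
#'
#' @param name Rule name (conventionally `RULE_*`).
#' @param variable Name of the derived variable the rule scores.
#' @param bands Data frame with columns `lower`, `upper`, `lower_closed`,
#'   `upper_closed`, `score`.
#' @return A `band_rule` object.
#' @export
band_rule <- function(name, variable, bands) {
  req <- c("lower", "upper", "lower_closed", "upper_closed", "score")
  if (!is.data.frame(bands) || !all(req %in% names(bands)))
    stop("validation error: bands must have columns ",
         paste(req, collapse = ", "))
  b <- bands[order(bands$lower, bands$upper), req, drop = FALSE]
  rownames(b) <- NULL
  if (!all(b$score %in% .rule_scores))
    stop("validation error: scores must be in {0, 3, 7, 10}")
  if (any(b$lower >= b$upper))
    stop("validation error: empty or inverted band")
  if (b$lower[1L] != -Inf || b$upper[nrow(b)] != Inf)
    stop("validation error: bands must cover the whole real line")
  if (nrow(b) > 1L) {
    for (i in seq_len(nrow(b) - 1L)) {
      if (b$upper[i] < b$lower[i + 1L])
        stop("validation error: gap between bands at ", b$upper[i])
      if (b$upper[i] > b$lower[i + 1L])
        stop("validation error: overlapping bands at ", b$lower[i + 1L])
      if (b$upper_closed[i] == b$lower_closed[i + 1L])
        stop("validation error: boundary ", b$upper[i],
             " must be closed on exactly one side")
    }
  }
  structure(list(name = name, variable = variable, bands = b),
            class = "band_rule")
}

# the printed ACWR band geometry, reused for the other expert rules
.acwr_band_geometry <- function() {
  data.frame(
    lower        = c(-Inf, 0.50, 0.70, 0.80, 1.30, 1.40, 1.60),
    upper        = c(0.50, 0.70, 0.80, 1.30, 1.40, 1.60, Inf),
    lower_closed = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    upper_closed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    score        = c(10, 7, 3, 0, 3, 7, 10)
  )
}

#' Default six-rule expert ruleset
#'
#' Ships `RULE_ACWR` with the published band geometry (safe in
#' \[0.80, 1.30\], escalating to 10 beyond 1.60 or below 0.50) and five
#' companion rules applying the same geometry to the analogous derived
#' ratios. Every band is overridable via [band_rule()] /
#' [write_ruleset()].
#'
#' @return An `injury_ruleset`: a named list of six [band_rule()] objects.
#' @export
default_ruleset <- function() {
  geom <- .acwr_band_geometry()
  vars <- c(RULE_ACWR = "REG_ACWR",
            RULE_HSR_R1 = "REG_HSR_R1_A",
            RULE_SPRINT_R1 = "REG_Sprint_R1_A",
            RULE_HSR_R2 = "REG_HSR_R2",
            RULE_SPRINT_R2 = "REG_Sprint_R2",
            RULE_ACC_DEC = "REG_ACC_DEC")
  rules <- lapply(names(vars), function(nm) band_rule(nm, vars[[nm]], geom))
  names(rules) <- names(vars)
  structure(rules, class = "injury_ruleset")
}

#' Score one value through a banded rule
#'
#' @param rule A [band_rule()].
#' @param value Numeric vector; `NA` values give `NA` scores (the rule is
#'   then excluded from the aggregate).
#' @return Numeric vector of scores in \{0, 3, 7, 10\} (or `NA`).
#' @export
score_rule <- function(rule, value) {
  if (!inherits(rule, "band_rule")) stop("expected a band_rule")
  out <- rep(NA_real_, length(value))
  b <- rule$bands
  for (i in seq_len(nrow(b))) {
    lo <- if (b$lower_closed[i]) value >= b$lower[i] else value > b$lower[i]
    hi <- if (b$upper_closed[i]) value <= b$upper[i] else value < b$upper[i]
    hit <- !is.na(value) & lo & hi
    out[hit] <- b$score[i]
  }
  out
}

#' Binary decision from an aggregated rule score
#'
#' @param mean_score Aggregated rule score(s) on \[0, 10\].
#' @param cutoff Decision cutoff; scores at least equal to it are flagged
#'   as injuries (inclusive, default 6.5).
#' @return Integer vector in \{0, 1\} (`NA` preserved).
#' @export
classify_mean_score <- function(mean_score, cutoff = 6.5) {
  as.integer(mean_score >= cutoff)
}

#' Evaluate a ruleset on one observation
#'
#' Scores every rule on its derived variable, aggregates the available
#' (non-missing) scores and applies the decision cutoff. All rules carry
#' equal weight.
#'
#' @param derived A one-row data frame or named list with the `REG_*`
#'   variables the ruleset references.
#' @param ruleset An `injury_ruleset` (default [default_ruleset()]).
#' @param cutoff Decision cutoff on the aggregate (default 6.5, inclusive).
#' @param aggregation `"mean"` (default), or the alternatives `"max"` and
#'   `"mode"` kept for comparison; `mode` breaks frequency ties towards the
#'   higher score.
#' @return A `rule_verdict`: list with `scores` (named), `mean_score` (the
#'   aggregate) and `decision` in \{0, 1\}.
#' @export
evaluate_rules <- function(derived, ruleset = default_ruleset(),
                           cutoff = 6.5,
                           aggregation = c("mean", "max", "mode")) {
  aggregation <- match.arg(aggregation)
  if (length(ruleset) == 0L) stop("validation error: empty ruleset")
  scores <- vapply(ruleset, function(r) {
    if (!r$variable %in% names(derived))
      stop("unknown variable '", r$variable, "' for rule ", r$name)
    as.numeric(derived[[r$variable]][1L])
  }, numeric(1))
  scores <- vapply(seq_along(ruleset), function(i)
    score_rule(ruleset[[i]], scores[i]), numeric(1))
  names(scores) <- vapply(ruleset, `[[`, character(1), "name")
  avail <- scores[!is.na(scores)]
  if (length(avail) == 0L)
    stop("undecidable: all rule scores are missing")
  agg <- switch(aggregation,
                mean = mean(avail),
                max = max(avail),
                mode = {
                  tab <- table(avail)
                  cand <- as.numeric(names(tab)[tab == max(tab)])
                  max(cand)
                })
  structure(list(scores = scores, mean_score = agg,
                 decision = classify_mean_score(agg, cutoff)),
            class = "rule_verdict")
}

#' Apply a ruleset to a whole feature table
#'
#' Vectorized version of [evaluate_rules()]: appends one score column per
#' rule, the aggregate `rule_mean` over available scores, and the binary
#' `rule_decision`. Rows where every rule score is missing get `NA`
#' aggregate and decision.
#'
#' @param features Feature table with the `REG_*` columns (see
#'   [compute_derived()]).
#' @inheritParams evaluate_rules
#' @return `features` with the rule columns appended.
#' @export
apply_ruleset <- function(features, ruleset = default_ruleset(),
                          cutoff = 6.5) {
  if (length(ruleset) == 0L) stop("validation error: empty ruleset")
  sc <- sapply(ruleset, function(r) {
    if (!r$variable %in% names(features))
      stop("unknown variable '", r$variable, "' for rule ", r$name)
    score_rule(r, features[[r$variable]])
  })
  sc <- matrix(sc, nrow = nrow(features),
               dimnames = list(NULL, names(ruleset)))
  for (nm in colnames(sc)) features[[nm]] <- sc[, nm]
  m <- rowMeans(sc, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  features$rule_mean <- m
  features$rule_decision <- classify_mean_score(m, cutoff)
  features
}

#' Write a ruleset to a JSON config file
#'
#' @param ruleset An `injury_ruleset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  ser <- lapply(unclass(ruleset), function(r) {
    b <- r$bands
    list(name = r$name, variable = r$variable,
         bands = lapply(seq_len(nrow(b)), function(i) list(
           lower = as.character(b$lower[i]),
           upper = as.character(b$upper[i]),
           lower_closed = b$lower_closed[i],
           upper_closed = b$upper_closed[i],
           score = b$score[i])))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a ruleset from a JSON config file
#'
#' Band validity (full coverage, no overlap, scores in \{0, 3, 7, 10\}) is
#' re-checked on load.
#'
#' @param path Path written by [write_ruleset()] (or hand-edited).
#' @return An `injury_ruleset`.
#' @export
load_ruleset <- function(path) {
  ser <- jsonlite::read_json(path)
  if (length(ser) == 0L)
    stop("validation error: ruleset file defines no rules")
  rules <- lapply(ser, function(r) {
    b <- do.call(rbind, lapply(r$bands, function(x) data.frame(
      lower = as.numeric(x$lower), upper = as.numeric(x$upper),
      lower_closed = isTRUE(x$lower_closed),
      upper_closed = isTRUE(x$upper_closed),
      score = as.numeric(x$score))))
    band_rule(r$name, r$variable, b)
  })
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  structure(rules, class = "injury_ruleset")
}
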