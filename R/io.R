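# CSV schema validation and the umbrella pipeline runner.

#' Schema of the session-level CSV
#'
#' @return A schema list consumable by [validate_schema()].
#' @export
session_schema <- function() {
  list(name = "sessions",
       required = .session_cols,
       types = c(player_id = "character", position = "character",
                 microcycle = "numeric", session_type = "character",
                 duration_min = "numeric", total_distance_m = "numeric",
                 hsr_m = "numeric", sprint_m = "numeric",
                 player_load = "numeric", accelerations = "numeric",
                 decelerations = "numeric"),
       nonneg = c("duration_min", "total_distance_m", "hsr_m", "sprint_m",
                  "player_load", "accelerations", "decelerations"),
       allowed_patterns = character())
}

#' Schema of the player-microcycle feature CSV
#'
#' Lag columns (`*_-1`, `*_-2`, ...), derived `REG_*` variables and rule
#' score columns are recognized by pattern.
#'
#' @return A schema list consumable by [validate_schema()].
#' @export
feature_schema <- function() {
  mets <- as.vector(outer(c("mc_", "md_"), names(.metric_map), paste0))
  list(name = "features",
       required = c("player_id", "position", "round", "mc_Microcycle",
                    "Injury", "TotalTrainingTime", "TotalGameTime",
                    "Games", "PlayInMatch", mets),
       types = c(player_id = "character", position = "character",
                 setNames(rep("numeric", 7 + length(mets)),
                          c("round", "mc_Microcycle", "Injury",
                            "TotalTrainingTime", "TotalGameTime", "Games",
                            "PlayInMatch", mets))),
       nonneg = c("TotalTrainingTime", "TotalGameTime", "Games", mets),
       allowed_patterns = c("^(mc|md)_[A-Za-z]+_-[0-9]+$", "^REG_",
                            "^RULE_", "^rule_mean$", "^rule_decision$",
                            "^fuzzy_load$", "^fuzzy_decision$"))
}

#' Validate a table against a schema
#'
#' Checks column presence, types, unexpected columns (those matching none
#' of the schema's allowed patterns) and non-negativity, reporting every
#' problem found, with row indices for cell-level violations.
#'
#' @param table Data frame to validate.
#' @param schema A schema list ([session_schema()], [feature_schema()]).
#' @param stop_on_error Stop with the full report (default), or return it.
#' @return `TRUE` invisibly when valid; otherwise a character vector of
#'   problems (if `stop_on_error = FALSE`).
#' @export
validate_schema <- function(table, schema, stop_on_error = TRUE) {
  problems <- character()
  miss <- setdiff(schema$required, names(table))
  if (length(miss))
    problems <- c(problems,
                  paste0("missing column: ", miss))
  extra <- setdiff(names(table), schema$required)
  if (length(extra) && length(schema$allowed_patterns)) {
    ok <- Reduce(`|`, lapply(schema$allowed_patterns, grepl, x = extra))
    extra <- extra[!ok]
  }
  if (length(extra))
    problems <- c(problems, paste0("unexpected column: ", extra))
  for (cl in intersect(names(schema$types), names(table))) {
    want <- schema$types[[cl]]
    got_ok <- switch(want,
                     numeric = is.numeric(table[[cl]]) ||
                       all(is.na(table[[cl]])),
                     character = is.character(table[[cl]]) ||
                       is.factor(table[[cl]]))
    if (!got_ok)
      problems <- c(problems, paste0("column '", cl, "' should be ", want,
                                     ", is ", class(table[[cl]])[1]))
  }
  for (cl in intersect(schema$nonneg, names(table))) {
    if (!is.numeric(table[[cl]])) next
    bad <- which(!is.na(table[[cl]]) & table[[cl]] < 0)
    if (length(bad))
      problems <- c(problems,
                    paste0("negative value in '", cl, "' at row(s) ",
                           paste(head(bad, 10L), collapse = ", ")))
  }
  if (length(problems)) {
    if (stop_on_error)
      stop("schema validation failed for '", schema$name, "':\n  ",
           paste(problems, collapse = "\n  "))
    return(problems)
  }
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed; each stochastic stage derives its own seed
#'   from it by a fixed offset so stages are independently reproducible.
#' @param sim A [simulation_config()]; its seed is overridden by `seed`.
#' @param ml An [ml_config()]; its seed is derived from `seed`.
#' @param ruleset An `injury_ruleset`.
#' @param kb A `fuzzy_kb`.
#' @param stages Named logical vector toggling `rules`, `fuzzy`, `ml`,
#'   `evaluate` (simulation and feature building always run).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = simulation_config(),
                            ml = ml_config(),
                            ruleset = default_ruleset(),
                            kb = default_knowledge_base(),
                            stages = c(rules = TRUE, fuzzy = TRUE,
                                       ml = TRUE, evaluate = TRUE)) {
  sim$seed <- as.integer(seed)
  ml$seed <- as.integer(seed) + 1000L
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 ml = ml, ruleset = ruleset, kb = kb, stages = stages),
            class = "pipeline_config")
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline: simulate, featurize, score, classify, evaluate
#'
#' Executes the stages in order, writes every intermediate table as CSV
#' into `config$out_dir` and finishes with a manifest (seed, config hash,
#' file checksums). Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory artifacts (`features`,
#'   `profiles`, rule/fuzzy/ml outputs, `comparison`, `manifest`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  paths <- character()
  emit <- function(df, file) {
    p <- file.path(config$out_dir, file)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  st <- config$stages
  sessions <- .run_stage("simulate", simulate_sessions(config$sim))
  labels <- .run_stage("simulate", assign_injuries(sessions, config$sim))
  .run_stage("simulate", validate_schema(sessions, session_schema()))
  emit(sessions, "sessions.csv")
  emit(labels, "labels.csv")

  feats <- .run_stage("featurize", {
    f <- aggregate_microcycle(sessions, labels,
                              round_boundary = config$sim$round_boundary)
    compute_derived(add_lags(f, depth = 3L))
  })
  .run_stage("featurize", validate_schema(feats, feature_schema()))
  profiles <- .run_stage("featurize", build_player_profile(feats))
  emit(feats, "features.csv")
  emit(profiles, "profiles.csv")
  out$features <- feats
  out$profiles <- profiles

  scored <- feats
  if (isTRUE(st[["rules"]])) {
    scored <- .run_stage("rules", apply_ruleset(scored, config$ruleset))
    emit(scored[, c("player_id", "mc_Microcycle",
                    grep("^RULE_|^rule_", names(scored), value = TRUE))],
         "rule_verdicts.csv")
    out$rules <- scored
  }
  if (isTRUE(st[["fuzzy"]])) {
    scored <- .run_stage("fuzzy", apply_fuzzy(scored, config$kb))
    emit(scored[, c("player_id", "mc_Microcycle", "fuzzy_load",
                    "fuzzy_decision")], "fuzzy_decisions.csv")
    out$fuzzy <- scored
  }
  if (isTRUE(st[["ml"]])) {
    parts <- .run_stage("ml", split_train_test(scored, boundary = 2L))
    model <- .run_stage("ml", train_and_tune(parts$train, config$ml))
    pred <- .run_stage("ml", predict(model, parts$test))
    imp <- .run_stage("ml", feature_importance(model))
    emit(data.frame(parts$test[, c("player_id", "mc_Microcycle")],
                    ml_prob = predict(model, parts$test, type = "prob"),
                    ml_decision = pred), "ml_predictions.csv")
    emit(imp, "importance.csv")
    out$ml <- list(model = model, predictions = pred, importance = imp)
  }
  if (isTRUE(st[["evaluate"]])) {
    comp <- .run_stage("evaluate", {
      parts <- split_train_test(scored, boundary = 2L)
      te <- parts$test
      preds <- list()
      if (!is.null(te$rule_decision)) preds$rule_based <- te$rule_decision
      if (!is.null(te$fuzzy_decision)) preds$fuzzy <- te$fuzzy_decision
      if (!is.null(out$ml)) preds$ml <- out$ml$predictions
      if (length(preds) == 0L)
        stop("no model decisions available to evaluate")
      compare_models(te$Injury, preds)
    })
    emit(comp, "comparison.csv")
    out$comparison <- comp
  }

  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = config$seed,
                            sim = config$sim[setdiff(names(config$sim),
                                                     "position_params")],
                            ml = unclass(config$ml)[setdiff(names(config$ml),
                                                            "grid")],
                            stages = as.list(config$stages)),
                       cfg_json, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_json)),
                   files = lapply(paths, function(p)
                     list(file = basename(p),
                          md5 = unname(tools::md5sum(p)))))
  unlink(cfg_json)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
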