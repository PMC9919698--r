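# Microcycle feature engineering: training-week vs match-day aggregates,
# lagged copies, player motor profiles and derived workload ratios.

.session_cols <- c("player_id", "position", "microcycle", "session_type",
                   "duration_min", "total_distance_m", "hsr_m", "sprint_m",
                   "player_load", "accelerations", "decelerations")

# metric name -> session column, shared by mc_ and md_ aggregates
.metric_map <- c(TotalDistance = "total_distance_m",
                 HSR = "hsr_m",
                 Sprint = "sprint_m",
                 TotalPlayerLoad = "player_load",
                 FieldTime = "duration_min",
                 Acceleration = "accelerations",
                 Deceleration = "decelerations")

#' Aggregate sessions into the player-microcycle feature schema
#'
#' Splits each player-microcycle into a training-week part (`mc_*` columns,
#' sums over training sessions, match day excluded) and a match-day part
#' (`md_*` columns; zero when the player did not play). Cumulative metadata
#' (`TotalTrainingTime`, `TotalGameTime`, `Games`) counts activity before
#' the current microcycle and resets at the round boundary.
#'
#' @param sessions Session data frame as produced by [simulate_sessions()]
#'   (or a real export with the same columns).
#' @param labels Optional data frame `(player_id, microcycle, Injury)`;
#'   unlabelled rows get `NA`.
#' @param round_boundary Optional first microcycle of the second round;
#'   `NULL` treats all data as one round.
#' @return One row per player-microcycle with columns `player_id`,
#'   `position`, `round`, `mc_Microcycle`, `Injury`, `TotalTrainingTime`,
#'   `TotalGameTime`, `Games`, `PlayInMatch` and the 14 `mc_*`/`md_*`
#'   aggregates.
#' @export
aggregate_microcycle <- function(sessions, labels = NULL,
                                 round_boundary = NULL) {
  miss <- setdiff(.session_cols, names(sessions))
  if (length(miss))
    stop("schema violation: sessions table lacks column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(sessions) == 0L)
    return(.empty_feature_frame())
  is_match <- sessions$session_type == "match"
  key <- .pm_key(sessions$player_id, sessions$microcycle)
  if (any(tapply(is_match, key, sum) > 1))
    stop("schema violation: more than one match session in a ",
         "player-microcycle")
  groups <- split(seq_len(nrow(sessions)), key)
  rows <- lapply(groups, function(idx) {
    s <- sessions[idx, , drop = FALSE]
    m <- s$session_type == "match"
    row <- list(player_id = s$player_id[1L],
                position = s$position[1L],
                mc_Microcycle = s$microcycle[1L],
                PlayInMatch = as.integer(any(m)))
    for (nm in names(.metric_map)) {
      col <- .metric_map[[nm]]
      row[[paste0("mc_", nm)]] <- sum(s[[col]][!m])
      row[[paste0("md_", nm)]] <- if (any(m)) s[[col]][m][1L] else 0
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$player_id, out$mc_Microcycle), , drop = FALSE]
  rownames(out) <- NULL
  out$round <- if (is.null(round_boundary)) 1L else
    1L + as.integer(out$mc_Microcycle >= round_boundary)
  grp <- interaction(out$player_id, out$round, drop = TRUE)
  cum_before <- function(x) ave(x, grp, FUN = function(v) cumsum(v) - v)
  out$TotalTrainingTime <- cum_before(out$mc_FieldTime)
  out$TotalGameTime <- cum_before(out$md_FieldTime)
  out$Games <- cum_before(as.numeric(out$PlayInMatch))
  out$Injury <- NA_integer_
  if (!is.null(labels)) {
    hit <- match(.pm_key(out$player_id, out$mc_Microcycle),
                 .pm_key(labels$player_id, labels$microcycle))
    out$Injury <- labels$Injury[hit]
  }
  front <- c("player_id", "position", "round", "mc_Microcycle", "Injury",
             "TotalTrainingTime", "TotalGameTime", "Games", "PlayInMatch")
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}

.empty_feature_frame <- function() {
  out <- data.frame(player_id = character(), position = character(),
                    round = integer(), mc_Microcycle = integer(),
                    Injury = integer(), TotalTrainingTime = numeric(),
                    TotalGameTime = numeric(), Games = numeric(),
                    PlayInMatch = integer(), stringsAsFactors = FALSE)
  for (nm in names(.metric_map)) {
    out[[paste0("mc_", nm)]] <- numeric()
    out[[paste0("md_", nm)]] <- numeric()
  }
  out
}

#' Add lagged copies of the microcycle metrics
#'
#' For every `mc_*`/`md_*` metric and lag `k` in `1:depth`, adds a column
#' `<metric>_-k` holding the same player's value `k` microcycles earlier
#' within the same round. Lags reaching before the round start, or into a
#' microcycle the player missed, are `NA`.
#'
#' @param rows Feature table from [aggregate_microcycle()].
#' @param depth Number of lags (default 3); 0 returns the input unchanged.
#' @return The input with `depth` lag columns appended per metric.
#' @export
add_lags <- function(rows, depth = 3L) {
  depth <- as.integer(depth)
  if (depth < 0L) stop("depth must be non-negative")
  if (depth == 0L || nrow(rows) == 0L) return(rows)
  metrics <- grep("^(mc|md)_", names(rows), value = TRUE)
  metrics <- setdiff(metrics, "mc_Microcycle")
  metrics <- metrics[!grepl("_-[0-9]+$", metrics)]
  rnd <- if ("round" %in% names(rows)) rows$round else 1L
  grp <- split(seq_len(nrow(rows)), interaction(rows$player_id, rnd,
                                                drop = TRUE))
  for (m in metrics) {
    for (k in seq_len(depth)) rows[[paste0(m, "_-", k)]] <- NA_real_
  }
  for (idx in grp) {
    mc <- rows$mc_Microcycle[idx]
    for (k in seq_len(depth)) {
      src <- match(mc - k, mc)
      for (m in metrics) {
        rows[[paste0(m, "_-", k)]][idx] <- rows[[m]][idx[src]]
      }
    }
  }
  rows
}

#' Build per-player motor profiles from match performances
#'
#' A player's reference value per metric is the median over their matches
#' of at least 75 minutes (inclusive). Players with no qualifying match get
#' the median of the profiles of qualifying players in the same position.
#'
#' @param rows Feature table with `md_*` columns and `md_FieldTime`.
#' @return Data frame with `player_id`, `position` and reference values for
#'   `TotalDistance`, `HSR`, `Sprint`, `Acceleration`, `Deceleration`.
#' @export
build_player_profile <- function(rows) {
  metrics <- c("TotalDistance", "HSR", "Sprint", "Acceleration",
               "Deceleration")
  qual <- rows$PlayInMatch == 1 & !is.na(rows$md_FieldTime) &
    rows$md_FieldTime >= 75
  players <- unique(rows[, c("player_id", "position")])
  rownames(players) <- NULL
  prof <- players
  for (m in metrics) prof[[m]] <- NA_real_
  own <- logical(nrow(prof))
  for (i in seq_len(nrow(prof))) {
    sel <- qual & rows$player_id == prof$player_id[i]
    if (any(sel)) {
      own[i] <- TRUE
      for (m in metrics)
        prof[[m]][i] <- median(rows[[paste0("md_", m)]][sel])
    }
  }
  for (i in which(!own)) {
    peers <- own & prof$position == prof$position[i]
    if (!any(peers))
      stop("profile unavailable: no player in position '",
           prof$position[i], "' has a match of at least 75 minutes")
    for (m in metrics) prof[[m]][i] <- median(prof[[m]][peers])
  }
  prof
}

# ratio with the expert-system fallback: zero denominator -> 1.1,
# missing numerator or denominator -> NA (propagated for imputation)
.reg_ratio <- function(num, den) {
  out <- num / den
  zero <- !is.na(den) & den == 0
  out[zero] <- 1.1
  out
}

#' Compute the derived workload ratio variables
#'
#' Appends the `REG_*` variables to a lagged feature table:
#' * `REG_<M>_R1_A` — current week total (training + match) over the
#'   previous week's total, for `M` in HSR, Sprint;
#' * `REG_<M>_R1_B`, `REG_<M>_R1_C` — the totals two and three microcycles
#'   back over the previous week's total;
#' * `REG_<M>_R2` — match-day value over the training-week sum;
#' * `REG_ACC_DEC` — match accelerations + decelerations over the
#'   training-week sum;
#' * `REG_ACWR_AC` — acute load: the week's total player load (match
#'   included); `REG_ACWR_HR` — chronic load: mean acute load over the
#'   current and three preceding microcycles; `REG_ACWR` — their ratio.
#'
#' Any ratio whose denominator is exactly zero takes the neutral fallback
#' value 1.1; ratios with missing inputs stay `NA` so that downstream
#' imputation can handle them.
#'
#' @param rows Feature table with lag columns (see [add_lags()]).
#' @return The input with 12 `REG_*` columns appended.
#' @export
compute_derived <- function(rows) {
  need <- c("mc_HSR", "md_HSR", "mc_Sprint", "md_Sprint",
            "mc_TotalPlayerLoad", "md_TotalPlayerLoad",
            "mc_Acceleration", "md_Acceleration",
            "mc_Deceleration", "md_Deceleration")
  lag_need <- as.vector(outer(
    c("mc_HSR", "md_HSR", "mc_Sprint", "md_Sprint",
      "mc_TotalPlayerLoad", "md_TotalPlayerLoad"),
    1:3, function(a, b) paste0(a, "_-", b)))
  miss <- setdiff(c(need, lag_need), names(rows))
  if (length(miss))
    stop("schema violation: missing column(s) ",
         paste(head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ...")
  r1 <- function(m, k) {
    den <- rows[[paste0("mc_", m, "_-1")]] + rows[[paste0("md_", m, "_-1")]]
    num <- if (k == 0) rows[[paste0("mc_", m)]] + rows[[paste0("md_", m)]]
    else rows[[paste0("mc_", m, "_-", k)]] + rows[[paste0("md_", m, "_-", k)]]
    .reg_ratio(num, den)
  }
  rows$REG_HSR_R1_A <- r1("HSR", 0)
  rows$REG_HSR_R1_B <- r1("HSR", 2)
  rows$REG_HSR_R1_C <- r1("HSR", 3)
  rows$REG_HSR_R2 <- .reg_ratio(rows$md_HSR, rows$mc_HSR)
  rows$REG_Sprint_R1_A <- r1("Sprint", 0)
  rows$REG_Sprint_R1_B <- r1("Sprint", 2)
  rows$REG_Sprint_R1_C <- r1("Sprint", 3)
  rows$REG_Sprint_R2 <- .reg_ratio(rows$md_Sprint, rows$mc_Sprint)
  rows$REG_ACC_DEC <- .reg_ratio(rows$md_Acceleration + rows$md_Deceleration,
                                 rows$mc_Acceleration + rows$mc_Deceleration)
  ac <- rows$mc_TotalPlayerLoad + rows$md_TotalPlayerLoad
  ac_l <- sapply(1:3, function(k)
    rows[[paste0("mc_TotalPlayerLoad_-", k)]] +
      rows[[paste0("md_TotalPlayerLoad_-", k)]])
  ac_l <- matrix(ac_l, nrow = nrow(rows))
  rows$REG_ACWR_AC <- ac
  rows$REG_ACWR_HR <- (ac + ac_l[, 1] + ac_l[, 2] + ac_l[, 3]) / 4
  rows$REG_ACWR <- .reg_ratio(rows$REG_ACWR_AC, rows$REG_ACWR_HR)
  rows
}
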