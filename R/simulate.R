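# Synthetic squad generator: session-level external-load records plus a
# configurable logistic injury hazard concentrated in workload extremes.

# Default per-session load medians by playing position (lognormal location =
# log of these). Values are plausible elite-football GPS magnitudes; no
# public per-session table exists for the population emulated here.
.default_position_params <- function(position_set) {
  base <- list(
    training = data.frame(
      position = c("CB", "FB", "CM", "WM", "FW"),
      distance = c(4200, 4600, 5000, 4800, 4400),
      hsr      = c(120, 200, 180, 240, 200),
      sprint   = c(25, 60, 35, 80, 70),
      acc      = c(30, 36, 40, 38, 34),
      dec      = c(32, 38, 42, 40, 36),
      duration = c(75, 75, 75, 75, 75),
      stringsAsFactors = FALSE
    ),
    match = data.frame(
      position = c("CB", "FB", "CM", "WM", "FW"),
      distance = c(9500, 10500, 11000, 10800, 10000),
      hsr      = c(500, 800, 700, 900, 750),
      sprint   = c(120, 250, 150, 300, 280),
      acc      = c(80, 95, 100, 96, 88),
      dec      = c(85, 100, 105, 100, 92),
      duration = c(90, 90, 90, 90, 90),
      stringsAsFactors = FALSE
    )
  )
  recycle <- function(tab) {
    idx <- match(position_set, tab$position)
    idx[is.na(idx)] <- rep_len(seq_len(nrow(tab)), sum(is.na(idx)))
    out <- tab[idx, , drop = FALSE]
    out$position <- position_set
    rownames(out) <- NULL
    out
  }
  list(training = recycle(base$training), match = recycle(base$match))
}

#' Configuration for the synthetic squad generator
#'
#' Defines the study conditions the generator emulates: a squad of outfield
#' players observed over two competition rounds, one row per player per
#' microcycle, a small fraction of skipped player-microcycles (call-ups,
#' illness, rotation), and an injury mechanism driven by workload extremes.
#'
#' @param n_players Number of players in the squad (goalkeepers excluded).
#' @param round_lengths Integer vector of length 2: microcycles in the first
#'   and second competition round. The total per player is their sum.
#' @param base_injury_rate Target injury probability per player-microcycle;
#'   the hazard intercept is calibrated so the expected rate matches it
#'   (see `hazard_coefficients`).
#' @param hazard_coefficients Named numeric vector with entries `intercept`,
#'   `acwr_deviation` (weight on `|log REG_ACWR|`), `hsr_spike` (weight on
#'   the high-speed-running week-over-week ratio excess above 1.3) and
#'   `decel_deficit` (weight on the shortfall of match decelerations versus
#'   the player's motor profile). An `NA` intercept means "calibrate so the
#'   mean injury probability equals `base_injury_rate`".
#' @param position_set Character vector of position labels.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   output.
#' @param spike_fraction,trough_fraction Fractions of player-microcycles
#'   whose weekly loads are scaled by a spike factor (1.6-2.8x) or a trough
#'   factor (0.25-0.45x), populating the risky ACWR bands.
#' @param p_match Probability that the player plays the microcycle's match
#'   (at most one match per player-microcycle).
#' @param p_full_match Probability a played match lasts the full 90 minutes
#'   (otherwise the player is a substitute with 10-89 minutes).
#' @param p_missing Probability a player-microcycle has no sessions at all.
#' @param sessions_range Integer range (min, max) of training sessions per
#'   microcycle.
#' @param noise_sdlog Lognormal sd of per-session metric noise; 0 gives
#'   deterministic (constant) loads.
#' @param player_sdlog Lognormal sd of the per-player ability multiplier.
#' @param position_params Optional list with `training` and `match` data
#'   frames of per-position metric medians (columns `position`, `distance`,
#'   `hsr`, `sprint`, `acc`, `dec`, `duration`); defaults are built in.
#' @return A list of class `sim_config`. `n_microcycles` and
#'   `round_boundary` (first microcycle of round 2) are derived fields.
#' @export
simulation_config <- function(n_players = 36L,
                              round_lengths = c(20L, 11L),
                              base_injury_rate = 0.063,
                              hazard_coefficients = c(intercept = NA_real_,
                                                      acwr_deviation = 3.0,
                                                      hsr_spike = 1.2,
                                                      decel_deficit = 1.0),
                              position_set = c("CB", "FB", "CM", "WM", "FW"),
                              seed = 1L,
                              spike_fraction = 0.10,
                              trough_fraction = 0.05,
                              p_match = 0.8,
                              p_full_match = 0.7,
                              p_missing = 0.045,
                              sessions_range = c(2L, 5L),
                              noise_sdlog = 0.35,
                              player_sdlog = 0.15,
                              position_params = NULL) {
  if (length(n_players) != 1L || is.na(n_players) || n_players < 1)
    stop("configuration error: n_players must be a positive count")
  if (length(round_lengths) != 2L || any(round_lengths < 1))
    stop("configuration error: round_lengths must be two positive counts")
  if (!is.numeric(base_injury_rate) || base_injury_rate <= 0 ||
      base_injury_rate >= 1)
    stop("configuration error: base_injury_rate must lie in (0, 1)")
  needed <- c("intercept", "acwr_deviation", "hsr_spike", "decel_deficit")
  if (!all(needed %in% names(hazard_coefficients)))
    stop("configuration error: hazard_coefficients must name ",
         paste(needed, collapse = ", "))
  if (spike_fraction < 0 || trough_fraction < 0 ||
      spike_fraction + trough_fraction > 1)
    stop("configuration error: spike/trough fractions invalid")
  if (length(sessions_range) != 2L || any(sessions_range < 1) ||
      sessions_range[1] > sessions_range[2])
    stop("configuration error: sessions_range invalid")
  if (p_match < 0 || p_match > 1 || p_missing < 0 || p_missing >= 1 ||
      p_full_match < 0 || p_full_match > 1)
    stop("configuration error: probabilities must lie in [0, 1]")
  if (noise_sdlog < 0 || player_sdlog < 0)
    stop("configuration error: sdlog parameters must be non-negative")
  if (is.null(position_params))
    position_params <- .default_position_params(position_set)
  structure(list(
    n_players = as.integer(n_players),
    round_lengths = as.integer(round_lengths),
    n_microcycles = as.integer(sum(round_lengths)),
    round_boundary = as.integer(round_lengths[1] + 1L),
    base_injury_rate = base_injury_rate,
    hazard_coefficients = hazard_coefficients,
    position_set = position_set,
    seed = as.integer(seed),
    spike_fraction = spike_fraction,
    trough_fraction = trough_fraction,
    p_match = p_match,
    p_full_match = p_full_match,
    p_missing = p_missing,
    sessions_range = as.integer(sessions_range),
    noise_sdlog = noise_sdlog,
    player_sdlog = player_sdlog,
    position_params = position_params
  ), class = "sim_config")
}

# one lognormal metric draw around a positional median
.draw <- function(n, med, sdlog) med * exp(rnorm(n, 0, sdlog))

#' Simulate session-level external-load records for a squad
#'
#' Generates one row per session (training or match). Each player-microcycle
#' holds 2-5 training sessions and at most one match; metric magnitudes are
#' lognormal with position-dependent medians, and a configurable fraction of
#' weeks carries a workload spike or trough so that the full range of
#' acute:chronic workload ratios occurs in the data.
#'
#' @param config A [simulation_config()] object.
#' @return A data frame with columns `player_id`, `position`, `microcycle`,
#'   `session_type`, `duration_min`, `total_distance_m`, `hsr_m`,
#'   `sprint_m`, `player_load`, `accelerations`, `decelerations`.
#' @export
simulate_sessions <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("configuration error: expected a simulation_config() object")
  set.seed(config$seed)
  n <- config$n_players
  players <- sprintf("P%02d", seq_len(n))
  positions <- sample(rep_len(config$position_set, n))
  player_eff <- exp(rnorm(n, 0, config$player_sdlog))
  tr <- config$position_params$training
  ma <- config$position_params$match
  sr <- config$sessions_range
  out <- vector("list", n * config$n_microcycles)
  slot <- 0L
  for (p in seq_len(n)) {
    ptr <- tr[tr$position == positions[p], ][1L, ]
    pma <- ma[ma$position == positions[p], ][1L, ]
    for (m in seq_len(config$n_microcycles)) {
      if (runif(1) < config$p_missing) next
      u <- runif(1)
      scale_wk <- if (u < config$spike_fraction) {
        runif(1, 1.6, 2.8)
      } else if (u < config$spike_fraction + config$trough_fraction) {
        runif(1, 0.25, 0.45)
      } else 1
      n_tr <- if (sr[1] == sr[2]) sr[1] else sample(seq(sr[1], sr[2]), 1L)
      eff <- player_eff[p] * scale_wk
      sdl <- config$noise_sdlog
      dist <- .draw(n_tr, ptr$distance, sdl) * eff
      hsr <- .draw(n_tr, ptr$hsr, sdl) * eff
      spr <- .draw(n_tr, ptr$sprint, sdl) * eff
      acc <- round(.draw(n_tr, ptr$acc, sdl) * eff)
      dec <- round(.draw(n_tr, ptr$dec, sdl) * eff)
      dur <- .draw(n_tr, ptr$duration, sdl * 0.3)
      load <- dist / 10 * exp(rnorm(n_tr, 0, sdl * 0.3))
      type <- rep("training", n_tr)
      if (runif(1) < config$p_match) {
        mdur <- if (runif(1) < config$p_full_match) 90 else runif(1, 10, 89)
        f <- mdur / 90
        dist <- c(dist, .draw(1, pma$distance, sdl) * eff * f)
        hsr <- c(hsr, .draw(1, pma$hsr, sdl) * eff * f)
        spr <- c(spr, .draw(1, pma$sprint, sdl) * eff * f)
        acc <- c(acc, round(.draw(1, pma$acc, sdl) * eff * f))
        dec <- c(dec, round(.draw(1, pma$dec, sdl) * eff * f))
        dur <- c(dur, mdur)
        load <- c(load, dist[length(dist)] / 10 * exp(rnorm(1, 0, sdl * 0.3)))
        type <- c(type, "match")
      }
      # keep sprint + HSR within total distance
      over <- (hsr + spr) > 0.6 * dist
      if (any(over)) {
        shrink <- 0.6 * dist[over] / (hsr[over] + spr[over])
        hsr[over] <- hsr[over] * shrink
        spr[over] <- spr[over] * shrink
      }
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        player_id = players[p], position = positions[p],
        microcycle = m, session_type = type,
        duration_min = dur, total_distance_m = dist,
        hsr_m = hsr, sprint_m = spr, player_load = load,
        accelerations = pmax(acc, 0), decelerations = pmax(dec, 0),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(slot)])
  rownames(res) <- NULL
  res
}

#' Assign injury labels from a logistic workload hazard
#'
#' Computes the microcycle feature table from the simulated sessions and
#' draws one Bernoulli injury label per player-microcycle with probability
#' `plogis(intercept + b_acwr * |log REG_ACWR| + b_hsr * HSR ratio excess +
#' b_dec * deceleration deficit)`. Signals that are unavailable (warm-up
#' rows, players without a motor profile) contribute zero. With an `NA`
#' intercept the intercept is solved so the mean probability equals the
#' configured base injury rate.
#'
#' @param records Session data frame from [simulate_sessions()].
#' @param config The [simulation_config()] used to generate them.
#' @return A data frame with columns `player_id`, `microcycle`, `Injury`.
#' @export
assign_injuries <- function(records, config) {
  if (!inherits(config, "sim_config"))
    stop("configuration error: expected a simulation_config() object")
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(player_id = character(), microcycle = integer(),
                      Injury = integer(), stringsAsFactors = FALSE))
  n_mc <- tapply(records$microcycle, records$player_id,
                 function(x) length(unique(x)))
  if (any(n_mc < 4))
    stop("warm-up error: every player needs records in at least 4 ",
         "microcycles to define the acute:chronic workload ratio")
  agg <- aggregate_microcycle(records, labels = NULL,
                              round_boundary = config$round_boundary)
  lagged <- add_lags(agg, depth = 3L)
  der <- compute_derived(lagged)

  co <- config$hazard_coefficients
  acwr_dev <- abs(log(der$REG_ACWR))
  acwr_dev[!is.finite(acwr_dev)] <- 0
  hsr_ex <- pmin(pmax(der$REG_HSR_R1_A - 1.3, 0), 3)
  hsr_ex[is.na(hsr_ex)] <- 0
  dec_def <- rep(0, nrow(der))
  prof <- tryCatch(build_player_profile(der), error = function(e) NULL)
  if (!is.null(prof)) {
    ref <- prof$Deceleration[match(der$player_id, prof$player_id)]
    idx <- der$PlayInMatch == 1 & !is.na(ref) & ref > 0
    dec_def[idx] <- pmax(0, 1 - der$md_Deceleration[idx] / ref[idx])
  }
  lin <- co[["acwr_deviation"]] * acwr_dev +
    co[["hsr_spike"]] * hsr_ex +
    co[["decel_deficit"]] * dec_def
  icpt <- co[["intercept"]]
  if (is.na(icpt)) {
    icpt <- uniroot(function(c0) mean(plogis(c0 + lin)) -
                      config$base_injury_rate,
                    interval = c(-25, 10), tol = 1e-10)$root
  }
  p <- plogis(icpt + lin)
  set.seed(config$seed + 7919L)
  data.frame(player_id = der$player_id,
             microcycle = der$mc_Microcycle,
             Injury = rbinom(length(p), 1L, p),
             stringsAsFactors = FALSE)
}

#' Simulate a full labelled synthetic dataset
#'
#' Convenience wrapper running [simulate_sessions()], [assign_injuries()]
#' and the feature pipeline in one call.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `sessions`, `labels` and `features` (the
#'   lagged feature table with derived `REG_*` variables and injury labels).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  sessions <- simulate_sessions(config)
  labels <- assign_injuries(sessions, config)
  feats <- aggregate_microcycle(sessions, labels = labels,
                                round_boundary = config$round_boundary)
  feats <- compute_derived(add_lags(feats, depth = 3L))
  list(sessions = sessions, labels = labels, features = feats)
}
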