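# shared fixtures: small squads and hand-built feature rows

small_config <- function(seed = 42L, n_players = 8L,
                         round_lengths = c(8L, 4L), ...) {
  simulation_config(n_players = n_players, round_lengths = round_lengths,
                    seed = seed, ...)
}

# deterministic squad: no noise, fixed session counts, everyone plays 90'
constant_config <- function(seed = 1L, ...) {
  simulation_config(n_players = 3L, round_lengths = c(8L, 4L), seed = seed,
                    spike_fraction = 0, trough_fraction = 0,
                    p_match = 1, p_full_match = 1, p_missing = 0,
                    sessions_range = c(3L, 3L), noise_sdlog = 0,
                    player_sdlog = 0, ...)
}

# one feature row with every column compute_derived() needs; override via ...
derived_row <- function(...) {
  vals <- list(
    mc_HSR = 600, md_HSR = 300, mc_Sprint = 150, md_Sprint = 80,
    mc_TotalPlayerLoad = 1500, md_TotalPlayerLoad = 1000,
    mc_Acceleration = 120, md_Acceleration = 90,
    mc_Deceleration = 130, md_Deceleration = 95
  )
  for (m in c("HSR", "Sprint", "TotalPlayerLoad")) {
    for (k in 1:3) {
      vals[[sprintf("mc_%s_-%d", m, k)]] <- vals[[paste0("mc_", m)]]
      vals[[sprintf("md_%s_-%d", m, k)]] <- vals[[paste0("md_", m)]]
    }
  }
  over <- list(...)
  vals[names(over)] <- over
  as.data.frame(vals, check.names = FALSE)
}

# hand-built session table: one list(...) per session
session_table <- function(...) {
  rows <- list(...)
  defaults <- list(player_id = "P01", position = "CM", microcycle = 1L,
                   session_type = "training", duration_min = 75,
                   total_distance_m = 5000, hsr_m = 200, sprint_m = 50,
                   player_load = 500, accelerations = 40,
                   decelerations = 42)
  do.call(rbind, lapply(rows, function(r) {
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
}
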