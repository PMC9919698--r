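test_that("training-week and match-day activity are aggregated separately", {
  s <- session_table(
    list(total_distance_m = 4000, hsr_m = 100),
    list(total_distance_m = 6000, hsr_m = 150)
  )
  f <- aggregate_microcycle(s)
  expect_equal(f$mc_TotalDistance, 10000)
  expect_equal(f$mc_HSR, 250)
  expect_identical(f$PlayInMatch, 0L)
  expect_equal(f$md_TotalDistance, 0)

  s2 <- session_table(
    list(total_distance_m = 4000, hsr_m = 100),
    list(session_type = "match", total_distance_m = 10000, hsr_m = 320)
  )
  f2 <- aggregate_microcycle(s2)
  expect_equal(f2$md_HSR, 320)
  expect_equal(f2$mc_HSR, 100)
  expect_identical(f2$PlayInMatch, 1L)
})

test_that("two matches in one player-microcycle violate the schema", {
  s <- session_table(list(session_type = "match"),
                     list(session_type = "match"))
  expect_error(aggregate_microcycle(s), "schema violation")
})

test_that("cumulative metadata counts activity before the microcycle and resets per round", {
  s <- do.call(rbind, lapply(1:4, function(m) session_table(
    list(microcycle = m, duration_min = 60),
    list(microcycle = m, session_type = "match", duration_min = 90)
  )))
  f <- aggregate_microcycle(s, round_boundary = 3L)
  expect_equal(f$TotalTrainingTime, c(0, 60, 0, 60))
  expect_equal(f$TotalGameTime, c(0, 90, 0, 90))
  expect_equal(f$Games, c(0, 1, 0, 1))
  expect_equal(f$round, c(1L, 1L, 2L, 2L))
})

test_that("lag columns shift by microcycle index within player and round", {
  s <- do.call(rbind, lapply(1:3, function(m) session_table(
    list(microcycle = m, player_load = 100 * m))))
  f <- add_lags(aggregate_microcycle(s), depth = 3L)
  expect_equal(f[["mc_TotalPlayerLoad_-1"]], c(NA, 100, 200))
  expect_equal(f[["mc_TotalPlayerLoad_-2"]], c(NA, NA, 100))
  expect_true(all(is.na(f[f$mc_Microcycle == 1,
                          grep("_-", names(f), value = TRUE)])))
  f0 <- aggregate_microcycle(s)
  expect_identical(add_lags(f0, depth = 0L), f0)
})

test_that("lag consistency holds on a simulated squad", {
  f <- add_lags(aggregate_microcycle(
    simulate_sessions(small_config(seed = 9L)), round_boundary = 9L))
  for (k in 1:3) {
    lagcol <- paste0("mc_TotalDistance_-", k)
    for (i in seq_len(nrow(f))) {
      src <- which(f$player_id == f$player_id[i] &
                     f$round == f$round[i] &
                     f$mc_Microcycle == f$mc_Microcycle[i] - k)
      if (length(src) == 1L)
        expect_equal(f[[lagcol]][i], f$mc_TotalDistance[src])
      else
        expect_true(is.na(f[[lagcol]][i]))
    }
  }
})

test_that("player profiles use medians of 75+ minute matches with positional fallback", {
  base <- list(player_id = "A", position = "CM", round = 1L, PlayInMatch = 1L)
  mk <- function(id, pos, ft, sprint) {
    r <- derived_row()
    r$player_id <- id; r$position <- pos; r$PlayInMatch <- 1L
    r$md_FieldTime <- ft; r$md_Sprint <- sprint
    r$md_TotalDistance <- 10000; r$md_HSR <- 700
    r
  }
  rows <- rbind(mk("A", "CM", 90, 100), mk("A", "CM", 80, 140),
                mk("A", "CM", 75, 120),     # inclusive threshold
                mk("B", "CM", 60, 999),     # no qualifying match
                mk("C", "CM", 90, 110), mk("C", "CM", 88, 130))
  prof <- build_player_profile(rows)
  expect_equal(prof$Sprint[prof$player_id == "A"], 120)
  # C's profile is median(110, 130) = 120; B falls back to median(A, C)
  expect_equal(prof$Sprint[prof$player_id == "B"], 120)
  rows$md_FieldTime[rows$player_id != "B"] <- 60
  expect_error(build_player_profile(rows), "profile unavailable")
})

test_that("derived ratios follow their definitions and the 1.1 fallback", {
  r <- derived_row(`mc_HSR_-1` = 0, `md_HSR_-1` = 0)
  expect_equal(compute_derived(r)$REG_HSR_R1_A, 1.1)
  r2 <- compute_derived(derived_row(md_HSR = 300, mc_HSR = 600))
  expect_equal(r2$REG_HSR_R2, 0.5)
  # constant player load over four microcycles: acute = chronic
  r3 <- compute_derived(derived_row())
  expect_equal(r3$REG_ACWR_AC, 2500)
  expect_equal(r3$REG_ACWR_HR, 2500)
  expect_equal(r3$REG_ACWR, 1.0)
  # missing lag propagates as NA, not as the fallback
  r4 <- compute_derived(derived_row(`mc_HSR_-1` = NA_real_))
  expect_true(is.na(r4$REG_HSR_R1_A))
})

test_that("derived ratios are invariant to rescaling a player's loads", {
  f <- compute_derived(add_lags(aggregate_microcycle(
    simulate_sessions(small_config(seed = 13L)), round_boundary = 9L)))
  mets <- grep("^(mc|md)_", names(f), value = TRUE)
  mets <- setdiff(mets, "mc_Microcycle")
  g <- f
  for (m in mets) g[[m]] <- g[[m]] * 3.7
  gd <- compute_derived(g[, setdiff(names(g), grep("^REG_", names(g),
                                                   value = TRUE))])
  ratios <- setdiff(grep("^REG_", names(f), value = TRUE),
                    c("REG_ACWR_AC", "REG_ACWR_HR"))
  for (m in ratios) expect_equal(gd[[m]], f[[m]], tolerance = 1e-12)
  expect_equal(gd$REG_ACWR_AC, f$REG_ACWR_AC * 3.7, tolerance = 1e-12)
  expect_equal(gd$REG_ACWR_HR, f$REG_ACWR_HR * 3.7, tolerance = 1e-12)
})

test_that("derived computation is total: no infinities, zero denominators fall back", {
  f <- compute_derived(add_lags(aggregate_microcycle(
    simulate_sessions(small_config(seed = 17L)), round_boundary = 9L)))
  regs <- grep("^REG_", names(f), value = TRUE)
  for (m in regs) expect_true(all(is.finite(f[[m]]) | is.na(f[[m]])))
  z <- compute_derived(derived_row(mc_Sprint = 0, md_Sprint = 5,
                                   `mc_Sprint_-1` = 0, `md_Sprint_-1` = 0))
  expect_equal(z$REG_Sprint_R1_A, 1.1)
})
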