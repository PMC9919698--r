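test_that("membership functions evaluate piecewise-linearly", {
  tr <- fuzzy_term("t", "trapezoidal", c(0, 1, 2, 3))
  expect_equal(membership(tr, 1.5), 1.0)
  expect_equal(membership(tr, 0.5), 0.5)
  expect_equal(membership(tr, 5), 0.0)
  expect_equal(membership(tr, c(-1, 0, 2.5, 3)), c(0, 0, 0.5, 0))
  tri <- fuzzy_term("t", "triangular", c(0, 1, 2))
  expect_equal(membership(tri, 1), 1)
  expect_equal(membership(tri, 0.25), 0.25)
  # zero-width edges behave as crisp shoulders
  sh <- fuzzy_term("t", "trapezoidal", c(0, 0, 1, 2))
  expect_equal(membership(sh, 0), 1)
  expect_error(fuzzy_term("t", "trapezoidal", c(1, 0, 2, 3)),
               "non-decreasing")
})

test_that("rule text parses, formats canonically and respects precedence", {
  txt <- "IF (HSR_R1_A IS small) AND (HSR_R1_B IS small) AND (HSR_R1_C IS small) THEN (load IS very_small)"
  r <- fuzzy_rule(txt)
  expect_identical(r$text, txt)
  expect_identical(r$antecedent$op, "and")
  expect_length(r$antecedent$args, 3L)
  mixed <- fuzzy_rule(
    "IF (a IS x) OR (b IS y) AND (c IS z) THEN (load IS small)")
  expect_identical(mixed$antecedent$op, "or")   # AND binds tighter
  grouped <- fuzzy_rule(
    "IF ((a IS x) OR (b IS y)) AND (c IS z) THEN (load IS small)")
  expect_identical(grouped$antecedent$op, "and")
  expect_identical(fuzzy_rule(grouped$text)$antecedent,
                   grouped$antecedent)          # canonical form round-trips
  expect_error(fuzzy_rule("IF (a IS x) THEN"), "parse error")
  expect_error(fuzzy_rule("(a IS x) THEN (load IS y)"), "parse error")
})

test_that("activation uses min for AND, max for OR, zero for missing input", {
  v <- linguistic_variable("x", c(0, 10), list(
    fuzzy_term("lo", "trapezoidal", c(0, 0, 2, 6)),
    fuzzy_term("hi", "trapezoidal", c(4, 8, 10, 10))))
  w <- linguistic_variable("y", c(0, 10), list(
    fuzzy_term("lo", "trapezoidal", c(0, 0, 2, 6)),
    fuzzy_term("hi", "trapezoidal", c(4, 8, 10, 10))))
  out <- linguistic_variable("load", c(0, 10), list(
    fuzzy_term("any", "trapezoidal", c(0, 0, 10, 10))))
  kb <- fuzzy_knowledge_base(list(v, w, out), list(
    "IF (x IS hi) AND (y IS hi) THEN (load IS any)",
    "IF (x IS hi) OR (y IS hi) THEN (load IS any)"))
  ins <- list(x = 4.8, y = 7.6)             # memberships 0.2 and 0.9
  expect_equal(rule_activation(kb$rules[[1]], ins, kb), 0.2)
  expect_equal(rule_activation(kb$rules[[2]], ins, kb), 0.9)
  expect_equal(rule_activation(kb$rules[[1]], list(x = 0, y = 10), kb), 0)
  expect_equal(rule_activation(kb$rules[[1]], list(x = 10, y = 10), kb), 1)
  expect_equal(rule_activation(kb$rules[[1]], list(y = 10), kb), 0)
  expect_error(fuzzy_knowledge_base(list(v, w, out),
                                    list("IF (z IS hi) THEN (load IS any)")),
               "unknown variable")
  expect_error(fuzzy_knowledge_base(list(v, w, out),
                                    list("IF (x IS huge) THEN (load IS any)")),
               "unknown term")
})

test_that("inference recovers symmetric centroids and falls back to the midpoint", {
  v <- linguistic_variable("x", c(0, 1), list(
    fuzzy_term("on", "trapezoidal", c(0, 0, 1, 1))))
  out <- linguistic_variable("load", c(0, 10), list(
    fuzzy_term("mid", "triangular", c(3, 5, 7)),
    fuzzy_term("low", "triangular", c(0, 2, 4)),
    fuzzy_term("high", "triangular", c(6, 8, 10)),
    fuzzy_term("cover", "trapezoidal", c(0, 0, 10, 10))))
  kb1 <- fuzzy_knowledge_base(list(v, out),
                              list("IF (x IS on) THEN (load IS mid)"))
  expect_equal(infer(kb1, list(x = 0.5)), 5, tolerance = 1e-6)
  kb2 <- fuzzy_knowledge_base(list(v, out), list(
    "IF (x IS on) THEN (load IS low)",
    "IF (x IS on) THEN (load IS high)"))
  expect_equal(infer(kb2, list(x = 0.5)), 5, tolerance = 1e-6)
  expect_equal(oracle_centroid(kb2, list(x = 0.5)), 5, tolerance = 1e-6)
  expect_warning(got <- infer(kb1, list(x = NA_real_)), "no rule fired")
  expect_equal(got, 5)
})

test_that("grid defuzzification matches a fine trapezoidal-integration oracle", {
  for (seed in 1:25) {
    kb <- random_kb(seed)
    set.seed(seed + 1000)
    for (x in runif(4, 0, 2)) {
      expect_equal(infer(kb, list(x = x)),
                   oracle_centroid(kb, list(x = x)),
                   tolerance = 1e-3)
    }
  }
})

test_that("the crisp output is always inside the output universe", {
  for (seed in 26:40) {
    kb <- random_kb(seed)
    set.seed(seed)
    for (x in runif(3, -1, 3)) {          # includes values needing clamping
      got <- suppressWarnings(infer(kb, list(x = x)))
      expect_gte(got, 0); expect_lte(got, 10)
    }
  }
})

test_that("the decision cutoff is strict at 0.6", {
  expect_identical(classify_fuzzy(0.7), 1L)
  expect_identical(classify_fuzzy(0.5), 0L)
  expect_identical(classify_fuzzy(0.6), 0L)
  expect_identical(default_knowledge_base()$cutoff, 0.6)
})

test_that("the shipped base has 34 rules and serializes the published rules verbatim", {
  kb <- default_knowledge_base()
  expect_length(kb$rules, 34L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_knowledge_base(kb, path)
  txt <- readLines(path)
  printed <- c(
    "IF (HSR_R1_A IS small) AND (HSR_R1_B IS small) AND (HSR_R1_C IS small) THEN (load IS very_small)",
    "IF (REG_ACWR IS small) OR (REG_ACWR IS big) THEN (load IS small)",
    "IF (HSR_R2 IS big) THEN (load IS big)",
    "IF (SPRINT_R1_A IS small) AND (SPRINT_R1_B IS small) AND (SPRINT_R1_C IS small) THEN (load IS very_small)",
    "IF (REG_ACC IS small) THEN (load IS small)")
  for (p in printed) expect_true(p %in% txt)
  kb2 <- read_knowledge_base(path)
  expect_identical(vapply(kb2$rules, `[[`, character(1), "text"),
                   vapply(kb$rules, `[[`, character(1), "text"))
  probe <- list(REG_HSR_R1_A = 0.3, REG_HSR_R1_B = 0.4, REG_HSR_R1_C = 0.5,
                REG_Sprint_R1_A = 1, REG_Sprint_R1_B = 1,
                REG_Sprint_R1_C = 1, REG_HSR_R2 = 0.4, REG_Sprint_R2 = 0.4,
                REG_ACWR = 1.8, REG_ACC_DEC = 0.2)
  expect_equal(infer(kb2, probe), infer(kb, probe))
})

test_that("pushing inputs towards workload extremes never lowers the crisp output", {
  kb <- default_knowledge_base()
  benign <- list(REG_HSR_R1_A = 1, REG_HSR_R1_B = 1, REG_HSR_R1_C = 1,
                 REG_Sprint_R1_A = 1, REG_Sprint_R1_B = 1,
                 REG_Sprint_R1_C = 1, REG_HSR_R2 = 1, REG_Sprint_R2 = 1,
                 REG_ACWR = 1, REG_ACC_DEC = 0.8)
  loads <- vapply(seq(1, 2.6, by = 0.2), function(a) {
    ins <- benign; ins$REG_ACWR <- a
    suppressWarnings(infer(kb, ins))
  }, numeric(1))
  expect_true(all(diff(loads) >= -1e-9))
  expect_gt(loads[length(loads)], loads[1])
})

test_that("fuzzy decisions for a whole table stay within bounds", {
  f <- compute_derived(add_lags(aggregate_microcycle(
    simulate_sessions(small_config(seed = 23L)), round_boundary = 9L)))
  out <- suppressWarnings(apply_fuzzy(f))
  expect_true(all(out$fuzzy_load >= 0 & out$fuzzy_load <= 10))
  expect_identical(out$fuzzy_decision,
                   as.integer(out$fuzzy_load > 0.6))
})
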