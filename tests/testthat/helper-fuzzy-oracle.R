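# Independent defuzzification oracle: recomputes memberships, activations
# and the centroid by trapezoidal integration on a fine grid, sharing no
# code with the package's inference path.

oracle_trap_mu <- function(params, x) {
  if (length(params) == 3L) params <- params[c(1, 2, 2, 3)]
  a <- params[1]; b <- params[2]; cc <- params[3]; d <- params[4]
  vapply(x, function(xi) {
    if (xi < a || xi > d) return(0)
    if (xi >= b && xi <= cc) return(1)
    if (xi < b) {
      if (b == a) return(1)
      return((xi - a) / (b - a))
    }
    if (d == cc) return(1)
    (d - xi) / (d - cc)
  }, numeric(1))
}

oracle_node_degree <- function(node, inputs, kb) {
  if (!is.null(node$var)) {
    v <- kb$variables[[node$var]]
    src <- if (is.null(v$source)) v$name else v$source
    x <- inputs[[src]]
    if (is.null(x) || is.na(x)) return(0)
    x <- min(max(x, v$universe[1]), v$universe[2])
    return(oracle_trap_mu(v$terms[[node$term]]$params, x))
  }
  degs <- vapply(node$args, oracle_node_degree, numeric(1),
                 inputs = inputs, kb = kb)
  if (node$op == "and") min(degs) else max(degs)
}

oracle_centroid <- function(kb, inputs, step = 1e-4) {
  outv <- kb$variables[[kb$output]]
  xs <- seq(outv$universe[1], outv$universe[2], by = step)
  agg <- numeric(length(xs))
  for (r in kb$rules) {
    act <- oracle_node_degree(r$antecedent, inputs, kb)
    mu <- pmin(act, oracle_trap_mu(outv$terms[[r$consequent$term]]$params,
                                   xs))
    agg <- pmax(agg, mu)
  }
  if (all(agg == 0)) return(mean(outv$universe))
  # trapezoidal rule for both integrals
  w <- c(0.5, rep(1, length(xs) - 2L), 0.5)
  sum(w * agg * xs) / sum(w * agg)
}

# random single-input knowledge base with covering random terms
random_kb <- function(seed) {
  set.seed(seed)
  n_terms <- sample(2:4, 1)
  knots_in <- sort(c(0, runif(n_terms + 1, 0, 2), 2))
  knots_out <- sort(c(0, runif(n_terms + 1, 0, 10), 10))
  mk_terms <- function(knots, n) {
    lapply(seq_len(n), function(i) {
      p <- knots[i:(i + 3)]
      if (i == 1L) p[1:2] <- knots[1]
      if (i == n) p[3:4] <- knots[length(knots)]
      fuzzy_term(paste0("t", i), "trapezoidal", p)
    })
  }
  vin <- linguistic_variable("x", c(0, 2), mk_terms(knots_in, n_terms))
  vout <- linguistic_variable("load", c(0, 10),
                              mk_terms(knots_out, n_terms))
  rules <- lapply(seq_len(n_terms), function(i)
    sprintf("IF (x IS t%d) THEN (load IS t%d)", i,
            sample(n_terms, 1)))
  fuzzy_knowledge_base(list(vin, vout), rules, cutoff = 0.6)
}
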