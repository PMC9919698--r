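# Mamdani fuzzy rule-based decision model: linguistic variables with
# triangular/trapezoidal terms, min/max connectives, clipping implication,
# max aggregation and centroid defuzzification on [0, 10].

#' Construct a fuzzy term
#'
#' @param label Term label (e.g. `"small"`).
#' @param shape `"trapezoidal"` (4 breakpoints) or `"triangular"` (3).
#' @param params Non-decreasing breakpoints: `(a, b, c, d)` for a
#'   trapezoid rising on `[a, b]`, flat on `[b, c]`, falling on `[c, d]`;
#'   `(a, b, c)` for a triangle with apex `b`.
#' @return A `fuzzy_term` object.
#' @export
fuzzy_term <- function(label, shape = c("trapezoidal", "triangular"),
                       params) {
  shape <- match.arg(shape)
  need <- if (shape == "trapezoidal") 4L else 3L
  if (length(params) != need)
    stop("fuzzy term '", label, "': ", shape, " shape needs ", need,
         " breakpoints")
  if (is.unsorted(params))
    stop("fuzzy term '", label, "': breakpoints must be non-decreasing")
  structure(list(label = label, shape = shape, params = as.numeric(params)),
            class = "fuzzy_term")
}

#' Membership degree of a value in a fuzzy term
#'
#' Piecewise-linear evaluation; a zero-width rising or falling edge is a
#' crisp shoulder (membership jumps to 1 at the breakpoint).
#'
#' @param term A [fuzzy_term()].
#' @param x Numeric vector.
#' @return Degrees in \[0, 1\]; `NA` input gives `NA`.
#' @export
membership <- function(term, x) {
  p <- term$params
  if (term$shape == "triangular") p <- c(p[1], p[2], p[2], p[3])
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  rise <- if (b > a) pmin(pmax((x - a) / (b - a), 0), 1) else
    as.numeric(x >= b)
  fall <- if (d > cc) pmin(pmax((d - x) / (d - cc), 0), 1) else
    as.numeric(x <= cc)
  pmin(rise, fall)
}

#' Construct a linguistic variable
#'
#' @param name Variable name as used in rule text.
#' @param universe Closed interval `c(lo, hi)`; inputs are clamped to it.
#' @param terms List of [fuzzy_term()] objects. Together they must cover
#'   the universe (every point has positive membership in some term).
#' @param source Name of the feature-table column feeding the variable
#'   (defaults to `name`); ignored for the output variable.
#' @return A `linguistic_variable` object.
#' @export
linguistic_variable <- function(name, universe, terms, source = name) {
  if (length(universe) != 2L || universe[1] >= universe[2])
    stop("variable '", name, "': universe must be an interval (lo, hi)")
  labels <- vapply(terms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("variable '", name, "': duplicate term labels")
  names(terms) <- labels
  grid <- seq(universe[1], universe[2], length.out = 513L)
  cover <- Reduce(pmax, lapply(terms, membership, x = grid))
  if (any(cover <= 0))
    stop("variable '", name, "': terms do not cover the universe")
  structure(list(name = name, universe = as.numeric(universe),
                 terms = terms, source = source),
            class = "linguistic_variable")
}

## ---- rule text parsing ----------------------------------------------------

.fuzzy_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# recursive-descent parser over tokens; grammar:
#   rule := IF expr THEN ( VAR IS term )
#   expr := conj (OR conj)* ; conj := atom (AND atom)*
#   atom := ( VAR IS term ) | ( expr )
.parse_expr <- function(toks, pos) {
  res <- .parse_conj(toks, pos)
  args <- list(res$node); pos <- res$pos
  while (pos <= length(toks) && toupper(toks[pos]) == "OR") {
    res <- .parse_conj(toks, pos + 1L)
    args <- c(args, list(res$node)); pos <- res$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  list(node = node, pos = pos)
}

.parse_conj <- function(toks, pos) {
  res <- .parse_atom(toks, pos)
  args <- list(res$node); pos <- res$pos
  while (pos <= length(toks) && toupper(toks[pos]) == "AND") {
    res <- .parse_atom(toks, pos + 1L)
    args <- c(args, list(res$node)); pos <- res$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  list(node = node, pos = pos)
}

.parse_atom <- function(toks, pos) {
  if (pos > length(toks) || toks[pos] != "(")
    stop("fuzzy rule parse error: expected '(' at token ", pos)
  if (pos + 2L <= length(toks) && toupper(toks[pos + 2L]) == "IS") {
    if (pos + 4L > length(toks) || toks[pos + 4L] != ")")
      stop("fuzzy rule parse error: malformed atom near '", toks[pos + 1L],
           "'")
    node <- list(var = toks[pos + 1L], term = toks[pos + 3L])
    list(node = node, pos = pos + 5L)
  } else {
    res <- .parse_expr(toks, pos + 1L)
    if (res$pos > length(toks) || toks[res$pos] != ")")
      stop("fuzzy rule parse error: unbalanced parentheses")
    list(node = res$node, pos = res$pos + 1L)
  }
}

#' Parse a fuzzy rule from its textual form
#'
#' Accepts the grammar `IF (VAR IS term) AND/OR ... THEN (VAR IS term)`,
#' with AND binding tighter than OR and parentheses available for
#' grouping.
#'
#' @param text Rule text.
#' @return A `fuzzy_rule` with fields `antecedent` (expression tree),
#'   `consequent` (`var`, `term`) and `text` (canonical form).
#' @export
fuzzy_rule <- function(text) {
  toks <- .fuzzy_tokenize(text)
  if (length(toks) < 7L || toupper(toks[1]) != "IF")
    stop("fuzzy rule parse error: rule must start with IF")
  res <- .parse_expr(toks, 2L)
  if (res$pos > length(toks) || toupper(toks[res$pos]) != "THEN")
    stop("fuzzy rule parse error: missing THEN")
  cons <- .parse_atom(toks, res$pos + 1L)
  if (is.null(cons$node$var))
    stop("fuzzy rule parse error: consequent must be a single atom")
  if (cons$pos <= length(toks))
    stop("fuzzy rule parse error: trailing tokens")
  rule <- structure(list(antecedent = res$node, consequent = cons$node),
                    class = "fuzzy_rule")
  rule$text <- format_fuzzy_rule(rule)
  rule
}

#' Canonical textual form of a fuzzy rule
#'
#' @param rule A [fuzzy_rule()].
#' @return Single string `IF ... THEN (var IS term)`.
#' @export
format_fuzzy_rule <- function(rule) {
  fmt <- function(node, parent_op = NULL) {
    if (!is.null(node$var))
      return(paste0("(", node$var, " IS ", node$term, ")"))
    sep <- if (node$op == "and") " AND " else " OR "
    body <- paste(vapply(node$args, fmt, character(1), parent_op = node$op),
                  collapse = sep)
    # parenthesize an OR nested under AND (precedence would otherwise flip)
    if (identical(parent_op, "and") && node$op == "or")
      body <- paste0("(", body, ")")
    body
  }
  paste0("IF ", fmt(rule$antecedent), " THEN (",
         rule$consequent$var, " IS ", rule$consequent$term, ")")
}

#' Assemble a fuzzy knowledge base
#'
#' @param variables List of [linguistic_variable()] objects, including the
#'   output variable.
#' @param rules List of [fuzzy_rule()] objects (or rule strings).
#' @param cutoff Crisp decision cutoff on the output (default 0.6,
#'   strict: outputs above it are flagged).
#' @param output Name of the output variable (default `"load"`).
#' @param grid_step Defuzzification grid step (default 0.01).
#' @return A `fuzzy_kb` object.
#' @export
fuzzy_knowledge_base <- function(variables, rules, cutoff = 0.6,
                                 output = "load", grid_step = 0.01) {
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  if (!output %in% names(variables))
    stop("knowledge-base error: output variable '", output, "' undefined")
  if (cutoff <= variables[[output]]$universe[1] ||
      cutoff >= variables[[output]]$universe[2])
    stop("knowledge-base error: cutoff outside the output universe")
  if (grid_step <= 0 || grid_step > 0.01)
    stop("knowledge-base error: grid_step must be in (0, 0.01]")
  rules <- lapply(rules, function(r)
    if (inherits(r, "fuzzy_rule")) r else fuzzy_rule(r))
  check_node <- function(node) {
    if (!is.null(node$var)) {
      if (!node$var %in% names(variables))
        stop("knowledge-base error: unknown variable '", node$var, "'")
      if (!node$term %in% names(variables[[node$var]]$terms))
        stop("knowledge-base error: unknown term '", node$term,
             "' for variable '", node$var, "'")
    } else lapply(node$args, check_node)
    invisible(NULL)
  }
  for (r in rules) {
    check_node(r$antecedent)
    if (r$consequent$var != output)
      stop("knowledge-base error: consequent must use the output variable")
    check_node(r$consequent)
  }
  structure(list(variables = variables, rules = rules, cutoff = cutoff,
                 output = output, grid_step = grid_step),
            class = "fuzzy_kb")
}

## ---- inference ------------------------------------------------------------

.node_degree <- function(node, inputs, kb) {
  if (!is.null(node$var)) {
    v <- kb$variables[[node$var]]
    x <- inputs[[v$source %||% v$name]]
    if (is.null(x) || length(x) == 0L || is.na(x)) return(0)
    x <- min(max(as.numeric(x), v$universe[1]), v$universe[2])
    return(membership(v$terms[[node$term]], x))
  }
  degs <- vapply(node$args, .node_degree, numeric(1), inputs = inputs,
                 kb = kb)
  if (node$op == "and") min(degs) else max(degs)
}

#' Activation degree of a fuzzy rule for crisp inputs
#'
#' AND combines operand degrees by minimum, OR by maximum. Missing inputs
#' contribute zero membership.
#'
#' @param rule A [fuzzy_rule()].
#' @param crisp_inputs Named list / one-row data frame of input values.
#' @param kb The [fuzzy_knowledge_base()] defining variables and terms.
#' @return Degree in \[0, 1\].
#' @export
rule_activation <- function(rule, crisp_inputs, kb) {
  .node_degree(rule$antecedent, crisp_inputs, kb)
}

#' Mamdani inference: crisp output for one observation
#'
#' Each rule's consequent term is clipped at the rule's activation, the
#' clipped sets are aggregated by pointwise maximum, and the crisp output
#' is the centroid of the aggregate on a uniform grid over the output
#' universe. If no rule fires the midpoint of the output universe is
#' returned with a warning.
#'
#' @param kb A [fuzzy_knowledge_base()].
#' @param derived Named list / one-row data frame holding the input values
#'   (matched through each variable's `source` column name).
#' @return Crisp output value within the output universe.
#' @export
infer <- function(kb, derived) {
  outv <- kb$variables[[kb$output]]
  grid <- seq(outv$universe[1], outv$universe[2], by = kb$grid_step)
  cons_mu <- lapply(kb$rules, function(r)
    membership(outv$terms[[r$consequent$term]], grid))
  agg <- numeric(length(grid))
  for (i in seq_along(kb$rules)) {
    act <- rule_activation(kb$rules[[i]], derived, kb)
    if (act > 0) agg <- pmax(agg, pmin(act, cons_mu[[i]]))
  }
  if (all(agg == 0)) {
    warning("no rule fired; returning midpoint of the output universe")
    return(mean(outv$universe))
  }
  .grid_centroid(agg, grid)
}

# centroid by trapezoidal quadrature (exact up to the grid's kink placement)
.grid_centroid <- function(mu, grid) {
  w <- c(0.5, rep(1, length(grid) - 2L), 0.5)
  sum(w * mu * grid) / sum(w * mu)
}

#' Binary decision from the crisp fuzzy output
#'
#' @param load Crisp output value(s).
#' @param cutoff Cutoff; values strictly above it are flagged as injuries
#'   (default 0.6).
#' @return Integer vector in \{0, 1\}.
#' @export
classify_fuzzy <- function(load, cutoff = 0.6) {
  as.integer(load > cutoff)
}

#' Apply a fuzzy knowledge base to a whole feature table
#'
#' @param features Feature table with the derived `REG_*` columns.
#' @param kb A [fuzzy_knowledge_base()] (default
#'   [default_knowledge_base()]).
#' @return `features` with `fuzzy_load` and `fuzzy_decision` appended.
#' @export
apply_fuzzy <- function(features, kb = default_knowledge_base()) {
  outv <- kb$variables[[kb$output]]
  grid <- seq(outv$universe[1], outv$universe[2], by = kb$grid_step)
  cons_mu <- lapply(kb$rules, function(r)
    membership(outv$terms[[r$consequent$term]], grid))
  load <- numeric(nrow(features))
  fired <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    inputs <- features[i, , drop = FALSE]
    agg <- numeric(length(grid))
    for (j in seq_along(kb$rules)) {
      act <- rule_activation(kb$rules[[j]], inputs, kb)
      if (act > 0) agg <- pmax(agg, pmin(act, cons_mu[[j]]))
    }
    if (all(agg == 0)) {
      load[i] <- mean(outv$universe)
    } else {
      fired[i] <- TRUE
      load[i] <- .grid_centroid(agg, grid)
    }
  }
  if (!all(fired))
    warning(sum(!fired), " row(s) fired no rule; midpoint returned")
  features$fuzzy_load <- load
  features$fuzzy_decision <- classify_fuzzy(load, kb$cutoff)
  features
}

## ---- shipped default knowledge base ---------------------------------------

.ratio_terms <- function() list(
  fuzzy_term("small", "trapezoidal", c(0, 0, 0.45, 0.7)),
  fuzzy_term("ok", "trapezoidal", c(0.55, 0.85, 1.25, 1.5)),
  fuzzy_term("big", "trapezoidal", c(1.35, 1.65, 2.0, 2.4)),
  fuzzy_term("very_big", "trapezoidal", c(2.0, 2.4, 3, 3))
)

.acwr_terms <- function() list(
  fuzzy_term("very_small", "trapezoidal", c(0, 0, 0.40, 0.55)),
  fuzzy_term("small", "trapezoidal", c(0.40, 0.55, 0.70, 0.85)),
  fuzzy_term("ok", "trapezoidal", c(0.70, 0.85, 1.25, 1.45)),
  fuzzy_term("big", "trapezoidal", c(1.25, 1.45, 1.65, 1.90)),
  fuzzy_term("very_big", "trapezoidal", c(1.65, 1.90, 3, 3))
)

.acc_terms <- function() list(
  fuzzy_term("very_small", "trapezoidal", c(0, 0, 0.15, 0.30)),
  fuzzy_term("small", "trapezoidal", c(0.15, 0.30, 0.45, 0.65)),
  fuzzy_term("ok", "trapezoidal", c(0.45, 0.65, 1.1, 1.4)),
  fuzzy_term("big", "trapezoidal", c(1.1, 1.4, 3, 3))
)

.load_terms <- function() list(
  fuzzy_term("very_small", "trapezoidal", c(0, 0, 0.3, 1.2)),
  fuzzy_term("small", "triangular", c(0.8, 2, 3.5)),
  fuzzy_term("medium", "triangular", c(3, 5, 7)),
  fuzzy_term("big", "triangular", c(5.5, 7.5, 9)),
  fuzzy_term("very_big", "trapezoidal", c(8, 9.5, 10, 10))
)

# The shipped 34-rule base. The first five rules are the published
# examples; the rest extend their patterns (jointly-small ratio triples ->
# very_small load, out-of-band ratios -> small load, big match-to-week
# ratios -> big load) across the HSR, Sprint and acc/dec families.
.default_rule_text <- function() c(
  "IF (HSR_R1_A IS small) AND (HSR_R1_B IS small) AND (HSR_R1_C IS small) THEN (load IS very_small)",
  "IF (REG_ACWR IS small) OR (REG_ACWR IS big) THEN (load IS small)",
  "IF (HSR_R2 IS big) THEN (load IS big)",
  "IF (SPRINT_R1_A IS small) AND (SPRINT_R1_B IS small) AND (SPRINT_R1_C IS small) THEN (load IS very_small)",
  "IF (REG_ACC IS small) THEN (load IS small)",
  "IF (HSR_R1_A IS big) AND (HSR_R1_B IS big) AND (HSR_R1_C IS big) THEN (load IS small)",
  "IF (SPRINT_R1_A IS big) AND (SPRINT_R1_B IS big) AND (SPRINT_R1_C IS big) THEN (load IS small)",
  "IF (HSR_R1_A IS ok) AND (HSR_R1_B IS ok) AND (HSR_R1_C IS ok) THEN (load IS very_small)",
  "IF (SPRINT_R1_A IS ok) AND (SPRINT_R1_B IS ok) AND (SPRINT_R1_C IS ok) THEN (load IS very_small)",
  "IF (HSR_R1_A IS small) AND (HSR_R1_B IS small) THEN (load IS small)",
  "IF (HSR_R1_A IS big) AND (HSR_R1_B IS big) THEN (load IS small)",
  "IF (HSR_R1_B IS small) AND (HSR_R1_C IS small) THEN (load IS small)",
  "IF (SPRINT_R1_A IS small) AND (SPRINT_R1_B IS small) THEN (load IS small)",
  "IF (SPRINT_R1_A IS big) AND (SPRINT_R1_B IS big) THEN (load IS small)",
  "IF (SPRINT_R1_B IS small) AND (SPRINT_R1_C IS small) THEN (load IS small)",
  "IF (HSR_R2 IS small) THEN (load IS very_small)",
  "IF (HSR_R2 IS ok) THEN (load IS very_small)",
  "IF (SPRINT_R2 IS big) THEN (load IS big)",
  "IF (SPRINT_R2 IS small) THEN (load IS very_small)",
  "IF (SPRINT_R2 IS ok) THEN (load IS very_small)",
  "IF (REG_ACWR IS ok) THEN (load IS very_small)",
  "IF (REG_ACWR IS very_small) OR (REG_ACWR IS very_big) THEN (load IS big)",
  "IF (REG_ACC IS ok) THEN (load IS very_small)",
  "IF (REG_ACC IS big) THEN (load IS small)",
  "IF (REG_ACC IS very_small) THEN (load IS small)",
  "IF (HSR_R1_A IS very_big) THEN (load IS medium)",
  "IF (SPRINT_R1_A IS very_big) THEN (load IS medium)",
  "IF (REG_ACWR IS big) AND (HSR_R1_A IS big) THEN (load IS big)",
  "IF (REG_ACWR IS small) AND (HSR_R1_A IS small) THEN (load IS big)",
  "IF (HSR_R2 IS big) AND (SPRINT_R2 IS big) THEN (load IS very_big)",
  "IF (REG_ACWR IS very_big) AND (HSR_R1_A IS very_big) THEN (load IS very_big)",
  "IF (REG_ACC IS small) AND (REG_ACWR IS small) THEN (load IS big)",
  "IF (HSR_R1_A IS ok) AND (SPRINT_R1_A IS ok) AND (REG_ACWR IS ok) THEN (load IS very_small)",
  "IF (HSR_R2 IS ok) AND (SPRINT_R2 IS ok) AND (REG_ACC IS ok) THEN (load IS very_small)"
)

#' Shipped default fuzzy knowledge base
#'
#' Thirty-four Mamdani rules over ten input linguistic variables (the
#' week-over-week HSR and Sprint ratio triples, the match-to-week R2
#' ratios, the acute:chronic workload ratio and the acc/dec match-to-week
#' ratio) and the output variable `load` on \[0, 10\] with a 0.6 decision
#' cutoff. Membership breakpoints blur the crisp band edges of the expert
#' ruleset (0.5, 0.7, 0.8, 1.3, 1.4, 1.6); the benign terms concentrate
#' output mass near zero so the low cutoff separates routine weeks from
#' flagged ones.
#'
#' @return A `fuzzy_kb` with exactly 34 rules.
#' @export
default_knowledge_base <- function() {
  mk_ratio <- function(name, source)
    linguistic_variable(name, c(0, 3), .ratio_terms(), source)
  vars <- list(
    mk_ratio("HSR_R1_A", "REG_HSR_R1_A"),
    mk_ratio("HSR_R1_B", "REG_HSR_R1_B"),
    mk_ratio("HSR_R1_C", "REG_HSR_R1_C"),
    mk_ratio("SPRINT_R1_A", "REG_Sprint_R1_A"),
    mk_ratio("SPRINT_R1_B", "REG_Sprint_R1_B"),
    mk_ratio("SPRINT_R1_C", "REG_Sprint_R1_C"),
    mk_ratio("HSR_R2", "REG_HSR_R2"),
    mk_ratio("SPRINT_R2", "REG_Sprint_R2"),
    linguistic_variable("REG_ACWR", c(0, 3), .acwr_terms(), "REG_ACWR"),
    linguistic_variable("REG_ACC", c(0, 3), .acc_terms(), "REG_ACC_DEC"),
    linguistic_variable("load", c(0, 10), .load_terms(), "load")
  )
  fuzzy_knowledge_base(vars, .default_rule_text(), cutoff = 0.6)
}

## ---- plain-text serialization ---------------------------------------------

#' Write a fuzzy knowledge base to a plain-text file
#'
#' The format mirrors the rule grammar: `VARIABLE`/`TERM` declarations
#' followed by a `RULES` section of `IF ... THEN ...` lines.
#'
#' @param kb A `fuzzy_kb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  lines <- c("# fuzzy knowledge base",
             paste("CUTOFF", format(kb$cutoff, digits = 15)),
             paste("GRID_STEP", format(kb$grid_step, digits = 15)),
             paste("OUTPUT", kb$output))
  for (v in kb$variables) {
    lines <- c(lines, paste("VARIABLE", v$name, "RANGE",
                            format(v$universe[1], digits = 15),
                            format(v$universe[2], digits = 15),
                            "SOURCE", v$source %||% v$name))
    for (tm in v$terms) {
      lines <- c(lines, paste("  TERM", tm$label, toupper(tm$shape),
                              paste(format(tm$params, digits = 15,
                                           trim = TRUE), collapse = " ")))
    }
  }
  lines <- c(lines, "RULES",
             vapply(kb$rules, `[[`, character(1), "text"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fuzzy knowledge base from a plain-text file
#'
#' @param path Path written by [write_knowledge_base()] (or hand-edited).
#' @return A `fuzzy_kb`; structural validity is re-checked on load.
#' @export
read_knowledge_base <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cutoff <- 0.6; grid_step <- 0.01; output <- "load"
  vars <- list(); rules <- character()
  cur <- NULL; in_rules <- FALSE
  flush_var <- function(cur, vars) {
    if (is.null(cur)) return(vars)
    v <- linguistic_variable(cur$name, cur$universe, cur$terms, cur$source)
    c(vars, list(v))
  }
  for (ln in lines) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (in_rules) {
      rules <- c(rules, ln)
    } else if (toks[1] == "CUTOFF") {
      cutoff <- as.numeric(toks[2])
    } else if (toks[1] == "GRID_STEP") {
      grid_step <- as.numeric(toks[2])
    } else if (toks[1] == "OUTPUT") {
      output <- toks[2]
    } else if (toks[1] == "VARIABLE") {
      vars <- flush_var(cur, vars)
      cur <- list(name = toks[2],
                  universe = as.numeric(toks[4:5]),
                  source = if (length(toks) >= 7) toks[7] else toks[2],
                  terms = list())
    } else if (toks[1] == "TERM") {
      shape <- if (toupper(toks[3]) == "TRIANGULAR") "triangular"
      else "trapezoidal"
      cur$terms <- c(cur$terms, list(
        fuzzy_term(toks[2], shape, as.numeric(toks[-(1:3)]))))
    } else if (toks[1] == "RULES") {
      vars <- flush_var(cur, vars); cur <- NULL
      in_rules <- TRUE
    } else {
      stop("knowledge-base file parse error at line: ", ln)
    }
  }
  fuzzy_knowledge_base(vars, rules, cutoff = cutoff, output = output,
                       grid_step = grid_step)
}
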