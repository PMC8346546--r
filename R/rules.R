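# Fuzzy rules, inference and defuzzification (steps 2 and 3 of the
# Mamdani controller).
#
# A rule is a conjunction of clauses plus an optional "k of n" group.
# Clause forms:
#   - levels = character vector  -> degree = s-norm over those levels (OR)
#   - levels = "*"               -> wildcard, degree 1
#   - negate = TRUE, one level   -> degree = s-norm over all OTHER levels
# Group ("any choice of one or more" / "any choice of two or more"): a list
# of (input, level) members; its degree is the k-th largest member degree,
# which is the min/max-algebra value of "at least k of these hold".

#' Construct a fuzzy rule
#'
#' @param action Consequent action: one of `proliferation`, `mortality`,
#'   `migration`, `early_differentiation`, `late_differentiation`.
#' @param level Consequent output level label (must exist in the action's
#'   output scale).
#' @param clauses List of clauses built with [fl_clause()] /
#'   [fl_clause_not()]; all must hold (t-norm).
#' @param any_of Optional list of `(input, level)` pairs (each a
#'   `list(input=, level=)`); the rule additionally requires at least
#'   `at_least` of them to hold.
#' @param at_least Either 1 ("any one or more") or 2 ("any two or more").
#' @return An object of class `fl_rule`.
#' @export
fl_rule <- function(action, level, clauses = list(), any_of = NULL,
                    at_least = 1L) {
  stopifnot(at_least %in% c(1L, 2L))
  if (!is.null(any_of)) {
    ok <- vapply(any_of, function(m)
      is.list(m) && all(c("input", "level") %in% names(m)), logical(1))
    if (!all(ok)) stop("any_of members must be list(input=, level=)")
    if (length(any_of) < at_least)
      stop("group has fewer members than 'at_least'")
  }
  structure(list(action = action, level = level, clauses = clauses,
                 any_of = any_of, at_least = as.integer(at_least)),
            class = "fl_rule")
}

#' @rdname fl_rule
#' @param input Input name the clause constrains.
#' @param levels Character vector of admissible levels, or `"*"` for a
#'   wildcard that matches every level.
#' @export
fl_clause <- function(input, levels = "*") {
  list(input = input, levels = levels, negate = FALSE)
}

#' @rdname fl_rule
#' @export
fl_clause_not <- function(input, level) {
  list(input = input, levels = level, negate = TRUE)
}

# degree of one clause for a list of fuzzified matrices (n rows each)
clause_degree <- function(clause, fuzz, snorm = pmax) {
  fm <- fuzz[[clause$input]]
  if (is.null(fm)) stop("unknown input in rule clause: ", clause$input)
  if (identical(clause$levels, "*") && !clause$negate)
    return(rep(1, nrow(fm)))
  lv <- if (clause$negate) setdiff(colnames(fm), clause$levels) else clause$levels
  miss <- setdiff(lv, colnames(fm))
  if (length(miss)) stop("unknown level(s) in rule clause: ",
                         paste(miss, collapse = ", "))
  Reduce(snorm, lapply(lv, function(l) fm[, l]))
}

# k-th largest across columns of a list of degree vectors, vectorized
kth_largest <- function(cols, k) {
  if (k == 1L) return(Reduce(pmax, cols))
  # running top-2
  m1 <- rep(-Inf, length(cols[[1]])); m2 <- m1
  for (d in cols) {
    bigger <- d > m1
    m2 <- ifelse(bigger, m1, pmax(m2, d))
    m1 <- pmax(m1, d)
  }
  m2
}

#' Fire one rule against fuzzified inputs
#'
#' Computes the activation strength of a rule: the t-norm (default `min`)
#' over its clause degrees and, when present, the "at least k of n" group
#' degree (the k-th largest member degree).
#'
#' @param rule An `fl_rule`.
#' @param fuzz Named list of fuzzified-degree matrices (one per input, as
#'   returned by [fl_fuzzify()]), all with the same row count.
#' @param tnorm,snorm Aggregation functions (vectorized, binary);
#'   defaults `pmin`/`pmax`, the Mamdani standard.
#' @return Numeric vector of activation strengths in `[0, 1]`.
#' @export
fl_fire_rule <- function(rule, fuzz, tnorm = pmin, snorm = pmax) {
  n <- nrow(fuzz[[1]])
  deg <- rep(1, n)
  for (cl in rule$clauses)
    deg <- tnorm(deg, clause_degree(cl, fuzz, snorm))
  if (!is.null(rule$any_of)) {
    cols <- lapply(rule$any_of, function(m) {
      fm <- fuzz[[m$input]]
      if (is.null(fm) || !(m$level %in% colnames(fm)))
        stop("unknown input/level in rule group: ", m$input, "/", m$level)
      fm[, m$level]
    })
    deg <- tnorm(deg, kth_largest(cols, rule$at_least))
  }
  deg
}

#' Output scale for one action
#'
#' Ordered output levels with their representative crisp values; the
#' defuzzified output is the strength-weighted mean of the representatives
#' of the activated levels.
#'
#' @param reps Named numeric vector of representative values, strictly
#'   increasing, all in `[0, 1]`, in level order.
#' @return An object of class `fl_scale`.
#' @export
fl_scale <- function(reps) {
  if (is.null(names(reps)) || any(names(reps) == ""))
    stop("representative values must be named by level")
  if (any(reps < 0 | reps > 1)) stop("representative values must lie in [0, 1]")
  if (any(diff(reps) <= 0))
    stop("representative values must be strictly increasing with level order")
  structure(list(reps = reps), class = "fl_scale")
}

#' Defuzzify activated output levels (weighted fuzzy mean)
#'
#' @param scale An `fl_scale` for the action.
#' @param strengths Named numeric vector/matrix of aggregated activation
#'   strengths per output level (columns named by level when a matrix).
#' @param default Crisp value returned when no level is activated.
#' @return Crisp value(s) in `[0, 1]`:
#'   `sum(strength * rep) / sum(strength)`, or `default` where all
#'   strengths are zero.
#' @export
fl_defuzzify <- function(scale, strengths, default = 0) {
  stopifnot(inherits(scale, "fl_scale"))
  if (is.matrix(strengths)) {
    lv <- colnames(strengths)
    if (!all(lv %in% names(scale$reps))) stop("unknown output level")
    num <- as.vector(strengths %*% scale$reps[lv])
    den <- rowSums(strengths)
  } else {
    lv <- names(strengths)
    if (!all(lv %in% names(scale$reps))) stop("unknown output level")
    num <- sum(strengths * scale$reps[lv])
    den <- sum(strengths)
  }
  out <- ifelse(den > 0, num / den, default)
  out
}

#' Assemble a Mamdani fuzzy-logic controller
#'
#' @param inputs Named list of `fl_input` objects (all seven cell inputs).
#' @param rules List of `fl_rule` objects.
#' @param scales Named list of `fl_scale` objects, one per action.
#' @param default Crisp output when no rule fires for an action (default 0,
#'   i.e. no action).
#' @return An object of class `fl_controller`.
#' @export
fl_controller <- function(inputs, rules, scales, default = 0) {
  ctrl <- structure(list(inputs = inputs, rules = rules, scales = scales,
                         default = default), class = "fl_controller")
  validate_controller(ctrl)
  ctrl
}

#' Validate a controller's internal consistency
#'
#' Checks that every rule references registered inputs/levels, that every
#' consequent level exists in its action's output scale, and that scales and
#' membership functions satisfy their invariants.
#'
#' @param ctrl An `fl_controller`.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_controller <- function(ctrl) {
  lvls <- lapply(ctrl$inputs, function(i)
    if (i$crisp) i$levels else names(i$levels))
  for (r in ctrl$rules) {
    sc <- ctrl$scales[[r$action]]
    if (is.null(sc)) stop("rule action without output scale: ", r$action)
    if (!(r$level %in% names(sc$reps)))
      stop("rule consequent level not in scale: ", r$action, "/", r$level)
    for (cl in r$clauses) {
      if (is.null(lvls[[cl$input]])) stop("rule references unknown input: ", cl$input)
      if (!identical(cl$levels, "*") &&
          !all(cl$levels %in% lvls[[cl$input]]))
        stop("rule references unknown level of ", cl$input, ": ",
             paste(setdiff(cl$levels, lvls[[cl$input]]), collapse = ", "))
    }
    for (m in r$any_of %||% list()) {
      if (is.null(lvls[[m$input]])) stop("rule group references unknown input: ", m$input)
      if (!(m$level %in% lvls[[m$input]]))
        stop("rule group references unknown level of ", m$input, ": ", m$level)
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the controller for a set of cells
#'
#' Runs fuzzification, rule inference and weighted-fuzzy-mean
#' defuzzification for every row of `x` and returns the five action
#' intensities. Early- and late-differentiation channels are both returned;
#' the cell model selects between them by comparing maturity with the
#' maturity threshold.
#'
#' @param ctrl An `fl_controller`.
#' @param x Data frame (or named list of equal-length numeric vectors) with
#'   columns `maturity`, `dna_damage`, `mg`, `alkalinity`, `bmp2`, `tgfb1`,
#'   `density`.
#' @return Data frame with columns `fP`, `fM`, `fMi`, `fD_early`, `fD_late`,
#'   all in `[0, 1]`.
#' @export
#' @examples
#' ctrl <- default_controller()
#' fl_evaluate(ctrl, data.frame(maturity = 0.1, dna_damage = 0, mg = 4.5,
#'   alkalinity = 0, bmp2 = 0, tgfb1 = 0, density = 0.2))
fl_evaluate <- function(ctrl, x) {
  need <- names(ctrl$inputs)
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing controller input(s): ",
                         paste(miss, collapse = ", "))
  out <- fl_evaluate_core(ctrl, x)
  data.frame(fP = out$fP, fM = out$fM, fMi = out$fMi,
             fD_early = out$fD_early, fD_late = out$fD_late)
}

# hot-path evaluation: same semantics as fl_evaluate, returns a plain list
fl_evaluate_core <- function(ctrl, x) {
  inputs <- ctrl$inputs
  n <- length(x[[1]])
  fuzz <- vector("list", length(inputs))
  names(fuzz) <- names(inputs)
  for (nm in names(inputs)) {
    inp <- inputs[[nm]]
    v <- x[[nm]]
    if (inp$crisp) {
      m <- cbind(as.numeric(v == 0), as.numeric(v == 1))
      colnames(m) <- inp$levels
    } else {
      lv <- names(inp$levels)
      m <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
      for (j in seq_along(lv)) m[, j] <- mf_degree(inp$levels[[j]], v)
    }
    fuzz[[nm]] <- m
  }
  actions <- names(ctrl$scales)
  agg <- vector("list", length(actions))
  names(agg) <- actions
  for (a in actions)
    agg[[a]] <- matrix(0, n, length(ctrl$scales[[a]]$reps),
                       dimnames = list(NULL, names(ctrl$scales[[a]]$reps)))
  for (r in ctrl$rules) {
    s <- rep(1, n)
    for (cl in r$clauses) {
      fm <- fuzz[[cl$input]]
      d <- if (identical(cl$levels, "*")) {
        NULL
      } else {
        lv <- if (cl$negate) setdiff(colnames(fm), cl$levels) else cl$levels
        dd <- fm[, lv[1]]
        for (l in lv[-1]) dd <- pmax(dd, fm[, l])
        dd
      }
      if (!is.null(d)) s <- pmin(s, d)
    }
    if (!is.null(r$any_of)) {
      cols <- lapply(r$any_of, function(m) fuzz[[m$input]][, m$level])
      s <- pmin(s, kth_largest(cols, r$at_least))
    }
    agg[[r$action]][, r$level] <- pmax(agg[[r$action]][, r$level], s)
  }
  dfz <- function(a) {
    m <- agg[[a]]; reps <- ctrl$scales[[a]]$reps
    num <- as.vector(m %*% reps)
    den <- rowSums(m)
    ifelse(den > 0, num / den, ctrl$default)
  }
  list(fP = dfz("proliferation"), fM = dfz("mortality"),
       fMi = dfz("migration"), fD_early = dfz("early_differentiation"),
       fD_late = dfz("late_differentiation"))
}

#' @export
print.fl_controller <- function(x, ...) {
  cat("<fl_controller>\n")
  cat("  inputs: ", paste(names(x$inputs), collapse = ", "), "\n")
  cat("  rules:  ", length(x$rules), "\n")
  cat("  actions:", paste(names(x$scales), collapse = ", "), "\n")
  invisible(x)
}

#' Expanded rule table
#'
#' Expands group combinators into explicit per-member (or per-pair) rows and
#' returns a readable table of the rule base; used by the `validate-rules`
#' command-line tool.
#'
#' @param ctrl An `fl_controller`.
#' @return Data frame with columns `rule`, `antecedent`, `action`, `level`.
#' @export
fl_rule_table <- function(ctrl) {
  rows <- list()
  fmt_cl <- function(cl) {
    if (identical(cl$levels, "*")) return(sprintf("%s is -", cl$input))
    if (cl$negate) return(sprintf("%s is not %s", cl$input, cl$levels))
    sprintf("%s is %s", cl$input, paste(cl$levels, collapse = "|"))
  }
  for (i in seq_along(ctrl$rules)) {
    r <- ctrl$rules[[i]]
    base <- vapply(r$clauses, fmt_cl, character(1))
    ants <- if (is.null(r$any_of)) {
      paste(base, collapse = " AND ")
    } else {
      mem <- vapply(r$any_of, function(m) sprintf("%s is %s", m$input, m$level),
                    character(1))
      combos <- if (r$at_least == 1L) as.list(mem) else
        utils::combn(mem, 2L, simplify = FALSE)
      vapply(combos, function(cc)
        paste(c(base, cc), collapse = " AND "), character(1))
    }
    for (a in ants)
      rows[[length(rows) + 1L]] <- data.frame(
        rule = i, antecedent = if (nzchar(a)) a else "-",
        action = r$action, level = r$level)
  }
  do.call(rbind, rows)
}
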