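# Reference (naive) Mamdani evaluator.
#
# A second, deliberately unoptimized implementation of the controller used
# for validation: group combinators are expanded to explicit rules
# (one per member for "any one or more", one per pair for "any two or
# more"), membership functions are evaluated by a scalar segment walk, and
# all aggregation is done with plain loops over the expanded table. It
# shares no evaluation code with fl_evaluate().

naive_mf <- function(mf, v) {
  x <- mf$x; y <- mf$y
  n <- length(x)
  if (v <= x[1]) return(y[1])
  if (v >= x[n]) return(y[n])
  for (i in seq_len(n - 1L)) {
    if (v >= x[i] && v <= x[i + 1L]) {
      if (x[i + 1L] == x[i]) return(y[i + 1L])
      return(y[i] + (y[i + 1L] - y[i]) * (v - x[i]) / (x[i + 1L] - x[i]))
    }
  }
  stop("unreachable")
}

naive_degree <- function(input, level, v) {
  if (input$crisp) {
    return(as.numeric(input$levels[ifelse(v == 0, 1L, 2L)] == level))
  }
  naive_mf(input$levels[[level]], v)
}

# expand a rule's group into a list of plain clause lists
naive_expand <- function(rule) {
  base <- rule$clauses
  if (is.null(rule$any_of)) return(list(base))
  mem <- lapply(rule$any_of, function(m)
    list(input = m$input, levels = m$level, negate = FALSE))
  combos <- if (rule$at_least == 1L) lapply(mem, list) else
    utils::combn(mem, 2L, simplify = FALSE)
  lapply(combos, function(cc) c(base, cc))
}

#' Brute-force reference evaluation of a controller (one input vector)
#'
#' Evaluates the controller for a single crisp input vector using an
#' independent, enumeration-based code path; intended for validating
#' [fl_evaluate()] and for regression testing custom rule bases.
#'
#' @param ctrl An `fl_controller`.
#' @param row Named list / one-row data frame with the seven crisp inputs.
#' @return Named numeric vector `fP`, `fM`, `fMi`, `fD_early`, `fD_late`.
#' @export
fl_evaluate_naive <- function(ctrl, row) {
  acts <- names(ctrl$scales)
  agg <- lapply(acts, function(a) {
    z <- rep(0, length(ctrl$scales[[a]]$reps))
    names(z) <- names(ctrl$scales[[a]]$reps)
    z
  })
  names(agg) <- acts
  for (rule in ctrl$rules) {
    for (clauses in naive_expand(rule)) {
      s <- 1
      for (cl in clauses) {
        inp <- ctrl$inputs[[cl$input]]
        v <- as.numeric(row[[cl$input]])
        d <- if (identical(cl$levels, "*")) {
          1
        } else if (cl$negate) {
          lv <- if (inp$crisp) inp$levels else names(inp$levels)
          dmax <- 0
          for (l in setdiff(lv, cl$levels))
            dmax <- max(dmax, naive_degree(inp, l, v))
          dmax
        } else {
          dmax <- 0
          for (l in cl$levels) dmax <- max(dmax, naive_degree(inp, l, v))
          dmax
        }
        s <- min(s, d)
      }
      if (s > agg[[rule$action]][rule$level])
        agg[[rule$action]][rule$level] <- s
    }
  }
  out <- vapply(acts, function(a) {
    s <- agg[[a]]; r <- ctrl$scales[[a]]$reps
    tot <- sum(s)
    if (tot == 0) ctrl$default else sum(s * r[names(s)]) / tot
  }, numeric(1))
  c(fP = unname(out["proliferation"]), fM = unname(out["mortality"]),
    fMi = unname(out["migration"]),
    fD_early = unname(out["early_differentiation"]),
    fD_late = unname(out["late_differentiation"]))
}
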