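# YAML round-trip for controllers (rule base + membership breakpoints).

#' Write a controller to a YAML file
#'
#' Serializes the membership functions, rule base, output scales and
#' default output of a controller to a structured text file that can be
#' hand-edited and re-read with [read_controller()]. The round trip is
#' exact: the re-read controller produces bit-identical outputs.
#'
#' @param ctrl An `fl_controller`.
#' @param path File path.
#' @return Invisibly `path`.
#' @export
write_controller <- function(ctrl, path) {
  inp <- lapply(ctrl$inputs, function(i) {
    if (i$crisp) list(crisp = TRUE, levels = as.list(i$levels))
    else list(crisp = FALSE, levels = lapply(i$levels, function(m)
      list(x = as.list(m$x), y = as.list(m$y))))
  })
  rul <- lapply(ctrl$rules, function(r) {
    out <- list(action = r$action, level = r$level, at_least = r$at_least)
    out$clauses <- lapply(r$clauses, function(cl)
      list(input = cl$input, levels = as.list(cl$levels),
           negate = cl$negate))
    if (!is.null(r$any_of))
      out$any_of <- lapply(r$any_of, function(m)
        list(input = m$input, level = m$level))
    out
  })
  sca <- lapply(ctrl$scales, function(s) as.list(s$reps))
  doc <- list(inputs = inp, rules = rul, scales = sca,
              default = ctrl$default)
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read a controller from a YAML file
#'
#' @param path File written by [write_controller()] (or hand-authored in
#'   the same layout).
#' @return An `fl_controller` (validated on load).
#' @export
read_controller <- function(path) {
  doc <- yaml::read_yaml(path)
  inputs <- lapply(names(doc$inputs), function(nm) {
    d <- doc$inputs[[nm]]
    if (isTRUE(d$crisp)) fl_input(nm, unlist(d$levels), crisp = TRUE)
    else fl_input(nm, lapply(d$levels, function(m)
      fl_mf(unlist(m$x), unlist(m$y))))
  })
  names(inputs) <- names(doc$inputs)
  rules <- lapply(doc$rules, function(r) {
    clauses <- lapply(r$clauses %||% list(), function(cl) {
      lv <- unlist(cl$levels)
      if (isTRUE(cl$negate)) fl_clause_not(cl$input, lv)
      else fl_clause(cl$input, lv)
    })
    any_of <- if (!is.null(r$any_of))
      lapply(r$any_of, function(m) list(input = m$input, level = m$level))
    fl_rule(r$action, r$level, clauses = clauses, any_of = any_of,
            at_least = r$at_least %||% 1L)
  })
  scales <- lapply(doc$scales, function(s) fl_scale(unlist(s)))
  fl_controller(inputs, rules, scales, default = doc$default %||% 0)
}
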