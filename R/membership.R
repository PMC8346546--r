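# Piecewise-linear membership functions and linguistic inputs.
#
# All membership functions are stored as (x, y) node lists with y in [0, 1];
# evaluation is linear interpolation with flat extension beyond the outer
# nodes, so shoulder functions saturate automatically.

#' Create a piecewise-linear membership function
#'
#' Membership functions map a crisp input value to a degree of membership in
#' a linguistic level. They are stored as interpolation nodes `(x, y)` and
#' evaluated by linear interpolation; outside the outer nodes the function is
#' flat, so shoulder shapes saturate at their outer plateau.
#'
#' @param x Numeric vector of breakpoints (non-decreasing), in input units.
#' @param y Numeric vector of membership degrees at the breakpoints, each in
#'   `[0, 1]`, same length as `x`.
#' @return An object of class `fl_mf`.
#' @seealso [mf_triangle()], [mf_trapezoid()], [mf_shoulder_low()],
#'   [mf_shoulder_high()] for the usual shapes.
#' @export
#' @examples
#' m <- mf_triangle(0, 1, 2)
#' mf_degree(m, c(-1, 0.5, 1, 1.5, 3))
fl_mf <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2)
    stop("membership function needs >= 2 (x, y) nodes of equal length")
  if (any(diff(x) < 0)) stop("membership breakpoints must be non-decreasing")
  if (any(y < 0 | y > 1)) stop("membership degrees must lie in [0, 1]")
  structure(list(x = x, y = y, dup = anyDuplicated(x) > 0L),
            class = "fl_mf")
}

#' @rdname fl_mf
#' @param a,b,c,d Breakpoints (see shape helpers).
#' @export
mf_triangle <- function(a, b, c) fl_mf(c(a, b, c), c(0, 1, 0))

#' @rdname fl_mf
#' @export
mf_trapezoid <- function(a, b, c, d) fl_mf(c(a, b, c, d), c(0, 1, 1, 0))

#' @rdname fl_mf
#' @export
mf_shoulder_low <- function(a, b) fl_mf(c(a, b), c(1, 0))

#' @rdname fl_mf
#' @export
mf_shoulder_high <- function(a, b) fl_mf(c(a, b), c(0, 1))

#' Evaluate a membership function
#'
#' @param mf An `fl_mf` object.
#' @param v Numeric vector of crisp values.
#' @return Numeric vector of membership degrees in `[0, 1]`.
#' @export
mf_degree <- function(mf, v) {
  if (!inherits(mf, "fl_mf")) stop("'mf' must be an fl_mf object")
  x <- mf$x; y <- mf$y
  if (isTRUE(mf$dup)) {
    # vertical segments: defer to approx's ordered-ties handling
    return(stats::approx(x, y, xout = v, method = "linear", rule = 2,
                         ties = "ordered")$y)
  }
  n <- length(x)
  vc <- pmin(pmax(v, x[1]), x[n])  # flat extension beyond the outer nodes
  i <- findInterval(vc, x, all.inside = TRUE)
  x1 <- x[i]; dx <- x[i + 1L] - x1
  y[i] + (y[i + 1L] - y[i]) * (vc - x1) / dx
}

#' @export
print.fl_mf <- function(x, ...) {
  cat("<fl_mf> nodes:",
      paste(sprintf("(%g, %g)", x$x, x$y), collapse = " "), "\n")
  invisible(x)
}

#' Define a linguistic input variable
#'
#' A linguistic input bundles an ordered set of named membership functions
#' for one controller input. Crisp inputs (DNA damage) bypass interpolation:
#' the value selects exactly one level at degree 1.
#'
#' @param name Input name, one of `maturity`, `dna_damage`, `mg`,
#'   `alkalinity`, `bmp2`, `tgfb1`, `density`.
#' @param levels Named list of `fl_mf` objects, in level order. For crisp
#'   inputs, a character vector of level names (value 0 maps to the first
#'   level, 1 to the second).
#' @param crisp Logical; if `TRUE` the input takes values in `{0, 1}` and is
#'   mapped to a single level at full degree.
#' @return An object of class `fl_input`.
#' @export
fl_input <- function(name, levels, crisp = FALSE) {
  if (crisp) {
    if (!is.character(levels) || length(levels) != 2)
      stop("crisp inputs need exactly two level names")
  } else {
    if (!is.list(levels) || is.null(names(levels)) || any(names(levels) == ""))
      stop("'levels' must be a named list of fl_mf objects")
    ok <- vapply(levels, inherits, logical(1), what = "fl_mf")
    if (!all(ok)) stop("all levels must be fl_mf objects")
  }
  structure(list(name = name, levels = levels, crisp = crisp),
            class = "fl_input")
}

#' Fuzzify crisp values
#'
#' Converts crisp input values into a matrix of membership degrees, one
#' column per linguistic level of the input (step 1 of the Mamdani
#' controller).
#'
#' @param input An `fl_input` object.
#' @param v Numeric vector of crisp values.
#' @return Numeric matrix, `length(v)` rows, one column per level; entries in
#'   `[0, 1]`. Crisp inputs yield exactly one `1` per row.
#' @export
#' @examples
#' mg <- fl_input("mg", list(
#'   negligible = mf_shoulder_low(0.8, 2),
#'   stimulatory = mf_triangle(0.8, 4.5, 10)))
#' fl_fuzzify(mg, c(0.4, 4.5))
fl_fuzzify <- function(input, v) {
  stopifnot(inherits(input, "fl_input"))
  v <- as.numeric(v)
  if (any(!is.finite(v))) stop("crisp values must be finite")
  if (input$crisp) {
    if (any(v != 0 & v != 1)) stop("crisp input must be 0 or 1")
    m <- cbind(as.numeric(v == 0), as.numeric(v == 1))
    colnames(m) <- input$levels
    return(m)
  }
  if (input$name %in% c("mg", "bmp2", "tgfb1") && any(v < 0))
    stop("concentrations must be non-negative")
  m <- vapply(input$levels, mf_degree, numeric(length(v)), v = v)
  if (length(v) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(input$levels)))
  m
}

#' @export
print.fl_input <- function(x, ...) {
  lv <- if (x$crisp) x$levels else names(x$levels)
  cat(sprintf("<fl_input> %s%s: %s\n", x$name,
              if (x$crisp) " (crisp)" else "", paste(lv, collapse = ", ")))
  invisible(x)
}
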