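# Shared helpers: tiny controllers and random controller-input vectors.

# a minimal two-input controller for combinator tests
tiny_controller <- function() {
  inputs <- list(
    a = fl_input("a", list(
      lo = mf_shoulder_low(0, 1),
      hi = mf_shoulder_high(0, 1))),
    b = fl_input("b", list(
      lo = mf_shoulder_low(0, 1),
      mid = mf_triangle(0, 0.5, 1),
      hi = mf_shoulder_high(0, 1))))
  scales <- list(act = fl_scale(c(low = 0.25, high = 0.75)))
  rules <- list(fl_rule("act", "high",
                        clauses = list(fl_clause("a", "hi"))))
  ctrl <- list(inputs = inputs, rules = rules, scales = scales, default = 0)
  class(ctrl) <- "fl_controller"
  ctrl
}

# random crisp input vectors spanning (and exceeding) the usual ranges
random_inputs <- function(n) {
  data.frame(
    maturity = runif(n),
    dna_damage = sample(0:1, n, replace = TRUE),
    mg = runif(n, 0, 80),
    alkalinity = runif(n, 0, 3),
    bmp2 = runif(n, 0, 2500),
    tgfb1 = runif(n, 0, 80),
    density = runif(n))
}

# evaluate controller and oracle over a data frame of inputs, return max
# absolute deviation across all five outputs
oracle_deviation <- function(ctrl, x) {
  fast <- fl_evaluate(ctrl, x)
  mx <- 0
  for (i in seq_len(nrow(x))) {
    slow <- fl_evaluate_naive(ctrl, as.list(x[i, ]))
    mx <- max(mx, max(abs(unlist(fast[i, ]) - slow)))
  }
  mx
}

# neutral input row: every input sits fully in a level no default rule
# group reacts to
neutral_row <- function() {
  list(maturity = 0, dna_damage = 0, mg = 0.4, alkalinity = 0,
       bmp2 = 0, tgfb1 = 0, density = 0.3)
}
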