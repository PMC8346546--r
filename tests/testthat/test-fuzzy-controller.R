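# Mamdani controller: fuzzification, rule firing, defuzzification,
# full-controller behavior and serialization.

test_that("membership functions are bounded, saturate, and interpolate", {
  tri <- mf_triangle(0, 1, 2)
  expect_equal(mf_degree(tri, c(-5, 0, 0.5, 1, 1.5, 2, 9)),
               c(0, 0, 0.5, 1, 0.5, 0, 0))
  sh <- mf_shoulder_high(1, 3)
  expect_equal(mf_degree(sh, c(0, 1, 2, 3, 100)), c(0, 0, 0.5, 1, 1))
  trap <- mf_trapezoid(0, 1, 2, 4)
  expect_equal(mf_degree(trap, c(0.5, 1.5, 3)), c(0.5, 1, 0.5))
  expect_error(fl_mf(c(1, 0), c(0, 1)), "non-decreasing")
  expect_error(fl_mf(c(0, 1), c(0, 2)), "\\[0, 1\\]")
})

test_that("Mg fuzzification matches the configured concentration bands", {
  p <- default_params()
  mg <- default_inputs(p)$mg
  # below the basal-medium bound: fully negligible, nothing else
  deg <- fl_fuzzify(mg, 0.4)
  expect_equal(unname(deg[1, "negligible"]), 1)
  expect_equal(sum(deg[1, setdiff(colnames(deg), "negligible")]), 0)
  # the stimulatory peak parameter marks full stimulatory membership
  deg <- fl_fuzzify(mg, p$cmlt)
  expect_equal(unname(deg[1, "stimulatory"]), 1)
  # midpoint between the stimulatory peak and its upper bound: degrees
  # follow the hand-evaluated piecewise-linear shapes
  v <- (p$cmlt + 10) / 2
  deg <- fl_fuzzify(mg, v)
  expect_equal(unname(deg[1, "stimulatory"]), (10 - v) / (10 - p$cmlt))
  expect_equal(unname(deg[1, "high"]), 0)
  expect_error(fl_fuzzify(mg, -1), "non-negative")
  expect_error(fl_fuzzify(mg, NaN), "finite")
})

test_that("crisp DNA damage always yields exactly one level at degree 1", {
  inp <- default_inputs()$dna_damage
  deg <- fl_fuzzify(inp, c(0, 1, 1, 0))
  expect_true(all(rowSums(deg) == 1))
  expect_true(all(deg %in% c(0, 1)))
  expect_equal(deg[, "high"], c(0, 1, 1, 0))
  expect_error(fl_fuzzify(inp, 0.5), "0 or 1")
})

test_that("rule firing implements t-norm, wildcard and group combinators", {
  fz <- list(a = matrix(c(1, 0.3, 0), 3, 2,
                        dimnames = list(NULL, c("lo", "hi"))),
             b = matrix(c(1, 0.6, 0.2), 3, 2,
                        dimnames = list(NULL, c("lo", "hi"))))
  fz$a[, "lo"] <- 1 - fz$a[, "hi"]
  fz$b[, "lo"] <- 1 - fz$b[, "hi"]
  # single clauses: min t-norm; degree-1 identity; degree-0 annihilator
  r <- fl_rule("x", "l", clauses = list(fl_clause("a", "hi"),
                                        fl_clause("b", "hi")))
  expect_equal(fl_fire_rule(r, fz), c(1, 0.3, 0))
  # wildcard contributes 1
  r <- fl_rule("x", "l", clauses = list(fl_clause("a", "*"),
                                        fl_clause("b", "hi")))
  expect_equal(fl_fire_rule(r, fz), c(1, 0.6, 0.2))
  # "not L" = max over the other levels
  r <- fl_rule("x", "l", clauses = list(fl_clause_not("a", "hi")))
  expect_equal(fl_fire_rule(r, fz), c(0, 0.7, 1))
  # any-one-or-more = max; any-two-or-more = second-largest
  g <- list(list(input = "a", level = "hi"), list(input = "b", level = "hi"))
  r1 <- fl_rule("x", "l", any_of = g, at_least = 1L)
  expect_equal(fl_fire_rule(r1, fz), c(1, 0.6, 0.2))
  r2 <- fl_rule("x", "l", any_of = g, at_least = 2L)
  expect_equal(fl_fire_rule(r2, fz), c(1, 0.3, 0))
})

test_that("defuzzification is the weighted fuzzy mean with a no-fire default", {
  sc <- fl_scale(c(low = 0.2, high = 0.9))
  # single activated level returns its representative value
  expect_equal(fl_defuzzify(sc, c(high = 0.4)), 0.9)
  # two levels: brute-force weighted mean
  expect_equal(fl_defuzzify(sc, c(low = 0.3, high = 0.6)),
               (0.3 * 0.2 + 0.6 * 0.9) / 0.9)
  # nothing fires: configured default
  expect_equal(fl_defuzzify(sc, c(low = 0, high = 0)), 0)
  expect_equal(fl_defuzzify(sc, c(low = 0, high = 0), default = 0.5), 0.5)
  expect_error(fl_scale(c(low = 0.9, high = 0.2)), "increasing")
})

test_that("controller equals the brute-force reference on random inputs", {
  ctrl <- default_controller()
  set.seed(42)
  x <- random_inputs(300)
  expect_lt(oracle_deviation(ctrl, x), 1e-12)
})

test_that("controller outputs are bounded in [0, 1] for extreme inputs", {
  ctrl <- default_controller()
  set.seed(7)
  x <- data.frame(
    maturity = runif(200), dna_damage = sample(0:1, 200, TRUE),
    mg = runif(200, 0, 1e4), alkalinity = runif(200, 0, 50),
    bmp2 = runif(200, 0, 1e6), tgfb1 = runif(200, 0, 1e4),
    density = runif(200))
  f <- fl_evaluate(ctrl, x)
  expect_true(all(as.matrix(f) >= 0 & as.matrix(f) <= 1))
})

test_that("DNA damage raises mortality; stimulatory Mg raises proliferation monotonically", {
  ctrl <- default_controller()
  base <- neutral_row()
  damaged <- base; damaged$dna_damage <- 1
  expect_gt(fl_evaluate(ctrl, as.data.frame(damaged))$fM,
            fl_evaluate(ctrl, as.data.frame(base))$fM)
  # fP non-decreasing along increasing stimulatory-Mg membership
  p <- default_params()
  mgs <- seq(0.8, p$cmlt, length.out = 15)
  x <- as.data.frame(base)[rep(1, 15), ]
  x$mg <- mgs
  fp <- fl_evaluate(ctrl, x)$fP
  expect_true(all(diff(fp) >= -1e-12))
})

test_that("missing inputs and unknown rule references are configuration errors", {
  ctrl <- default_controller()
  expect_error(fl_evaluate(ctrl, data.frame(maturity = 0.1)), "missing")
  bad <- fl_rule("proliferation", "high",
                 clauses = list(fl_clause("unobtainium", "hi")))
  expect_error(
    fl_controller(default_inputs(), c(default_rules(), list(bad)),
                  default_scales()),
    "unknown input")
  bad2 <- fl_rule("proliferation", "no_such_level")
  expect_error(
    fl_controller(default_inputs(), list(bad2), default_scales()),
    "not in scale")
})

test_that("controller round-trips through YAML bit-identically", {
  ctrl <- default_controller()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_controller(ctrl, path)
  ctrl2 <- read_controller(path)
  set.seed(11)
  x <- random_inputs(100)
  expect_identical(fl_evaluate(ctrl, x), fl_evaluate(ctrl2, x))
})

test_that("the expanded rule table covers group combinators", {
  tab <- fl_rule_table(default_controller())
  expect_true(all(c("rule", "antecedent", "action", "level") %in% names(tab)))
  # an any-two-or-more rule over 3 members expands to 3 pairs
  r6 <- tab[tab$rule == 6, ]
  expect_equal(nrow(r6), 3)
  expect_true(all(grepl(" AND ", r6$antecedent)))
})
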