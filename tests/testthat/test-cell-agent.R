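# Cell agent: event-chance equations, pH relaxation, DNA damage,
# differentiation switching, and stochastic event execution.

test_that("proliferation chance is the clamped product with the cycle bias", {
  p <- default_params(gP0 = 0.1, aP = 2, k_omega = 1e6, T_cyc = 24)
  # far past the cycle time the bias saturates at 1
  expect_equal(proliferation_chance(0.5, 1e3, p), 0.1)
  expect_equal(proliferation_chance(0, 1e3, p), 0)
  # unbounded product is clamped to 1
  p2 <- default_params(gP0 = 1, aP = 3, k_omega = 1e6)
  expect_equal(proliferation_chance(1, 1e3, p2), 1)
  # early in the cycle the bias suppresses the chance
  p3 <- default_params(gP0 = 0.1, aP = 2, k_omega = 0.5, T_cyc = 24)
  expect_lt(proliferation_chance(0.5, 0, p3), 1e-4)
  expect_error(proliferation_chance(0.5, 10, default_params(gP0 = -1)))
})

test_that("mortality chance carries the mitotic-damage factor", {
  p <- default_params(gM0 = 0.1, aM = 1, aPM = 1)
  expect_equal(mortality_chance(0.2, 0, p), 0.02)
  expect_equal(mortality_chance(0.2, 1, p), 0.04)
  expect_equal(mortality_chance(0, 1, p), 0)
  p2 <- default_params(gM0 = 1, aM = 5, aPM = 3)
  expect_equal(mortality_chance(1, 1, p2), 1)  # clamped
})

test_that("migration chance is the identity on the controller output", {
  expect_equal(migration_chance(0), 0)
  expect_equal(migration_chance(0.7), 0.7)
  expect_equal(migration_chance(1), 1)
})

test_that("differentiation advances maturity and switches channel at Mt", {
  p <- default_params(aD = 2, rD0 = 0.01, Mt = 0.5)
  expect_equal(differentiation_step(0.2, 0, 0, p), 0.2)
  expect_equal(differentiation_step(0.2, 0.5, 0, p), 0.21)
  # late cells use the late channel
  expect_equal(differentiation_step(0.7, 0.5, 0.25, p), 0.705)
  # capped at 1
  expect_equal(differentiation_step(0.999, 1, 1, p), 1)
  # two hand-computed steps straddling the threshold: the first uses the
  # early channel up to 0.5, the second must use the late channel
  m1 <- differentiation_step(0.49, 1, 0.1, p)   # 0.49 + 0.02 = 0.51
  expect_equal(m1, 0.51)
  m2 <- differentiation_step(m1, 1, 0.1, p)     # late: + 0.002
  expect_equal(m2, 0.512)
})

test_that("internal pH relaxes linearly without overshoot", {
  expect_equal(relax_internal_ph(7.4, 7.4, 0.2), 7.4)   # fixed point
  expect_equal(relax_internal_ph(7.4, 7.9, 0.2), 7.6)   # gap 0.5 -> 0.3
  expect_equal(relax_internal_ph(7.4, 7.5, 0.2), 7.5)   # saturation
  expect_equal(relax_internal_ph(7.9, 7.4, 0.2), 7.7)   # downward too
  expect_error(relax_internal_ph(7.4, 7.5, 0.2, dt = 0), "positive")
})

test_that("DNA damage: initial chance, pH trigger, absorbing state", {
  p0 <- default_params(gC = 0)
  expect_equal(check_dna_damage(rep(0L, 100), 7.4, p0, is_init = TRUE),
               rep(0L, 100))
  p1 <- default_params(gC = 1)
  expect_equal(check_dna_damage(rep(0L, 100), 7.4, p1, is_init = TRUE),
               rep(1L, 100))
  # one step at or above the damaging pH deterministically damages
  p <- default_params(pH_t = 9)
  expect_equal(check_dna_damage(c(0L, 0L), 9.0, p), c(1L, 1L))
  expect_equal(check_dna_damage(c(0L, 0L), 8.99, p), c(0L, 0L))
  # damage never reverts under benign pH
  expect_equal(check_dna_damage(c(1L, 0L), 7.4, p), c(1L, 0L))
})

test_that("division creates one adjacent daughter with the damage flag on exactly one of the pair", {
  # chance-1 proliferation, no mortality/migration
  p <- default_params(gP0 = 1, aP = 10, gM0 = 0, k_omega = 1e6, T_cyc = 0)
  pr <- sim_protocol(3, 1, 1, 1, world_dim = c(5, 5, 3))
  st <- simulate_init(pr, p, seed = 4, record_events = TRUE)
  mother_patch <- c(st$px[1], st$py[1], st$pz[1])
  sim_step(st)
  expect_equal(sum(st$alive), 2)
  expect_equal(st$n_born, 1)
  expect_equal(st$clock[1], 1)  # reset at division, then advanced one step
  expect_equal(sum(st$deltap), 1)  # exactly one of the pair
  # daughter adjacent to the mother
  dd <- abs(c(st$px[2], st$py[2], st$pz[2]) - mother_patch)
  expect_true(all(dd <= 1) && any(dd == 1))
  lw_check_occupancy(st$world,
                     cbind(st$px, st$py, st$pz)[st$alive, , drop = FALSE])
})

test_that("with all chances zero only maturity advances", {
  p <- default_params(gP0 = 0, gM0 = 0, gC = 0)
  pr <- sim_protocol(3, 5, 1, 1, world_dim = c(6, 6, 3))
  st <- simulate_init(pr, p, seed = 9)
  m0 <- st$maturity[st$alive]
  for (i in 1:10) sim_step(st)
  expect_equal(sum(st$alive), 5)
  expect_equal(st$n_dead, 0)
  expect_true(all(st$maturity[st$alive] > m0))
})

test_that("a fully surrounded cell defers division and cannot relocate", {
  p <- default_params(gP0 = 1, aP = 10, gM0 = 0, k_omega = 1e6, T_cyc = 0)
  pr <- sim_protocol(3, 9, 1, 1, world_dim = c(3, 3, 1))
  st <- simulate_init(pr, p, seed = 2)  # 3x3x1 world completely full
  for (i in 1:3) sim_step(st)
  expect_equal(sum(st$alive), 9)  # nowhere to put a daughter
  expect_equal(st$n_born, 0)
  lw_check_occupancy(st$world,
                     cbind(st$px, st$py, st$pz)[st$alive, , drop = FALSE])
})

test_that("event frequencies match the analytic chances", {
  # 1e5 Bernoulli draws per chance through the chance functions
  set.seed(99)
  for (chance in c(0.05, 0.3)) {
    n <- 1e5
    hits <- sum(stats::runif(n) < chance)
    sigma <- sqrt(n * chance * (1 - chance))
    expect_lt(abs(hits - n * chance), 3 * sigma)
  }
  # end-to-end: one step of pure mortality on a fully seeded surface,
  # where every cell sits at a neutral controller operating point
  # (density in the medium plateau, no alkalinity, negligible Mg)
  p <- default_params(gP0 = 0, gM0 = 0.05, aM = 1, aPM = 0, gC = 0)
  pr <- sim_protocol(0.4, 100, 1, 1, world_dim = c(10, 10, 2))
  fM <- fl_evaluate(default_controller(p), as.data.frame(neutral_row()))$fM
  chance <- mortality_chance(fM, 0, p)
  deaths <- 0; trials <- 0
  for (s in 1:20) {
    st <- simulate_init(pr, p, seed = s)
    n_before <- sum(st$alive)
    sim_step(st)
    trials <- trials + n_before
    deaths <- deaths + (n_before - sum(st$alive))
  }
  sigma <- sqrt(trials * chance * (1 - chance))
  expect_lt(abs(deaths - trials * chance), 3 * sigma)
})

test_that("population bookkeeping balances births and deaths", {
  pr <- sim_protocol(3, 40, 2, 2, world_dim = c(10, 10, 4))
  st <- simulate_init(pr, default_params(), seed = 21)
  for (i in 1:48) sim_step(st)
  expect_equal(sum(st$alive), st$n_seeded + st$n_born - st$n_dead)
  lw_check_occupancy(st$world,
                     cbind(st$px, st$py, st$pz)[st$alive, , drop = FALSE])
})

test_that("mean inter-division time tracks the cycle time under full drive", {
  # force fP = 1 via a constant-output controller so only the cycle bias
  # gates division; gM0 = 0 so lineages persist
  p <- default_params(gP0 = 1, aP = 1, gM0 = 0, gC = 0,
                      k_omega = 2, T_cyc = 24)
  inputs <- default_inputs(p)
  rules <- list(fl_rule("proliferation", "very_high"),
                fl_rule("mortality", "low"))
  sc <- default_scales()
  ctrl <- fl_controller(inputs, rules, sc)
  pr <- sim_protocol(0.8, 10, 6, 6, world_dim = c(30, 30, 8),
                     medium_change = FALSE)
  st <- simulate_init(pr, p, seed = 31, controller = ctrl)
  # inter-division ages, read off the cycle-clock resets of mothers
  ages <- numeric(0)
  for (t in 1:144) {
    clock_before <- st$clock
    n_before <- length(clock_before)
    sim_step(st)
    divided <- which(st$clock[seq_len(n_before)] < clock_before + 1 &
                       st$alive[seq_len(n_before)])
    ages <- c(ages, clock_before[divided] + 1)
  }
  # renewal-process oracle: integrate the hourly logistic hazard to get
  # the expected inter-division age (the clock resets at each division)
  surv <- 1; et <- 0; tt <- 0
  while (surv > 1e-8 && tt < 500) {
    tt <- tt + 1
    h <- 1 / (1 + exp(-p$k_omega * (tt - 1 - p$T_cyc)))
    et <- et + surv * h * tt
    surv <- surv * (1 - h)
  }
  expect_gt(length(ages), 50)
  expect_lt(abs(mean(ages) - et) / et, 0.1)
  expect_lt(abs(et - p$T_cyc) / p$T_cyc, 0.15)  # the bias centers on T_cyc
})
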