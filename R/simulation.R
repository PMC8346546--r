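# The coordinator: initialize, advance the world hour by hour, measure.
#
# State lives in an environment with parallel per-cell vectors (position,
# maturity, DNA damage, internal pH, cycle clock, mitotic-damage flag,
# alive flag) plus the lattice occupancy array and the environment fields.
# Everything chance-based draws from R's global RNG stream, so a single
# set.seed() makes whole trajectories bit-reproducible.

#' Define an experiment protocol
#'
#' @param mg Mg concentration of the condition (mM).
#' @param n_seed Number of cells seeded on the culture surface (z = 0).
#' @param days Culture duration in days.
#' @param measure_days Measurement days (each becomes one row set in the
#'   output); must lie within `days`.
#' @param observables Character vector drawn from `live_count`,
#'   `viability`, `dna`, `alp`, `oc`, `tgfb1`, `bmp2`.
#' @param world_dim Integer triple of patch counts (default 30 x 30 x 8).
#' @param medium_change Apply the 2.5-day medium change (only ever active
#'   for protocols longer than 3 days).
#' @return A `sim_protocol` list.
#' @export
sim_protocol <- function(mg, n_seed, days, measure_days,
                         observables = c("live_count", "viability"),
                         world_dim = c(30, 30, 8), medium_change = TRUE) {
  obs_ok <- c("live_count", "viability", "dna", "alp", "oc", "tgfb1", "bmp2")
  if (!all(observables %in% obs_ok))
    stop("unknown observable(s): ",
         paste(setdiff(observables, obs_ok), collapse = ", "))
  if (any(measure_days > days) || any(measure_days <= 0))
    stop("measurement schedule must lie within the culture duration")
  structure(list(mg = mg, n_seed = n_seed, days = days,
                 measure_days = sort(measure_days),
                 observables = observables, world_dim = world_dim,
                 medium_change = medium_change),
            class = "sim_protocol")
}

#' Initialize a simulation state
#'
#' Seeds `n_seed` cells uniformly at random on the z = 0 layer, draws the
#' initial DNA damage with chance `gC`, sets the environment from the
#' protocol's Mg concentration via [ph_from_mg()], and builds the fuzzy
#' controller from `params` unless one is supplied.
#'
#' @param protocol A `sim_protocol`.
#' @param params Parameter set from [default_params()].
#' @param seed Integer RNG seed (the only source of randomness).
#' @param controller Optional `fl_controller`; default builds
#'   [default_controller()] from `params`.
#' @param record_events Keep a per-event log (step, cell, event, patch)?
#' @return A `sim_state` environment.
#' @export
simulate_init <- function(protocol, params = default_params(), seed = 1L,
                          controller = NULL, record_events = FALSE) {
  stopifnot(inherits(protocol, "sim_protocol"))
  d <- protocol$world_dim
  if (protocol$n_seed > d[1] * d[2])
    stop("seeding count exceeds the capacity of the z = 0 layer")
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$protocol <- protocol
  st$params <- params
  st$ctrl <- controller %||% default_controller(params)
  st$world <- lattice_world(d[1], d[2], d[3], params$patch_size)
  st$env <- environment_state(protocol$mg, d, params)
  n <- protocol$n_seed
  surf <- sample.int(d[1] * d[2], n) - 1L
  st$px <- as.integer(surf %% d[1])
  st$py <- as.integer(surf %/% d[1])
  st$pz <- rep(0L, n)
  st$plin <- lin_index(d, st$px, st$py, st$pz)
  st$world$occ[st$plin] <- seq_len(n)
  st$alive <- rep(TRUE, n)
  st$maturity <- rep(0, n)
  st$dna <- check_dna_damage(rep(0L, n), st$env$ambient_ph, params,
                             is_init = TRUE)
  st$iph <- rep(params$internal_pH0, n)
  st$clock <- rep(0, n)
  st$deltap <- rep(0L, n)
  st$t <- 0L
  st$n_seeded <- n
  st$n_dead <- 0L
  st$n_born <- 0L
  st$events <- if (record_events) list() else NULL
  class(st) <- "sim_state"
  st
}

lin_index <- function(d, x, y, z) x + d[1] * (y + d[2] * z) + 1L

# vacant neighbor linear indices of the patch with linear index `lin`
vacant_lin <- function(world, lin) {
  v <- world$nb_lin[[lin]]
  v[world$occ[v] == 0L]
}

log_event <- function(st, step, cell, event, lin) {
  st$events[[length(st$events) + 1L]] <-
    list(step = step, cell = cell, event = event, patch = lin)
  invisible(NULL)
}

#' Advance the simulation by one hour
#'
#' One step executes, in order: internal-pH relaxation, the DNA-damage
#' check, controller evaluation for every live cell, mortality draws,
#' proliferation draws (daughters placed in a uniformly random vacant
#' Moore neighbor; deferred when fully surrounded; the mitotic-damage flag
#' assigned to exactly one of the two cells), migration draws (one patch
#' toward a uniformly random vacant neighbor), the continuous
#' differentiation update, the growth-factor reaction + diffusion update,
#' and the medium change when due. Cells created this step act from the
#' next step on.
#'
#' @param st A `sim_state`.
#' @return The state, advanced in place (invisibly).
#' @export
sim_step <- function(st) {
  p <- st$params
  env <- st$env
  w <- st$world
  d <- w$dim
  st$t <- st$t + 1L
  logging <- !is.null(st$events)

  # hoist the per-cell registry into locals for the event loops
  alive <- st$alive; px <- st$px; py <- st$py; pz <- st$pz
  plin <- st$plin; maturity <- st$maturity; dna <- st$dna
  iph <- st$iph; clock <- st$clock; deltap <- st$deltap
  occ <- w$occ; nb_total <- w$nb_total; nb_lin <- w$nb_lin
  n0 <- length(alive)
  idx <- which(alive)

  if (length(idx)) {
    # intrinsic updates
    iph[idx] <- relax_internal_ph(iph[idx], env$ambient_ph, p$r_r)
    dna[idx] <- check_dna_damage(dna[idx], env$ambient_ph, p)

    # controller inputs
    lin <- plin[idx]
    occn <- occupied_neighbor_counts(w)
    dens <- occn[lin] / nb_total[lin]
    f <- fl_evaluate_core(st$ctrl, list(
      maturity = maturity[idx], dna_damage = dna[idx],
      mg = rep(env$mg, length(idx)),
      alkalinity = pmax(0, env$ambient_ph - iph[idx]),
      bmp2 = env$bmp2[lin], tgfb1 = env$tgfb1[lin], density = dens))

    # --- mortality ---
    pM <- mortality_chance(f$fM, deltap[idx], p)
    die <- stats::runif(length(idx)) < pM
    if (any(die)) {
      ki <- idx[die]
      alive[ki] <- FALSE
      occ[plin[ki]] <- 0L
      st$n_dead <- st$n_dead + length(ki)
      if (logging) for (k in ki) log_event(st, st$t, k, "mortality", plin[k])
    }
    surv <- !die

    # --- proliferation (crowding pre-screen on the post-mortality map) ---
    pP <- proliferation_chance(f$fP, clock[idx], p)
    want <- which(surv & stats::runif(length(idx)) < pP)
    # the post-mortality counts are also a valid (never wrongly excluding)
    # pre-screen for migration, since divisions only add occupancy and the
    # event loops re-check exact vacancy per attempt
    occn2 <- if (any(die)) {
      w$occ <- occ
      occupied_neighbor_counts(w)
    } else occn
    if (length(want)) {
      feasible <- occn2[plin[idx[want]]] < nb_total[plin[idx[want]]]
      want <- want[feasible]  # fully surrounded: division deferred
    }
    if (length(want)) {
      ord <- want[sample.int(length(want))]
      for (j in ord) {
        ci <- idx[j]
        v <- nb_lin[[plin[ci]]]
        vac <- v[occ[v] == 0L]
        if (!length(vac)) next  # crowded meanwhile: deferred
        tgt <- if (length(vac) == 1L) vac else vac[sample.int(length(vac), 1L)]
        nd <- length(alive) + 1L
        t0 <- tgt - 1L
        px[nd] <- as.integer(t0 %% d[1])
        py[nd] <- as.integer((t0 %/% d[1]) %% d[2])
        pz[nd] <- as.integer(t0 %/% (d[1] * d[2]))
        plin[nd] <- tgt
        alive[nd] <- TRUE
        maturity[nd] <- maturity[ci]
        dna[nd] <- dna[ci]
        iph[nd] <- iph[ci]
        clock[nd] <- 0
        clock[ci] <- 0
        # mitotic damage to exactly one of the two daughters
        if (stats::runif(1) < 0.5) {
          deltap[ci] <- 1L; deltap[nd] <- 0L
        } else {
          deltap[ci] <- 0L; deltap[nd] <- 1L
        }
        occ[tgt] <- nd
        st$n_born <- st$n_born + 1L
        if (logging) log_event(st, st$t, ci, "proliferation", tgt)
      }
    }

    # --- migration ---
    pMi <- migration_chance(f$fMi)
    mv <- which(surv & alive[idx] & stats::runif(length(idx)) < pMi)
    if (length(mv)) {
      feasible <- occn2[plin[idx[mv]]] < nb_total[plin[idx[mv]]]
      mv <- mv[feasible]  # fully surrounded at pre-screen: no relocation
    }
    if (length(mv)) {
      ord <- mv[sample.int(length(mv))]
      for (j in ord) {
        ci <- idx[j]
        v <- nb_lin[[plin[ci]]]
        vac <- v[occ[v] == 0L]
        if (!length(vac)) next
        tgt <- if (length(vac) == 1L) vac else vac[sample.int(length(vac), 1L)]
        occ[plin[ci]] <- 0L
        t0 <- tgt - 1L
        px[ci] <- as.integer(t0 %% d[1])
        py[ci] <- as.integer((t0 %/% d[1]) %% d[2])
        pz[ci] <- as.integer(t0 %/% (d[1] * d[2]))
        plin[ci] <- tgt
        occ[tgt] <- ci
        if (logging) log_event(st, st$t, ci, "migration", tgt)
      }
    }

    # --- differentiation (can co-occur with proliferation) ---
    dif <- idx[alive[idx]]
    if (length(dif)) {
      sel <- match(dif, idx)
      maturity[dif] <- differentiation_step(
        maturity[dif], f$fD_early[sel], f$fD_late[sel], p)
    }

    # cycle clocks advance for pre-existing cells; the mitotic-damage flag
    # decays after one cell cycle
    adv <- which(alive[seq_len(n0)])
    clock[adv] <- clock[adv] + 1
    deltap[deltap == 1L & clock >= p$deltaP_persist] <- 0L
  }

  # write the registry back
  st$alive <- alive; st$px <- px; st$py <- py; st$pz <- pz
  st$plin <- plin; st$maturity <- maturity; st$dna <- dna
  st$iph <- iph; st$clock <- clock; st$deltap <- deltap
  w$occ <- occ

  # --- growth factors: reaction then diffusion ---
  if (is.null(st$stencil)) st$stencil <- make_stencil(d)
  live <- which(alive)
  clin <- plin[live]
  late <- maturity[live] >= p$Mt
  env$tgfb1 <- gf_react(env$tgfb1, clin, late, p$prod_tgfb1_early,
                        p$prod_tgfb1_late, p$wc, p$deg_tgfb1)
  env$bmp2 <- gf_react(env$bmp2, clin, late, p$prod_bmp2_early,
                       p$prod_bmp2_late, p$wc, p$deg_bmp2)
  env$tgfb1 <- diffuse_with_stencil(env$tgfb1, p$D_tgfb1, 1, p$patch_size,
                                    st$stencil)
  env$bmp2 <- diffuse_with_stencil(env$bmp2, p$D_bmp2, 1, p$patch_size,
                                   st$stencil)

  # --- medium change (protocols longer than 3 days only) ---
  if (st$protocol$medium_change && st$protocol$days > 3 &&
      st$t %% p$medium_interval == 0L)
    medium_change(env)

  invisible(st)
}

#' Measure summary statistics of a state
#'
#' Observable mappings: `live_count` is the number of live cells;
#' `viability` is `100 * alive / (alive + cumulative dead)`; `dna` is
#' proportional to the live count; `alp` sums the early-phase weight
#' `maturity / Mt` over live cells below the maturity threshold; `oc` sums
#' the late-phase weight `(maturity - Mt) / (1 - Mt)` over cells at or
#' above it; `tgfb1` and `bmp2` are the medium field totals.
#'
#' @param st A `sim_state`.
#' @param observables Character vector of observables (defaults to the
#'   protocol's).
#' @return Named numeric vector.
#' @export
sim_measure <- function(st, observables = st$protocol$observables) {
  p <- st$params
  m <- st$maturity[st$alive]
  n_live <- length(m)
  vals <- c(
    live_count = n_live,
    viability = if (n_live + st$n_dead == 0) 0 else
      100 * n_live / (n_live + st$n_dead),
    dna = p$kappa_dna * n_live,
    alp = p$kappa_alp * sum(m[m < p$Mt] / p$Mt),
    oc = p$kappa_oc * sum((m[m >= p$Mt] - p$Mt) / (1 - p$Mt)),
    tgfb1 = sum(st$env$tgfb1),
    bmp2 = sum(st$env$bmp2))
  vals[observables]
}

#' Run one protocol to completion
#'
#' Steps the simulation hourly for `days * 24` steps and records the
#' scheduled observables.
#'
#' @inheritParams simulate_init
#' @param check_occupancy Assert the single-occupancy invariant after every
#'   step (debug mode; slows large runs).
#' @return Data frame with columns `condition` (Mg, mM), `day`,
#'   `observable`, `value`.
#' @export
simulate_protocol <- function(protocol, params = default_params(),
                              seed = 1L, controller = NULL,
                              check_occupancy = FALSE) {
  st <- simulate_init(protocol, params, seed, controller)
  hours <- protocol$measure_days * 24
  out <- list()
  for (t in seq_len(protocol$days * 24)) {
    sim_step(st)
    if (check_occupancy)
      lw_check_occupancy(st$world,
                         cbind(st$px, st$py, st$pz)[st$alive, , drop = FALSE])
    hit <- which(hours == t)
    if (length(hit)) {
      v <- sim_measure(st)
      out[[length(out) + 1L]] <- data.frame(
        condition = protocol$mg, day = protocol$measure_days[hit],
        observable = names(v), value = unname(v))
    }
  }
  do.call(rbind, out)
}

#' Run protocols over replicate seeds and aggregate
#'
#' Runs every protocol for `replicates` independent seeds (all derived
#' deterministically from `seed`) and returns mean and standard deviation
#' per (condition, day, observable), mirroring how culture studies report
#' their measurements.
#'
#' @param protocols A `sim_protocol` or list of them (one per condition).
#' @param params Parameter set.
#' @param seed Master seed.
#' @param replicates Number of replicate runs per protocol.
#' @param controller Optional shared `fl_controller`.
#' @return Data frame `condition`, `day`, `observable`, `mean`, `sd`
#'   (`sd` is 0 when `replicates == 1`); the per-replicate table is
#'   attached as attribute `"raw"`.
#' @export
run_experiment <- function(protocols, params = default_params(), seed = 1L,
                           replicates = 1L, controller = NULL) {
  if (inherits(protocols, "sim_protocol")) protocols <- list(protocols)
  stopifnot(replicates >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             replicates * length(protocols)),
                  nrow = replicates)
  raw <- list()
  for (ip in seq_along(protocols)) {
    for (r in seq_len(replicates)) {
      df <- simulate_protocol(protocols[[ip]], params, seeds[r, ip],
                              controller)
      df$replicate <- r
      raw[[length(raw) + 1L]] <- df
    }
  }
  raw <- do.call(rbind, raw)
  key <- interaction(raw$condition, raw$day, raw$observable, drop = TRUE)
  agg <- do.call(rbind, lapply(split(raw, key), function(g)
    data.frame(condition = g$condition[1], day = g$day[1],
               observable = g$observable[1], mean = mean(g$value),
               sd = if (nrow(g) > 1) stats::sd(g$value) else 0)))
  agg <- agg[order(agg$condition, agg$day, agg$observable), ]
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  agg
}

#' Write a world snapshot as CSV
#'
#' One row per live cell: id, 0-based patch coordinates, maturity, and
#' state flags — the format used for visualizing simulated cultures.
#'
#' @param st A `sim_state`.
#' @param path Output CSV path.
#' @return Invisibly the snapshot data frame.
#' @export
write_snapshot <- function(st, path) {
  idx <- which(st$alive)
  df <- data.frame(cell = idx, x = st$px[idx], y = st$py[idx],
                   z = st$pz[idx], maturity = st$maturity[idx],
                   dna_damage = st$dna[idx], mitotic_damage = st$deltap[idx],
                   t = st$t)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %d h, %d live / %d dead / %d born (Mg %g mM)\n",
              x$t, sum(x$alive), x$n_dead, x$n_born, x$env$mg))
  invisible(x)
}
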