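# Iterative calibration: fractional-factorial sensitivity screening with
# ANOVA ranking, rejection ABC on the top parameters, and a
# posterior-narrowing acceptance rule, repeated until no new parameter is
# inferred.

#' Wrap empirical measurements for calibration
#'
#' @param df Data frame with columns `condition` (Mg, mM), `day`,
#'   `observable`, `mean` and optionally `sd`.
#' @param min_viability Optional minimum-viability constraint (percent):
#'   parameter sets whose simulated viability drops below it anywhere are
#'   assigned the worst possible distance. Used for datasets that lack
#'   viability measurements, to keep the fit from buying accuracy with
#'   unrealistic mortality.
#' @return The data frame with class `observed_dataset` and the constraint
#'   attached as an attribute.
#' @export
observed_dataset <- function(df, min_viability = NULL) {
  need <- c("condition", "day", "observable", "mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dataset lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(df$sd) && any(df$sd < 0)) stop("sd must be non-negative")
  attr(df, "min_viability") <- min_viability
  class(df) <- c("observed_dataset", class(df))
  df
}

#' Goodness of fit as normalized absolute difference
#'
#' For each observable, `R^2 = 1 - sum(|sim - obs|) / sum(|obs|)`; the
#' returned value is the mean over observables. A perfect match gives 1; a
#' simulation stuck at zero gives 0; the value is unbounded below for
#' gross misfits.
#'
#' @param sim Data frame with columns `condition`, `day`, `observable` and
#'   a value column (`value` or `mean`).
#' @param obs An [observed_dataset()] (or data frame with a `mean` column).
#' @return Scalar fit value; attribute `"per_observable"` carries the
#'   per-observable values.
#' @export
r_squared <- function(sim, obs) {
  sv <- sim$value %||% sim$mean
  key_s <- paste(sim$condition, sim$day, sim$observable, sep = "\r")
  key_o <- paste(obs$condition, obs$day, obs$observable, sep = "\r")
  m <- match(key_o, key_s)
  if (anyNA(m)) stop("simulation results lack (condition, day, observable) ",
                     "keys present in the data")
  sv <- sv[m]
  per <- vapply(split(seq_along(sv), obs$observable), function(i) {
    denom <- sum(abs(obs$mean[i]))
    if (denom == 0) return(as.numeric(all(sv[i] == 0)))
    1 - sum(abs(sv[i] - obs$mean[i])) / denom
  }, numeric(1))
  structure(mean(per), per_observable = per)
}

#' Build the simulate-and-score function used by screening and ABC
#'
#' Returns a closure `fit(theta, seed)` that overrides the base parameters
#' with the named vector `theta`, simulates every protocol, and returns
#' the [r_squared()] fit against the dataset together with the minimum
#' simulated viability (for the optional constraint). Invalid parameter
#' combinations (breakpoint-ordering violations) score `-Inf`.
#'
#' @param protocols List of `sim_protocol` objects covering the dataset's
#'   conditions.
#' @param data An [observed_dataset()].
#' @param params Base parameter set.
#' @param controller_fn Function `params -> fl_controller`; defaults to
#'   [default_controller()] so membership breakpoints follow the sampled
#'   parameters.
#' @return Function `(theta, seed) -> list(r2, min_viability)`.
#' @export
make_fit_fun <- function(protocols, data, params = default_params(),
                         controller_fn = default_controller) {
  if (inherits(protocols, "sim_protocol")) protocols <- list(protocols)
  force(data); force(params); force(controller_fn)
  function(theta, seed) {
    p <- params
    p[names(theta)] <- as.list(unname(theta))
    ok <- tryCatch({ validate_params(p); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(list(r2 = -Inf, min_viability = 0))
    ctrl <- controller_fn(p)
    sim <- list(); via <- numeric(0)
    for (i in seq_along(protocols)) {
      pr <- protocols[[i]]
      obs2 <- union(pr$observables, "viability")
      pr2 <- pr; pr2$observables <- obs2
      df <- simulate_protocol(pr2, p, seed + i - 1L, ctrl)
      via <- c(via, df$value[df$observable == "viability"])
      sim[[i]] <- df
    }
    sim <- do.call(rbind, sim)
    list(r2 = as.numeric(r_squared(sim, data)),
         min_viability = min(via))
  }
}

#' Two-level fractional factorial design (resolution IV)
#'
#' Builds a regular two-level design for `k` factors by assigning factors
#' to interaction columns of a `2^b` full factorial (resolution III) and
#' folding the design over, which lifts it to resolution IV: main effects
#' are orthogonal and unconfounded with two-factor interactions.
#'
#' @param k Number of factors (>= 2).
#' @param min_runs Optional lower bound on the run count; a larger base
#'   factorial is used until `2 * 2^b >= min_runs` (more runs buy a lower
#'   noise floor for the effect estimates of a stochastic response).
#' @return A `(2 * 2^b) x k` matrix of -1/+1 levels, `b` the smallest
#'   integer with `2^b - 1 >= k` (and satisfying `min_runs`).
#' @export
ffd_design <- function(k, min_runs = 0) {
  stopifnot(k >= 2)
  b <- ceiling(log2(k + 1))
  while (2 * 2^b < min_runs) b <- b + 1
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), b)))
  cols <- list()
  for (sz in seq_len(b)) {
    for (cmb in utils::combn(b, sz, simplify = FALSE)) {
      cols[[length(cols) + 1L]] <- apply(base[, cmb, drop = FALSE], 1, prod)
    }
  }
  X <- do.call(cbind, cols)[, seq_len(k), drop = FALSE]
  rbind(X, -X)
}

#' Fractional-factorial sensitivity screen with ANOVA ranking
#'
#' Maps the design levels to the prior bounds, evaluates the fit metric
#' for every design row, fits a main-effects ANOVA, and returns each
#' parameter's F statistic scaled so the largest equals 1.
#'
#' @param priors Priors for the free parameters ([default_priors()]).
#' @param fit_fun Closure from [make_fit_fun()].
#' @param data Optional [observed_dataset()]; when it declares a
#'   minimum-viability constraint, design rows violating it are assigned
#'   the worst observed score, so the screen ranks effects on the same
#'   penalized objective the ABC stage minimizes (without this, extreme
#'   mortality can mask proliferation effects by erasing overshooting
#'   populations).
#' @param seed RNG seed; the same simulator seed(s) are used for every
#'   design row (common random numbers) so the screen ranks parameter
#'   effects, not seed noise.
#' @param replicates Simulator replicates averaged per design row (tames
#'   the stochastic-trajectory noise of the response).
#' @param min_runs Passed to [ffd_design()].
#' @return Data frame `name`, `effect` (F scaled to max 1), `F_value`,
#'   `p_value`, sorted as supplied.
#' @export
ffd_screen <- function(priors, fit_fun, data = NULL, seed = 1L,
                       replicates = 1L, min_runs = 0) {
  k <- nrow(priors)
  if (k < 2) stop("sensitivity screening needs at least 2 free parameters")
  X <- ffd_design(k, min_runs)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  y <- numeric(nrow(X))
  viab <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    theta <- priors$lo + (X[i, ] + 1) / 2 * (priors$hi - priors$lo)
    names(theta) <- priors$name
    res <- lapply(sim_seeds, function(s) fit_fun(theta, s))
    y[i] <- mean(vapply(res, `[[`, numeric(1), "r2"))
    viab[i] <- min(vapply(res, function(r) r$min_viability %||% 100,
                          numeric(1)))
  }
  minv <- attr(data, "min_viability")
  if (!is.null(minv)) {
    bad <- viab < minv
    if (any(bad) && any(!bad & is.finite(y)))
      y[bad] <- min(y[!bad & is.finite(y)])
  }
  y[!is.finite(y)] <- min(y[is.finite(y)], 0) - 1  # worst score for invalid rows
  # one-way ANOVA per factor, exact for an orthogonal balanced +/-1
  # design: SS_j = n * betahat_j^2, tested against the residual of the
  # full main-effects model
  n <- nrow(X)
  beta <- as.vector(crossprod(X, y)) / n
  ss <- n * beta^2
  sse <- sum((y - mean(y) - X %*% beta)^2)
  dfe <- n - k - 1
  if (sse > 1e-12 * max(ss, 1)) {
    Fv <- ss / (sse / dfe)
    pv <- stats::pf(Fv, 1, dfe, lower.tail = FALSE)
  } else {
    # (near-)saturated response: rank by effect sums of squares
    Fv <- ss
    pv <- rep(NA_real_, k)
  }
  eff <- if (max(Fv) > 0) Fv / max(Fv) else Fv
  data.frame(name = priors$name, effect = eff, F_value = Fv, p_value = pv,
             row.names = NULL)
}

#' Select the most influential parameters
#'
#' @param effects Data frame from [ffd_screen()].
#' @param k Number of parameters to keep (default 5); ties broken by
#'   parameter name order for determinism.
#' @return Character vector of the top-`k` parameter names.
#' @export
select_top <- function(effects, k = 5) {
  if (k > nrow(effects)) stop("k exceeds the parameter pool size")
  ord <- order(-effects$effect, effects$name)
  effects$name[ord][seq_len(k)]
}

#' Rejection approximate Bayesian computation
#'
#' Samples `n_runs` parameter vectors from the priors of the selected
#' parameters, simulates each, scores it by the distance `1 - R^2`, and
#' keeps the `n_keep` best as the posterior sample. When the dataset
#' declares a minimum-viability constraint, parameter sets violating it
#' anywhere receive the worst distance.
#'
#' @param priors Priors of the selected parameters.
#' @param fit_fun Closure from [make_fit_fun()].
#' @param data The [observed_dataset()] (source of the viability
#'   constraint).
#' @param n_runs Number of simulator runs (prior samples).
#' @param n_keep Posterior sample size (`<= n_runs`).
#' @param seed RNG seed; parameter draws and per-run simulator seeds are
#'   derived from it.
#' @return List of class `mgfabm_abc`: `samples` (kept parameter vectors),
#'   `r2` and `distance` for the kept runs, `all_samples`, `all_distance`,
#'   and `degenerate` (`TRUE` when every run violated the constraint).
#' @export
abc_reject <- function(priors, fit_fun, data, n_runs = 500, n_keep = 100,
                       seed = 1L) {
  stopifnot(n_keep <= n_runs)
  set.seed(seed)
  thetas <- sample_priors(priors, n_runs)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  minv <- attr(data, "min_viability")
  r2 <- numeric(n_runs); dist <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    th <- unlist(thetas[i, , drop = FALSE])
    res <- fit_fun(th, seeds[i])
    r2[i] <- res$r2
    dist[i] <- 1 - res$r2
    if (!is.null(minv) && res$min_viability < minv) dist[i] <- Inf
  }
  keep <- order(dist)[seq_len(n_keep)]
  structure(list(samples = thetas[keep, , drop = FALSE],
                 r2 = r2[keep], distance = dist[keep],
                 all_samples = thetas, all_distance = dist,
                 degenerate = all(!is.finite(dist))),
            class = "mgfabm_abc")
}

#' Posterior-narrowing acceptance test
#'
#' Accepts a parameter when its posterior interquartile range is strictly
#' smaller than `rho` times the prior IQR (a uniform prior's IQR is half
#' its range). Accepted parameters are fixed at the posterior median;
#' rejected ones return to the free pool.
#'
#' @param samples Numeric posterior sample for one parameter.
#' @param lo,hi Prior bounds.
#' @param rho Narrowing factor (default 0.5).
#' @return List `accept` (logical) and `median`.
#' @export
narrowing_test <- function(samples, lo, hi, rho = 0.5) {
  stopifnot(length(samples) >= 1, hi > lo)
  iqr_post <- stats::IQR(samples, type = 7)
  iqr_prior <- 0.5 * (hi - lo)
  list(accept = iqr_post < rho * iqr_prior,
       median = stats::median(samples))
}

#' Iterative calibration loop
#'
#' Repeats screen -> select top -> ABC -> narrowing test, fixing accepted
#' parameters at their posterior medians, until an iteration infers no new
#' parameter (or `max_iter` is reached). Records per iteration the effect
#' ranking, the ABC posterior, the accepted values and the mean/sd of the
#' best runs' fit.
#'
#' @param priors Priors for the initial free-parameter pool.
#' @param fit_fun Closure from [make_fit_fun()]; called with the union of
#'   fixed values and sampled values.
#' @param data The [observed_dataset()].
#' @param k_top Parameters forwarded to ABC each iteration (default 5).
#' @param n_runs,n_keep ABC budget per iteration.
#' @param max_iter Iteration cap.
#' @param rho Narrowing factor for [narrowing_test()].
#' @param seed Master seed; everything (designs, draws, simulator seeds)
#'   derives from it.
#' @param screen_replicates,screen_min_runs Passed to [ffd_screen()].
#' @param min_delta_r2 Optional alternative stopping rule: also stop when
#'   the improvement of the mean top fit over the previous iteration falls
#'   below this tolerance (disabled when `NULL`).
#' @return List of class `mgfabm_calibration`: `fixed` (named accepted
#'   medians), `free` (remaining priors), `iterations` (per-iteration
#'   records with `effects`, `selected`, `posterior`, `accepted`,
#'   `r2_mean`, `r2_sd`), `converged`.
#' @export
calibrate <- function(priors, fit_fun, data, k_top = 5, n_runs = 500,
                      n_keep = 100, max_iter = 10, rho = 0.5, seed = 1L,
                      screen_replicates = 1L, screen_min_runs = 0,
                      min_delta_r2 = NULL) {
  fixed <- numeric(0)
  free <- priors
  iterations <- list()
  set.seed(seed)
  iter_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * max_iter),
                       ncol = 2)
  fit_with_fixed <- function(theta, s) {
    th <- c(fixed, theta[setdiff(names(theta), names(fixed))])
    fit_fun(th, s)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (nrow(free) == 0) { converged <- TRUE; break }
    if (nrow(free) >= 2) {
      eff <- ffd_screen(free, fit_with_fixed, data = data,
                        seed = iter_seeds[it, 1],
                        replicates = screen_replicates,
                        min_runs = screen_min_runs)
      sel <- select_top(eff, min(k_top, nrow(free)))
    } else {
      eff <- data.frame(name = free$name, effect = 1, F_value = NA,
                        p_value = NA)
      sel <- free$name
    }
    pri_sel <- free[match(sel, free$name), , drop = FALSE]
    abc <- abc_reject(pri_sel, fit_with_fixed, data, n_runs = n_runs,
                      n_keep = n_keep, seed = iter_seeds[it, 2])
    accepted <- numeric(0)
    for (nm in sel) {
      nt <- narrowing_test(abc$samples[[nm]],
                           pri_sel$lo[pri_sel$name == nm],
                           pri_sel$hi[pri_sel$name == nm], rho)
      if (nt$accept && !abc$degenerate) accepted[nm] <- nt$median
    }
    fixed <- c(fixed, accepted)
    free <- free[!(free$name %in% names(accepted)), , drop = FALSE]
    r2_fin <- abc$r2[is.finite(abc$r2)]
    iterations[[it]] <- list(
      effects = eff, selected = sel, posterior = abc,
      accepted = accepted,
      r2_mean = if (length(r2_fin)) mean(r2_fin) else NA_real_,
      r2_sd = if (length(r2_fin) > 1) stats::sd(r2_fin) else NA_real_)
    if (length(accepted) == 0) { converged <- TRUE; break }
    if (!is.null(min_delta_r2) && it > 1) {
      d <- iterations[[it]]$r2_mean - iterations[[it - 1]]$r2_mean
      if (is.finite(d) && d < min_delta_r2) { converged <- TRUE; break }
    }
  }
  structure(list(fixed = fixed, free = free, iterations = iterations,
                 converged = converged),
            class = "mgfabm_calibration")
}

#' @export
print.mgfabm_calibration <- function(x, ...) {
  cat("<mgfabm_calibration>", length(x$iterations), "iteration(s),",
      length(x$fixed), "parameter(s) inferred,",
      nrow(x$free), "still free\n")
  if (length(x$fixed))
    cat("  accepted:", paste(sprintf("%s=%.4g", names(x$fixed), x$fixed),
                             collapse = ", "), "\n")
  tr <- vapply(x$iterations, function(i) i$r2_mean, numeric(1))
  if (length(tr))
    cat("  mean top fit per iteration:",
        paste(sprintf("%.3f", tr), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.mgfabm_abc <- function(x, ...) {
  cat(sprintf("<mgfabm_abc> kept %d of %d runs; best fit %.3f%s\n",
              nrow(x$samples), nrow(x$all_samples), max(x$r2),
              if (x$degenerate) " (degenerate: all runs violated constraints)" else ""))
  invisible(x)
}
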