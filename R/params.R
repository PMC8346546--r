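# Model parameters: defaults, the free-parameter pool, and priors.

#' Default model parameters
#'
#' Returns the full parameter set of the model. The first 20 entries listed
#' by [free_parameters()] are the free parameters exposed to sensitivity
#' analysis and calibration; the remainder are structural constants
#' (controller output geometry, cycle-bias shape, observable scales,
#' growth-factor kinetics, world geometry) that are configurable but fixed
#' by default.
#'
#' Units: chances are per hourly step; rates are per hour; concentrations in
#' mM (Mg) or ng/mL (growth factors); maturity and density are
#' dimensionless in `[0, 1]`; pH quantities in pH units; lengths in
#' micrometers.
#'
#' @param ... Named overrides of individual parameters.
#' @return Named list of parameters (class `mgfabm_params`).
#' @export
#' @examples
#' p <- default_params(gP0 = 0.4)
#' p$gP0
default_params <- function(...) {
  p <- list(
    # --- free parameters (calibration pool) ---
    gP0   = 0.30,   # base proliferation chance per step
    gM0   = 0.010,  # base mortality chance per step
    aP    = 2.0,    # proliferation scale factor
    aM    = 1.0,    # mortality scale factor
    aPM   = 1.0,    # mitotic-damage weight on mortality
    aD    = 1.0,    # differentiation scale factor
    rD0   = 0.002,  # base differentiation rate per hour
    Mt    = 0.5,    # maturity threshold (early/late split)
    gC    = 0.05,   # initial DNA-damage chance (cell passaging)
    pH_t  = 9.0,    # ambient pH causing DNA damage after one step
    r_r   = 0.02,   # internal-pH recovery rate (pH units/h)
    A_t   = 1.0,    # alkalinity gap marking start of the severe level
    cmlt  = 4.5,    # Mg: peak of the stimulatory level (mM)
    cmmt  = 15,     # Mg: peak of the high level (mM)
    cmht  = 30,     # Mg: peak of the destructive level (mM)
    cclt1 = 0.02,   # density: low-level shoulder start
    cclt2 = 0.08,   # density: low-level shoulder end
    ccht1 = 0.50,   # density: high-level shoulder start
    ccht2 = 0.80,   # density: high-level shoulder end
    wc    = 0.005,  # cellular consumption weight for growth factors (/h)
    # --- cycle bias ---
    k_omega = 0.5,  # logistic growth rate of the cycle bias (1/h)
    T_cyc   = 24,   # mean cell-cycle time (h)
    # --- pH / Mg coupling (well-mixed medium) ---
    pH0      = 7.4,  # medium pH at the control Mg concentration
    pH_slope = 0.02, # pH increase per mM Mg above control
    mg0      = 0.8,  # control Mg concentration (mM, basal medium)
    pH_max   = 10,   # physiological ceiling for the ambient pH
    internal_pH0 = 7.4,
    # --- growth-factor kinetics (reconstructed reaction-diffusion) ---
    D_tgfb1 = 100,    # diffusion coefficient (um^2/h)
    D_bmp2  = 100,
    deg_tgfb1 = 0.01, # first-order degradation (/h)
    deg_bmp2  = 0.01,
    prod_tgfb1_early = 4e-4, # per-cell production (ng/mL/h), early phase
    prod_tgfb1_late  = 1e-4, # late phase (lower; see methods vignette)
    prod_bmp2_early  = 3e-4,
    prod_bmp2_late   = 1e-4,
    init_tgfb1 = 0,   # medium concentration at t = 0 and after resets
    init_bmp2  = 0,
    # --- world / protocol constants ---
    patch_size = 15,        # patch edge length (um)
    medium_interval = 60,   # medium change every 2.5 days (h)
    # --- observable scales ---
    kappa_dna = 1, kappa_alp = 1, kappa_oc = 1,
    # --- mitotic-damage persistence (one cell cycle) ---
    deltaP_persist = 24
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  class(p) <- "mgfabm_params"
  validate_params(p)
  p
}

#' Names of the 20 free model parameters
#'
#' @return Character vector of the default free-parameter pool.
#' @export
free_parameters <- function() {
  c("gP0", "gM0", "aP", "aM", "aPM", "aD", "rD0", "Mt", "gC", "pH_t",
    "r_r", "A_t", "cmlt", "cmmt", "cmht", "cclt1", "cclt2", "ccht1",
    "ccht2", "wc")
}

#' Validate a parameter set
#'
#' Checks non-negativity of chances and rates and the ordering invariants of
#' the membership breakpoints (`cclt1 < cclt2 <= ccht1 < ccht2`,
#' `cmlt < cmmt < cmht`).
#'
#' @param p A parameter list from [default_params()].
#' @return Invisibly `TRUE`; stops on the first violation.
#' @export
validate_params <- function(p) {
  nonneg <- c("gP0", "gM0", "aP", "aM", "aPM", "aD", "rD0", "gC", "r_r",
              "wc", "D_tgfb1", "D_bmp2", "deg_tgfb1", "deg_bmp2")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter must be non-negative: ", nm)
  if (p$Mt <= 0 || p$Mt >= 1) stop("Mt must lie in (0, 1)")
  if (!(p$cclt1 < p$cclt2 && p$cclt2 <= p$ccht1 && p$ccht1 < p$ccht2))
    stop("density breakpoints must satisfy cclt1 < cclt2 <= ccht1 < ccht2")
  if (!(p$cmlt < p$cmmt && p$cmmt < p$cmht))
    stop("Mg membership peaks must satisfy cmlt < cmmt < cmht")
  invisible(TRUE)
}

#' Default uniform priors for the free parameters
#'
#' Plausible ranges around the defaults, used by the sensitivity screen and
#' by ABC when no user priors are supplied. Ranges are chosen so that any
#' sampled combination respects the breakpoint-ordering invariants.
#'
#' @param params Character vector of parameter names (default: all 20 free
#'   parameters).
#' @return Data frame with columns `name`, `lo`, `hi`, `dist` (class
#'   `mgfabm_priors`).
#' @export
default_priors <- function(params = free_parameters()) {
  tab <- list(
    gP0 = c(0.05, 0.6), gM0 = c(0.001, 0.05), aP = c(0.5, 4),
    aM = c(0.5, 4), aPM = c(0, 3), aD = c(0.5, 4),
    rD0 = c(5e-4, 5e-3), Mt = c(0.3, 0.7), gC = c(0, 0.2),
    pH_t = c(8.5, 9.5), r_r = c(0.005, 0.1), A_t = c(0.5, 1.5),
    cmlt = c(2, 10), cmmt = c(10.5, 19.5), cmht = c(20, 40),
    cclt1 = c(0.005, 0.05), cclt2 = c(0.06, 0.2),
    ccht1 = c(0.3, 0.6), ccht2 = c(0.62, 0.95), wc = c(0.001, 0.02))
  miss <- setdiff(params, names(tab))
  if (length(miss)) stop("no default prior for: ", paste(miss, collapse = ", "))
  out <- data.frame(
    name = params,
    lo = vapply(params, function(n) tab[[n]][1], numeric(1)),
    hi = vapply(params, function(n) tab[[n]][2], numeric(1)),
    dist = "uniform", row.names = NULL)
  class(out) <- c("mgfabm_priors", "data.frame")
  out
}

#' Sample parameter vectors from priors
#'
#' @param priors Priors data frame ([default_priors()]).
#' @param n Number of samples.
#' @return Data frame, one column per parameter, `n` rows.
#' @export
sample_priors <- function(priors, n) {
  stopifnot(all(priors$lo < priors$hi))
  out <- as.data.frame(lapply(seq_len(nrow(priors)), function(i)
    stats::runif(n, priors$lo[i], priors$hi[i])))
  names(out) <- priors$name
  out
}

#' @export
print.mgfabm_params <- function(x, ...) {
  free <- free_parameters()
  cat("<mgfabm_params>", length(free), "free /",
      length(x) - length(free), "structural parameters\n")
  cat("  free:", paste(sprintf("%s=%g", free, unlist(x[free])),
                       collapse = ", "), "\n")
  invisible(x)
}
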