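# The culture environment: well-mixed Mg and pH, spatial growth-factor
# fields with production / consumption / degradation / diffusion, and the
# 2.5-day medium change.
#
# Mg and ambient pH are spatially uniform (ions equilibrate fast relative
# to proteins in a stirred well); TGF-b1 and BMP2 are per-patch fields
# solved with an explicit 7-point stencil and no-flux boundaries.

#' Ambient pH implied by the Mg concentration
#'
#' Affine map `pH = pH0 + pH_slope * (mg - mg0)`, clamped at the
#' physiological ceiling `pH_max`; `mg0` is the basal-medium (control)
#' concentration at which the medium sits at `pH0`.
#'
#' @param mg Mg concentration (mM, vectorized).
#' @param params Parameter set.
#' @return Ambient pH value(s).
#' @export
ph_from_mg <- function(mg, params = default_params()) {
  if (any(mg < 0)) stop("Mg concentration must be non-negative")
  pmin(params$pH_max, params$pH0 + params$pH_slope * (mg - params$mg0))
}

#' One explicit diffusion update of a concentration field
#'
#' Forward-Euler 7-point-stencil diffusion with no-flux (reflecting)
#' boundaries. If the stability number `D * dt / h^2` exceeds the 3D limit
#' 1/6 the step is internally divided into equal substeps. The update is
#' conservative: absent reactions, total mass is preserved to rounding.
#'
#' @param conc 3D concentration array (ng/mL).
#' @param D Diffusion coefficient (um^2/h).
#' @param dt Time step (h).
#' @param h Patch edge length (um).
#' @return Updated concentration array.
#' @export
gf_diffuse <- function(conc, D, dt = 1, h = 15) {
  diffuse_with_stencil(conc, D, dt, h, make_stencil(dim(conc)))
}

# flat neighbor indices with edge replication: a replicated boundary
# neighbor equals the center and contributes 0 to the Laplacian, which is
# exactly the no-flux (reflecting) condition and keeps the update
# conservative. Built once per world and cached by the simulation state.
make_stencil <- function(d) {
  npatch <- prod(d)
  p0 <- seq_len(npatch) - 1L
  X <- p0 %% d[1]; Y <- (p0 %/% d[1]) %% d[2]; Z <- p0 %/% (d[1] * d[2])
  flat <- function(x, y, z) x + d[1] * (y + d[2] * z) + 1L
  list(flat(pmax(X - 1L, 0L), Y, Z), flat(pmin(X + 1L, d[1] - 1L), Y, Z),
       flat(X, pmax(Y - 1L, 0L), Z), flat(X, pmin(Y + 1L, d[2] - 1L), Z),
       flat(X, Y, pmax(Z - 1L, 0L)), flat(X, Y, pmin(Z + 1L, d[3] - 1L)))
}

diffuse_with_stencil <- function(conc, D, dt, h, stc) {
  if (D == 0 || dt == 0) return(conc)
  mu <- D * dt / h^2
  nsub <- max(1L, ceiling(mu / (1 / 6)))
  mu <- mu / nsub
  d <- dim(conc)
  v <- as.vector(conc)
  i1 <- stc[[1]]; i2 <- stc[[2]]; i3 <- stc[[3]]
  i4 <- stc[[4]]; i5 <- stc[[5]]; i6 <- stc[[6]]
  for (s in seq_len(nsub))
    v <- v + mu * (v[i1] + v[i2] + v[i3] + v[i4] + v[i5] + v[i6] - 6 * v)
  array(v, dim = d)
}

#' Reaction update of a growth-factor field
#'
#' Per patch and hour: cellular production (early- or late-phase rate,
#' if a cell occupies the patch), first-order cellular consumption with
#' weight `wc` (if a cell occupies the patch), and first-order degradation.
#' Concentrations are floored at zero.
#'
#' @param conc 3D concentration array.
#' @param cell_idx Integer vector of 1-based linear patch indices occupied
#'   by live cells (possibly empty).
#' @param late_phase Logical vector parallel to `cell_idx`: `TRUE` for
#'   cells past the maturity threshold.
#' @param prod_early,prod_late Per-cell production rates (ng/mL/h).
#' @param wc Cellular consumption weight (/h).
#' @param decay Degradation rate (/h).
#' @param dt Time step (h).
#' @return Updated concentration array.
#' @export
gf_react <- function(conc, cell_idx, late_phase, prod_early, prod_late,
                     wc, decay, dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  conc <- conc - decay * conc * dt
  if (length(cell_idx)) {
    prod <- ifelse(late_phase, prod_late, prod_early)
    conc[cell_idx] <- conc[cell_idx] + prod * dt -
      wc * conc[cell_idx] * dt
  }
  conc[conc < 0] <- 0
  conc
}

#' Create the environment state for one culture condition
#'
#' @param mg Mg concentration of the condition (mM).
#' @param world_dim Integer triple of patch counts.
#' @param params Parameter set.
#' @return An environment of class `environment_state` holding the Mg
#'   concentration, ambient pH, the two growth-factor fields and the reset
#'   (initial) values.
#' @export
environment_state <- function(mg, world_dim, params = default_params()) {
  stopifnot(mg >= 0)
  e <- new.env(parent = emptyenv())
  e$mg <- mg
  e$ambient_ph <- ph_from_mg(mg, params)
  e$tgfb1 <- array(params$init_tgfb1, dim = world_dim)
  e$bmp2 <- array(params$init_bmp2, dim = world_dim)
  e$init <- list(mg = mg, ambient_ph = e$ambient_ph,
                 tgfb1 = params$init_tgfb1, bmp2 = params$init_bmp2)
  class(e) <- "environment_state"
  e
}

#' Medium change: reset growth factors and pH to initial values
#'
#' Restores the growth-factor fields, the ambient pH and the Mg
#' concentration exactly to the condition's initial values; cells are
#' untouched. The simulation applies it every `medium_interval` hours
#' (2.5 days), and only for protocols longer than 3 days.
#'
#' @param env An `environment_state`.
#' @return The same environment, reset (invisibly).
#' @export
medium_change <- function(env) {
  env$mg <- env$init$mg
  env$ambient_ph <- env$init$ambient_ph
  env$tgfb1[] <- env$init$tgfb1
  env$bmp2[] <- env$init$bmp2
  invisible(env)
}

#' @export
print.environment_state <- function(x, ...) {
  cat(sprintf("<environment_state> Mg %g mM, pH %.2f, total TGF-b1 %.3g, total BMP2 %.3g\n",
              x$mg, x$ambient_ph, sum(x$tgfb1), sum(x$bmp2)))
  invisible(x)
}
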