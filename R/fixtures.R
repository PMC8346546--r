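# Synthetic-study generator: templates shaped like the three calibration
# cell-culture studies, run at known ground-truth parameters, with
# configurable observation noise. Enables download-free tests of
# measurement, sensitivity screening and parameter recovery.

#' Protocol templates for the three study shapes
#'
#' * `study1` — five Mg conditions (0.8, 3, 6, 12, 60 mM), live cell count
#'   and viability at day 3 (population-focused short study).
#' * `study2` — two Mg conditions (0.78, 5 mM), differentiation markers
#'   ALP and OC plus DNA and medium TGF-b1/BMP2 at days 7, 14, 21.
#' * `study3` — four Mg conditions (0.8, 3, 6, 14 mM), live cell count at
#'   days 3, 6, 9.
#'
#' @param template One of `"study1"`, `"study2"`, `"study3"`.
#' @param world_dim Patch counts (scaled-down defaults keep desk-scale
#'   recovery experiments fast; see the methods vignette).
#' @param n_seed Cells seeded on the surface layer.
#' @return List of `sim_protocol` objects, one per Mg condition.
#' @export
study_protocols <- function(template = c("study1", "study2", "study3"),
                            world_dim = c(20, 20, 8),
                            n_seed = round(0.2 * world_dim[1] * world_dim[2])) {
  template <- match.arg(template)
  tmpl <- switch(template,
    study1 = list(mg = c(0.8, 3, 6, 12, 60), days = 3, measure = 3,
                  obs = c("live_count", "viability")),
    study2 = list(mg = c(0.78, 5), days = 21, measure = c(7, 14, 21),
                  obs = c("dna", "alp", "oc", "tgfb1", "bmp2")),
    study3 = list(mg = c(0.8, 3, 6, 14), days = 9, measure = c(3, 6, 9),
                  obs = "live_count"))
  lapply(tmpl$mg, function(m)
    sim_protocol(m, n_seed, tmpl$days, tmpl$measure, tmpl$obs,
                 world_dim = world_dim))
}

#' Generate a synthetic measurement table
#'
#' Runs the simulator at a known ground-truth parameter set over the
#' chosen study template, averages over replicates, applies Gaussian
#' relative observation noise, and returns the table in the exact schema
#' calibration expects, together with the truth for recovery scoring.
#'
#' @param template Study template name or a list of `sim_protocol`s.
#' @param truth Ground-truth parameter set ([default_params()] or a
#'   modified copy).
#' @param noise Relative observation noise (sd as a fraction of the mean;
#'   0 reproduces the simulated means exactly). Default 0.15, the typical
#'   magnitude of culture-study error bars.
#' @param seed RNG seed (drives both the simulation and the noise).
#' @param replicates Simulator replicates averaged per condition.
#' @param min_viability Optional viability constraint recorded on the
#'   dataset (conventionally 50 for count-only study shapes).
#' @param ... Passed to [study_protocols()] when `template` is a name.
#' @return List of class `mgfabm_synth`: `data` (an [observed_dataset()]),
#'   `truth`, `protocols`, `noise`, `seed`.
#' @export
generate_study <- function(template = "study3", truth = default_params(),
                           noise = 0.15, seed = 1L, replicates = 1L,
                           min_viability = NULL, ...) {
  stopifnot(noise >= 0)
  protocols <- if (is.character(template))
    study_protocols(template, ...) else template
  set.seed(seed)
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  agg <- run_experiment(protocols, truth, seed = sim_seed,
                        replicates = replicates)
  df <- data.frame(condition = agg$condition, day = agg$day,
                   observable = agg$observable, mean = agg$mean,
                   sd = agg$sd)
  set.seed(noise_seed)
  if (noise > 0) {
    df$mean <- df$mean * (1 + stats::rnorm(nrow(df), 0, noise))
    df$mean <- pmax(df$mean, 0)
    df$mean[df$observable == "viability"] <-
      pmin(df$mean[df$observable == "viability"], 100)
    df$sd <- abs(df$mean) * noise
  }
  structure(list(data = observed_dataset(df, min_viability = min_viability),
                 truth = truth, protocols = protocols, noise = noise,
                 seed = seed),
            class = "mgfabm_synth")
}

#' @export
print.mgfabm_synth <- function(x, ...) {
  cat(sprintf("<mgfabm_synth> %d rows, %d condition(s), noise %.0f%%\n",
              nrow(x$data), length(unique(x$data$condition)),
              100 * x$noise))
  invisible(x)
}
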