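# The default linguistic inputs and rule base.
#
# The rule base is data: it can be replaced wholesale, or loaded from a YAML
# file (see read_controller/write_controller). The default set encodes the
# qualitative biology the model rests on:
#   - stimulatory Mg / BMP2 / TGF-b1 upregulate proliferation and early
#     differentiation;
#   - any Mg above the negligible band, stimulatory TGF-b1, and severe
#     alkalinity downregulate late differentiation; stimulatory BMP2
#     upregulates it;
#   - destructive Mg, severe alkalinity, inhibitory BMP2, crowding,
#     solitude and DNA damage raise mortality and depress proliferation;
#     multiple simultaneous insults raise mortality further;
#   - mild and severe alkalinity both depress proliferation, only severe
#     affects differentiation;
#   - high density triggers migration and differentiation onset
#     (contact inhibition).

#' Default linguistic inputs
#'
#' Builds the seven linguistic input variables with piecewise-linear
#' membership functions. Breakpoints involving free model parameters
#' (`cmlt`, `cmmt`, `cmht`, `A_t`, `cclt1`, `cclt2`, `ccht1`, `ccht2`,
#' `Mt`) are taken from `params`; the remaining breakpoints encode the
#' literature concentration bands (Mg negligible below 0.8 mM, stimulatory
#' 2-10 mM, toxic 20-40 mM; BMP2 stimulus onset 0.008 ng/mL, stimulatory
#' 10-20, neutral 50-200, inhibitory 500-2000; TGF-b1 stimulatory onset
#' 0.05 ng/mL, plateau 14.2-36.3 ng/mL).
#'
#' @param params Parameter set from [default_params()].
#' @return Named list of `fl_input` objects.
#' @export
default_inputs <- function(params = default_params()) {
  p <- params
  list(
    maturity = fl_input("maturity", list(
      early = mf_shoulder_low(p$Mt - 0.05, p$Mt + 0.05),
      late  = mf_shoulder_high(p$Mt - 0.05, p$Mt + 0.05))),
    dna_damage = fl_input("dna_damage", c("low", "high"), crisp = TRUE),
    mg = fl_input("mg", list(
      negligible  = mf_shoulder_low(0.8, 2),
      inhibitory  = mf_triangle(0.8, 1.4, 2),
      stimulatory = mf_triangle(0.8, p$cmlt, 10),
      high        = mf_triangle(10, p$cmmt, 20),
      destructive = mf_shoulder_high(20, p$cmht))),
    alkalinity = fl_input("alkalinity", list(
      none   = mf_shoulder_low(0.1, 0.4),
      mild   = mf_trapezoid(0.1, 0.4, 0.7 * p$A_t, p$A_t),
      severe = mf_shoulder_high(0.7 * p$A_t, p$A_t))),
    bmp2 = fl_input("bmp2", list(
      negligible  = mf_shoulder_low(0.004, 0.008),
      stimulatory = mf_trapezoid(0.004, 10, 20, 50),
      neutral     = mf_trapezoid(20, 50, 200, 500),
      inhibitory  = mf_shoulder_high(200, 500))),
    tgfb1 = fl_input("tgfb1", list(
      negligible  = mf_shoulder_low(0.03, 0.05),
      stimulatory = mf_trapezoid(0.03, 14.2, 36.3, 60),
      saturated   = mf_shoulder_high(36.3, 60))),
    density = fl_input("density", list(
      low    = mf_shoulder_low(p$cclt1, p$cclt2),
      medium = mf_trapezoid(p$cclt1, p$cclt2, p$ccht1, p$ccht2),
      high   = mf_shoulder_high(p$ccht1, p$ccht2)))
  )
}

#' Default output scales
#'
#' Evenly spaced representative values for the four output levels of every
#' action: low 0.25, medium 0.5, high 0.75, very_high 1.
#'
#' @return Named list of `fl_scale` objects, one per action.
#' @export
default_scales <- function() {
  reps <- c(low = 0.25, medium = 0.5, high = 0.75, very_high = 1)
  list(proliferation = fl_scale(reps),
       mortality = fl_scale(reps),
       migration = fl_scale(reps),
       early_differentiation = fl_scale(reps),
       late_differentiation = fl_scale(reps))
}

#' Default fuzzy rule base
#'
#' @return List of `fl_rule` objects (see the module header for the encoded
#'   biology).
#' @export
default_rules <- function() {
  any1 <- function(...) lapply(list(...), function(m)
    list(input = m[[1]], level = m[[2]]))
  list(
    # proliferation
    fl_rule("proliferation", "medium"),
    fl_rule("proliferation", "high", any_of = any1(
      c("mg", "stimulatory"), c("bmp2", "stimulatory"),
      c("tgfb1", "stimulatory"))),
    fl_rule("proliferation", "low", any_of = any1(
      c("mg", "high"), c("mg", "destructive"), c("bmp2", "inhibitory"),
      c("alkalinity", "mild"), c("alkalinity", "severe"),
      c("density", "high"), c("density", "low"),
      c("dna_damage", "high"))),
    # mortality
    fl_rule("mortality", "low"),
    fl_rule("mortality", "high", any_of = any1(
      c("mg", "destructive"), c("alkalinity", "severe"),
      c("bmp2", "inhibitory"), c("density", "high"),
      c("density", "low"), c("dna_damage", "high"))),
    fl_rule("mortality", "very_high", at_least = 2L, any_of = any1(
      c("mg", "destructive"), c("alkalinity", "severe"),
      c("dna_damage", "high"))),
    # migration (contact inhibition only)
    fl_rule("migration", "high",
            clauses = list(fl_clause("density", "high"))),
    # early differentiation
    fl_rule("early_differentiation", "medium"),
    fl_rule("early_differentiation", "high", any_of = any1(
      c("mg", "stimulatory"), c("bmp2", "stimulatory"),
      c("tgfb1", "stimulatory"), c("density", "high"))),
    fl_rule("early_differentiation", "low",
            clauses = list(fl_clause("alkalinity", "severe"))),
    # late differentiation
    fl_rule("late_differentiation", "medium"),
    fl_rule("late_differentiation", "low",
            clauses = list(fl_clause_not("mg", "negligible"))),
    fl_rule("late_differentiation", "low",
            clauses = list(fl_clause("tgfb1", "stimulatory"))),
    fl_rule("late_differentiation", "high",
            clauses = list(fl_clause("bmp2", "stimulatory"))),
    fl_rule("late_differentiation", "low",
            clauses = list(fl_clause("alkalinity", "severe")))
  )
}

#' The default Mamdani controller
#'
#' Assembles [default_inputs()], [default_rules()] and [default_scales()]
#' into a ready-to-use controller. Membership breakpoints that are free
#' model parameters follow `params`.
#'
#' @param params Parameter set from [default_params()].
#' @return An `fl_controller`.
#' @export
default_controller <- function(params = default_params()) {
  fl_controller(default_inputs(params), default_rules(), default_scales())
}
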