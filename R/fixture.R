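#' Built-in antipyresis study fixture
#'
#' Mean plasma concentration-time profiles of baicalin and geniposide and the
#' corresponding control-corrected rectal-temperature change in pyrexia-model
#' rats over the 2.5 h effect window after a single intraperitoneal dose of
#' Qingkailing injection (13 shared sampling times). Doses are the
#' constituent-equivalent amounts delivered by the 5.2 mL/kg injection:
#' 23.04 mg/kg baicalin and 2.38 mg/kg geniposide.
#'
#' The temperature-change column is stored as printed in the source study:
#' positive values are the magnitude of antipyretic suppression (model-treated
#' rats rising less than model-control rats), and the 0-h value (0.065)
#' reflects pre-dose group imbalance and is retained as data.
#'
#' `references` carries the external anchors used by the derived-effect
#' metrics: the maximal fever increment observed in model-control rats
#' (1.38 degrees C) and the full-study mean Cmax of each analyte in
#' model-treated rats (ng/mL), both of which come from the richer 0-48 h
#' study arm rather than the 2.5 h window shipped here.
#'
#' @return A list with elements `conc_baicalin`, `conc_geniposide`
#'   ([conc_profile]), `delta_t` ([temp_profile] in `delta_t` form), `doses`
#'   (named numeric, mg/kg) and `references` (list with `max_increment`,
#'   `cmax`).
#' @examples
#' fx <- qkl_fixture()
#' max(fx$conc_baicalin$conc)  # 56117.21 ng/mL at 0.17 h
#' @export
qkl_fixture <- function() {
  times <- c(0, 0.033, 0.067, 0.1, 0.17, 0.25, 0.33, 0.5, 0.75, 1, 1.5, 2, 2.5)
  baicalin <- c(0, 23053, 46133.46, 54852.34, 56117.21, 32275.86, 19552.27,
                13953.74, 6173.46, 3587.83, 2536.16, 2224.68, 2050.67)
  geniposide <- c(0, 3777.28, 5616.80, 6921.36, 6684.34, 4248.63, 3280.44,
                  1739.75, 762.76, 322.06, 68.59, 42.08, 36.64)
  dT <- c(0.065, 0.098, 0.132, 0.224, 0.324, 0.684, 0.729, 0.801, 0.862,
          1.082, 0.382, 0.253, 0.081)
  doses <- c(baicalin = 23.04, geniposide = 2.38)
  list(
    conc_baicalin = conc_profile("mean-MTG", "baicalin", doses[["baicalin"]],
                                 times, baicalin),
    conc_geniposide = conc_profile("mean-MTG", "geniposide", doses[["geniposide"]],
                                   times, geniposide),
    delta_t = temp_profile("mean-MTG", "MTG", times, delta_t = dT),
    doses = doses,
    references = list(
      max_increment = 1.38,
      cmax = c(baicalin = 59063.86, geniposide = 7083.28)))
}
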