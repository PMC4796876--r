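# Two-state thermodynamics: Gibbs-Helmholtz stability curves and the
# relations between the stability change and the melting-temperature
# change that motivate the model structures. Internally everything is in
# Kelvin and kcal/mol; the folding sign convention is used throughout
# (folding enthalpy negative for a stable fold, delta-delta-G positive =
# destabilizing).

#' Two-state protein stability curve
#'
#' Parameterizes the folding free energy `dG(T)` of a two-state protein
#' with temperature-independent heat capacity:
#' `dG(T) = dHm (1 - T/Tm) + dCp (T - Tm - T ln(T/Tm))`,
#' which vanishes at `T = Tm` by construction.
#'
#' @param tm Melting temperature (Kelvin).
#' @param dhm Folding enthalpy at `tm` (kcal/mol, negative under the
#'   folding convention).
#' @param dcp Folding heat capacity (kcal/(mol K), T-independent).
#' @return An object of class `ms_stability_curve`.
#' @export
#' @examples
#' wt <- stability_curve(tm = 350, dhm = -100, dcp = -1.5)
#' gibbs_energy(wt, 298)
stability_curve <- function(tm, dhm, dcp = 0) {
  stopifnot(tm > 0, is.finite(dhm), is.finite(dcp))
  if (dhm >= 0) warning("dhm >= 0: not a stable fold under the folding ",
                        "sign convention")
  structure(list(tm = tm, dhm = dhm, dcp = dcp),
            class = "ms_stability_curve")
}

#' @export
print.ms_stability_curve <- function(x, ...) {
  cat(sprintf("<stability curve> Tm = %.2f K, dHm = %.1f kcal/mol, dCp = %.2f kcal/(mol K)\n",
              x$tm, x$dhm, x$dcp))
  invisible(x)
}

#' Folding free energy at a temperature
#'
#' @param curve An [stability_curve()].
#' @param temp Temperature(s) in Kelvin (> 0).
#' @return `dG(temp)` in kcal/mol.
#' @export
gibbs_energy <- function(curve, temp) {
  stopifnot(all(temp > 0))
  curve$dhm * (1 - temp / curve$tm) +
    curve$dcp * (temp - curve$tm - temp * log(temp / curve$tm))
}

#' Solve for the melting temperature of a stability function
#'
#' Finds the temperature where `dG = 0` by scanning the bracket for sign
#' changes and refining each with root bisection to machine-level
#' tolerance; when several zeros exist (cold and heat denaturation), the
#' one nearest `near` is returned.
#'
#' @param dg Either an `ms_stability_curve` or a function of temperature
#'   (Kelvin) returning kcal/mol.
#' @param bracket Search interval in Kelvin.
#' @param near Preferred location of the root (Kelvin); defaults to the
#'   curve's own `tm`, else the bracket midpoint.
#' @return Melting temperature in Kelvin with `|dG| < 1e-9`.
#' @export
melting_temperature <- function(dg, bracket = c(250, 450), near = NULL) {
  if (inherits(dg, "ms_stability_curve")) {
    if (is.null(near)) near <- dg$tm
    curve <- dg
    dg <- function(t) gibbs_energy(curve, t)
  }
  if (is.null(near)) near <- mean(bracket)
  grid <- seq(bracket[1], bracket[2], length.out = 400)
  vals <- vapply(grid, dg, numeric(1))
  sgn <- sign(vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- grid[vals == 0]
  for (k in flips) {
    roots <- c(roots, stats::uniroot(dg, c(grid[k], grid[k + 1]),
                                     tol = 1e-12)$root)
  }
  if (length(roots) == 0) {
    stop("dG does not change sign on [", bracket[1], ", ", bracket[2],
         "] K; no melting transition in bracket")
  }
  roots[which.min(abs(roots - near))]
}

#' Small-perturbation melting-temperature change
#'
#' Under a two-state transition with small mutational perturbation and
#' unchanged folding enthalpy and heat capacity, the melting-temperature
#' shift is proportional to the stability change:
#' `dTm = Tm * ddG / dHm`. Since the folding enthalpy is negative, `ddG`
#' and `dTm` are anticorrelated: a destabilizing mutation lowers the
#' melting temperature.
#'
#' @param ddg Stability change (kcal/mol; positive = destabilizing).
#' @param tm_wild Wild-type melting temperature (Kelvin).
#' @param dhm Wild-type folding enthalpy at `tm_wild` (kcal/mol, nonzero).
#' @return `dTm` in Kelvin.
#' @export
#' @examples
#' dtm_linear(1, tm_wild = 350, dhm = -100) # -3.5 K
dtm_linear <- function(ddg, tm_wild, dhm) {
  if (any(dhm == 0)) stop("dhm must be nonzero")
  tm_wild * ddg / dhm
}

#' General two-state melting-temperature change
#'
#' Drops the small-perturbation assumptions: the mutant stability curve is
#' constructed from the wild type by shifting the folding enthalpy by
#' `ddhm` and the heat capacity by `ddcp`, with a constant offset chosen
#' so that the mutant `dG` at the reference temperature `t_ref` equals the
#' wild-type value plus `ddg`. The mutant melting temperature is then
#' solved numerically and compared with the wild type's. With nonzero
#' `ddhm` the room-temperature stability and the melting temperature can
#' even move independently (stability curves that cross).
#'
#' @param wt An [stability_curve()] for the wild type.
#' @param ddg Stability change at `t_ref` (kcal/mol).
#' @param ddhm Change of the folding enthalpy (kcal/mol).
#' @param ddcp Change of the folding heat capacity (kcal/(mol K)).
#' @param t_ref Reference temperature (Kelvin, default 298).
#' @param bracket Search interval for the mutant melting temperature.
#' @return `dTm` in Kelvin.
#' @export
dtm_two_state <- function(wt, ddg, ddhm = 0, ddcp = 0, t_ref = 298,
                          bracket = c(250, 450)) {
  stopifnot(inherits(wt, "ms_stability_curve"))
  dhm_mut <- wt$dhm + ddhm
  dcp_mut <- wt$dcp + ddcp
  base <- function(t) dhm_mut * (1 - t / wt$tm) +
    dcp_mut * (t - wt$tm - t * log(t / wt$tm))
  offset <- gibbs_energy(wt, t_ref) + ddg - base(t_ref)
  dg_mut <- function(t) base(t) + offset
  melting_temperature(dg_mut, bracket = bracket, near = wt$tm) - wt$tm
}
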