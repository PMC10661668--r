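#' @include AllClasses.R
NULL

#' Resistance of an electrolyte-filled rectangular channel
#'
#' Pouillet's law for a uniform conductor: `R = L / (sigma * w * h)`.
#'
#' @param geom a [ChannelGeometry-class].
#' @param medium an [Electrolyte-class].
#' @return resistance in ohms.
#' @examples
#' channelResistance(ChannelGeometry(10e-3, 7e-3, 0.8e-3), Electrolyte(1.5))
#' @export
channelResistance <- function(geom, medium) {
  stopifnot(is(geom, "ChannelGeometry"), is(medium, "Electrolyte"))
  validObject(geom); validObject(medium)
  geom@length / (medium@conductivity * crossSection(geom))
}

#' Electric field generated by a current in a channel section
#'
#' `E = i / (sigma * w * h)` in V/m (1 V/m = 1 mV/mm). The field is linear in
#' the drive current, which is what makes a current divider a field divider.
#'
#' @param i current through the section, amperes (>= 0).
#' @param geom a [ChannelGeometry-class].
#' @param medium an [Electrolyte-class].
#' @return field in V/m.
#' @export
fieldFromCurrent <- function(i, geom, medium) {
  stopifnot(is(geom, "ChannelGeometry"), is(medium, "Electrolyte"))
  validObject(geom); validObject(medium)
  if (any(i < 0)) stop("current must be >= 0")
  i / (medium@conductivity * crossSection(geom))
}

#' Current density on a disk electrode
#'
#' `j = i / (pi * (d/2)^2)`.
#'
#' @param i drive current, amperes (>= 0).
#' @param electrode an [ElectrodeSpec-class].
#' @return current density in A/m^2 (divide by 1e-2 for uA/cm^2: 1 A/m^2 =
#'   100 uA/cm^2).
#' @export
diskCurrentDensity <- function(i, electrode) {
  stopifnot(is(electrode, "ElectrodeSpec"))
  validObject(electrode)
  if (any(i < 0)) stop("current must be >= 0")
  i / (pi * (electrode@diameter / 2)^2)
}

#' Total charge delivered by a stimulation protocol
#'
#' DC: `Q = i * duration`. Pulsed: `Q = i * pulseOn * nPulses`; the off
#' intervals carry no current and contribute nothing.
#'
#' @param protocol a [StimulationProtocol-class].
#' @return charge in coulombs.
#' @examples
#' deliveredCharge(pulsedProtocol(1.29e-3, 0.1, 0.5, 100))  # 12.9 mC
#' deliveredCharge(dcProtocol(43.5e-6, 600))                # 26.1 mC
#' @export
deliveredCharge <- function(protocol) {
  stopifnot(is(protocol, "StimulationProtocol"))
  validObject(protocol)
  if (protocol@mode == "dc") protocol@current * protocol@duration
  else protocol@current * protocol@pulseOn * protocol@nPulses
}

#' Capacitive discharge window of an electrode
#'
#' How long a constant current can be supplied purely by charging the
#' electrode's double layer before the usable voltage window is exhausted:
#' `t = C * dV / i`. Returns `Inf` at zero current.
#'
#' @param electrode an [ElectrodeSpec-class] with capacitance and voltage
#'   window set.
#' @param i drive current, amperes.
#' @return time in seconds (monotonically decreasing in `i`).
#' @export
capacitiveDischargeTime <- function(electrode, i) {
  stopifnot(is(electrode, "ElectrodeSpec"))
  validObject(electrode)
  if (is.na(electrode@capacitance) || is.na(electrode@voltageWindow))
    stop("electrode needs capacitance and voltageWindow")
  if (any(i < 0)) stop("current must be >= 0")
  ifelse(i == 0, Inf, electrode@capacitance * electrode@voltageWindow / i)
}

#' Charge capacity implied by an observed capacitive window
#'
#' Inverse of [capacitiveDischargeTime()]: the product `C * dV = t * i` in
#' coulombs, recoverable from a measured discharge window without knowing C
#' and dV separately.
#'
#' @param t capacitive window, seconds.
#' @param i drive current, amperes.
#' @return `C * dV` in coulombs.
#' @export
capacitiveChargeBudget <- function(t, i) {
  if (any(t < 0) || any(i < 0)) stop("t and i must be >= 0")
  t * i
}
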