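#' Stimulator pulse specification
#'
#' Describes the biphasic stimulator waveform: a short bipolar pulse of one
#' carrier cycle (0.4 ms at 2.5 kHz) whose peak current and voltage at 100%
#' machine output (MO) are given by the manufacturer. The damping factor
#' models the amplitude decay per half-cycle of the real (damped) pulse;
#' the manufacturer does not publish it, so it defaults to 0 (ideal
#' symmetric biphasic) and is configurable for synthetic studies.
#'
#' @param frequency Carrier frequency (Hz).
#' @param duration Pulse duration (s); one biphasic cycle, `~ 1/frequency`.
#' @param peak_current_100 Peak coil current at 100% MO (A).
#' @param peak_voltage_100 Peak voltage at 100% MO (V).
#' @param damping Dimensionless amplitude decay per half-cycle in `[0, 1)`:
#'   the envelope loses this fraction of its amplitude every half period.
#' @return An object of class `pulse_spec`.
#' @export
#' @examples
#' pulse_spec()  # the 2.5 kHz / 5500 A / 1650 V stimulator
pulse_spec <- function(frequency = 2500, duration = 4e-4,
                       peak_current_100 = 5500, peak_voltage_100 = 1650,
                       damping = 0) {
  if (frequency <= 0) stopf("frequency must be > 0")
  if (abs(duration * frequency - 1) > 0.5)
    stopf("duration should span about one biphasic cycle (~ 1/frequency)")
  if (damping < 0 || damping >= 1) stopf("damping must be in [0, 1)")
  structure(list(frequency = frequency, duration = duration,
                 peak_current_100 = peak_current_100,
                 peak_voltage_100 = peak_voltage_100,
                 damping = damping),
            class = "pulse_spec")
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf("pulse_spec: %.3g kHz biphasic, %.3g ms, %g A / %g V at 100%% MO, damping %.3g\n",
              x$frequency / 1e3, x$duration * 1e3, x$peak_current_100,
              x$peak_voltage_100, x$damping))
  invisible(x)
}

# exponential decay rate lambda from the per-half-cycle damping factor:
# exp(-lambda T/2) = 1 - damping
pulse_lambda <- function(pulse) {
  -2 * pulse$frequency * log(1 - pulse$damping)
}

#' Damped-sinusoid current waveform of a pulse
#'
#' `I(t) = MO * Ipeak * exp(-lambda t) * sin(2 pi f t)` with the decay rate
#' `lambda` derived from the spec's per-half-cycle damping factor. Intended
#' for synthetic studies; the real stimulator's damping is not published.
#'
#' @param pulse A [pulse_spec()].
#' @param machine_output Machine output as a fraction in (0, 1].
#' @param t Time(s) since pulse onset (s).
#' @return Current(s) in amperes.
#' @export
pulse_waveform <- function(pulse, machine_output, t) {
  check_mo(machine_output)
  machine_output * pulse$peak_current_100 *
    exp(-pulse_lambda(pulse) * t) * sin(2 * pi * pulse$frequency * t)
}

check_mo <- function(machine_output) {
  if (any(machine_output <= 0) || any(machine_output > 1))
    stopf("machine_output must be a fraction in (0, 1]")
  invisible(machine_output)
}

#' Maximum dI/dt of the pulse
#'
#' The quantity that drives the quasi-static FEM: the current slope over
#' the first quarter period of the biphasic pulse, approximated as a
#' linear ramp from 0 to the peak, i.e.
#' `MO * Ipeak / (1 / (4 f))`. At 70% MO with 5500 A and 2.5 kHz this
#' gives 38.5e6 A/s. A sinusoidal-slope alternative
#' `2 pi f * MO * Ipeak` is available behind `method = "sinusoidal"` but is
#' not the convention used for the reported drive values.
#'
#' @inheritParams pulse_waveform
#' @param method `"ramp"` (default, linear quarter-period ramp) or
#'   `"sinusoidal"` (slope of the undamped sinusoid at onset).
#' @return Maximum dI/dt in A/s; linear in `machine_output`.
#' @export
#' @examples
#' max_didt(pulse_spec(), 0.70)  # 38.5e6 A/s
max_didt <- function(pulse, machine_output, method = c("ramp", "sinusoidal")) {
  check_mo(machine_output)
  method <- match.arg(method)
  peak <- machine_output * pulse$peak_current_100
  switch(method,
         ramp = peak * 4 * pulse$frequency,
         sinusoidal = 2 * pi * pulse$frequency * peak)
}

#' Equivalent DC current of the damped biphasic pulse
#'
#' The time-averaged integral of the current waveform over the pulse
#' duration, `(1/T) integral I(t) dt`: the constant current that would
#' accumulate the same net MR phase as the actual bipolar pulse. Exactly 0
#' for an undamped (symmetric) pulse; nonzero once damping makes the first
#' polarity dominate. Computed in closed form; `n_samples` switches to
#' trapezoidal quadrature of [pulse_waveform()] (useful as a cross-check).
#'
#' @inheritParams pulse_waveform
#' @param n_samples If non-`NULL`, integrate numerically with this many
#'   trapezoid samples instead of using the closed form.
#' @return Equivalent DC current (A); linear in `machine_output`.
#' @export
#' @examples
#' dc_equivalent_current(pulse_spec(damping = 0.5), 0.01)
dc_equivalent_current <- function(pulse, machine_output, n_samples = NULL) {
  check_mo(machine_output)
  i0 <- machine_output * pulse$peak_current_100
  Tdur <- pulse$duration
  if (!is.null(n_samples)) {
    t <- seq(0, Tdur, length.out = as.integer(n_samples))
    y <- pulse_waveform(pulse, machine_output, t)
    return(sum((y[-1] + y[-length(y)]) / 2) * diff(t)[1] / Tdur)
  }
  lam <- pulse_lambda(pulse)
  om <- 2 * pi * pulse$frequency
  if (lam == 0) return(0)  # symmetric biphasic cancels exactly
  integral <- i0 * (om - exp(-lam * Tdur) *
                      (lam * sin(om * Tdur) + om * cos(om * Tdur))) /
    (lam^2 + om^2)
  integral / Tdur
}

#' Apply the current distribution factor of a coil model
#'
#' Rescales the base (spiral-model) current by the model's distribution
#' factor `w`: about 7 for the single-loop model (the wire-length ratio
#' between spiral and single-loop geometry), 1 for the spiral, and
#' `1/n_layers` for each layer of the stacked model. Note that quoted
#' drive tables for this coil family carry an internal inconsistency: the single-loop
#' human-FEM dI/dt equals 7.5x the spiral value although the stated rule is
#' the wire-length factor 7; this function follows the stated `* w` rule.
#'
#' @param base_current Base current of the spiral model (A).
#' @param w Distribution factor (> 0).
#' @return `base_current * w`.
#' @export
#' @examples
#' model_current(3.576, 7)      # single-loop drive, A
#' model_current(3.576, 1 / 7)  # per-layer stacked drive, A
model_current <- function(base_current, w) {
  if (any(w <= 0)) stopf("distribution factor w must be > 0")
  base_current * w
}

#' Wire-length ratio between two coil paths
#'
#' The ratio `wire_length(spiral) / wire_length(single)` that defines the
#' single-loop distribution factor; for the shipped presets it rounds to 7.
#' Using the winding count (9) instead would misestimate the single-loop
#' current by roughly 23%.
#'
#' @param single [wire_path()] of the single-loop model.
#' @param spiral [wire_path()] of the spiral model.
#' @return Positive real length ratio.
#' @export
#' @examples
#' s <- build_single_loop_figure8(coil_preset("bsm811"))
#' p <- build_spiral_figure8(coil_preset("bsm819"))
#' round(length_ratio_factor(s, p))
length_ratio_factor <- function(single, spiral) {
  ls <- wire_length(single)
  if (ls == 0) stopf("zero-length path")
  wire_length(spiral) / ls
}

#' Drive report for a coil model
#'
#' Summarizes the drive quantities for a stimulator setting: the model
#' current after the distribution factor, the equivalent DC current, and
#' the maximum dI/dt (total and after `w`).
#'
#' @inheritParams pulse_waveform
#' @param w Distribution factor of the coil model.
#' @param base_current Optional base (spiral-model) current (A); defaults
#'   to `machine_output * peak_current_100`.
#' @return A list suitable for JSON serialization.
#' @export
drive_report <- function(pulse, machine_output, w = 1, base_current = NULL) {
  check_mo(machine_output)
  base <- base_current %||% (machine_output * pulse$peak_current_100)
  list(machine_output = machine_output,
       distribution_factor = w,
       base_current_A = base,
       model_current_A = model_current(base, w),
       dc_equivalent_A = dc_equivalent_current(pulse, machine_output),
       max_didt_As = max_didt(pulse, machine_output),
       model_didt_As = max_didt(pulse, machine_output) * w)
}
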