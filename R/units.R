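#' Frequency unit conversions
#'
#' Spectra are exposed in ordinary frequency (Hz) while the model works in
#' angular frequency omega (rad/ms). `hz_to_radms()` computes
#' `omega = 2 * pi * f / 1000`, and `radms_to_hz()` inverts it.
#'
#' @param f Frequency in Hz.
#' @param omega Angular frequency in rad/ms.
#' @return A numeric vector in the target unit.
#' @examples
#' hz_to_radms(1000)       # 2*pi rad/ms
#' radms_to_hz(2 * pi)     # 1000 Hz
#' @export
hz_to_radms <- function(f) 2 * pi * f / 1000

#' @rdname hz_to_radms
#' @export
radms_to_hz <- function(omega) omega * 1000 / (2 * pi)
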