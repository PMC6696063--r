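#' Crop water stress index
#'
#' CWSI normalises canopy temperature between the wet (fully transpiring)
#' and dry (non-transpiring) reference-leaf temperatures:
#' \deqn{CWSI = (T_{canopy} - T_{wet}) / (T_{dry} - T_{wet})}
#' so 0 means an unstressed, fully transpiring canopy and 1 a fully
#' stressed one. Values outside \[0, 1\] indicate a canopy temperature
#' beyond the references; they are returned as-is (the masking stage
#' normally prevents them) with a `beyond_reference` attribute flagging the
#' offending elements.
#'
#' @param t_canopy canopy temperature(s), degrees C. Vectorised.
#' @param refs a [reference_readings()] object.
#' @return Numeric vector of dimensionless index values.
#' @seealso [ig()]; the two satisfy `cwsi * (1 + ig) = 1` where both are
#'   defined.
#' @export
#' @examples
#' refs <- reference_readings(t_wet = 20, t_dry = 30)
#' cwsi(25, refs)  # 0.5
cwsi <- function(t_canopy, refs) {
  stopifnot(inherits(refs, "reference_readings"))
  v <- (t_canopy - refs$t_wet) / (refs$t_dry - refs$t_wet)
  out <- v
  beyond <- which(v < 0 | v > 1)
  if (length(beyond)) attr(out, "beyond_reference") <- beyond
  out
}

#' Infrared index Ig
#'
#' The infrared index of Jones, proportional to leaf conductance to water
#' vapour (stomatal conductance, gs):
#' \deqn{I_g = (T_{dry} - T_{canopy}) / (T_{canopy} - T_{wet})}
#' A cool, freely transpiring canopy gives a large Ig; a canopy at the dry
#' reference gives 0. At `t_canopy <= t_wet` the index is undefined
#' (denominator non-positive) and `NA` is returned with a warning.
#'
#' @inheritParams cwsi
#' @return Numeric vector of dimensionless index values (`NA` where
#'   undefined).
#' @export
#' @examples
#' refs <- reference_readings(20, 30)
#' ig(25, refs)            # 1
#' 1 / cwsi(26, refs) - 1  # equals ig(26, refs)
ig <- function(t_canopy, refs) {
  stopifnot(inherits(refs, "reference_readings"))
  denom <- t_canopy - refs$t_wet
  v <- ifelse(denom > 0, (refs$t_dry - t_canopy) / denom, NA_real_)
  if (anyNA(v) && !anyNA(t_canopy)) {
    warning("Ig undefined for t_canopy <= t_wet; returning NA", call. = FALSE)
  }
  out <- v
  beyond <- which(!is.na(v) & v < 0)
  if (length(beyond)) attr(out, "beyond_reference") <- beyond
  out
}
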