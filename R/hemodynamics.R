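## Hemodynamics: Poiseuille wall shear stress from flow and geometry.

#' @rdname meanFlow
setMethod("meanFlow", "FlowTrace", function(trace) {
  n <- length(trace@timeS)
  if (n == 0L) stop("empty flow trace")
  if (n == 1L) {
    warning("single-sample trace: returning that sample as the mean")
    return(trace@flowMlMin / 60)
  }
  avg <- pracma::trapz(trace@timeS, trace@flowMlMin) /
    (trace@timeS[n] - trace@timeS[1])
  avg / 60
})

#' Wall shear stress by the Poiseuille relation
#'
#' Computes tau = 4 eta Q / (pi R^3) in dyn/cm^2, with Q the mean volumetric
#' flow in cm^3/s, eta the blood viscosity in dyn s/cm^2 and R the internal
#' radius in cm. The relation is applicable to vessels with diameter greater
#' than 0.1 mm, which holds for the fistula model.
#'
#' @param Q mean flow, cm^3/s (scalar; see [meanFlow()]), or a
#'   [FlowTrace-class] which is reduced by its time-averaged mean flow.
#' @param geometry a [VesselGeometry-class].
#' @return A [ShearStressEstimate-class].
#' @export
#' @examples
#' poiseuilleWSS(0.0867, vesselGeometry(0.1))
poiseuilleWSS <- function(Q, geometry) {
  if (is(Q, "FlowTrace")) Q <- meanFlow(Q)
  stopifnot(is(geometry, "VesselGeometry"))
  if (any(Q < 0)) stop("Q must be >= 0")
  validObject(geometry)
  t <- 4 * geometry@viscosity * Q / (pi * geometry@radiusCm^3)
  new("ShearStressEstimate", tau = t, meanFlowCm3S = Q,
      radiusCm = geometry@radiusCm, viscosity = geometry@viscosity)
}

#' Percent change relative to a baseline
#'
#' @param value observed value(s).
#' @param baseline baseline value, must be positive.
#' @return 100 * (value - baseline) / baseline.
#' @export
#' @examples
#' percentChange(12.48, 5.2)  # 140
percentChange <- function(value, baseline) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  100 * (value - baseline) / baseline
}

#' Per-day wall-shear-stress time-course
#'
#' Reduces each trace by its mean flow, applies the Poiseuille relation with
#' the matching same-rat same-day geometry, and summarizes per day as group
#' mean, standard error and fold-change versus the fistula-creation day
#' (day 0 when present, otherwise the earliest post-baseline day).
#'
#' @param traces list of [FlowTrace-class] objects.
#' @param geometries data.frame with columns `ratId`, `day`, `radiusCm`,
#'   `viscosity`.
#' @return data.frame with columns `day`, `n`, `meanTau`, `seTau`,
#'   `foldVsDay0`.
#' @export
wssTimecourse <- function(traces, geometries) {
  stopifnot(is.list(traces), is.data.frame(geometries))
  rows <- lapply(traces, function(tr) {
    g <- geometries[geometries$ratId == tr@ratId & geometries$day == tr@day, ]
    if (nrow(g) != 1L)
      stop(sprintf("no matching geometry for rat %s day %g", tr@ratId, tr@day))
    est <- poiseuilleWSS(meanFlow(tr),
                         vesselGeometry(g$radiusCm, g$viscosity))
    data.frame(ratId = tr@ratId, day = tr@day, tau = est@tau)
  })
  d <- do.call(rbind, rows)
  days <- sort(unique(d$day))
  out <- do.call(rbind, lapply(days, function(dy) {
    v <- d$tau[d$day == dy]
    data.frame(day = dy, n = length(v), meanTau = mean(v),
               seTau = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  post <- out$day[out$day >= 0]
  refDay <- if (length(post)) min(post) else min(out$day)
  out$foldVsDay0 <- out$meanTau / out$meanTau[out$day == refDay]
  out
}
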