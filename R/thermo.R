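#' @include AllClasses.R
NULL

#' Mechanical surface tension from a pressure-tensor series
#'
#' Per frame, the tension is the pressure anisotropy scaled by the box
#' length along the interface normal and divided by the number of
#' interfaces:
#' \deqn{\gamma(t) = \frac{L_N}{n}\left(P_{NN}(t) -
#'   \frac{P_{T_1T_1}(t) + P_{T_2T_2}(t)}{2}\right)}
#' Positive tension means the interface resists expansion (the normal
#' component exceeds the tangential mean in this arrangement). A periodic
#' slab has two interfaces (\code{nInterfaces = 2}). The standard error is
#' computed by block averaging (5 equal blocks by default), appropriate for
#' the strong autocorrelation of pressure series.
#'
#' @param series a [PressureSeries-class].
#' @param axis interface normal axis.
#' @param nInterfaces 1 or 2.
#' @param nBlocks blocks for the block-averaged SE.
#' @return a [TensionEstimate-class].
#' @examples
#' s <- makePressureSeries(300, boxLength = 10, nInterfaces = 2,
#'                         nFrames = 100)
#' tensionMean(surfaceTension(s))
#' @export
surfaceTension <- function(series, axis = "x", nInterfaces = 2,
                           nBlocks = 5) {
  if (!nInterfaces %in% 1:2)
    stop("nInterfaces must be 1 or 2")
  ax <- .axisIndex(axis)
  d <- pressureData(series)
  P <- cbind(d$Pxx, d$Pyy, d$Pzz)
  L <- cbind(d$Lx, d$Ly, d$Lz)[, ax]
  tang <- setdiff(1:3, ax)
  gamma <- L / nInterfaces * (P[, ax] - (P[, tang[1]] + P[, tang[2]]) / 2)
  n <- length(gamma)
  se <- NA_real_
  if (n >= nBlocks) {
    blk <- split(gamma, cut(seq_len(n), nBlocks, labels = FALSE))
    bm <- vapply(blk, mean, 0)
    se <- sd(bm) / sqrt(length(bm))
  }
  new("TensionEstimate", mean = mean(gamma), se = se, gamma = gamma,
      axis = ax, nInterfaces = as.integer(nInterfaces),
      nBlocks = as.integer(nBlocks))
}

#' Girifalco--Good interaction parameter
#'
#' Relates the interfacial tension between two liquids to the geometric
#' mean of their pure-liquid surface tensions:
#' \deqn{\phi = \frac{\gamma_A + \gamma_B - \gamma_{AB}}
#'   {2\sqrt{\gamma_A\gamma_B}}}
#' Non-associated liquid pairs such as water/dichloromethane fall in the
#' experimental range 0.5--0.8 (with pure-liquid tensions around 720 and
#' 280 bar nm respectively).
#'
#' @param gammaA,gammaB pure-liquid surface tensions (bar nm, > 0).
#' @param gammaAB interfacial tension between the liquids (bar nm, >= 0).
#' @return phi (dimensionless).
#' @examples
#' girifalcoGoodPhi(720, 280, 551)  # ~0.5
#' @export
girifalcoGoodPhi <- function(gammaA, gammaB, gammaAB) {
  if (any(c(gammaA, gammaB) <= 0))
    stop("pure-liquid tensions must be positive")
  if (gammaAB < 0) stop("interfacial tension must be nonnegative")
  (gammaA + gammaB - gammaAB) / (2 * sqrt(gammaA * gammaB))
}
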