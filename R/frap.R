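#' Double normalization of a FRAP trace
#'
#' Corrects for acquisition photobleaching and normalizes to the pre-bleach
#' level: N(t) = [I_bleach(t) / I_ref(t)] / [I_bleach_pre / I_ref_pre].
#' Photobleaching common to both channels cancels exactly in the ratio; the
#' normalized recovery runs from ~0 (right after the bleach) toward ~1
#' (full recovery).
#'
#' @param trace a [FRAPTrace-class].
#' @return data.frame with columns `time` (s) and `value` (normalized
#'   intensity), all samples; post-bleach samples are those with
#'   `time >= 0`.
#' @export
normalizeFrap <- function(trace) {
  if (any(trace@reference <= 0))
    stop("reference intensities must be positive for double normalization")
  value <- (trace@bleached / trace@reference) /
    (trace@preBleached / trace@preReference)
  data.frame(time = trace@time, value = value)
}

#' Fit the mono-exponential recovery Y = A e^(-kt) + B
#'
#' Nonlinear least squares on the post-bleach samples, with the amplitude A
#' signed: upward FRAP recovery corresponds to A < 0, so the printed
#' exponential form holds verbatim and the half-time depends only on k.
#' Initialization: B0 = mean of the last 3 points, A0 = Y(0) - B0, k0 from
#' the time at which the curve has covered half of |B0 - Y(0)|.
#'
#' @param series data.frame with columns `time` and `value` (output of
#'   [normalizeFrap]), or a [FRAPTrace-class] (normalized internally).
#' @param normalized when FALSE and a [FRAPTrace-class] is given, the raw
#'   bleached-channel trace is fitted instead of the normalized one.
#' @return An [ExpFit-class]; `converged` is FALSE when the optimizer
#'   failed or ended at k <= 0.
#' @export
fitRecovery <- function(series, normalized = TRUE) {
  if (is(series, "FRAPTrace")) {
    series <- if (normalized) normalizeFrap(series)
              else data.frame(time = series@time, value = series@bleached)
  }
  stopifnot(all(c("time", "value") %in% names(series)))
  post <- series[series$time >= 0, , drop = FALSE]
  if (nrow(post) < 5L) stop("need >= 5 post-bleach points")
  tt <- post$time - post$time[1]
  y <- post$value

  B0 <- mean(utils::tail(y, 3))
  A0 <- y[1] - B0
  span <- B0 - y[1]
  iHalf <- which(abs(y - y[1]) >= abs(span) / 2)[1]
  k0 <- if (!is.na(iHalf) && tt[iHalf] > 0) log(2) / tt[iHalf] else 1 / max(median(tt), 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ B + A * exp(-k * tt),
                      start = list(A = A0, k = k0, B = B0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("ExpFit", A = 0, k = NA_real_, B = mean(y), tHalf = NA_real_,
               rss = sum((y - mean(y))^2), converged = FALSE))
  }
  p <- coef(fit)
  ok <- is.finite(p[["k"]]) && p[["k"]] > 0
  new("ExpFit", A = unname(p[["A"]]), k = unname(p[["k"]]), B = unname(p[["B"]]),
      tHalf = if (ok) log(2) / p[["k"]] else NA_real_,
      rss = sum(resid(fit)^2), converged = ok)
}
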