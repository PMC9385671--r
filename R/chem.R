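#' Henderson-Hasselbalch pKa fit of an NMR titration
#'
#' Least-squares fit of the two-state fast-exchange titration curve
#' delta(pH) = delta_HA + (delta_A - delta_HA) / (1 + 10^(pKa - pH))
#' to observed chemical shifts. Initialization takes the plateaus from the
#' shifts at the pH extremes and pKa from the pH of the mid-shift point.
#' Halogenation of the tyrosine phenol lowers this pKa from 9.9 (Tyr) to
#' ~8.3 (mono-) and ~6.5 (di-halogenated).
#'
#' @param pH pH values (>= 6 points, within [0, 14]).
#' @param delta observed chemical shifts, ppm.
#' @return An [HHFit-class] with the fitted pKa, the two plateau shifts,
#'   the residual sd and the 95% confidence half-width on pKa.
#' @examples
#' tit <- makeTitration(6.52, 7.10, 6.70, seq(4, 10, 0.25))
#' fitPka(tit$pH, tit$delta)
#' @export
fitPka <- function(pH, delta) {
  stopifnot(length(pH) == length(delta))
  if (length(pH) < 6L) stop("need >= 6 titration points")
  if (any(pH < 0 | pH > 14)) stop("pH values must lie in [0, 14]")
  if (diff(range(delta)) == 0)
    stop("transition not sampled: chemical shift is constant (delta_HA = delta_A)")

  o <- order(pH)
  pHo <- pH[o]; del <- delta[o]
  dHA0 <- del[1]; dA0 <- del[length(del)]
  mid <- (dHA0 + dA0) / 2
  pKa0 <- pHo[which.min(abs(del - mid))]

  fit <- tryCatch(
    minpack.lm::nlsLM(del ~ dHA + (dA - dHA) / (1 + 10^(pKa - pHo)),
                      start = list(pKa = pKa0, dHA = dHA0, dA = dA0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) stop("transition not sampled: titration fit failed (",
                             conditionMessage(e), ")"))
  p <- coef(fit)
  residSd <- sd(resid(fit))
  if (abs(p[["dHA"]] - p[["dA"]]) < 3 * residSd)
    stop("transition not sampled: shift range below 3x residual sd")
  se <- tryCatch(summary(fit)$coefficients["pKa", "Std. Error"],
                 error = function(e) NA_real_)
  if (p[["pKa"]] < min(pHo) - 1 || p[["pKa"]] > max(pHo) + 1)
    warning("fitted pKa lies outside the sampled pH range +/- 1")
  new("HHFit", pKa = unname(p[["pKa"]]), deltaHA = unname(p[["dHA"]]),
      deltaA = unname(p[["dA"]]), residSd = residSd,
      ciHalfWidth = unname(1.96 * se))
}

#' pH-dependent distribution coefficient of a monoprotic acid
#'
#' logD(pH) = logP - log10(1 + 10^(pH - pKa)): the standard first-order
#' acid-partitioning model in which only the neutral (protonated) species
#' partitions into the organic phase. Captures the interplay seen for
#' halogenated tyrosines: each halogen raises the intrinsic lipophilicity
#' (logP) but lowers the phenolic pKa, so at physiological pH the ionized
#' fraction grows and the apparent lipophilicity falls.
#'
#' @param logP intrinsic (neutral-species) partition coefficient.
#' @param pKa acid dissociation constant of the ionizable group.
#' @param pH pH grid, within [0, 14].
#' @return numeric vector of logD values.
#' @examples
#' logdProfile(1.0, 6.52, c(6, 7.4, 9))
#' @export
logdProfile <- function(logP, pKa, pH) {
  stopifnot(all(pH >= 0 & pH <= 14))
  logP - log10(1 + 10^(pH - pKa))
}

# standard atomic masses (IUPAC 2021 conventional) and monoisotopic masses
.atomicMass <- list(
  average      = c(H = 1.008,        Cl = 35.45,       Br = 79.904,     I = 126.904),
  monoisotopic = c(H = 1.0078250319, Cl = 34.96885268, Br = 78.9183376, I = 126.9044719))

#' Mass shift from hydrogen-to-halogen substitution
#'
#' Theoretical mass shift of a protein when ring hydrogens of a tyrosine
#' are replaced by halogens: sum of n_X * (m(X) - m(H)) over the chosen
#' halogen counts, for comparison with observed intact-mass shifts of
#' halogenated protein variants.
#'
#' @param nCl,nBr,nI number of substituted chlorine/bromine/iodine atoms
#'   (>= 0).
#' @param mode `"average"` (standard atomic weights) or `"monoisotopic"`.
#' @return mass shift in Da.
#' @examples
#' halogenMassShift(nCl = 1)           # ~ +34.44 Da
#' halogenMassShift(nI = 2)            # ~ +251.79 Da
#' @export
halogenMassShift <- function(nCl = 0, nBr = 0, nI = 0,
                             mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (nCl < 0 || nBr < 0 || nI < 0) stop("halogen counts must be >= 0")
  m <- .atomicMass[[mode]]
  nCl * (m[["Cl"]] - m[["H"]]) + nBr * (m[["Br"]] - m[["H"]]) +
    nI * (m[["I"]] - m[["H"]])
}
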