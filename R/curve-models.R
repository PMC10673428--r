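## Spectral summarization and fitting of pH, chemical and thermal
## denaturation curves. All fits use Levenberg-Marquardt least squares
## (minpack.lm) with heuristic initialization: the midpoint seed is the
## abscissa of the largest |numerical derivative| of the signal and baseline
## seeds come from the terminal 20% of points at each end.

IRREVERSIBILITY_CAVEAT <- paste(
  "apparent parameters: denaturation assumed irreversible;",
  "no Gibbs energy of folding should be derived from this fit")

#' Spectral mass center of an emission spectrum
#'
#' The intensity-weighted mean of the reciprocal emission wavelength,
#' \eqn{\langle\lambda\rangle = \sum_i (I_i/\lambda_i) / \sum_i I_i},
#' reported in inverse micrometers. An intensive summary of the whole
#' spectrum: invariant under intensity scaling, bounded by the reciprocal
#' wavelength range.
#'
#' @param trace a [SpectralTrace-class] (wavelengths in nm).
#' @return numeric scalar in um^-1.
#' @examples
#' spectralCenter(SpectralTrace(500, 1))          # 2.0
#' spectralCenter(SpectralTrace(c(400, 500), c(1, 1)))  # 2.25
#' @export
spectralCenter <- function(trace) {
  stopifnot(is(trace, "SpectralTrace"))
  itot <- sum(trace@intensity)
  if (itot <= 0) stop("total intensity must be > 0")
  ## nm^-1 -> um^-1 conversion factor 1000
  1000 * sum(trace@intensity / trace@wavelength) / itot
}

#' Hill titration model
#'
#' Signal of a mixture of protonated and deprotonated species,
#' X = (Xa + Xb 10^(n (pH - pKa))) / (1 + 10^(n (pH - pKa))). At pH = pKa
#' the signal is (Xa + Xb)/2 for any Hill coefficient n; as n grows the
#' model approaches a two-level step.
#'
#' @param pH numeric pH values.
#' @param pKa apparent midpoint.
#' @param n Hill coefficient.
#' @param Xa,Xb acidic / basic intrinsic signals.
#' @return numeric signal values.
#' @export
hillEval <- function(pH, pKa, n = 1, Xa = 1, Xb = 0) {
  ## algebraically identical to (Xa + Xb r)/(1 + r) with r = 10^(n(pH-pKa)),
  ## but stable when r overflows
  r <- 10^(n * (pH - pKa))
  Xb + (Xa - Xb) / (1 + r)
}

#' Linear extrapolation model Gibbs energy
#'
#' dG = m ([D]_1/2 - [D]) in kcal mol^-1: positive below the midpoint,
#' zero at it, negative above.
#'
#' @param m slope, kcal mol^-1 M^-1.
#' @param D_half midpoint concentration, M.
#' @param D denaturant concentration(s), M.
#' @return numeric kcal mol^-1.
#' @export
lemGibbs <- function(m, D_half, D) m * (D_half - D)

## seed for the midpoint: abscissa of the max |dy/dx| after light smoothing
## (a raw point-to-point derivative is noise-dominated on dense grids)
midpointSeed <- function(x, y) {
  k <- min(max(1L, round(length(y) / 30)), (length(y) - 1L) %/% 2L)
  if (k > 0) {
    sm <- stats::filter(y, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
    y <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  d <- abs(diff(y) / diff(x))
  mean(x[which.max(d) + c(0, 1)])
}

## terminal-baseline seeds: mean of first/last 20% of points
edgeMeans <- function(y) {
  k <- max(2L, ceiling(length(y) * 0.2))
  c(lo = mean(utils::head(y, k)), hi = mean(utils::tail(y, k)))
}

## shared nlsLM wrapper returning estimates/se/convergence
runNls <- function(formula, data, start, lower = NULL, upper = NULL) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- tryCatch(
    if (is.null(lower))
      minpack.lm::nlsLM(formula, data = data, start = start, control = ctl)
    else
      minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                        upper = upper, control = ctl),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(ok = FALSE, message = conditionMessage(fit)))
  sm <- summary(fit)
  est <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  list(ok = TRUE, estimates = est, se = se,
       sigma = sm$sigma, fitted = stats::fitted(fit),
       iterations = fit$convInfo$finIter, message = fit$convInfo$stopMessage)
}

## is there any usable signal variation?
isFlat <- function(y, tol = 1e-10) diff(range(y)) <= tol * max(1, max(abs(y)))

#' Fit the Hill titration model to a pH curve
#'
#' Nonlinear least-squares estimate of (pKa, n, Xa, Xb). A constant signal
#' is unidentifiable and raises an error; non-convergence is returned as a
#' flagged failure with diagnostics.
#'
#' @param curve a [DenaturationCurve-class] with `axisKind == "pH"` and at
#'   least 6 points spanning the transition.
#' @return a [TitrationFit-class].
#' @export
fitTitration <- function(curve) {
  stopifnot(is(curve, "DenaturationCurve"))
  if (axisKind(curve) != "pH") stop("curve axis must be pH")
  x <- xValues(curve); y <- signalValues(curve)
  if (length(x) < 6L) stop("at least 6 points are required")
  if (isFlat(y)) stop("constant signal: titration parameters unidentifiable")
  em <- edgeMeans(y)
  start <- list(pKa = midpointSeed(x, y), n = 1, Xa = em[["lo"]],
                Xb = em[["hi"]])
  res <- runNls(y ~ (Xa + Xb * 10^(n * (x - pKa))) / (1 + 10^(n * (x - pKa))),
                data.frame(x = x, y = y), start)
  newFit("TitrationFit", res, required_pos = "n")
}

#' Fit the linear extrapolation model to a chemical denaturation curve
#'
#' Two-state model with LEM Gibbs energy and baselines linear in the
#' denaturant concentration:
#' X = (XN(D) + XD(D) K) / (1 + K), K = exp(-m([D]_1/2 - [D]) / (R T)).
#' Because chemical denaturations of this kind are typically irreversible,
#' the reported (m, [D]_1/2) are apparent values and the fit carries an
#' irreversibility caveat. Inputs without a sigmoidal region (flat or
#' linear curves) yield a flagged, non-converged result.
#'
#' @param curve a [DenaturationCurve-class] with `axisKind ==
#'   "denaturant_M"` and `temperatureK` set.
#' @return a [ChemicalFit-class] with coefficients `m`, `D_half`, `XN`,
#'   `sN`, `XD`, `sD` (baseline intercepts and slopes).
#' @export
fitChemical <- function(curve) {
  stopifnot(is(curve, "DenaturationCurve"))
  if (axisKind(curve) != "denaturant_M") stop("curve axis must be denaturant_M")
  tK <- curve@temperatureK
  if (is.na(tK)) stop("temperatureK must be set for chemical fits")
  x <- xValues(curve); y <- signalValues(curve)
  RT <- GAS_CONSTANT_KCAL * tK
  em <- edgeMeans(y)
  start <- list(m = 2, D_half = midpointSeed(x, y), XN = em[["lo"]], sN = 0,
                XD = em[["hi"]], sD = 0)
  fail <- function(msg) newFit("ChemicalFit", list(ok = FALSE, message = msg))
  if (isFlat(y)) return(fail("flat curve: no sigmoidal region"))
  res <- runNls(
    y ~ ((XN + sN * x) + (XD + sD * x) * exp(-m * (D_half - x) / RT)) /
      (1 + exp(-m * (D_half - x) / RT)),
    data.frame(x = x, y = y), start)
  fit <- newFit("ChemicalFit", res, required_pos = "m")
  ## reject pseudo-fits of curves with no transition inside the range: the
  ## midpoint must fall inside the window and the 10-90% transition width
  ## 2 RT log(81) / m must not exceed it (else the "sigmoid" is a trend)
  if (fit@converged) {
    est <- coef(fit)
    width <- 2 * RT * log(81) / est[["m"]]   # 10-90% transition width
    dh <- est[["D_half"]]
    amp <- abs((est[["XN"]] + est[["sN"]] * dh) -
                 (est[["XD"]] + est[["sD"]] * dh))
    if (dh <= min(x) || dh >= max(x) || width > diff(range(x)) ||
        amp < 0.1 * diff(range(y)))
      return(fail("no sigmoidal region inside the measured range"))
  }
  fit
}

#' Fit a two-state Gibbs-Helmholtz model to a thermal denaturation curve
#'
#' Two-state model with
#' dG(T) = dHm (1 - T/Tm) - dCp (Tm - T + T log(T/Tm)) evaluated in kelvin
#' and baselines linear in the Celsius temperature. dCp is a free parameter
#' by default; a van't Hoff dCp from one irreversible curve is weakly
#' identified, so it can be fixed via `fix_dCp` (0 gives the plain van't
#' Hoff form). Reported parameters are apparent values.
#'
#' @param curve a [DenaturationCurve-class] with `axisKind ==
#'   "temperature_C"`.
#' @param fix_dCp optional fixed dCp in kcal mol^-1 K^-1 (`NULL` = free).
#' @return a [ThermalFit-class] with coefficients `Tm` (degrees Celsius),
#'   `dHm`, `dCp`, and baselines `XN`, `sN`, `XD`, `sD`.
#' @export
fitThermal <- function(curve, fix_dCp = NULL) {
  stopifnot(is(curve, "DenaturationCurve"))
  if (axisKind(curve) != "temperature_C") stop("curve axis must be temperature_C")
  x <- xValues(curve); y <- signalValues(curve)
  fail <- function(msg) newFit("ThermalFit", list(ok = FALSE, message = msg))
  if (isFlat(y)) return(fail("flat curve: no transition in range"))
  em <- edgeMeans(y)
  start <- list(Tm = midpointSeed(x, y), dHm = 60, XN = em[["lo"]], sN = 0,
                XD = em[["hi"]], sD = 0)
  lower <- c(Tm = min(x) - 20, dHm = 1e-3, XN = -Inf, sN = -Inf, XD = -Inf,
             sD = -Inf)
  upper <- c(Tm = max(x) + 20, dHm = Inf, XN = Inf, sN = Inf, XD = Inf,
             sD = Inf)
  if (is.null(fix_dCp)) {
    start$dCp <- 0
    lower <- c(lower, dCp = -Inf); upper <- c(upper, dCp = Inf)
    form <- y ~ gibbsHelmholtzSignal(x, Tm, dHm, dCp, XN, sN, XD, sD)
  } else {
    dCpFixed <- fix_dCp
    form <- y ~ gibbsHelmholtzSignal(x, Tm, dHm, dCpFixed, XN, sN, XD, sD)
  }
  res <- multiStartNls(form, data.frame(x = x, y = y), start, lower, upper,
                       tmName = "Tm", x = x)
  if (res$ok && !is.null(fix_dCp)) {
    res$estimates <- c(res$estimates, dCp = fix_dCp)
    res$se <- c(res$se, dCp = NA_real_)
  }
  fit <- newFit("ThermalFit", res, required_pos = "dHm")
  if (fit@converged &&
      (coef(fit)[["Tm"]] <= min(x) || coef(fit)[["Tm"]] >= max(x) ||
       coef(fit)[["dHm"]] < 1))
    return(fail("no transition inside the measured temperature range"))
  fit
}

## Levenberg-Marquardt with a few alternative midpoint starting values
## (smoothed-derivative seed first, then window quantiles); the converged
## candidate with the smallest residual standard deviation wins.
multiStartNls <- function(form, data, start, lower, upper, tmName, x) {
  cand <- unique(c(start[[tmName]],
                   stats::quantile(x, c(0.35, 0.5, 0.65), names = FALSE)))
  best <- list(ok = FALSE, message = "no converged candidate")
  for (tm in cand) {
    st <- start
    st[[tmName]] <- tm
    res <- runNls(form, data, st, lower = lower[names(st)],
                  upper = upper[names(st)])
    if (res$ok && (!best$ok || res$sigma < best$sigma)) best <- res
  }
  best
}

## two-state Gibbs-Helmholtz signal with linear baselines; temperatures in
## degrees Celsius, dG evaluated in kelvin
gibbsHelmholtzSignal <- function(x, Tm, dHm, dCp, XN, sN, XD, sD) {
  tk <- celsiusToKelvin(x); tmk <- celsiusToKelvin(Tm)
  dG <- dHm * (1 - tk / tmk) - dCp * (tmk - tk + tk * log(tk / tmk))
  K <- exp(-dG / (GAS_CONSTANT_KCAL * tk))
  ((XN + sN * x) + (XD + sD * x) * K) / (1 + K)
}

## construct a fit-result object from a runNls result; required_pos names a
## coefficient that must be > 0 for the fit to be accepted.
newFit <- function(class, res, required_pos = NULL) {
  if (!res$ok)
    return(new(class, coefficients = numeric(), se = numeric(),
               converged = FALSE,
               diagnostics = list(message = res$message),
               caveat = IRREVERSIBILITY_CAVEAT))
  conv <- TRUE
  msg <- res$message
  if (!is.null(required_pos) && res$estimates[[required_pos]] <= 0) {
    conv <- FALSE
    msg <- paste0(required_pos, " <= 0: fit rejected")
  }
  new(class, coefficients = res$estimates, se = res$se, converged = conv,
      diagnostics = list(sigma = res$sigma, iterations = res$iterations,
                         message = msg),
      caveat = IRREVERSIBILITY_CAVEAT)
}
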