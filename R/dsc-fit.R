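## DSC thermogram deconvolution: two-transition (two independent energetic
## domains) or sequential three-state model, fitted to baseline-subtracted
## excess heat capacity by Levenberg-Marquardt least squares.

## Tm seeds: the two largest local maxima of a lightly smoothed thermogram.
dscSeeds <- function(tC, cp) {
  k <- max(1L, round(length(cp) / 100))
  sm <- stats::filter(cp, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  sm[is.na(sm)] <- cp[is.na(sm)]
  n <- length(sm)
  ispeak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                sm[2:(n - 1)] >= sm[3:n], FALSE)
  peaks <- which(ispeak)
  if (length(peaks) == 0L) peaks <- which.max(sm)
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  ## keep the two highest maxima at least 5 degC apart
  tm1 <- tC[peaks[1]]
  sep <- peaks[abs(tC[peaks] - tm1) > 5]
  tm2 <- if (length(sep)) tC[sep[1]] else tm1 + 10
  ## enthalpy seed from peak height via the two-state relation
  ## dH^2 ~ 4 R Tm^2 Cp_max
  dhFromPeak <- function(tm, cpmax)
    sqrt(max(4 * GAS_CONSTANT_KCAL * celsiusToKelvin(tm)^2 * max(cpmax, 0.1),
             1))
  tms <- sort(c(tm1, tm2))
  cpAt <- function(tm) cp[which.min(abs(tC - tm))]
  list(tm1 = tms[1], dh1 = dhFromPeak(tms[1], cpAt(tms[1])),
       tm2 = tms[2], dh2 = dhFromPeak(tms[2], cpAt(tms[2])))
}

#' Fit a two-transition (or three-state) model to a DSC thermogram
#'
#' Deconvolutes a baseline-subtracted excess-heat-capacity curve into two
#' unfolding transitions. The two-transition model treats the protein as two
#' independently unfolding energetic domains, partition function
#' Q = (1 + K1)(1 + K2); the sequential three-state alternative uses
#' Q = 1 + K1 + K1 K2. Transitions are relabeled so Tm1 <= Tm2 after
#' fitting, and the state populations implied by the fit are returned
#' alongside the estimates. dCp per transition is fixed (default 0, the
#' convention for thermograms whose heat-capacity step was removed with a
#' progress baseline) unless `free_dCp = TRUE`.
#'
#' Initialization: Tm seeds at the two largest local maxima of the
#' thermogram; dH seeds from the peak height via dH^2 ~ 4 R Tm^2 Cp_max.
#' Non-convergence or parameter collapse (coincident Tm with degenerate
#' enthalpies) is returned as a flagged failure.
#'
#' @param thermogram a [Thermogram-class] (baseline-subtracted).
#' @param model `"two_transition"` (default) or `"three_state"`.
#' @param free_dCp estimate a dCp per transition (default FALSE).
#' @return a [DscFit-class] with coefficients `Tm1`, `dH1`, `Tm2`, `dH2`
#'   (plus `dCp1`, `dCp2` when free).
#' @export
fitDsc <- function(thermogram, model = c("two_transition", "three_state"),
                   free_dCp = FALSE) {
  model <- match.arg(model)
  stopifnot(is(thermogram, "Thermogram"))
  tC <- thermogram@temperature
  cp <- thermogram@excessCp
  emptyPops <- statePopulations(list(TransitionParams(0, 0),
                                     TransitionParams(0, 0)), tC)
  fail <- function(msg) new("DscFit", coefficients = numeric(),
                            se = numeric(), converged = FALSE,
                            diagnostics = list(message = msg),
                            caveat = character(), model = model,
                            populations = emptyPops)
  if (isFlat(cp)) return(fail("flat thermogram: no transition"))
  sd0 <- dscSeeds(tC, cp)
  start <- list(Tm1 = sd0$tm1, dH1 = sd0$dh1, Tm2 = sd0$tm2, dH2 = sd0$dh2)
  if (free_dCp) start <- c(start, list(dCp1 = 0, dCp2 = 0))
  modelTag <- model
  cpModel <- function(Tm1, dH1, Tm2, dH2, dCp1 = 0, dCp2 = 0)
    excessCpValues(list(TransitionParams(Tm1, dH1, dCp1),
                        TransitionParams(Tm2, dH2, dCp2)),
                   celsiusToKelvin(tC), model = modelTag)
  form <- if (free_dCp)
    cp ~ cpModel(Tm1, dH1, Tm2, dH2, dCp1, dCp2)
  else cp ~ cpModel(Tm1, dH1, Tm2, dH2)
  lower <- c(Tm1 = min(tC) - 30, dH1 = 0.1, Tm2 = min(tC) - 30, dH2 = 0.1)
  upper <- c(Tm1 = max(tC) + 30, dH1 = Inf, Tm2 = max(tC) + 30, dH2 = Inf)
  if (free_dCp) {
    lower <- c(lower, dCp1 = -5, dCp2 = -5)
    upper <- c(upper, dCp1 = 5, dCp2 = 5)
  }
  res <- runNls(form, data.frame(cp = cp), start,
                lower = lower[names(start)], upper = upper[names(start)])
  if (!res$ok) return(fail(res$message))
  est <- res$estimates; se <- res$se
  ## relabel so Tm1 <= Tm2
  if (est[["Tm1"]] > est[["Tm2"]]) {
    sw <- function(v) {
      v[c("Tm1", "dH1", "Tm2", "dH2")] <- v[c("Tm2", "dH2", "Tm1", "dH1")]
      if ("dCp1" %in% names(v))
        v[c("dCp1", "dCp2")] <- v[c("dCp2", "dCp1")]
      v
    }
    est <- sw(est); se <- sw(se)
  }
  if (abs(est[["Tm1"]] - est[["Tm2"]]) < 0.5 &&
      min(est[["dH1"]], est[["dH2"]]) < 1)
    return(fail("parameter collapse: coincident Tm with degenerate enthalpy"))
  tr <- list(TransitionParams(est[["Tm1"]], est[["dH1"]],
                              if (free_dCp) est[["dCp1"]] else 0),
             TransitionParams(est[["Tm2"]], est[["dH2"]],
                              if (free_dCp) est[["dCp2"]] else 0))
  new("DscFit", coefficients = est, se = se, converged = TRUE,
      diagnostics = list(sigma = res$sigma, iterations = res$iterations,
                         message = res$message),
      caveat = character(), model = model,
      populations = statePopulations(tr, tC))
}

## plain-function form of thermofluorSignal for use inside nls formulas
thermofluorModel <- function(x, Tm, dH, dCp, aN, bN, aU, bU) {
  tk <- celsiusToKelvin(x); tmk <- celsiusToKelvin(Tm)
  dG <- dH * (1 - tk / tmk) + dCp * (tk - tmk - tk * log(tk / tmk))
  K <- exp(-dG / (GAS_CONSTANT_KCAL * tk))
  ((aN + bN * x) + (aU + bU * x) * K) / (1 + K)
}

#' Fit the two-state thermal-shift model to a fluorescence trace
#'
#' Estimates (Tm, dH(Tm), dCp) together with the four linear baseline
#' parameters from a thermal-shift (differential scanning fluorimetry)
#' trace, using the population-weighted two-state model of
#' [thermofluorSignal()]. dCp is fixed at `fix_dCp` (default 0) because a
#' van't Hoff dCp is weakly identified from a single trace; pass `NULL` to
#' free it. The fitted Tm is invariant under overall signal scaling, so
#' traces recorded at different protein concentrations give the same Tm.
#'
#' @param curve a [DenaturationCurve-class] with a temperature axis.
#' @return a [ThermalFit-class] with coefficients `Tm`, `dH`, `dCp`, `aN`,
#'   `bN`, `aU`, `bU`.
#' @param fix_dCp fixed dCp (kcal mol^-1 K^-1) or NULL to estimate it.
#' @export
fitThermofluor <- function(curve, fix_dCp = 0) {
  stopifnot(is(curve, "DenaturationCurve"))
  if (axisKind(curve) != "temperature_C")
    stop("curve axis must be temperature_C")
  x <- xValues(curve); y <- signalValues(curve)
  fail <- function(msg) newFit("ThermalFit", list(ok = FALSE, message = msg))
  if (isFlat(y)) return(fail("flat trace: no transition"))
  k <- max(2L, ceiling(length(y) * 0.2))
  ## baseline seeds: linear fits over the terminal 20% at each end
  loFit <- stats::lm(y ~ x, data.frame(x = utils::head(x, k),
                                       y = utils::head(y, k)))
  hiFit <- stats::lm(y ~ x, data.frame(x = utils::tail(x, k),
                                       y = utils::tail(y, k)))
  start <- list(Tm = midpointSeed(x, y), dH = 80,
                aN = stats::coef(loFit)[[1]], bN = stats::coef(loFit)[[2]],
                aU = stats::coef(hiFit)[[1]], bU = stats::coef(hiFit)[[2]])
  free <- is.null(fix_dCp)
  if (free) start$dCp <- 0 else dCpFixed <- fix_dCp
  form <- if (free)
    y ~ thermofluorModel(x, Tm, dH, dCp, aN, bN, aU, bU)
  else
    y ~ thermofluorModel(x, Tm, dH, dCpFixed, aN, bN, aU, bU)
  lower <- c(Tm = min(x) - 20, dH = 1e-3, aN = -Inf, bN = -Inf, aU = -Inf,
             bU = -Inf, dCp = -Inf)
  upper <- c(Tm = max(x) + 20, dH = Inf, aN = Inf, bN = Inf, aU = Inf,
             bU = Inf, dCp = Inf)
  res <- multiStartNls(form, data.frame(x = x, y = y), start, lower, upper,
                       tmName = "Tm", x = x)
  if (res$ok && !free) {
    res$estimates <- c(res$estimates, dCp = fix_dCp)
    res$se <- c(res$se, dCp = NA_real_)
  }
  fit <- newFit("ThermalFit", res, required_pos = "dH")
  if (fit@converged &&
      (coef(fit)[["Tm"]] <= min(x) || coef(fit)[["Tm"]] >= max(x)))
    return(fail("no transition inside the measured temperature range"))
  fit
}
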