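#' Fit a one-site specific binding model to a steady-state curve
#'
#' Least-squares fit of `R(C) = Rmax * C / (KD + C)` (the steady-state
#' analysis used for TCR-pMHC surface plasmon resonance). Initial guesses are
#' `Rmax = max(response)` and `KD =` the concentration whose response is
#' nearest half-maximal; both parameters are constrained positive. Responses
#' normalized to the fitted Rmax are reported alongside the fit.
#'
#' @param curve A `binding_curve` data.frame (`concentration`, `response`),
#'   or a numeric vector of concentrations.
#' @param response Responses when `curve` is a plain concentration vector.
#' @return A `one_site_fit` with elements `kd`, `rmax`, `residual_norm`,
#'   `normalized_responses`, `data` and the underlying `nls` fit. Methods:
#'   `print`, `coef`, `predict`, `plot`.
#' @export
fit_one_site <- function(curve, response = NULL) {
  if (is.data.frame(curve)) {
    conc <- curve$concentration
    resp <- curve$response
  } else {
    conc <- curve
    resp <- response
  }
  stopifnot(length(conc) == length(resp), all(conc > 0))
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct analyte concentrations")
  rmax0 <- max(resp)
  kd0 <- conc[which.min(abs(resp - rmax0 / 2))]
  df <- data.frame(conc = conc, resp = resp)
  fit <- tryCatch(
    minpack.lm::nlsLM(resp ~ rmax * conc / (kd + conc), data = df,
                      start = list(rmax = rmax0, kd = kd0),
                      lower = c(rmax = 1e-12, kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("one-site fit failed to converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  structure(list(kd = unname(est["kd"]), rmax = unname(est["rmax"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 normalized_responses = resp / unname(est["rmax"]),
                 data = df, fit = fit),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, digits = 4, ...) {
  cat(sprintf("One-site specific binding fit: KD = %s uM, Rmax = %s RU (residual norm %.3g)\n",
              format(x$kd, digits = digits), format(x$rmax, digits = digits),
              x$residual_norm))
  invisible(x)
}

#' @export
coef.one_site_fit <- function(object, ...) {
  c(kd = object$kd, rmax = object$rmax)
}

#' @param object A `one_site_fit`.
#' @param concentrations Concentrations at which to evaluate the fitted
#'   model (defaults to the fitted data).
#' @rdname fit_one_site
#' @export
predict.one_site_fit <- function(object, concentrations = NULL, ...) {
  if (is.null(concentrations)) concentrations <- object$data$conc
  object$rmax * concentrations / (object$kd + concentrations)
}

#' @export
plot.one_site_fit <- function(x, ...) {
  graphics::plot(x$data$conc, x$data$resp, log = "x",
                 xlab = "analyte concentration (uM)", ylab = "response (RU)",
                 ...)
  cc <- exp(seq(log(min(x$data$conc)), log(max(x$data$conc)), length.out = 200))
  graphics::lines(cc, predict(x, cc))
  graphics::abline(v = x$kd, lty = 2)
  invisible(x)
}

#' Melting temperature from a thermal melt curve
#'
#' `method = "derivative"` (default): the temperature at which the smoothed
#' fluorescence derivative dF/dT is maximal; smoothing is a centred
#' moving average of width `window` (odd). `method = "boltzmann"`: the
#' midpoint of a fitted two-state sigmoid
#' `f_low + (f_high - f_low)/(1 + exp((tm - T)/width))`. A curve without a
#' rising transition is an error.
#'
#' @param melt A `melt_curve` data.frame (`temperature`, `fluorescence`).
#' @param method `"derivative"` or `"boltzmann"`.
#' @param window Moving-average window for the derivative method (odd,
#'   default 5).
#' @return A `tm_fit` list: `tm` (deg C), `method`, `details`.
#' @export
fit_tm <- function(melt, method = c("derivative", "boltzmann"), window = 5) {
  method <- match.arg(method)
  temp <- melt$temperature
  fl <- melt$fluorescence
  stopifnot(length(temp) >= 10, all(diff(temp) > 0))
  if (window %% 2 != 1) stop("window must be odd")
  rng <- diff(range(fl))
  if (rng <= 1e-9 * max(1, abs(median(fl))))
    stop("no melting transition: curve is flat")
  if (method == "derivative") {
    sm <- stats::filter(fl, rep(1 / window, window), sides = 2)
    ok <- !is.na(sm)
    t_ok <- temp[ok]; sm <- as.numeric(sm[ok])
    n <- length(sm)
    if (n < 3) stop("too few points after smoothing")
    # central differences evaluated at the grid points
    dfdt <- (sm[-(1:2)] - sm[seq_len(n - 2)]) /
      (t_ok[-(1:2)] - t_ok[seq_len(n - 2)])
    t_mid <- t_ok[2:(n - 1)]
    if (max(dfdt) <= 0)
      stop("no melting transition: fluorescence never increases")
    tm <- t_mid[which.max(dfdt)]
    details <- list(dfdt = dfdt, t_mid = t_mid)
  } else {
    df <- data.frame(t = temp, f = fl)
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ fl0 + (fh - fl0) / (1 + exp((tm - t) / w)),
                        data = df,
                        start = list(fl0 = min(fl), fh = max(fl),
                                     tm = temp[which.min(abs(fl - mean(range(fl))))],
                                     w = 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("Boltzmann melt fit failed: ",
                               conditionMessage(e)))
    est <- coef(fit)
    if (est[["w"]] <= 0 || est[["fh"]] <= est[["fl0"]])
      stop("no melting transition: fitted sigmoid is not a rising transition")
    tm <- unname(est["tm"])
    details <- as.list(est)
  }
  structure(list(tm = tm, method = method, details = details),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (%s method)\n", x$tm, x$method))
  invisible(x)
}

#' ROUT-style outlier flags for replicate values
#'
#' Univariate (constant-model) version of the ROUT procedure used for
#' intracellular-cytokine-staining replicates: the robust centre is the
#' median; the robust scale (RSDR) is the 68.27th-percentile order statistic
#' of the absolute residuals scaled by `n/(n-1)`; each point's
#' t-statistic (df = n-1) yields a two-sided p-value, and the flag set is
#' chosen by Benjamini-Hochberg at FDR `q_percent`/100 over the ranked
#' residuals. Identical values are never flagged, and flags are invariant to
#' input order.
#'
#' @param values Numeric vector (n >= 3).
#' @param q_percent Maximum desired FDR, in percent (default 1).
#' @return Logical vector of flags.
#' @export
rout_outliers <- function(values, q_percent = 1) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  stopifnot(q_percent > 0)
  res <- values - median(values)
  ares <- sort(abs(res))
  rsdr <- ares[ceiling(0.6827 * n)] * n / (n - 1)
  if (rsdr == 0) return(rep(FALSE, n))
  p <- 2 * pt(abs(res) / rsdr, df = n - 1, lower.tail = FALSE)
  q <- q_percent / 100
  ord <- order(p)
  flag <- rep(FALSE, n)
  k <- which(p[ord] <= q * seq_len(n) / n)
  if (length(k)) flag[ord[seq_len(max(k))]] <- TRUE
  flag
}

#' In vivo specific-killing percentage
#'
#' From ratios of target-pulsed to reference-pulsed dyed donor cells in
#' vaccinated (`exp_ratio`) versus control (`ctrl_ratio`) animals:
#' `100 * (1 - exp_ratio / ctrl_ratio)`, clipped to `[0, 100]` with a
#' `clipped` attribute when clipping occurred.
#'
#' @param exp_ratio,ctrl_ratio Positive ratios of target to reference cell
#'   counts (a vanished target population may be passed as `exp_ratio = 0`).
#' @return Percent specific killing with attribute `clipped`.
#' @export
specific_killing <- function(exp_ratio, ctrl_ratio) {
  if (exp_ratio < 0 || ctrl_ratio <= 0)
    stop("ratios must be positive (exp_ratio may be 0 when no targets remain)")
  raw <- 100 * (1 - exp_ratio / ctrl_ratio)
  out <- min(100, max(0, raw))
  attr(out, "clipped") <- out != raw
  out
}
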