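#' Construct a structural-relaxation map
#'
#' A set of (temperature, relaxation time) points for one sample, as
#' obtained by HN-fitting dielectric spectra across temperature.
#'
#' @param temperature Temperatures in K (distinct).
#' @param tau Relaxation times in s (> 0). Must decrease as temperature
#'   increases.
#' @param sample_label Optional sample name.
#' @return Object of class `relaxation_map`: a data frame `temperature_K`,
#'   `tau_s` sorted by temperature, with the label as an attribute.
#' @export
relaxation_map <- function(temperature, tau, sample_label = "") {
  if (length(temperature) != length(tau))
    stop("temperature and tau must have equal length", call. = FALSE)
  if (anyDuplicated(temperature))
    stop("temperatures must be distinct", call. = FALSE)
  if (any(tau <= 0)) stop("relaxation times must be > 0", call. = FALSE)
  o <- order(temperature)
  temperature <- temperature[o]; tau <- tau[o]
  if (any(diff(tau) >= 0))
    stop("tau must decrease strictly with increasing temperature", call. = FALSE)
  structure(data.frame(temperature_K = temperature, tau_s = tau),
            class = c("relaxation_map", "data.frame"),
            sample_label = sample_label)
}

#' Vogel-Fulcher-Tammann parameter set
#'
#' Natural-log convention \eqn{\tau(T) = \tau_\infty \exp[B/(T - T_0)]},
#' with B in K (B = D T0, D the strength parameter) and the pre-exponential
#' reported as log10(tau_inf / s). This convention reproduces the derived
#' quantities (kinetic Tg, fragility, isochronal temperatures) of standard
#' broadband-dielectric analyses.
#'
#' @param log10_tau_inf log10 of the pre-exponential time in seconds.
#' @param B Activation strength, K (> 0).
#' @param T0_vogel Vogel temperature, K (> 0).
#' @param valid_range Optional `c(Tmin, Tmax)` K over which the fit holds.
#' @return Object of class `vft_parameters`.
#' @export
vft_parameters <- function(log10_tau_inf, B, T0_vogel, valid_range = NULL) {
  if (!is.finite(B) || B <= 0) stop("B must be > 0", call. = FALSE)
  if (!is.finite(T0_vogel) || T0_vogel <= 0)
    stop("T0_vogel must be > 0", call. = FALSE)
  if (!is.null(valid_range) && T0_vogel >= valid_range[1])
    stop("T0_vogel must lie below the valid temperature range", call. = FALSE)
  structure(list(log10_tau_inf = log10_tau_inf, B = B, T0_vogel = T0_vogel,
                 valid_range = valid_range),
            class = "vft_parameters")
}

#' Evaluate the VFT law
#'
#' @param T Temperatures in K (> T0).
#' @param p A [vft_parameters()].
#' @return Relaxation times in s.
#' @export
vft_tau <- function(T, p) {
  if (any(T <= p$T0_vogel))
    stop("T must exceed the Vogel temperature", call. = FALSE)
  10^p$log10_tau_inf * exp(p$B / (T - p$T0_vogel))
}

#' Fit the VFT equation to a relaxation map
#'
#' Least squares of \eqn{\log_{10}\tau = \log_{10}\tau_\infty +
#' B / [\ln 10\,(T - T_0)]} by Levenberg-Marquardt. Starting values come
#' from the Stickel linearisation (a straight-line fit of
#' \eqn{[-d\log_{10}\tau/dT]^{-1/2}} against T yields B and T0 directly),
#' which makes convergence essentially immediate for VFT-like data.
#'
#' @param map A [relaxation_map()] (or data frame with `temperature_K`,
#'   `tau_s`).
#' @param range Optional `c(Tmin, Tmax)` restricting the fit window, K.
#' @return A [vft_parameters()] with attributes `std_errors` (named vector),
#'   `residual_norm` (RMS of log10 tau residuals) and `n_points`.
#' @export
fit_vft <- function(map, range = NULL) {
  d <- as.data.frame(map)
  if (!is.null(range))
    d <- d[d$temperature_K >= range[1] & d$temperature_K <= range[2], ]
  if (nrow(d) < 5) stop("need at least 5 points to fit VFT", call. = FALSE)
  Tv <- d$temperature_K; y <- log10(d$tau_s)
  # Stickel-based initialisation
  init <- tryCatch({
    st <- stickel_transform(relaxation_map(Tv, d$tau_s))
    cf <- stats::coef(stats::lm(phi ~ temperature_K, data = st$points))
    s <- cf[2]; T0i <- -cf[1] / cf[2]
    Bi <- log(10) / s^2
    if (!is.finite(Bi) || Bi <= 0 || T0i <= 0 || T0i >= min(Tv)) stop("bad")
    lt <- mean(y - Bi / (log(10) * (Tv - T0i)))
    unname(c(lt, Bi, T0i))
  }, error = function(e) c(-12, 1500, max(min(Tv) - 50, 1)))
  lower <- c(-30, 1, 1)
  upper <- c(0, 1e5, min(Tv) - 1)
  init[3] <- min(max(init[3], lower[3]), upper[3] - 1)
  fit <- minpack.lm::nls.lm(
    par = init, lower = lower, upper = upper,
    fn = function(v) v[1] + v[2] / (log(10) * (Tv - v[3])) - y,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit$info %in% 1:4)
    stop("VFT fit did not converge: ", fit$message, call. = FALSE)
  v <- fit$par
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  names(se) <- c("log10_tau_inf", "B", "T0_vogel")
  out <- vft_parameters(v[1], v[2], v[3], valid_range = range(Tv))
  attr(out, "std_errors") <- se
  attr(out, "residual_norm") <- sqrt(mean(fit$fvec^2))
  attr(out, "n_points") <- length(Tv)
  out
}

#' Stickel derivative transform of a relaxation map
#'
#' Computes \eqn{\phi(T) = [-d\log_{10}\tau_\alpha/dT]^{-1/2}} by central
#' differences on neighbouring raw points (no smoothing by default). For
#' exact VFT data the identity
#' \eqn{[d\log\tau/dT]^{-1/2} = (T - T_0) B^{-1/2}} makes \eqn{\phi} a
#' straight line in T, so curvature or a slope break in \eqn{\phi} exposes a
#' change of dynamic regime that the raw map hides. Points with
#' non-negative derivative (noise artefacts) are dropped with a warning.
#'
#' @param map A [relaxation_map()].
#' @param sg_smooth If TRUE, Savitzky-Golay pre-smoothing (window 5, degree
#'   2, via [pracma::savgol()]) is applied to log10 tau before
#'   differentiation.
#' @return List of class `stickel_result`: `points` (data frame
#'   `temperature_K`, `phi`), `n_dropped`.
#' @export
stickel_transform <- function(map, sg_smooth = FALSE) {
  d <- as.data.frame(map)
  if (nrow(d) < 4) stop("need at least 4 points", call. = FALSE)
  Tv <- d$temperature_K; y <- log10(d$tau_s)
  if (sg_smooth && length(y) >= 5) y <- pracma::savgol(y, 5, forder = 2)
  n <- length(y)
  i <- 2:(n - 1)
  deriv <- (y[i + 1] - y[i - 1]) / (Tv[i + 1] - Tv[i - 1])
  keep <- deriv < 0
  if (any(!keep))
    warning(sum(!keep), " point(s) with non-negative derivative dropped")
  if (sum(keep) < 3)
    stop("fewer than 3 usable derivative points", call. = FALSE)
  structure(list(points = data.frame(temperature_K = Tv[i][keep],
                                     phi = (-deriv[keep])^(-0.5)),
                 n_dropped = sum(!keep)),
            class = "stickel_result")
}

#' Detect a dynamic crossover in a Stickel transform
#'
#' Fits every admissible two-segment piecewise-linear model (each segment
#' >= 3 points) to \eqn{\phi(T)} and keeps the breakpoint minimising the
#' total squared residual. The two-line model is accepted only when it
#' improves on the single straight line by an F-ratio above `f_threshold`
#' (variance-ratio test with 2 extra parameters); otherwise the sample is
#' single-VFT and `NA` is returned. The reported crossover temperature is
#' the intersection of the two fitted lines.
#'
#' @param sr A `stickel_result` from [stickel_transform()], with >= 6 points.
#' @param f_threshold Acceptance F-ratio (default 4).
#' @param min_slope_contrast Minimum relative difference between the two
#'   segment slopes (default 0.05): a breakpoint whose segments have
#'   indistinguishable slopes is not a physical regime change (it is what
#'   finite-difference discretisation error looks like on a smooth map).
#' @return List: `T_cross` (K, or `NA_real_` for single-VFT behaviour),
#'   `f_ratio`, `segments` (two-row data frame of slopes/intercepts, or NULL).
#' @export
detect_crossover <- function(sr, f_threshold = 4, min_slope_contrast = 0.05) {
  stopifnot(inherits(sr, "stickel_result"))
  pts <- sr$points
  n <- nrow(pts)
  if (n < 6) stop("need at least 6 transform points", call. = FALSE)
  Tv <- pts$temperature_K; phi <- pts$phi
  sse_line <- function(idx) {
    f <- stats::lm.fit(cbind(1, Tv[idx]), phi[idx])
    sum(f$residuals^2)
  }
  sse1 <- sse_line(seq_len(n))
  # a single line already at numerical precision: collinear, no crossover
  if (sse1 <= n * (1e-7 * mean(abs(phi)))^2)
    return(list(T_cross = NA_real_, f_ratio = 0, segments = NULL))
  best <- list(sse = Inf, k = NA_integer_)
  for (k in 3:(n - 3)) {
    s <- sse_line(1:k) + sse_line((k + 1):n)
    if (s < best$sse) best <- list(sse = s, k = k)
  }
  # F-test: 2 extra parameters for the second segment
  df2 <- n - 4
  f_ratio <- if (best$sse <= 0) Inf else
    ((sse1 - best$sse) / 2) / (best$sse / df2)
  if (!is.finite(f_ratio) && best$sse == 0 && sse1 == 0) f_ratio <- 0
  if (is.na(f_ratio) || f_ratio <= f_threshold)
    return(list(T_cross = NA_real_, f_ratio = f_ratio, segments = NULL))
  k <- best$k
  c1 <- stats::coef(stats::lm(phi[1:k] ~ Tv[1:k]))
  c2 <- stats::coef(stats::lm(phi[(k + 1):n] ~ Tv[(k + 1):n]))
  contrast <- abs(c1[2] - c2[2]) / max(abs(c1[2]), abs(c2[2]))
  if (!is.finite(contrast) || contrast < min_slope_contrast)
    return(list(T_cross = NA_real_, f_ratio = f_ratio, segments = NULL))
  T_cross <- (c2[1] - c1[1]) / (c1[2] - c2[2])
  segs <- data.frame(segment = c("low-T", "high-T"),
                     intercept = c(c1[1], c2[1]),
                     slope = c(c1[2], c2[2]),
                     T_min = c(Tv[1], Tv[k + 1]),
                     T_max = c(Tv[k], Tv[n]))
  list(T_cross = unname(T_cross), f_ratio = f_ratio, segments = segs)
}

#' Construct the high-temperature VFT regime joining a low-temperature one
#'
#' Builds the second VFT law of a two-regime (crossover) relaxation map so
#' that both the relaxation time and its temperature derivative are
#' continuous at `T_cross`. In the Stickel representation each regime is a
#' straight line; matching value and slope of \eqn{\tau(T)} at `T_cross`
#' makes the two lines intersect exactly there, which is how the crossover
#' temperature is defined and read off experimentally. Given the second
#' regime's activation strength `B2`, continuity fixes its Vogel
#' temperature, \eqn{T_{0,2} = T_{cross} - \sqrt{B_2/B_1}(T_{cross} -
#' T_{0,1})}, and its pre-exponential.
#'
#' @param vft1 Low-temperature [vft_parameters()].
#' @param T_cross Crossover temperature, K (> T0 of `vft1`).
#' @param B2 Activation strength of the high-temperature regime, K. Must
#'   differ from `vft1$B` for a detectable slope break.
#' @return A [vft_parameters()] for the high-temperature regime.
#' @export
vft_second_regime <- function(vft1, T_cross, B2) {
  stopifnot(inherits(vft1, "vft_parameters"))
  if (T_cross <= vft1$T0_vogel)
    stop("T_cross must exceed the Vogel temperature of vft1", call. = FALSE)
  T02 <- T_cross - sqrt(B2 / vft1$B) * (T_cross - vft1$T0_vogel)
  log10_tau_cross <- vft1$log10_tau_inf +
    vft1$B / (log(10) * (T_cross - vft1$T0_vogel))
  lt2 <- log10_tau_cross - B2 / (log(10) * (T_cross - T02))
  vft_parameters(lt2, B2, T02)
}

#' Temperature grid spanning a prescribed relaxation-time window
#'
#' Inverts a VFT law at log-spaced relaxation times so that every
#' generated spectrum has its loss peak inside a given frequency window.
#' The defaults place \eqn{\tau_\alpha} between 0.03 s and 3e-7 s, well
#' inside a 1e-1 to 1e7 Hz measurement range.
#'
#' @param p A [vft_parameters()].
#' @param log10_tau_range `c(hi, lo)` log10 relaxation times, s.
#' @param n Number of temperatures.
#' @return Increasing temperature vector, K.
#' @export
bds_temperature_grid <- function(p, log10_tau_range = c(-1.5, -6.5), n = 11) {
  taus <- 10^seq(log10_tau_range[1], log10_tau_range[2], length.out = n)
  sort(vapply(taus, function(tt) kinetic_tg(p, tau_ref = tt), 0))
}

#' Kinetic glass-transition temperature from VFT parameters
#'
#' Inverts the VFT law at a reference relaxation time: the kinetic Tg is
#' conventionally the temperature at which \eqn{\tau_\alpha} reaches 100 s,
#' \deqn{T_g = T_0 + \frac{B}{\ln(\tau_{ref}/\tau_\infty)}.}
#'
#' @param p A [vft_parameters()].
#' @param tau_ref Reference time in s (default 100).
#' @return Temperature in K.
#' @examples
#' p <- vft_parameters(-15.68, 2386, 244.0)
#' kinetic_tg(p)            # ~303 K
#' @export
kinetic_tg <- function(p, tau_ref = 100) {
  tau_inf <- 10^p$log10_tau_inf
  if (tau_ref <= tau_inf)
    stop("tau_ref must exceed the pre-exponential time", call. = FALSE)
  p$T0_vogel + p$B / log(tau_ref / tau_inf)
}

#' Isochronal temperature for a target relaxation time
#'
#' Temperature at which the sample's structural relaxation time equals
#' `tau_target` — the condition used to compare the crystallization
#' tendency of different samples at equal molecular mobility. Same closed
#' form as [kinetic_tg()]; the default 0.63 microseconds corresponds to a
#' loss peak near 2.5e5 Hz.
#'
#' @param p A [vft_parameters()].
#' @param tau_target Target relaxation time in s (default 0.63e-6).
#' @return Temperature in K.
#' @export
isochronal_temperature <- function(p, tau_target = 0.63e-6) {
  kinetic_tg(p, tau_ref = tau_target)
}

#' Fragility (steepness index)
#'
#' \deqn{m_p = \left.\frac{d\log_{10}\tau}{d(T_g/T)}\right|_{T=T_g}
#'       = \frac{B\,T_g}{\ln 10\,(T_g - T_0)^2}}
#' evaluated at the kinetic Tg (tau = 100 s) by default. Values near 16
#' indicate strong (Arrhenius-like) liquids; typical fragile
#' pharmaceutical glass-formers sit near 70-150.
#'
#' @param p A [vft_parameters()].
#' @param tg Glass-transition temperature in K; default [kinetic_tg()] of
#'   `p`.
#' @return Dimensionless steepness index.
#' @export
fragility <- function(p, tg = kinetic_tg(p)) {
  if (tg <= p$T0_vogel)
    stop("tg must exceed the Vogel temperature", call. = FALSE)
  p$B * tg / (log(10) * (tg - p$T0_vogel)^2)
}

#' Dynamics summary row for one sample
#'
#' Convenience wrapper computing the derived dynamic quantities from one
#' VFT parameter set: kinetic Tg, fragility, and the isochronal temperature.
#'
#' @param p A [vft_parameters()].
#' @param sample Sample label.
#' @param tau_iso Isochrone, s (default 0.63e-6).
#' @return One-row data frame `sample`, `Tg_BDS_K`, `m_p`, `log10_tau_inf`,
#'   `B_K`, `T0_K`, `T_iso_K`.
#' @export
dynamics_summary <- function(p, sample = "", tau_iso = 0.63e-6) {
  tg <- kinetic_tg(p)
  data.frame(sample = sample,
             Tg_BDS_K = tg,
             m_p = fragility(p, tg),
             log10_tau_inf = p$log10_tau_inf,
             B_K = p$B,
             T0_K = p$T0_vogel,
             T_iso_K = isochronal_temperature(p, tau_iso))
}

#' VFT parameter presets for the ezetimibe/simvastatin/fenofibrate study set
#'
#' Reference VFT-fit parameters (low-temperature regime) for neat amorphous
#' ezetimibe (EZB), simvastatin (SVT) and fenofibrate (FEN) and their
#' ternary amorphous mixtures at the listed EZB/SVT/FEN mass ratios, as
#' reported from broadband dielectric experiments. These ship as generator
#' presets and reference inputs for round-trip tests.
#'
#' Two rows carry documented internal inconsistencies in the source data
#' and are excluded from quantitative checks (`derived_ok = FALSE`): the
#' neat-EZB row (its printed derived quantities are not reproduced by
#' inverting its printed VFT parameters) and the 10/40/50 row (its printed
#' Vogel temperature 277.7 K exceeds its printed Tg of 271 K, which is
#' physically impossible — likely a transcription of 227.7 K).
#'
#' @return Data frame: `sample`, `log10_tau_inf`, `B_K`, `T0_K`,
#'   `T_cross_K` (NA for single-VFT samples), `derived_ok`.
#' @export
vft_presets <- function() {
  data.frame(
    sample = c("EZB", "SVT", "FEN", "70/10/20", "40/40/20", "10/70/20",
               "30/30/40", "40/10/50", "10/40/50", "10/20/70",
               "5.3/10.5/84.2"),
    log10_tau_inf = c(-11.81, -15.68, -13.52, -12.51, -12.93, -13.78,
                      -12.75, -12.79, -13.18, -12.57, -12.55),
    B_K = c(1130, 2386, 1465, 1483, 1576, 1769, 1514, 1564, 1553, 1346, 1280),
    T0_K = c(301.1, 244.0, 209.3, 266.5, 256.4, 242.4, 240.1, 237.1, 277.7,
             223.1, 219.0),
    T_cross_K = c(355, NA, NA, 395, 382, 368, 355, 361, 344, NA, NA),
    derived_ok = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                   TRUE, TRUE))
}
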