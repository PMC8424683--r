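#' Construct a DSC thermogram
#'
#' Temperature-indexed heat-flow trace. The internal canonical sign
#' convention is endo-up: endothermic events (melting) appear as positive
#' peaks. Instruments using the endo-down convention are handled by
#' `endo_direction = "down"`, which flips the signal on input.
#'
#' @param temperature Strictly increasing numeric vector, K (length >= 50).
#' @param heat_flow Heat-flow signal, same length (arbitrary units; W/g if
#'   mass-normalised by the instrument).
#' @param heating_rate Heating rate in K/min.
#' @param sample_mass Optional sample mass in mg (for enthalpy
#'   normalisation).
#' @param endo_direction `"up"` (default) or `"down"`: the direction in which
#'   endotherms point in `heat_flow`.
#' @return Object of class `thermogram`.
#' @export
thermogram <- function(temperature, heat_flow, heating_rate,
                       sample_mass = NULL, endo_direction = c("up", "down")) {
  endo_direction <- match.arg(endo_direction)
  if (length(temperature) != length(heat_flow))
    stop("temperature and heat_flow must have equal length", call. = FALSE)
  if (length(temperature) < 50)
    stop("thermogram needs at least 50 points", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperature must be strictly increasing", call. = FALSE)
  if (!is.finite(heating_rate) || heating_rate <= 0)
    stop("heating_rate must be positive (K/min)", call. = FALSE)
  if (endo_direction == "down") heat_flow <- -heat_flow
  structure(list(temperature = temperature, heat_flow = heat_flow,
                 heating_rate = heating_rate, sample_mass = sample_mass),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d points, %.1f-%.1f K, rate %.1f K/min\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              x$heating_rate))
  invisible(x)
}

#' Read / write a thermogram CSV
#'
#' Two-column CSV (`temperature_K, heat_flow`) with `# key: value` header
#' comment lines carrying the heating rate and optional sample mass.
#'
#' @param file Path.
#' @param tg A `thermogram` (for writing).
#' @return `read_thermogram` returns a [thermogram()].
#' @export
read_thermogram <- function(file) {
  hdr <- readLines(file, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list(heating_rate = NA_real_, sample_mass = NULL)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":")[[1]]
    if (length(kv) == 2) {
      key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
      if (key == "heating_rate_K_min") meta$heating_rate <- val
      if (key == "sample_mass_mg") meta$sample_mass <- val
    }
  }
  if (!is.finite(meta$heating_rate))
    stop("thermogram file missing '# heating_rate_K_min:' header", call. = FALSE)
  d <- utils::read.csv(file, comment.char = "#")
  thermogram(d$temperature_K, d$heat_flow, meta$heating_rate, meta$sample_mass)
}

#' @rdname read_thermogram
#' @export
write_thermogram <- function(tg, file) {
  stopifnot(inherits(tg, "thermogram"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# heating_rate_K_min: %g", tg$heating_rate), con)
  if (!is.null(tg$sample_mass))
    writeLines(sprintf("# sample_mass_mg: %g", tg$sample_mass), con)
  utils::write.csv(data.frame(temperature_K = tg$temperature,
                              heat_flow = tg$heat_flow),
                   con, row.names = FALSE)
  invisible(file)
}

# rolling-median detrend used to estimate the noise floor for the
# prominence default
detrended_mad <- function(y, k = 31L) {
  k <- min(k, length(y) - (1 - length(y) %% 2))
  base <- stats::runmed(y, k)
  stats::mad(y - base)
}

#' Detect melting endotherms in a thermogram
#'
#' Peaks are located by local-extremum search with a prominence filter
#' (default threshold: 5 times the median absolute deviation of the
#' detrended trace, a noise-adaptive choice). For each peak the onset is the
#' intersection of the pre-peak baseline tangent with the steepest-slope
#' tangent on the leading edge — the standard DSC extrapolated-onset
#' construction — and the enthalpy is the trapezoidal area above a linear
#' baseline spanning the peak bounds, converted from the temperature axis to
#' time via the heating rate and normalised by sample mass when available.
#'
#' @param tg A [thermogram()].
#' @param prominence_threshold Minimum peak prominence in signal units;
#'   `NULL` (default) uses the noise-adaptive rule.
#' @return Data frame with one row per endotherm (ordered by temperature):
#'   `onset_K`, `peak_K`, `height`, `prominence`, `enthalpy` (signal.K/min,
#'   or J/g when the signal is W/g and mass given). Zero rows when no peak
#'   clears the threshold.
#' @export
detect_endotherms <- function(tg, prominence_threshold = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  y <- tg$heat_flow; Tv <- tg$temperature
  n <- length(y)
  empty <- data.frame(onset_K = numeric(0), peak_K = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      enthalpy = numeric(0))
  # baseline: wide running median (window well beyond typical peak widths)
  kb <- min(n - (1 - n %% 2), 2L * (n %/% 8L) + 1L)
  kb <- max(kb, 3L)
  baseline <- stats::runmed(y, kb)
  detr <- y - baseline
  if (is.null(prominence_threshold))
    prominence_threshold <- 5 * detrended_mad(y)
  if (prominence_threshold <= 0) prominence_threshold <- 1e-12
  # light smoothing so run-based peak finding and tangents resist noise
  ys <- as.numeric(stats::filter(detr, rep(1 / 7, 7), sides = 2))
  ys[is.na(ys)] <- detr[is.na(ys)]
  pk <- pracma::findpeaks(ys, zero = "+",
                          minpeakheight = prominence_threshold,
                          minpeakdistance = max(5L, n %/% 100L))
  if (is.null(pk)) return(empty)
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  out <- lapply(seq_len(nrow(pk)), function(r) {
    ip <- pk[r, 2]
    # peak bounds: walk out until the detrended signal decays to 2% of the
    # peak height (or the noise floor)
    floor_lvl <- max(0.02 * ys[ip], prominence_threshold / 5)
    ilo <- ip
    while (ilo > 1 && ys[ilo - 1] > floor_lvl && ys[ilo - 1] < ys[ilo] * 1.5)
      ilo <- ilo - 1
    ihi <- ip
    while (ihi < n && ys[ihi + 1] > floor_lvl && ys[ihi + 1] < ys[ihi] * 1.5)
      ihi <- ihi + 1
    # linear baseline between the peak bounds, on the raw signal
    base <- function(idx) {
      y[ilo] + (y[ihi] - y[ilo]) * (Tv[idx] - Tv[ilo]) / (Tv[ihi] - Tv[ilo])
    }
    seg <- ilo:ihi
    above <- pmax(y[seg] - base(seg), 0)
    area_TK <- pracma::trapz(Tv[seg], above)          # signal * K
    enth <- area_TK / (tg$heating_rate / 60)          # signal * s = J/g if W/g
    if (!is.null(tg$sample_mass)) enth <- enth / tg$sample_mass  # mW -> J/g
    # extrapolated onset: steepest leading-edge tangent vs pre-peak baseline
    lead <- ilo:ip
    onset <- Tv[ilo]
    if (length(lead) >= 4) {
      ysm <- ys[lead] + baseline[lead]
      slopes <- diff(ysm) / diff(Tv[lead])
      im <- which.max(slopes)
      s <- slopes[im]
      Tm <- (Tv[lead[im]] + Tv[lead[im + 1]]) / 2
      ym <- (ysm[im] + ysm[im + 1]) / 2
      yb <- base(ilo)
      if (is.finite(s) && s > 0) onset <- Tm - (ym - yb) / s
      onset <- min(max(onset, Tv[ilo]), Tv[ip])
    }
    data.frame(onset_K = onset, peak_K = Tv[ip],
               height = y[ip] - base(ip),
               prominence = ys[ip],
               enthalpy = enth)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Glass-transition temperature as the heat-capacity-step midpoint
#'
#' Fits linear baselines to the glassy (pre-step) and liquid (post-step)
#' portions of the trace and returns the temperature at which the signal
#' crosses halfway between them — the midpoint of the heat-capacity
#' increment. Robust to a superposed enthalpy-overshoot bump because the
#' crossing is taken on the rising edge (first crossing).
#'
#' @param tg A [thermogram()].
#' @param pre_window,post_window Temperature intervals `c(lo, hi)` (K) over
#'   which to fit the glassy / liquid baselines. Defaults: first and last 20%
#'   of the scanned range.
#' @param min_step Minimum step height, in units of the residual noise MAD,
#'   for a transition to count as detected (default 5).
#' @return Midpoint temperature in K.
#' @export
glass_transition_midpoint <- function(tg, pre_window = NULL, post_window = NULL,
                                      min_step = 5) {
  stopifnot(inherits(tg, "thermogram"))
  Tv <- tg$temperature; y <- tg$heat_flow
  rng <- range(Tv)
  if (is.null(pre_window)) pre_window <- c(rng[1], rng[1] + 0.2 * diff(rng))
  if (is.null(post_window)) post_window <- c(rng[2] - 0.2 * diff(rng), rng[2])
  pre <- Tv >= pre_window[1] & Tv <= pre_window[2]
  post <- Tv >= post_window[1] & Tv <= post_window[2]
  if (sum(pre) < 5 || sum(post) < 5)
    stop("baseline windows contain too few points", call. = FALSE)
  fit_pre <- stats::lm(y[pre] ~ Tv[pre])
  fit_post <- stats::lm(y[post] ~ Tv[post])
  b_pre <- function(T) stats::coef(fit_pre)[1] + stats::coef(fit_pre)[2] * T
  b_post <- function(T) stats::coef(fit_post)[1] + stats::coef(fit_post)[2] * T
  mid <- (b_pre(Tv) + b_post(Tv)) / 2
  step_h <- abs(mean(b_post(Tv[post]) - b_pre(Tv[post])))
  noise <- stats::mad(stats::residuals(fit_pre))
  if (noise > 0 && step_h < min_step * noise)
    stop("no detectable heat-capacity step", call. = FALSE)
  d <- y - mid
  cross <- which(d[-1] * d[-length(d)] < 0 |
                   (d[-length(d)] == 0 & d[-1] != 0))
  # ignore crossings inside the baseline windows themselves
  cross <- cross[Tv[cross] > pre_window[2] & Tv[cross + 1] < post_window[1]]
  if (length(cross) == 0)
    stop("no detectable heat-capacity step", call. = FALSE)
  i <- cross[1]
  Tv[i] + (0 - d[i]) * (Tv[i + 1] - Tv[i]) / (d[i + 1] - d[i])
}

#' Solidus and liquidus temperatures from detected endotherms
#'
#' Mixture convention: the solidus is the extrapolated onset of the first
#' (eutectic) endotherm; the liquidus is the peak-maximum temperature of the
#' last endotherm. A single-event thermogram (melting at the eutectic
#' composition, or a neat substance) returns equal values and is flagged
#' eutectic-like.
#'
#' @param events Data frame from [detect_endotherms()] with >= 1 row.
#' @return List with `solidus_K`, `liquidus_K`, `eutectic_like` (logical),
#'   `n_events`.
#' @export
solidus_liquidus <- function(events) {
  if (!is.data.frame(events) || nrow(events) < 1)
    stop("need at least one endotherm", call. = FALSE)
  events <- events[order(events$peak_K), , drop = FALSE]
  n <- nrow(events)
  if (n == 1L) {
    list(solidus_K = events$onset_K[1], liquidus_K = events$onset_K[1],
         eutectic_like = TRUE, n_events = 1L)
  } else {
    list(solidus_K = events$onset_K[1], liquidus_K = events$peak_K[n],
         eutectic_like = FALSE, n_events = n)
  }
}
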