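#' Generator configuration
#'
#' Shared configuration for the synthetic-data generators. A fixed seed
#' makes every generator fully deterministic: identical config gives
#' bit-identical output.
#'
#' @param seed Integer random seed.
#' @param noise_model One of `"none"`, `"gaussian-additive"`,
#'   `"multiplicative"`.
#' @param noise_scale Relative noise amplitude (fraction of signal scale).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, noise_model = c("none",
                                                        "gaussian-additive",
                                                        "multiplicative"),
                             noise_scale = 0.01) {
  noise_model <- match.arg(noise_model)
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 noise_scale = noise_scale),
            class = "generator_config")
}

apply_noise <- function(y, cfg, scale = stats::sd(y)) {
  switch(cfg$noise_model,
         "none" = y,
         "gaussian-additive" = y + stats::rnorm(length(y), 0,
                                                cfg$noise_scale * scale),
         "multiplicative" = y * (1 + stats::rnorm(length(y), 0,
                                                  cfg$noise_scale)))
}

# asymmetric Gaussian melting peak; leading-edge width sigma_l fixes the
# extrapolated onset analytically at peak - 2*sigma_l (tangent construction
# on a Gaussian flank intersects the baseline two sigma below the maximum)
melt_peak <- function(T, peak_K, height, sigma_l, sigma_r = sigma_l / 2) {
  s <- ifelse(T <= peak_K, sigma_l, sigma_r)
  height * exp(-(T - peak_K)^2 / (2 * s^2))
}

#' Generate a synthetic DSC thermogram with known ground truth
#'
#' Builds a heating trace as: sloped baseline + glass-transition sigmoid
#' step + one asymmetric Gaussian endotherm per expected melting event. The
#' mixture Tg follows a Gordon-Taylor mixing rule with unit interaction
#' parameter (a mass-fraction-weighted mean of component Tg values) — a
#' modelling convenience for generating plausible traces, not a claim about
#' the real mixtures. Event temperatures come from the system's ideal phase
#' diagram: the eutectic melting at `T_e` plus one dissolution endotherm per
#' component whose liquidus branch sits resolvably above `T_e`, with areas
#' proportional to melting fractions. Peak positions shift upward with
#' heating rate by `rate_lag_K_per_Kmin` (thermal-lag emulation).
#'
#' @param components List of 2 or 3 [pure_component()] objects.
#' @param x Mole-fraction vector matching `components`.
#' @param rate Heating rate, K/min (default 10).
#' @param cfg A [generator_config()].
#' @param component_tg Component glass-transition temperatures, K, used for
#'   the Tg step (default none: no step for fully crystalline samples).
#' @param T_range Temperature window, K; default covers Tg - 40 K (if any)
#'   or `T_e` - 60 K up to the hottest event + 30 K.
#' @param dT Sampling step, K (default 0.1).
#' @param peak_sigma_K Leading-edge width of melt peaks (default 1.5 K).
#' @param rate_lag_K_per_Kmin Peak shift per K/min of rate (default 0.15).
#' @return A [thermogram()] with attribute `ground_truth`: list with
#'   `events` (data frame `peak_K`, `onset_K`, `area`), `tg_K` (or NA),
#'   `T_e_K`, `n_events`.
#' @export
make_dsc <- function(components, x, rate = 10, cfg = generator_config(),
                     component_tg = NULL, T_range = NULL, dT = 0.1,
                     peak_sigma_K = 1.5, rate_lag_K_per_Kmin = 0.15) {
  stopifnot(length(x) == length(components))
  set.seed(cfg$seed)
  eut <- if (length(x) == 2L)
    binary_eutectic(components[[1]], components[[2]])
  else ternary_eutectic(components[[1]], components[[2]], components[[3]],
                        surface = FALSE)
  T_e <- eut$T_e
  lag <- rate_lag_K_per_Kmin * rate
  # events: eutectic melting + per-component dissolution up to the liquidus
  branch_T <- vapply(seq_along(x), function(i)
    if (x[i] > 0) svl_liquidus(x[i], components[[i]]) else -Inf, 0)
  above <- which(branch_T > T_e + 1)
  peaks <- c(T_e, branch_T[above]) + lag
  # melting fractions: eutectic fraction vs material crystallising on each branch
  areas <- c(60, 40 * x[above] / max(sum(x[above]), 1e-9))
  areas <- areas[seq_along(peaks)]
  tg_K <- NA_real_
  if (!is.null(component_tg)) {
    w <- mole_to_weight(x, vapply(components, `[[`, 0, "molar_mass"))
    tg_K <- sum(w * component_tg) / sum(w)   # Gordon-Taylor, unit k
  }
  if (is.null(T_range)) {
    lo <- if (is.finite(tg_K)) tg_K - 40 else T_e - 60
    T_range <- c(lo, max(peaks) + 30)
  }
  Tv <- seq(T_range[1], T_range[2], by = dT)
  y <- 0.02 + 1e-4 * (Tv - Tv[1])            # gently sloped baseline
  if (is.finite(tg_K))
    y <- y + 0.15 / (1 + exp(-(Tv - tg_K) / 1.2))  # cp step, height 0.15
  sig <- rep(peak_sigma_K, length(peaks))
  # asymmetric peak (right flank sigma/2): true area = h * (3/4) sig sqrt(2 pi)
  height <- areas / (0.75 * sig * sqrt(2 * pi))
  for (j in seq_along(peaks))
    y <- y + melt_peak(Tv, peaks[j], height[j], sig[j])
  y <- apply_noise(y, cfg, scale = diff(range(y)))
  tg <- thermogram(Tv, y, heating_rate = rate)
  ev <- data.frame(peak_K = peaks, onset_K = peaks - 2 * sig, area = areas)
  ev <- ev[order(ev$peak_K), , drop = FALSE]
  rownames(ev) <- NULL
  attr(tg, "ground_truth") <- list(
    events = ev, tg_K = tg_K, T_e_K = T_e, n_events = length(peaks))
  tg
}

#' Generate a temperature series of synthetic HN dielectric spectra
#'
#' For each temperature the target structural relaxation time is prescribed
#' by a VFT law (one regime, or two regimes joined at `T_cross` with the
#' high-temperature law applying above it); the HN time constant is then
#' back-computed so that the loss-peak conversion returns exactly the
#' prescribed \eqn{\tau_\alpha}. Conductivity follows an activated
#' (Arrhenius) law. Multiplicative noise per the config (applied to both
#' components).
#'
#' @param vft A [vft_parameters()] for the (low-temperature) regime.
#' @param T_grid Temperatures, K.
#' @param cfg A [generator_config()].
#' @param shape List with HN shape `a`, `b`, `delta_eps`, `eps_inf`
#'   (defaults a=0.8, b=0.6, delta_eps=6, eps_inf=3).
#' @param vft2 Optional second [vft_parameters()] for T > `T_cross`.
#' @param T_cross Crossover temperature, K (required with `vft2`).
#' @param freq_decades Log10 frequency range (default c(-1, 7)).
#' @param points_per_decade Default 10.
#' @param sigma0,E_sigma_K Conductivity prefactor (S/m) and activation
#'   temperature (K) for `sigma = sigma0 * exp(-E_sigma_K / T)`; defaults
#'   give a small low-frequency upturn.
#' @return List of [dielectric_spectrum()] objects with attribute
#'   `ground_truth`: data frame `temperature_K`, `tau_alpha_s`, `tau_hn_s`,
#'   plus the shape parameters and the generating VFT law(s).
#' @export
make_bds_series <- function(vft, T_grid, cfg = generator_config(),
                            shape = list(), vft2 = NULL, T_cross = NULL,
                            freq_decades = c(-1, 7), points_per_decade = 10,
                            sigma0 = 1e-6, E_sigma_K = 4000) {
  set.seed(cfg$seed)
  sh <- utils::modifyList(list(a = 0.8, b = 0.6, delta_eps = 6, eps_inf = 3),
                          shape)
  if (!is.null(vft2) && is.null(T_cross))
    stop("T_cross required when a second VFT regime is given", call. = FALSE)
  f <- 10^seq(freq_decades[1], freq_decades[2],
              by = 1 / points_per_decade)
  gt <- data.frame(temperature_K = T_grid, tau_alpha_s = NA_real_,
                   tau_hn_s = NA_real_)
  specs <- vector("list", length(T_grid))
  for (i in seq_along(T_grid)) {
    Tk <- T_grid[i]
    law <- if (!is.null(vft2) && Tk > T_cross) vft2 else vft
    tau_a <- vft_tau(Tk, law)
    tau_hn <- tau_hn_from_alpha(tau_a, sh$a, sh$b)
    p <- hn_parameters(sh$eps_inf, sh$delta_eps, tau_hn, sh$a, sh$b,
                       sigma_dc = sigma0 * exp(-E_sigma_K / Tk))
    m <- hn_model(f, p)
    er <- apply_noise(m$eps_real, cfg, scale = sh$delta_eps)
    ei <- apply_noise(m$eps_imag, cfg, scale = max(m$eps_imag))
    specs[[i]] <- dielectric_spectrum(f, er, pmax(ei, 1e-12), Tk)
    gt$tau_alpha_s[i] <- tau_a
    gt$tau_hn_s[i] <- tau_hn
  }
  attr(specs, "ground_truth") <- c(list(map = gt, vft = vft, vft2 = vft2,
                                        T_cross = T_cross), sh)
  specs
}

#' Generate a synthetic isothermal crystallization series
#'
#' Avrami-type decay of the static permittivity,
#' \deqn{\varepsilon'(t) = \varepsilon'_\infty + (\varepsilon'_0 -
#'   \varepsilon'_\infty)\exp[-\ln 2\,(t/t_{1/2})^n]}
#' so that the normalised curve crosses 1/2 exactly at `t_half` in the
#' noiseless limit, sampled every `step` seconds.
#'
#' @param t_half Half-life in s.
#' @param avrami_n Avrami exponent (default 3, three-dimensional growth).
#' @param eps0,epsinf Initial and final static permittivity (defaults
#'   9 and 4).
#' @param duration Total duration, s (default `4 * t_half`).
#' @param step Sampling interval, s (default 600, the standard registration
#'   interval for such experiments).
#' @param temperature Hold temperature, K (metadata).
#' @param cfg A [generator_config()].
#' @param sample_label Label.
#' @return A [crystallization_series()] with attribute `ground_truth`
#'   (list `t_half_s`, `avrami_n`, `eps0`, `epsinf`).
#' @export
make_crystallization <- function(t_half, avrami_n = 3, eps0 = 9, epsinf = 4,
                                 duration = 4 * t_half, step = 600,
                                 temperature = NA_real_,
                                 cfg = generator_config(),
                                 sample_label = "") {
  set.seed(cfg$seed)
  t <- seq(0, duration, by = step)
  eps <- epsinf + (eps0 - epsinf) * exp(-log(2) * (t / t_half)^avrami_n)
  eps <- apply_noise(eps, cfg, scale = eps0 - epsinf)
  cs <- crystallization_series(t, eps, temperature, sample_label)
  attr(cs, "ground_truth") <- list(t_half_s = t_half, avrami_n = avrami_n,
                                   eps0 = eps0, epsinf = epsinf)
  cs
}

#' Crystallization scenario presets
#'
#' Named half-life presets matching the reported isochronal (tau = 0.63 us)
#' devitrification half-lives of the study set: neat ezetimibe 79 min, neat
#' fenofibrate 114 min, neat simvastatin 330 min, and the therapeutic
#' 5.3/10.5/84.2 ternary mixture 10.5 h.
#'
#' @return Data frame `scenario`, `t_half_s`, `temperature_K` (the
#'   isochronal hold temperature where known).
#' @export
crystallization_presets <- function() {
  data.frame(
    scenario = c("neat-EZB", "neat-FEN", "neat-SVT", "ternary-5.3/10.5/84.2"),
    t_half_s = c(79 * 60, 114 * 60, 330 * 60, 10.5 * 3600),
    temperature_K = c(388, 298, 353, NA))
}
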