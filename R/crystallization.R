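#' Construct an isothermal crystallization series
#'
#' Time series of the static permittivity (real part of the complex
#' permittivity at a fixed low frequency) recorded during isothermal
#' devitrification: as crystals grow, mobile dipoles are removed from the
#' supercooled liquid and the static permittivity decays sigmoidally.
#'
#' @param time Strictly increasing times in s, starting at 0 (length >= 10).
#' @param eps_static Static permittivity values, same length.
#' @param temperature Hold temperature, K.
#' @param sample_label Optional label.
#' @return Object of class `crystallization_series`.
#' @export
crystallization_series <- function(time, eps_static, temperature = NA_real_,
                                   sample_label = "") {
  if (length(time) != length(eps_static))
    stop("time and eps_static must have equal length", call. = FALSE)
  if (length(time) < 10) stop("series needs at least 10 points", call. = FALSE)
  if (time[1] != 0) stop("time must start at 0", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  structure(list(time = time, eps_static = eps_static,
                 temperature = temperature, sample_label = sample_label),
            class = "crystallization_series")
}

#' Normalised crystallization progress from a permittivity decay
#'
#' \deqn{\varepsilon'_N(t) = \frac{\varepsilon'(0) - \varepsilon'(t)}
#'   {\varepsilon'(0) - \varepsilon'(\infty)}}
#' so that \eqn{\varepsilon'_N = 0} before crystallization starts and 1 when
#' it is complete. The endpoint levels \eqn{\varepsilon'(0)} and
#' \eqn{\varepsilon'(\infty)} are estimated as means over initial and final
#' plateau windows (first/last 5% of points by default) unless supplied.
#' The construction is invariant to gain/offset (affine) changes of the raw
#' permittivity.
#'
#' @param cs A [crystallization_series()].
#' @param eps0,epsinf Optional endpoint permittivities overriding the
#'   plateau estimates.
#' @param plateau_frac Fraction of points in each plateau window
#'   (default 0.05, minimum 3 points).
#' @return Data frame `time_s`, `eps_N`, with attribute `flagged` — indices
#'   where the normalised value falls outside [-0.05, 1.05] (diagnostic for
#'   a bad plateau estimate).
#' @export
normalize_series <- function(cs, eps0 = NULL, epsinf = NULL,
                             plateau_frac = 0.05) {
  stopifnot(inherits(cs, "crystallization_series"))
  n <- length(cs$time)
  k <- max(3L, ceiling(plateau_frac * n))
  if (is.null(eps0)) eps0 <- mean(cs$eps_static[seq_len(k)])
  if (is.null(epsinf)) epsinf <- mean(cs$eps_static[seq(n - k + 1, n)])
  if (eps0 <= epsinf)
    stop("no decay: initial permittivity does not exceed the final plateau",
         call. = FALSE)
  eN <- (eps0 - cs$eps_static) / (eps0 - epsinf)
  flagged <- which(eN < -0.05 | eN > 1.05)
  structure(data.frame(time_s = cs$time, eps_N = eN),
            flagged = flagged, eps0 = eps0, epsinf = epsinf)
}

#' Crystallization onset, half-life and endset times
#'
#' Reads characteristic times off a normalised crystallization curve by
#' linear interpolation of threshold crossings: onset at
#' \eqn{\varepsilon'_N = 0.05}, half-life at 0.5, endset at 0.95
#' (thresholds configurable; they are analysis conventions, not physical
#' constants). When a threshold is never reached the corresponding field is
#' `NA` and the summary is flagged partial.
#'
#' @param eN Data frame from [normalize_series()] (columns `time_s`,
#'   `eps_N`).
#' @param thresholds Named numeric vector `c(onset=, half=, endset=)`.
#' @return List: `onset_s`, `t_half_s`, `endset_s`, `eps0`, `epsinf`,
#'   `partial` (TRUE when any threshold was not reached). Always
#'   `onset_s <= t_half_s <= endset_s` where defined.
#' @export
kinetic_times <- function(eN, thresholds = c(onset = 0.05, half = 0.5,
                                             endset = 0.95)) {
  stopifnot(all(c("time_s", "eps_N") %in% names(eN)))
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be increasing (onset < half < endset)", call. = FALSE)
  cross <- function(level) {
    y <- eN$eps_N; t <- eN$time_s
    idx <- which(y[-1] >= level & y[-length(y)] < level)
    if (y[1] >= level) return(t[1])
    if (length(idx) == 0) return(NA_real_)
    i <- idx[1]
    if (y[i + 1] == y[i]) return(t[i + 1])
    t[i] + (level - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
  }
  out <- list(onset_s = cross(thresholds[["onset"]]),
              t_half_s = cross(thresholds[["half"]]),
              endset_s = cross(thresholds[["endset"]]),
              eps0 = attr(eN, "eps0"), epsinf = attr(eN, "epsinf"))
  out$partial <- any(is.na(c(out$onset_s, out$t_half_s, out$endset_s)))
  out
}

#' Avrami diagnostic fit to a normalised crystallization curve
#'
#' Optional diagnostic: fits \eqn{\varepsilon'_N(t) = 1 - \exp[-(kt)^n]}
#' by least squares. The package's kinetic summaries are model-free
#' (threshold crossings); this fit only characterises curve shape.
#'
#' @param eN Data frame from [normalize_series()].
#' @return List `k` (1/s), `n` (Avrami exponent), `t_half_s`
#'   (\eqn{(\ln 2)^{1/n}/k}), `residual_norm`.
#' @export
fit_avrami <- function(eN) {
  t <- eN$time_s; y <- pmin(pmax(eN$eps_N, 0), 1)
  use <- t > 0 & y > 1e-4 & y < 1 - 1e-4
  if (sum(use) < 5) stop("too few points in the transformation window",
                         call. = FALSE)
  # linearised start: log(-log(1-y)) = n log k + n log t
  lin <- stats::lm(log(-log(1 - y[use])) ~ log(t[use]))
  n0 <- max(unname(stats::coef(lin)[2]), 0.2)
  k0 <- exp(unname(stats::coef(lin)[1]) / n0)
  fit <- minpack.lm::nls.lm(
    par = c(log(k0), n0), lower = c(-50, 0.1), upper = c(10, 10),
    fn = function(v) 1 - exp(-(exp(v[1]) * t)^v[2]) - eN$eps_N)
  k <- exp(unname(fit$par[1])); n <- unname(fit$par[2])
  list(k = k, n = n, t_half_s = log(2)^(1 / n) / k,
       residual_norm = sqrt(mean(fit$fvec^2)))
}

#' Read / write a crystallization series CSV
#'
#' Columns `time_s, eps_prime`, with `# temperature_K:` and
#' `# sample_label:` comment headers.
#' @param file Path.
#' @param cs A `crystallization_series` (for writing).
#' @export
read_crystallization <- function(file) {
  hdr <- readLines(file, n = 5)
  temp <- NA_real_; label <- ""
  for (h in hdr[startsWith(hdr, "#")]) {
    kv <- strsplit(sub("^#\\s*", "", h), ":")[[1]]
    if (length(kv) == 2) {
      if (trimws(kv[1]) == "temperature_K") temp <- as.numeric(trimws(kv[2]))
      if (trimws(kv[1]) == "sample_label") label <- trimws(kv[2])
    }
  }
  d <- utils::read.csv(file, comment.char = "#")
  crystallization_series(d$time_s, d$eps_prime, temp, label)
}

#' @rdname read_crystallization
#' @export
write_crystallization <- function(cs, file) {
  stopifnot(inherits(cs, "crystallization_series"))
  con <- file(file, "w")
  on.exit(close(con))
  if (is.finite(cs$temperature))
    writeLines(sprintf("# temperature_K: %g", cs$temperature), con)
  writeLines(sprintf("# sample_label: %s", cs$sample_label), con)
  utils::write.csv(data.frame(time_s = cs$time, eps_prime = cs$eps_static),
                   con, row.names = FALSE)
  invisible(file)
}
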