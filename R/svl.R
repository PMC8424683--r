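#' Schroeder-Van Laar liquidus temperature
#'
#' Ideal-solution liquidus: the temperature at which a melt containing the
#' component at mole fraction `x` is in equilibrium with the pure crystal,
#' obtained from
#' \deqn{\ln x = -\frac{\Delta H_0}{R}\left(\frac{1}{T} - \frac{1}{T_0}\right)}
#' i.e. \eqn{1/T = 1/T_0 - R \ln x / \Delta H_0}. Activity coefficients are
#' taken as 1 (ideal mixing); no solid solubility.
#'
#' @param x Mole fraction of the component in the melt, in (0, 1].
#' @param comp A [pure_component()].
#' @return Liquidus temperature in K. `T = T0` at `x = 1`; strictly
#'   increasing in `x`.
#' @examples
#' fen <- pure_component("FEN", 360.83, 353.4, 33500)
#' svl_liquidus(1, fen)     # 353.4
#' svl_liquidus(0.5, fen)   # depressed melting
#' @export
svl_liquidus <- function(x, comp) {
  stopifnot(inherits(comp, "pure_component"))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("mole fraction x must be in (0, 1]", call. = FALSE)
  if (any(x > 1 + 1e-12))
    stop("mole fraction x must be <= 1", call. = FALSE)
  invT <- 1 / comp$melt_temperature -
    GAS_CONSTANT * log(pmin(x, 1)) / comp$fusion_enthalpy
  if (any(invT <= 0))
    stop("x too small: ideal liquidus diverges (1/T <= 0)", call. = FALSE)
  1 / invT
}

# mole fraction on a component's liquidus branch at temperature T (inverse
# of svl_liquidus); > 1 for T > T0
svl_branch_x <- function(T, comp) {
  exp(-comp$fusion_enthalpy / GAS_CONSTANT *
        (1 / T - 1 / comp$melt_temperature))
}

#' Binary eutectic point from the Schroeder-Van Laar model
#'
#' Finds the composition where the two ideal liquidus branches intersect:
#' `svl_liquidus(x, A) == svl_liquidus(1 - x, B)`. Solved by bracketed
#' root-finding (Brent) on x in `[1e-6, 1 - 1e-6]`; the residual common
#' temperature is refined to better than 1e-6 K.
#'
#' @param A,B [pure_component()] objects.
#' @return List with `x_e` (mole fraction of `A` at the eutectic), `T_e`
#'   (eutectic temperature, K), and `residual_K` (absolute branch-temperature
#'   mismatch at the solution).
#' @examples
#' A <- pure_component("A", 400, 400, 25000)
#' B <- pure_component("B", 350, 350, 20000)
#' binary_eutectic(A, B)
#' @export
binary_eutectic <- function(A, B) {
  stopifnot(inherits(A, "pure_component"), inherits(B, "pure_component"))
  f <- function(x) svl_liquidus(x, A) - svl_liquidus(1 - x, B)
  lo <- 1e-6; hi <- 1 - 1e-6
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no eutectic: liquidus branches do not cross on (0, 1)", call. = FALSE)
  r <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)
  x_e <- r$root
  T_e <- svl_liquidus(x_e, A)
  list(x_e = x_e, T_e = T_e, residual_K = abs(f(x_e)))
}

#' Ternary eutectic point from the Schroeder-Van Laar model
#'
#' The ternary eutectic is the unique composition/temperature at which all
#' three ideal liquidus branches meet. Because each branch inverts in closed
#' form (\eqn{x_i(T) = \exp[-\Delta H_i / R (1/T - 1/T_{0,i})]}), the
#' three-branch intersection reduces to the scalar root of
#' \eqn{g(T) = x_A(T) + x_B(T) + x_C(T) - 1}, which is strictly increasing in
#' T. The root is bracketed and solved to a residual below 1e-6 K, then
#' branch-temperature equality is verified.
#'
#' @param A,B,C [pure_component()] objects.
#' @param grid_resolution Barycentric step for the exported liquidus surface
#'   grid (default 0.02; set smaller for plotting).
#' @param surface If `TRUE` (default) attach the full liquidus surface grid.
#' @return List with `x_e` (length-3 mole-fraction vector, ordered A, B, C),
#'   `T_e` (K), `residual_K`, and (if `surface`) a data frame `grid` with
#'   columns `x1, x2, x3, T_liquidus_K, governing_component` giving for each
#'   grid composition the surface temperature `max_i T_i(x_i)` and the index
#'   of the component whose branch governs it.
#' @export
ternary_eutectic <- function(A, B, C, grid_resolution = 0.02, surface = TRUE) {
  comps <- list(A, B, C)
  stopifnot(all(vapply(comps, inherits, TRUE, "pure_component")))
  g <- function(T) sum(vapply(comps, function(cc) svl_branch_x(T, cc), 0)) - 1
  hi <- min(vapply(comps, `[[`, 0, "melt_temperature"))
  # g(hi) >= 0 (the lowest-melting branch alone contributes x = 1 there);
  # walk down until g < 0 to bracket
  lo <- hi
  repeat {
    lo <- lo * 0.9
    if (lo < 1) stop("ternary eutectic solver failed to bracket a root",
                     call. = FALSE)
    if (g(lo) < 0) break
  }
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-10)
  T_e <- r$root
  x_e <- vapply(comps, function(cc) svl_branch_x(T_e, cc), 0)
  x_e <- x_e / sum(x_e)
  resid <- max(abs(vapply(seq_along(comps), function(i)
    svl_liquidus(x_e[i], comps[[i]]), 0) - T_e))
  if (resid > 1e-6)
    stop(sprintf("ternary eutectic did not converge (residual %.2e K)", resid),
         call. = FALSE)
  out <- list(x_e = x_e, T_e = T_e, residual_K = resid)
  if (surface)
    out$grid <- liquidus_surface(A, B, C, grid_resolution)
  out
}

#' Ideal liquidus surface of a ternary system on a barycentric grid
#'
#' At each composition the liquidus is the highest of the three per-component
#' Schroeder-Van Laar branch temperatures; the governing component is the one
#' attaining that maximum (its crystal is the primary phase there).
#'
#' @inheritParams ternary_eutectic
#' @param resolution Barycentric grid step.
#' @return Data frame `x1, x2, x3, T_liquidus_K, governing_component`.
#' @export
liquidus_surface <- function(A, B, C, resolution = 0.02) {
  comps <- list(A, B, C)
  s <- seq(0, 1, by = resolution)
  grid <- expand.grid(x1 = s, x2 = s)
  grid$x3 <- 1 - grid$x1 - grid$x2
  grid <- grid[grid$x3 > -1e-12, , drop = FALSE]
  grid$x3[grid$x3 < 0] <- 0
  Ts <- vapply(seq_len(3), function(i) {
    xi <- grid[[i]]
    out <- rep(-Inf, length(xi))
    ok <- xi > 0
    out[ok] <- svl_liquidus(xi[ok], comps[[i]])
    out
  }, numeric(nrow(grid)))
  grid$T_liquidus_K <- apply(Ts, 1, max)
  grid$governing_component <- apply(Ts, 1, which.max)
  grid
}

#' Expected number of DSC melting endotherms at a composition
#'
#' A mixture at the eutectic composition melts in a single event; away from
#' it the thermogram shows the eutectic melting followed by one dissolution
#' endotherm for each component whose liquidus branch lies resolvably above
#' the eutectic temperature. The count is
#' `1 + #\{i : T_i(x_i) > T_e + tol\}`: 1 at the eutectic, 2 for binary
#' off-eutectic mixtures, up to 3 in a ternary system.
#'
#' @param x Mole-fraction vector (length 2 or 3, sums to 1).
#' @param components List of [pure_component()] objects matching `x`.
#' @param resolvability_K Branches closer than this to the eutectic
#'   temperature are not counted as separate events (default 1 K).
#' @return Integer count of expected endotherms.
#' @export
expected_endotherm_count <- function(x, components, resolvability_K = 1) {
  stopifnot(length(x) == length(components), length(x) %in% c(2L, 3L))
  if (abs(sum(x) - 1) > 1e-6) stop("composition must sum to 1", call. = FALSE)
  eut <- if (length(x) == 2L) {
    binary_eutectic(components[[1]], components[[2]])
  } else {
    ternary_eutectic(components[[1]], components[[2]], components[[3]],
                     surface = FALSE)
  }
  Tb <- vapply(seq_along(x), function(i) {
    if (x[i] <= 0) return(-Inf)
    svl_liquidus(x[i], components[[i]])
  }, 0)
  as.integer(1L + sum(Tb > eut$T_e + resolvability_K))
}

#' Assemble an experimental phase diagram from DSC-derived records
#'
#' Takes per-composition solidus/liquidus temperatures (as extracted by
#' [solidus_liquidus()]) and locates the experimental eutectic: the
#' composition showing a single endotherm (liquidus equal to solidus within
#' `single_event_tol_K`), or, absent one, the minimum of the liquidus curve
#' interpolated across composition (for a V-shaped binary diagram the branch
#' intersection).
#'
#' @param records Data frame with columns `x` (mole fraction of the first
#'   component; for ternary systems pass `x1`, `x2`, `x3`), `solidus_K`,
#'   `liquidus_K` (either may be NA). At least 3 records.
#' @param single_event_tol_K |liquidus - solidus| below which a record counts
#'   as a single melting event (default 2 K, instrument-resolution scale).
#' @return List with `eutectic` (row: composition + `T_e_K` + `method`,
#'   where method is `"single-endotherm"` or `"interpolated-minimum"`) and
#'   `records` (the input augmented with `n_events`).
#' @export
assemble_experimental_diagram <- function(records, single_event_tol_K = 2) {
  records <- as.data.frame(records)
  comp_cols <- intersect(c("x", "x1", "x2", "x3"), names(records))
  if (length(comp_cols) == 0)
    stop("records need a composition column (x, or x1/x2/x3)", call. = FALSE)
  if (nrow(records) < 3) stop("need at least 3 records", call. = FALSE)
  if (all(is.na(records$liquidus_K)))
    stop("all liquidus temperatures missing", call. = FALSE)
  both <- !is.na(records$solidus_K) & !is.na(records$liquidus_K)
  records$n_events <- ifelse(
    both & abs(records$liquidus_K - records$solidus_K) < single_event_tol_K,
    1L, 2L)
  single <- which(records$n_events == 1L)
  if (length(single) > 0) {
    i <- single[which.min(records$liquidus_K[single])]
    eut <- records[i, c(comp_cols, "liquidus_K")]
    names(eut)[names(eut) == "liquidus_K"] <- "T_e_K"
    eut$method <- "single-endotherm"
  } else {
    ok <- !is.na(records$liquidus_K)
    if ("x" %in% comp_cols && sum(ok) >= 3) {
      # interpolate the liquidus across composition; its minimum approximates
      # the branch intersection
      xs <- seq(min(records$x[ok]), max(records$x[ok]), length.out = 2001)
      Ts <- stats::approx(records$x[ok], records$liquidus_K[ok], xout = xs)$y
      j <- which.min(Ts)
      eut <- data.frame(x = xs[j], T_e_K = Ts[j],
                        method = "interpolated-minimum")
    } else {
      j <- which.min(records$liquidus_K)
      eut <- records[j, c(comp_cols, "liquidus_K")]
      names(eut)[names(eut) == "liquidus_K"] <- "T_e_K"
      eut$method <- "interpolated-minimum"
    }
  }
  rownames(eut) <- NULL
  list(eutectic = eut, records = records)
}
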