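#' Physical constants used throughout the package
#'
#' `GAS_CONSTANT` is the molar gas constant in J mol^-1 K^-1; `EPS0` the
#' vacuum permittivity in F/m.
#' @name constants
#' @keywords internal
NULL

GAS_CONSTANT <- 8.314
EPS0 <- 8.8541878128e-12

#' Create a pure-component record
#'
#' A `pure_component` bundles the thermodynamic identity of one drug
#' substance: molar mass, melting point and enthalpy of fusion. These three
#' numbers are all the Schroeder-Van Laar liquidus model needs.
#'
#' @param name Component name (character scalar).
#' @param molar_mass Molar mass in g/mol. Must be positive.
#' @param melt_temperature Melting point T0 in K. Must be positive.
#' @param fusion_enthalpy Enthalpy of fusion in J/mol. Must be positive.
#' @return An object of class `pure_component` (a named list).
#' @examples
#' pure_component("FEN", 360.83, 353.4, 33500)
#' @export
pure_component <- function(name, molar_mass, melt_temperature, fusion_enthalpy) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be a positive finite number (g/mol)", call. = FALSE)
  if (!is.finite(melt_temperature) || melt_temperature <= 0)
    stop("melt_temperature must be a positive finite number (K)", call. = FALSE)
  if (!is.finite(fusion_enthalpy) || fusion_enthalpy <= 0)
    stop("fusion_enthalpy must be a positive finite number (J/mol)", call. = FALSE)
  structure(
    list(name = name, molar_mass = molar_mass,
         melt_temperature = melt_temperature,
         fusion_enthalpy = fusion_enthalpy),
    class = "pure_component")
}

#' @export
print.pure_component <- function(x, ...) {
  cat(sprintf("<pure_component> %s: Mw = %.2f g/mol, T0 = %.1f K, dHfus = %.0f J/mol\n",
              x$name, x$molar_mass, x$melt_temperature, x$fusion_enthalpy))
  invisible(x)
}

#' Built-in component registry
#'
#' Returns the registry of drug substances used in the worked examples:
#' ezetimibe (EZB), simvastatin (SVT) and fenofibrate (FEN). Molar masses are
#' the certified values for the substances. Melting points and fusion
#' enthalpies are literature placeholder constants: the source study reports
#' neither quantity numerically, so these values are user-replaceable and all
#' quantitative phase-diagram checks in this package run on synthetic
#' constants. Replace them with your own calorimetric determinations for any
#' real prediction (see [pure_component()]).
#'
#' @param file Optional path to a CSV with columns
#'   `name, molar_mass_g_mol, Tm_K, dHfus_J_mol` to load instead of the
#'   built-in table.
#' @return A named list of [pure_component()] objects.
#' @export
component_registry <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "components.csv", package = "amorphstab")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "molar_mass_g_mol", "Tm_K", "dHfus_J_mol")
  if (!all(need %in% names(tab)))
    stop("component registry must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    pure_component(tab$name[i], tab$molar_mass_g_mol[i], tab$Tm_K[i],
                   tab$dHfus_J_mol[i]))
  names(out) <- tab$name
  out
}

#' Convert weight fractions to mole fractions
#'
#' @param weight_fractions Numeric vector of weight fractions summing to 1.
#' @param molar_masses Numeric vector of molar masses in g/mol, same length.
#' @param tol Tolerance on the fraction sum (default 1e-6).
#' @return Numeric vector of mole fractions summing to 1.
#' @examples
#' # 10 wt% ezetimibe in an ezetimibe/fenofibrate blend
#' weight_to_mole(c(0.10, 0.90), c(409.4, 360.83))[1]  # ~0.089
#' @seealso [mole_to_weight()]
#' @export
weight_to_mole <- function(weight_fractions, molar_masses, tol = 1e-6) {
  check_fractions(weight_fractions, molar_masses, tol)
  moles <- weight_fractions / molar_masses
  moles / sum(moles)
}

#' Convert mole fractions to weight fractions
#'
#' Inverse of [weight_to_mole()]; the round trip is an identity to within
#' numerical precision.
#'
#' @inheritParams weight_to_mole
#' @param mole_fractions Numeric vector of mole fractions summing to 1.
#' @return Numeric vector of weight fractions summing to 1.
#' @export
mole_to_weight <- function(mole_fractions, molar_masses, tol = 1e-6) {
  check_fractions(mole_fractions, molar_masses, tol)
  mass <- mole_fractions * molar_masses
  mass / sum(mass)
}

check_fractions <- function(fractions, molar_masses, tol) {
  if (length(fractions) != length(molar_masses))
    stop("fractions and molar_masses must have the same length", call. = FALSE)
  if (any(!is.finite(molar_masses)) || any(molar_masses <= 0))
    stop("all molar masses must be positive", call. = FALSE)
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fractions) - 1) > tol)
    stop(sprintf("fractions must sum to 1 (got %.8f)", sum(fractions)),
         call. = FALSE)
  invisible(TRUE)
}

#' Build a composition in both weight- and mole-fraction representation
#'
#' @param components Named list of [pure_component()] objects, or a character
#'   vector of names paired with `molar_masses`.
#' @param weight_fractions Weight fractions (give exactly one of
#'   `weight_fractions` / `mole_fractions`).
#' @param mole_fractions Mole fractions.
#' @param molar_masses Molar masses in g/mol, only needed when `components`
#'   is a character vector.
#' @return An object of class `composition`: list with `names`,
#'   `weight_fractions`, `mole_fractions`, `molar_masses`.
#' @export
composition <- function(components, weight_fractions = NULL,
                        mole_fractions = NULL, molar_masses = NULL) {
  if (is.list(components) && all(vapply(components, inherits, TRUE, "pure_component"))) {
    nm <- vapply(components, `[[`, character(1), "name")
    mm <- vapply(components, `[[`, numeric(1), "molar_mass")
  } else {
    nm <- as.character(components)
    if (is.null(molar_masses))
      stop("molar_masses required when components are given by name", call. = FALSE)
    mm <- molar_masses
  }
  if (is.null(weight_fractions) == is.null(mole_fractions))
    stop("give exactly one of weight_fractions or mole_fractions", call. = FALSE)
  if (is.null(mole_fractions)) {
    w <- weight_fractions
    x <- weight_to_mole(w, mm)
  } else {
    x <- mole_fractions
    w <- mole_to_weight(x, mm)
  }
  structure(list(names = nm, weight_fractions = w, mole_fractions = x,
                 molar_masses = mm),
            class = "composition")
}
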