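#' Atomic scattering factors
#'
#' X-ray atomic form factors in the 4-Gaussian + constant parameterization
#' of International Tables for Crystallography Vol. C:
#' \deqn{f(s) = \sum_{m=1}^{4} \alpha_m \exp(-\beta_m s^2) + c,}
#' with \eqn{s = \sin\theta/\lambda} in inverse angstrom, optionally damped
#' by an isotropic Debye-Waller factor \eqn{\exp(-B s^2)}. The shipped
#' coefficient table covers H, C, N, O, Na, Mg, P, S, Cl (and the chloride
#' ion CL1-), K, Ca, Fe and Zn; a user table in the same CSV layout can be
#' substituted.
#'
#' @name scattering
NULL

.xrdsim_env <- new.env(parent = emptyenv())

#' Load a scattering-coefficient table
#'
#' @param file CSV with columns `element,a1..a4,b1..b4,c`; default is the
#'   packaged International Tables set.
#' @return invisibly, the table as a data frame (also installed as the
#'   active table for [form_factor()]).
#' @export
load_scattering_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "it92_coefficients.csv", package = "xrdsim")
  # na.strings must be empty: the sodium symbol is literally "NA"
  tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                         na.strings = character(0))
  need <- c("element", paste0("a", 1:4), paste0("b", 1:4), "c")
  if (!all(need %in% names(tab)))
    stop("load_scattering_table: missing columns")
  if (any(as.matrix(tab[, paste0("b", 1:4)]) < 0))
    stop("load_scattering_table: negative Gaussian widths")
  tab$element <- toupper(tab$element)
  rownames(tab) <- tab$element
  assign("scattering_table", tab, envir = .xrdsim_env)
  invisible(tab)
}

scattering_table <- function() {
  if (!exists("scattering_table", envir = .xrdsim_env))
    load_scattering_table()
  get("scattering_table", envir = .xrdsim_env)
}

.coeff_row <- function(element) {
  tab <- scattering_table()
  el <- toupper(element)
  if (!el %in% rownames(tab))
    stop("unknown element in scattering table: ", element)
  tab[el, ]
}

#' Atomic form factor with Debye-Waller damping
#'
#' @param element element symbol present in the active coefficient table
#'   (case-insensitive; `"CL1-"` selects the chloride-ion entry).
#' @param s momentum-transfer argument \eqn{\sin\theta/\lambda}, inverse
#'   angstrom; may be a vector.
#' @param b_factor isotropic B factor in angstrom^2 (scalar), 0 by default
#'   — the operating point for ensemble snapshots, where the small-scale
#'   motion is carried by the ensemble itself rather than by B.
#' @return real amplitude in electrons per unit incident amplitude, same
#'   length as `s`.
#' @examples
#' form_factor("C", 0)           # ~ 6 electrons
#' form_factor("O", 0.3, b_factor = 10)
#' @export
form_factor <- function(element, s, b_factor = 0) {
  if (any(s < 0)) stop("form_factor: negative s")
  if (length(b_factor) != 1 || b_factor < 0)
    stop("form_factor: b_factor must be a scalar >= 0")
  cf <- .coeff_row(element)
  s2 <- s * s
  f <- rep(as.numeric(cf$c), length(s))
  for (m in 1:4)
    f <- f + as.numeric(cf[[paste0("a", m)]]) *
      exp(-as.numeric(cf[[paste0("b", m)]]) * s2)
  f * exp(-b_factor * s2)
}

#' Electron count implied by the coefficient table
#'
#' `f(0)`, i.e. the sum of Gaussian amplitudes plus the constant term; for
#' a correct table this equals the element's electron count to within
#' 0.1 e.
#'
#' @inheritParams form_factor
#' @export
electron_count <- function(element) {
  cf <- .coeff_row(element)
  sum(as.numeric(cf[paste0("a", 1:4)])) + as.numeric(cf$c)
}

# Form factors for a set of atoms at a set of s values: returns an
# n_elements x n_s matrix keyed by the unique elements, used by the
# photograph engine to evaluate the per-pixel sum by element group.
form_factor_matrix <- function(elements, s) {
  uel <- unique(elements)
  out <- matrix(0, length(uel), length(s), dimnames = list(uel, NULL))
  for (el in uel) out[el, ] <- form_factor(el, s)
  out
}
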