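# Element reference data for Z = 1..104 and tabulated ground-state
# electron configurations (including the non-Aufbau elements).

.econf_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf"
)

# IUPAC standard atomic weights (abridged, conventional values for interval
# elements); for elements with no stable isotope, the mass number of the most
# stable isotope.
.econf_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.95, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 98, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
  121.76, 127.60, 126.90, 131.29, 132.91, 137.33, 138.91, 140.12, 140.91, 144.24,
  145, 150.36, 151.96, 157.25, 158.93, 162.50, 164.93, 167.26, 168.93, 173.05,
  174.97, 178.49, 180.95, 183.84, 186.21, 190.23, 192.22, 195.08, 196.97, 200.59,
  204.38, 207.2, 208.98, 209, 210, 222, 223, 226, 227, 232.04,
  231.04, 238.03, 237, 244, 243, 247, 247, 251, 252, 257,
  258, 259, 266, 267
)

#' Element reference table
#'
#' Symbols, atomic numbers and atomic masses for the 104 elements accepted by
#' the descriptor (hydrogen through rutherfordium).
#'
#' @return A data.frame with columns `symbol`, `z`, `mass` (g/mol), one row
#'   per element, ordered by atomic number.
#' @export
#' @examples
#' head(element_table())
element_table <- function() {
  data.frame(symbol = .econf_symbols, z = seq_along(.econf_symbols),
             mass = .econf_masses, stringsAsFactors = FALSE)
}

.econf_z_max <- 104L

# Madelung (n + l) filling order used as the baseline occupation scheme.
.aufbau_order <- c(
  "1s", "2s", "2p", "3s", "3p", "4s", "3d", "4p", "5s", "4d",
  "5p", "6s", "4f", "5d", "6p", "7s", "5f", "6d", "7p"
)

.subshell_capacity <- c(s = 2L, p = 6L, d = 10L, f = 14L)

# Experimentally observed departures from the Madelung fill (NIST ground-state
# table), expressed as occupation deltas applied after the naive fill.
.config_exceptions <- list(
  `24`  = c(`4s` = -1L, `3d` = 1L),   # Cr
  `29`  = c(`4s` = -1L, `3d` = 1L),   # Cu
  `41`  = c(`5s` = -1L, `4d` = 1L),   # Nb
  `42`  = c(`5s` = -1L, `4d` = 1L),   # Mo
  `44`  = c(`5s` = -1L, `4d` = 1L),   # Ru
  `45`  = c(`5s` = -1L, `4d` = 1L),   # Rh
  `46`  = c(`5s` = -2L, `4d` = 2L),   # Pd
  `47`  = c(`5s` = -1L, `4d` = 1L),   # Ag
  `57`  = c(`4f` = -1L, `5d` = 1L),   # La
  `58`  = c(`4f` = -1L, `5d` = 1L),   # Ce
  `64`  = c(`4f` = -1L, `5d` = 1L),   # Gd
  `78`  = c(`6s` = -1L, `5d` = 1L),   # Pt
  `79`  = c(`6s` = -1L, `5d` = 1L),   # Au
  `89`  = c(`5f` = -1L, `6d` = 1L),   # Ac
  `90`  = c(`5f` = -2L, `6d` = 2L),   # Th
  `91`  = c(`5f` = -1L, `6d` = 1L),   # Pa
  `92`  = c(`5f` = -1L, `6d` = 1L),   # U
  `93`  = c(`5f` = -1L, `6d` = 1L),   # Np
  `96`  = c(`5f` = -1L, `6d` = 1L),   # Cm
  `103` = c(`6d` = -1L, `7p` = 1L)    # Lr (7s2 7p1, not 6d1)
)

.symbol_to_z <- function(symbol) {
  z <- match(symbol, .econf_symbols)
  if (anyNA(z)) {
    bad <- symbol[is.na(z)]
    stop("unknown element symbol: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  z
}

.resolve_z <- function(element) {
  if (is.character(element)) {
    z <- .symbol_to_z(element)
  } else {
    z <- as.integer(element)
  }
  if (any(is.na(z)) || any(z < 1L) || any(z > .econf_z_max)) {
    stop("unsupported element: atomic number must be in 1..", .econf_z_max,
         call. = FALSE)
  }
  z
}

#' Ground-state electron configuration of an element
#'
#' Returns the tabulated experimental ground-state configuration (Madelung
#' filling corrected for the known exceptions such as Cr 3d5 4s1 or
#' Pd 4d10), not a naive Aufbau fill. Elements 1..104 are supported;
#' configurations for the heaviest actinides/transactinides are the accepted
#' predicted ones.
#'
#' @param element Element symbol (e.g. `"Cr"`) or atomic number.
#' @return An object of class `ground_state_config`: a list with `z`,
#'   `symbol`, and `occupation`, a data.frame of (`shell`, `subshell`,
#'   `electrons`) rows ordered by ascending shell then s < p < d < f,
#'   containing only occupied subshells.
#' @export
#' @examples
#' ground_state_config("O")   # 1s2 2s2 2p4
#' ground_state_config("Cu")  # 3d10 4s1
ground_state_config <- function(element) {
  z <- .resolve_z(element)
  stopifnot(length(z) == 1L)

  occ <- integer(length(.aufbau_order))
  names(occ) <- .aufbau_order
  remaining <- z
  for (sub in .aufbau_order) {
    cap <- .subshell_capacity[[substr(sub, 2L, 2L)]]
    take <- min(cap, remaining)
    occ[[sub]] <- take
    remaining <- remaining - take
    if (remaining == 0L) break
  }

  delta <- .config_exceptions[[as.character(z)]]
  if (!is.null(delta)) occ[names(delta)] <- occ[names(delta)] + delta

  keep <- occ > 0L
  shells <- as.integer(substr(names(occ), 1L, 1L))
  subshells <- substr(names(occ), 2L, 2L)
  ord <- order(shells, match(subshells, c("s", "p", "d", "f")))
  ord <- ord[keep[ord]]

  cfg <- list(
    z = z,
    symbol = .econf_symbols[z],
    occupation = data.frame(shell = shells[ord], subshell = subshells[ord],
                            electrons = unname(occ[ord]),
                            stringsAsFactors = FALSE)
  )
  class(cfg) <- "ground_state_config"

  if (sum(cfg$occupation$electrons) != z) {
    stop("internal error: configuration electron count does not match Z = ", z)
  }
  cfg
}

#' @export
format.ground_state_config <- function(x, ...) {
  o <- x$occupation
  paste0(x$symbol, ": ",
         paste0(o$shell, o$subshell, o$electrons, collapse = " "))
}

#' @export
print.ground_state_config <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
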