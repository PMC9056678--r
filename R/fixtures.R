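# Synthetic formula/property tables with known structure: random inorganic
# compositions whose property is linear in the electron-configuration bits,
# so that descriptor computation, pruning, splitting and model fitting can
# all be exercised and checked end to end.

#' Specification for a synthetic endpoint dataset
#'
#' The generator draws random element multisets from `element_pool`, renders
#' them as formula strings (a fraction with parenthesized groups or hydrate
#' notation, to exercise the parser), and assigns each compound the property
#' `y = beta . compound_vector(formula) + Normal(0, noise_sd^2)`. The target
#' is linear in the spin-orbital bits — not in the element counts — so the
#' electron-configuration features carry strictly more signal than plain
#' composition. `beta` is sparse: `n_active` coefficients drawn N(0, 1) on
#' bits that actually vary over the pool.
#'
#' @param n_compounds Number of compounds.
#' @param element_pool Element symbols to draw from. The default covers
#'   common inorganic chemistry: alkali/alkaline-earth and transition metals
#'   plus main-group non-metals.
#' @param max_atoms_per_element Upper bound on each element's count.
#' @param n_active Number of nonzero coefficients in `beta`.
#' @param noise_frac Noise standard deviation as a fraction of the noiseless
#'   y range (0 for a deterministic target).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 300L,
                           element_pool = c("H", "O", "N", "S", "Cl", "F",
                                            "Na", "K", "Ca", "Mg", "Al",
                                            "Fe", "Cu", "Zn", "Mo", "Ba"),
                           max_atoms_per_element = 8L,
                           n_active = 10L,
                           noise_frac = 0.05,
                           seed = 0L) {
  if (length(element_pool) == 0L) stop("element_pool must be non-empty", call. = FALSE)
  .resolve_z(element_pool)  # validates symbols
  stopifnot(n_compounds >= 1L, max_atoms_per_element >= 1L, noise_frac >= 0)
  structure(list(n_compounds = as.integer(n_compounds),
                 element_pool = element_pool,
                 max_atoms_per_element = as.integer(max_atoms_per_element),
                 n_active = as.integer(n_active),
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.render_random_formula <- function(syms, counts, style) {
  plain <- paste0(syms, ifelse(counts > 1L, counts, ""), collapse = "")
  if (style == "plain" || length(syms) < 2L) return(plain)
  if (style == "group") {
    # wrap the last element in a parenthesized group: A (B)k
    k <- counts[length(counts)]
    head <- paste0(syms[-length(syms)],
                   ifelse(counts[-length(counts)] > 1L,
                          counts[-length(counts)], ""), collapse = "")
    return(paste0(head, "(", syms[length(syms)], ")",
                  if (k > 1L) k else ""))
  }
  # hydrate: move any H2O-compatible pair is overkill; append a real hydrate
  paste0(plain, "·5H2O")
}

#' Generate random formula strings
#'
#' @param spec A [synthetic_spec()].
#' @return Character vector of `n_compounds` formulas, reproducible by seed;
#'   every formula re-parses successfully.
#' @export
generate_formulas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    vapply(seq_len(spec$n_compounds), function(i) {
      k <- sample.int(min(4L, length(spec$element_pool)), 1L)
      syms <- sample(spec$element_pool, k)
      counts <- sample.int(spec$max_atoms_per_element, k, replace = TRUE)
      style <- sample(c("plain", "plain", "plain", "group", "hydrate"), 1L)
      .render_random_formula(syms, counts, style)
    }, character(1))
  })
}

#' Generate endpoint values for a set of formulas
#'
#' @param spec A [synthetic_spec()].
#' @param formulas Character vector of parseable formulas.
#' @return List with `y` (numeric vector), `beta` (named length-118
#'   coefficient vector), and `noise_sd` (the realized noise standard
#'   deviation in endpoint units).
#' @export
generate_endpoint <- function(spec, formulas) {
  stopifnot(inherits(spec, "synthetic_spec"))
  X <- featurize_table(formulas)
  varying <- colnames(X)[apply(X, 2L, function(col) any(col != col[1L]))]
  withr::with_seed(spec$seed + 1L, {
    beta <- stats::setNames(numeric(ncol(X)), colnames(X))
    active <- sample(varying, min(spec$n_active, length(varying)))
    beta[active] <- stats::rnorm(length(active))
    y0 <- unname(drop(X %*% beta))
    noise_sd <- spec$noise_frac * diff(range(y0))
    y <- y0 + stats::rnorm(length(y0), sd = noise_sd)
    list(y = y, beta = beta, noise_sd = noise_sd)
  })
}

#' Generate a complete synthetic endpoint table
#'
#' Convenience wrapper: formulas plus endpoint values as a data.frame ready
#' for [inorganic_filter()], [split_dataset()] and featurization.
#'
#' @param spec A [synthetic_spec()].
#' @return Data.frame with columns `formula`, `value`, and attributes `beta`
#'   and `noise_sd`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  formulas <- generate_formulas(spec)
  ep <- generate_endpoint(spec, formulas)
  out <- data.frame(formula = formulas, value = ep$y,
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- ep$beta
  attr(out, "noise_sd") <- ep$noise_sd
  out
}
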