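# Electron-configuration bit-vector descriptor: one signed integer per
# spin-orbital, 118 positions in a fixed canonical order.

.orbital_components <- list(
  s = "",
  p = c("x", "y", "z"),
  d = c("xy", "yz", "xz", "z2", "x2-y2"),
  f = c("xyz", "xz2", "yz2", "z3", "z(x2-y2)", "x(x2-3y2)", "y(3x2-y2)")
)

# Subshells carried by the descriptor: s in every period, p from period 2,
# d in periods 3-6, f in periods 4-5 -> 118 spin-orbitals in total.
.descriptor_subshells <- c(
  "1s", "2s", "2p", "3s", "3p", "3d", "4s", "4p", "4d", "4f",
  "5s", "5p", "5d", "5f", "6s", "6p", "6d", "7s", "7p"
)

.build_orbital_index <- function() {
  shells <- as.integer(substr(.descriptor_subshells, 1L, 1L))
  subs <- substr(.descriptor_subshells, 2L, 2L)
  ord <- order(shells, match(subs, c("s", "p", "d", "f")))
  rows <- lapply(ord, function(i) {
    comps <- .orbital_components[[subs[i]]]
    data.frame(
      shell = shells[i], subshell = subs[i],
      component = rep(comps, each = 2L),
      spin = rep(c("+", "-"), times = length(comps)),
      stringsAsFactors = FALSE
    )
  })
  idx <- do.call(rbind, rows)
  idx$label <- paste0(
    idx$shell, idx$subshell,
    ifelse(idx$component == "", "", paste0("_", idx$component)),
    idx$spin
  )
  idx
}

.orbital_index <- .build_orbital_index()

#' Spin-orbital index of the descriptor
#'
#' The canonical 118-position index underlying every configuration vector:
#' ascending shell, subshells in s < p < d < f order, degenerate components in
#' their conventional listing order (p: x, y, z; d: xy, yz, xz, z2, x2-y2;
#' f: xyz, xz2, yz2, z3, z(x2-y2), x(x2-3y2), y(3x2-y2)), spin-plus before
#' spin-minus. Column labels of all featurized matrices follow this order.
#'
#' @return A data.frame with columns `shell`, `subshell`, `component`, `spin`,
#'   `label` (118 rows).
#' @export
orbital_index <- function() .orbital_index

#' Labels of the 118 spin-orbital bits
#' @return Character vector of length 118, e.g. `"2p_x+"`, `"4d_xy-"`.
#' @export
orbital_labels <- function() .orbital_index$label

#' Element configuration bit vector
#'
#' Converts a ground-state configuration into the signed 118-bit vector.
#' Within each subshell, electrons obey Hund's rule: the degenerate
#' components are singly occupied with spin-plus electrons first (in
#' canonical component order); only once every component of the subshell
#' holds a spin-plus electron are spin-minus bits set, again in component
#' order. Spin-plus bits are +1, spin-minus bits are -1, all others 0.
#'
#' @param config A `ground_state_config`, an element symbol, or an atomic
#'   number.
#' @return Named integer vector of length 118 (labels from
#'   [orbital_labels()]), values in `{-1, 0, 1}`.
#' @export
#' @examples
#' v <- element_bits("O")
#' v[v != 0]
element_bits <- function(config) {
  if (!inherits(config, "ground_state_config")) {
    config <- ground_state_config(config)
  }
  bits <- integer(nrow(.orbital_index))
  names(bits) <- .orbital_index$label
  occ <- config$occupation
  for (i in seq_len(nrow(occ))) {
    sub <- occ$subshell[i]
    k <- occ$electrons[i]
    comps <- .orbital_components[[sub]]
    g <- length(comps)
    if (k > 2L * g) {
      stop("invalid configuration: ", occ$shell[i], sub, k,
           " exceeds subshell capacity ", 2L * g, call. = FALSE)
    }
    sel <- .orbital_index$shell == occ$shell[i] & .orbital_index$subshell == sub
    plus_labels <- .orbital_index$label[sel & .orbital_index$spin == "+"]
    minus_labels <- .orbital_index$label[sel & .orbital_index$spin == "-"]
    n_plus <- min(k, g)
    bits[plus_labels[seq_len(n_plus)]] <- 1L
    if (k > g) bits[minus_labels[seq_len(k - g)]] <- -1L
  }
  bits
}

#' Compound configuration bit vector
#'
#' The descriptor of a compound: each constituent element's bit vector is
#' multiplied by its stoichiometric count and the scaled vectors are summed
#' index-wise. The sum of absolute bit values therefore equals the total
#' electron count of the formula.
#'
#' @param counts An `element_count` from [parse_formula()], or a formula
#'   string.
#' @return Named integer vector of length 118.
#' @export
#' @examples
#' v <- compound_vector("Al2(MoO4)3")
#' v["1s+"]           # 17 = 2 (Al) + 3 (Mo) + 12 (O)
#' sum(abs(v))        # 248 electrons
compound_vector <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  bits <- integer(nrow(.orbital_index))
  names(bits) <- .orbital_index$label
  for (sym in names(counts)) {
    bits <- bits + counts[[sym]] * element_bits(sym)
  }
  bits
}

#' Featurize a list of formulas
#'
#' Builds the descriptor matrix for a character vector of molecular formulas:
#' one row per compound, the 118 canonical spin-orbital bits as columns. All
#' unparseable formulas are collected and reported together with their row
#' numbers.
#'
#' @param formulas Character vector of molecular formulas.
#' @return Integer matrix `length(formulas)` x 118 with column names from
#'   [orbital_labels()] and `formulas` as row names.
#' @export
#' @examples
#' featurize_table(c("H2", "He"))[, 1:2]
featurize_table <- function(formulas) {
  formulas <- as.character(formulas)
  labels <- .orbital_index$label
  mat <- matrix(0L, nrow = length(formulas), ncol = length(labels),
                dimnames = list(formulas, labels))
  failures <- character(0)
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(formulas)) {
    f <- formulas[i]
    row <- tryCatch({
      key <- f
      if (is.null(cache[[key]])) cache[[key]] <- compound_vector(f)
      cache[[key]]
    }, error = function(e) {
      failures[length(failures) + 1L] <<-
        paste0("row ", i, " ('", f, "'): ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) mat[i, ] <- row
  }
  if (length(failures) > 0L) {
    stop("failed to featurize ", length(failures), " formula(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  mat
}

#' Remove constant descriptor columns
#'
#' Drops every column whose standard deviation over all rows is exactly zero.
#' Such orbital bits carry no information for the dataset at hand and their
#' model weights cannot be trained. The kept labels are returned so that new
#' inputs can later be aligned to the fitted column set with
#' [align_columns()].
#'
#' @param mat Descriptor matrix (rows = compounds).
#' @return List with `matrix` (pruned columns) and `kept` (character vector of
#'   retained column labels).
#' @export
prune_constant_bits <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 1L) {
    stop("a matrix with at least one row is required", call. = FALSE)
  }
  constant <- apply(mat, 2L, function(col) all(col == col[1L]))
  kept <- colnames(mat)[!constant]
  if (length(kept) == 0L) {
    warning("all columns are constant; returning an empty matrix")
  }
  list(matrix = mat[, kept, drop = FALSE], kept = kept)
}

#' Align a descriptor matrix to a fitted column set
#'
#' @param mat Full (118-column) descriptor matrix.
#' @param kept Character vector of column labels retained at fit time.
#' @return Matrix restricted to `kept`, in that order.
#' @export
align_columns <- function(mat, kept) {
  missing <- setdiff(kept, colnames(mat))
  if (length(missing) > 0L) {
    stop("descriptor matrix lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mat[, kept, drop = FALSE]
}
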