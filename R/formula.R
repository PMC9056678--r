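# Molecular formula parsing: nested parentheses, hydrate dot notation,
# strict element-symbol tokenization.

#' Parse a molecular formula into element counts
#'
#' Expands a molecular formula string into its stoichiometric element counts.
#' Supports nested parentheses/brackets with group multipliers and hydrate
#' notation: formula units separated by a middle dot, a period, or an
#' asterisk, each unit optionally prefixed with an integer multiplier (e.g.
#' `"CuSO4·5H2O"`). Charge notation (`"+"`, `"-"`, `"^"`) is rejected: all
#' species are treated as neutral ground-state compounds. A leading integer
#' anywhere is read as a unit multiplier, so mass-number isotope prefixes
#' have no representation and isotopes cannot be distinguished.
#'
#' @param formula A single non-empty formula string.
#' @return A named integer vector of class `element_count`: element symbols
#'   mapped to positive counts, ordered by first appearance.
#' @export
#' @examples
#' parse_formula("Al2(MoO4)3")       # Al 2, Mo 3, O 12
#' parse_formula("Cu(NO3)2·3H2O")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(trimws(formula))) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  s <- trimws(formula)
  if (grepl("[-+^]", s)) {
    stop("charge notation is not supported in '", s,
         "'; formulas must be neutral species", call. = FALSE)
  }

  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[pos] else ""
  read_count <- function(default = 1L) {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
    if (pos == start) return(default)
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }
  add <- function(acc, counts, mult) {
    for (sym in names(counts)) {
      acc[sym] <- (if (sym %in% names(acc)) acc[[sym]] else 0L) +
        counts[[sym]] * mult
    }
    acc
  }

  closers <- c("(" = ")", "[" = "]")
  separators <- c("·", ".", "*")

  # a run of element/group tokens, ending at a separator, closer, or the end
  parse_tokens <- function() {
    acc <- integer(0)
    repeat {
      ch <- peek()
      if (ch == "" || ch %in% separators || ch %in% c(")", "]")) {
        return(acc)
      }
      if (ch %in% c("(", "[")) {
        open_pos <- pos
        pos <<- pos + 1L
        inner <- parse_sequence(closer = closers[[ch]])
        if (peek() != closers[[ch]]) {
          stop("unbalanced parentheses in '", s, "' at position ", open_pos,
               call. = FALSE)
        }
        pos <<- pos + 1L
        mult <- read_count()
        acc <- add(acc, inner, mult)
      } else if (grepl("[A-Z]", ch)) {
        sym <- ch
        pos <<- pos + 1L
        if (grepl("[a-z]", peek())) {
          two <- paste0(sym, peek())
          if (two %in% .econf_symbols) {
            sym <- two
            pos <<- pos + 1L
          } else {
            stop("unknown element symbol '", two, "' in '", s,
                 "' at position ", pos - 1L, call. = FALSE)
          }
        }
        if (!sym %in% .econf_symbols) {
          stop("unknown element symbol '", sym, "' in '", s,
               "' at position ", pos - 1L, call. = FALSE)
        }
        cnt <- read_count()
        acc <- add(acc, stats::setNames(cnt, sym), 1L)
      } else {
        stop("unexpected character '", ch, "' in '", s, "' at position ", pos,
             call. = FALSE)
      }
    }
  }

  # hydrate-style sequence: unit (separator unit)*, each unit optionally
  # prefixed with an integer multiplier; used at the top level and inside
  # parenthesized groups alike
  parse_sequence <- function(closer = NULL) {
    acc <- integer(0)
    repeat {
      unit_mult <- read_count()
      unit <- parse_tokens()
      if (length(unit) == 0L) {
        stop("empty formula unit in '", s, "' at position ", pos,
             call. = FALSE)
      }
      acc <- add(acc, unit, unit_mult)
      ch <- peek()
      if (ch %in% separators) {
        pos <<- pos + 1L
        next
      }
      if (is.null(closer)) {
        if (ch != "") {
          stop("unbalanced parentheses in '", s, "' at position ", pos,
               call. = FALSE)
        }
      }
      return(acc)
    }
  }

  total <- parse_sequence()
  total <- total[total > 0L]
  storage.mode(total) <- "integer"
  class(total) <- "element_count"
  total
}

#' Render element counts as a formula string
#'
#' Hill-like ordering: carbon first, then hydrogen, then remaining elements
#' alphabetically; purely alphabetical when no carbon is present. Re-parsing
#' the rendered string recovers the identical counts.
#'
#' @param counts An `element_count` (named integer vector).
#' @return A formula string.
#' @export
format_formula <- function(counts) {
  syms <- names(counts)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}

#' Molecular weight from element counts
#'
#' @param counts An `element_count` as returned by [parse_formula()], or a
#'   formula string.
#' @return Molecular weight in g/mol.
#' @export
#' @examples
#' molecular_weight("H2O")
molecular_weight <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  z <- .symbol_to_z(names(counts))
  sum(as.numeric(counts) * .econf_masses[z])
}

#' @export
print.element_count <- function(x, ...) {
  cat(format_formula(x), "\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}
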