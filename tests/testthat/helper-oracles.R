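# Independent reference implementations used as oracles. These deliberately
# re-derive everything from scratch (own orbital tables, electron-by-electron
# loops, textbook metric formulas) so they share no code path with the
# package internals they check.

# -- spin-orbital labels, rebuilt independently ------------------------------
oracle_labels <- local({
  comp <- list(
    s = "",
    p = c("x", "y", "z"),
    d = c("xy", "yz", "xz", "z2", "x2-y2"),
    f = c("xyz", "xz2", "yz2", "z3", "z(x2-y2)", "x(x2-3y2)", "y(3x2-y2)")
  )
  subshells <- c("1s", "2s", "2p", "3s", "3p", "3d", "4s", "4p", "4d", "4f",
                 "5s", "5p", "5d", "5f", "6s", "6p", "6d", "7s", "7p")
  out <- character(0)
  for (ss in subshells) {
    l <- substr(ss, 2, 2)
    for (cm in comp[[l]]) {
      base <- if (cm == "") ss else paste0(ss, "_", cm)
      out <- c(out, paste0(base, "+"), paste0(base, "-"))
    }
  }
  out
})

# -- brute-force electron-by-electron Hund filler ----------------------------
# Places the electrons of each occupied subshell one at a time: the first g
# electrons go spin-up across the g degenerate components in order, any
# further electrons pair up spin-down in the same component order.
oracle_element_bits <- function(element) {
  cfg <- ground_state_config(element)
  degeneracy <- c(s = 1L, p = 3L, d = 5L, f = 7L)
  bits <- setNames(integer(length(oracle_labels)), oracle_labels)
  comp <- list(
    s = "",
    p = c("x", "y", "z"),
    d = c("xy", "yz", "xz", "z2", "x2-y2"),
    f = c("xyz", "xz2", "yz2", "z3", "z(x2-y2)", "x(x2-3y2)", "y(3x2-y2)")
  )
  for (i in seq_len(nrow(cfg$occupation))) {
    row <- cfg$occupation[i, ]
    g <- degeneracy[[row$subshell]]
    cms <- comp[[row$subshell]]
    for (e in seq_len(row$electrons)) {
      if (e <= g) {
        cm <- cms[e]; spin <- "+"; val <- 1L
      } else {
        cm <- cms[e - g]; spin <- "-"; val <- -1L
      }
      base <- paste0(row$shell, row$subshell,
                     if (cm == "") "" else paste0("_", cm))
      bits[[paste0(base, spin)]] <- val
    }
  }
  bits
}

# -- textbook metric formulas ------------------------------------------------
oracle_r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}
oracle_mae <- function(obs, pred) sum(abs(obs - pred)) / length(obs)
oracle_spearman <- function(obs, pred) {
  stats::cor(obs, pred, method = "spearman")
}

# random element-count vector for round-trip style properties
random_counts <- function(n_elements = 4L) {
  syms <- sample(element_table()$symbol, n_elements)
  structure(setNames(sample.int(9L, n_elements, replace = TRUE), syms),
            class = "element_count")
}
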