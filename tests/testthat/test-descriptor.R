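test_that("the spin-orbital index is canonical and complete", {
  idx <- orbital_index()
  expect_identical(nrow(idx), 118L)
  expect_false(anyDuplicated(idx$label) > 0)
  expect_identical(idx$label, oracle_labels)
  # s/p/d/f multiplicities: 7 s, 6 p, 4 d, 2 f subshells
  expect_identical(as.integer(table(idx$subshell)[c("s", "p", "d", "f")]),
                   c(14L, 36L, 40L, 28L))
})

test_that("oxygen and closed-shell element vectors match the Hund filling", {
  v <- element_bits("O")
  expect_identical(v[c("1s+", "1s-", "2s+", "2s-")], c(`1s+` = 1L, `1s-` = -1L,
                                                       `2s+` = 1L, `2s-` = -1L))
  expect_identical(v[c("2p_x+", "2p_y+", "2p_z+")],
                   c(`2p_x+` = 1L, `2p_y+` = 1L, `2p_z+` = 1L))
  expect_identical(v[["2p_x-"]], -1L)
  expect_identical(v[["2p_y-"]], 0L)
  expect_identical(v[["2p_z-"]], 0L)
  expect_identical(sum(v != 0), 8L)

  he <- element_bits("He")
  expect_identical(he[["1s+"]], 1L)
  expect_identical(he[["1s-"]], -1L)
  expect_identical(sum(he != 0), 2L)

  n <- element_bits("N")
  expect_identical(unname(n[c("2p_x+", "2p_y+", "2p_z+")]), rep(1L, 3))
  expect_identical(unname(n[c("2p_x-", "2p_y-", "2p_z-")]), rep(0L, 3))
})

test_that("element vectors agree with the brute-force electron filler for all Z", {
  for (z in 1:104) {
    expect_identical(element_bits(z), oracle_element_bits(z),
                     label = paste("Z =", z))
  }
})

test_that("Hund ordering holds within every subshell of every element", {
  idx <- orbital_index()
  key <- paste0(idx$shell, idx$subshell)
  for (z in 1:104) {
    v <- element_bits(z)
    for (ss in unique(key)) {
      plus <- v[idx$label[key == ss & idx$spin == "+"]]
      minus <- v[idx$label[key == ss & idx$spin == "-"]]
      if (any(minus != 0)) {
        expect_true(all(plus == 1L),
                    label = paste0("Z=", z, " subshell ", ss))
      }
    }
  }
})

test_that("electron count is conserved in compound vectors", {
  et <- element_table()
  withr::with_seed(21, {
    for (i in 1:20) {
      counts <- random_counts(sample(1:5, 1))
      v <- compound_vector(counts)
      z_total <- sum(as.integer(counts) * et$z[match(names(counts), et$symbol)])
      expect_identical(sum(abs(v)), z_total)
    }
  })
})

test_that("signed bit sum equals the number of unpaired electrons", {
  expect_identical(sum(element_bits("O")), 2L)
  expect_identical(sum(element_bits("N")), 3L)
  expect_identical(sum(element_bits("Cr")), 6L)  # 3d5 4s1
  expect_identical(sum(element_bits("Ne")), 0L)
  expect_identical(sum(element_bits("Pd")), 0L)  # 4d10, closed
})

test_that("the worked compound example is reproduced bit-exactly", {
  cv <- compound_vector("Al2(MoO4)3")
  expect_identical(cv[["1s+"]], 17L)      # 2 Al + 3 Mo + 12 O
  expect_identical(sum(abs(cv)), 248L)    # 2*13 + 3*42 + 12*8 electrons
  o12 <- 12L * element_bits("O")
  expect_identical(o12[["1s+"]], 12L)
  expect_identical(o12[["1s-"]], -12L)
  expect_identical(o12[["2p_x-"]], -12L)
  expect_identical(unname(o12[c("2p_x+", "2p_y+", "2p_z+")]), rep(12L, 3))
  # single-element compound is the element vector itself
  expect_identical(compound_vector("W"), element_bits("W"))
})

test_that("compound vectors are linear over disjoint concatenation", {
  v <- compound_vector("Na2SFeCl3")
  expect_identical(v, compound_vector("Na2S") + compound_vector("FeCl3"))
})

test_that("featurize_table builds labeled rows and collects all failures", {
  m <- featurize_table(c("H2", "He"))
  expect_identical(dim(m), c(2L, 118L))
  expect_identical(colnames(m), orbital_labels())
  expect_identical(m["H2", "1s+"], 2L)
  expect_identical(m["H2", "1s-"], 0L)
  expect_identical(m["He", c("1s+", "1s-")], c(`1s+` = 1L, `1s-` = -1L))

  empty <- featurize_table(character(0))
  expect_identical(dim(empty), c(0L, 118L))
  expect_identical(colnames(empty), orbital_labels())

  err <- tryCatch(featurize_table(c("H2O", "Xq", "NaCl", "Al2(")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "row 2")
  expect_match(err, "row 4")
  expect_match(err, "2 formula")
})

test_that("constant-bit pruning drops exactly the zero-variance columns", {
  m <- featurize_table(c("H2O", "H2S", "NaCl"))
  pr <- prune_constant_bits(m)
  keep_ref <- colnames(m)[apply(m, 2, function(col) length(unique(col)) > 1)]
  expect_identical(pr$kept, keep_ref)

  # idempotence
  pr2 <- prune_constant_bits(pr$matrix)
  expect_identical(pr2$matrix, pr$matrix)
  expect_identical(pr2$kept, pr$kept)

  # two rows differing in exactly one bit -> one kept column
  m2 <- featurize_table(c("H", "H2"))
  expect_identical(prune_constant_bits(m2)$kept, "1s+")

  # all-constant matrix warns and returns empty
  m3 <- featurize_table(c("He", "He"))
  expect_warning(pr3 <- prune_constant_bits(m3), "constant")
  expect_identical(ncol(pr3$matrix), 0L)

  expect_error(prune_constant_bits(m[0, , drop = FALSE]), "at least one row")
})

test_that("align_columns restores a fitted column set and flags mismatches", {
  m <- featurize_table(c("H2O", "NaCl"))
  pr <- prune_constant_bits(m)
  new <- featurize_table("KBr")
  aligned <- align_columns(new, pr$kept)
  expect_identical(colnames(aligned), pr$kept)
  expect_error(align_columns(aligned[, -1, drop = FALSE], pr$kept),
               "lacks required columns")
})

test_that("unsupported atomic numbers are rejected", {
  expect_error(ground_state_config(105), "unsupported element")
  expect_error(ground_state_config(0), "unsupported element")
  expect_error(element_bits("Zz"), "unknown element")
})
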