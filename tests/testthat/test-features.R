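test_that("logistic PSSM normalization matches direct evaluation", {
  expect_equal(normalize_pssm(matrix(0))[1, 1], 0.5)
  # independent arithmetic: 1/(1+exp(-2)) = 0.8807970779...
  expect_equal(normalize_pssm(matrix(2))[1, 1], 0.8807971, tolerance = 1e-7)
  x <- matrix(sample(-13:13, 200, replace = TRUE), 10, 20)
  n <- normalize_pssm(x)
  expect_true(all(n > 0 & n < 1))
})

test_that("window encoding pads with (N-1)/2 pseudoterminal rows", {
  mat <- matrix(seq_len(6 * 2), 6, 2)
  w9 <- window_encode(mat, window = 9)
  expect_equal(ncol(w9), 9 * 2)
  # residue 1 sees 4 pad positions before it, all zero
  expect_equal(unname(w9[1, 1:8]), rep(0, 8))
  expect_true(all(w9[1, 9:10] == mat[1, ]))
  # last residue sees 4 pad positions after it
  expect_equal(unname(w9[6, 11:18]), rep(0, 8))

  w1 <- window_encode(mat, window = 1)
  expect_equal(unname(w1), unname(mat), ignore_attr = TRUE)

  expect_error(window_encode(mat, window = 4), class = "cbep_config_error")
  # windows larger than the chain are legal: all-pad positions allowed
  wide <- window_encode(mat, window = 2 * 6 + 3)
  expect_equal(ncol(wide), 15 * 2)
})

test_that("window width on a 20-column profile is 20 * N", {
  mat <- matrix(rnorm(5 * 20), 5, 20)
  expect_equal(ncol(window_encode(mat, 11)), 220)
})

test_that("dipeptide composition matches brute-force enumeration", {
  v <- dipeptide_composition("AA")
  expect_length(v, 420)
  expect_equal(unname(v["aac_A"]), 1)
  expect_equal(sum(v[1:20]), 1)
  expect_equal(unname(v["dp_AA"]), 1)
  expect_equal(sum(v[21:420]), 1)

  v2 <- dipeptide_composition("ACA")
  expect_equal(unname(v2["aac_A"]), 2 / 3)
  expect_equal(unname(v2["aac_C"]), 1 / 3)
  expect_equal(unname(v2["dp_AC"]), 0.5)
  expect_equal(unname(v2["dp_CA"]), 0.5)

  # brute-force oracle on random sequences: count overlapping pairs directly
  withr::with_seed(11, {
    for (rep in 1:10) {
      s <- paste(sample(cbep:::aa_standard, 30, replace = TRUE),
                 collapse = "")
      v <- dipeptide_composition(s)
      ch <- strsplit(s, "")[[1]]
      pairs <- paste0(ch[-30], ch[-1])
      for (p in unique(pairs)) {
        expect_equal(unname(v[paste0("dp_", p)]), sum(pairs == p) / 29)
      }
      expect_equal(sum(v[21:420]), 1)
    }
  })

  expect_error(dipeptide_composition(""), class = "cbep_format_error")
})

test_that("encoded feature width obeys the block identity for any odd N", {
  rec <- tiny_record(len = 15)
  for (n in c(1, 3, 7, 11)) {
    enc <- encode_residues(rec, window = n)
    blocks <- attr(enc, "feature_blocks")
    expect_equal(sum(blocks$width), 30 * n + 420)
    expect_equal(length(feature_cols(enc)), 30 * n + 420)
  }
  enc11 <- encode_residues(rec, window = 11)
  expect_equal(length(feature_cols(enc11)), 750)
  blocks <- attr(enc11, "feature_blocks")
  expect_equal(blocks$width, c(220L, 33L, 11L, 66L, 420L))
})

test_that("per-block value ranges hold after encoding", {
  rec <- tiny_record(len = 20, seed = 3)
  enc <- encode_residues(rec, window = 11)
  pssm_cols <- grep("^pssm:", names(enc), value = TRUE)
  dis_cols <- grep("^dis:", names(enc), value = TRUE)
  pv <- as.matrix(enc[, pssm_cols])
  expect_true(all(pv >= 0 & pv < 1))          # pad rows are exactly 0
  expect_true(all(pv[6:15, ] > 0))
  dv <- as.matrix(enc[, dis_cols])
  expect_true(all(dv %in% c(0, 1)))
})

test_that("dipeptide block is constant across residues of a chain", {
  rec <- tiny_record(len = 10, seed = 5)
  enc <- encode_residues(rec)
  dipep <- as.matrix(enc[, grep("^dipep:", names(enc))])
  expect_equal(max(apply(dipep, 2, function(col) diff(range(col)))), 0)
})

test_that("encoding a reversed chain mirrors the windows", {
  rec <- tiny_record(len = 14, seed = 7)
  len <- nchar(rec$sequence)
  rev_rec <- antigen_record(
    "rev", paste(rev(cbep:::seq_chars(rec$sequence)), collapse = ""),
    pssm = rec$pssm[len:1, ], ss2 = rec$ss2[len:1, ],
    disorder = rev(rec$disorder))
  n <- 5
  half <- (n - 1) / 2
  fwd <- as.matrix(encode_residues(rec, window = n)[
    , grep("^pssm:", names(encode_residues(rec, window = n)))])
  bwd <- as.matrix(encode_residues(rev_rec, window = n)[
    , grep("^pssm:", names(encode_residues(rev_rec, window = n)))])
  # offset o of residue i forward == offset -o of residue L+1-i reversed
  perm <- as.vector(vapply(rev(seq_len(n)), function(k)
    (k - 1) * 20 + 1:20, numeric(20)))
  for (i in c(1, 4, 14)) {
    expect_equal(unname(fwd[i, ]), unname(bwd[len + 1 - i, perm]))
  }
})

test_that("missing profiles are reported by name", {
  rec <- antigen_record("nop", "ACDEFGHIK")
  expect_error(encode_residues(rec), "pssm",
               class = "cbep_missing_profile_error")
})

test_that("physicochemical scales are min-max normalized over 20 residues", {
  sc <- default_scales()
  expect_equal(nrow(sc), 20)
  for (col in setdiff(names(sc), "aa")) {
    expect_equal(min(sc[[col]]), 0)
    expect_equal(max(sc[[col]]), 1)
  }
  # non-standard letters score 0 on every scale
  rows <- cbep:::scale_rows("AXU", sc)
  expect_equal(unname(rows[2, ]), rep(0, 6))
  expect_equal(unname(rows[3, ]), rep(0, 6))
})
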