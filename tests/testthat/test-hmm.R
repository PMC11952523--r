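test_that("profiles are counted and pseudocounted as specified", {
  # gap-free identical rows: one match state per column, modal residue max
  m <- msa(paste0("r", 1:3), rep("MKLVWYAAST", 3))
  p <- build_profile(m)
  expect_equal(p$n_match, 10L)
  res <- strsplit("MKLVWYAAST", "")[[1]]
  for (i in 1:10) {
    expect_equal(names(which.max(p$match_emissions[i, ])), res[i])
  }
  expect_equal(unname(rowSums(p$match_emissions)), rep(1, 10),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(p$insert_emissions)), rep(1, 11),
               tolerance = 1e-9)
  expect_true(all(p$match_emissions > 0))

  # gap-majority column becomes an insert column
  m2 <- msa(paste0("r", 1:4), c("MA", "M-", "M-", "M-"))  # col2 gap 0.75
  p2 <- build_profile(m2, gap_threshold = 0.5)
  expect_equal(p2$n_match, 1L)

  expect_error(build_profile(msa("r", "---")), "non-protein|no match")
})

test_that("a two-row gapped alignment reproduces hand-computed parameters", {
  # rows "AC" / "A-": both columns are match states (gap fractions 0, 0.5)
  p <- build_profile(msa(c("r1", "r2"), c("AC", "A-")),
                     gap_threshold = 0.5, pseudocount = 1.0)
  expect_equal(p$n_match, 2L)
  # match 1: counts A=2, n=2, uniform background 1/20
  expect_equal(unname(p$match_emissions[1, "A"]), (2 + 0.05) / 3, tolerance = 1e-12)
  expect_equal(unname(p$match_emissions[1, "C"]), 0.05 / 3, tolerance = 1e-12)
  # match 2: counts C=1, n=1
  expect_equal(unname(p$match_emissions[2, "C"]), (1 + 0.05) / 2, tolerance = 1e-12)
  # transitions: begin->M seen twice; M1 -> M once, -> D once;
  # final states have no delete successor (2 valid choices)
  expect_equal(unname(p$trans_m[1, ]), c((2 + 1/3) / 3, (1/3) / 3, (1/3) / 3),
               tolerance = 1e-12)
  expect_equal(unname(p$trans_m[2, ]), c((1 + 1/3) / 3, (1/3) / 3, (1 + 1/3) / 3),
               tolerance = 1e-12)
  expect_equal(unname(p$trans_m[3, ]), c((1 + 0.5) / 2, 0.5 / 2, 0),
               tolerance = 1e-12)
  expect_equal(unname(p$trans_d[2, ]), c((1 + 0.5) / 2, 0.5 / 2, 0),
               tolerance = 1e-12)
})

test_that("Viterbi and forward match exhaustive path enumeration", {
  set.seed(77)
  worst_v <- worst_f <- 0
  for (rep in 1:100) {
    p <- random_small_profile(max_match = 4)
    s <- random_protein(sample(0:6, 1))
    if (nchar(s) == 0) s <- "A"
    oracle <- hmm_enum_oracle(p, s)
    v <- viterbi_score(p, s)$bit_score
    f <- forward_score(p, s)
    worst_v <- max(worst_v, abs(v - oracle$viterbi))
    worst_f <- max(worst_f, abs(f - oracle$forward))
  }
  expect_lt(worst_v, 1e-9)
  expect_lt(worst_f, 1e-9)
})

test_that("forward dominates Viterbi and scoring is invariant to row order", {
  set.seed(78)
  for (rep in 1:20) {
    p <- random_small_profile()
    s <- random_protein(sample(1:8, 1))
    expect_gte(forward_score(p, s) + 1e-12, viterbi_score(p, s)$bit_score)
  }
  rows <- c("MKLVWY", "MKLVAY", "MRLVWY")
  p1 <- build_profile(msa(c("a", "b", "c"), rows))
  p2 <- build_profile(msa(c("c", "a", "b"), rows[c(3, 1, 2)]))
  s <- "MKLVWY"
  expect_equal(viterbi_score(p1, s)$bit_score, viterbi_score(p2, s)$bit_score)
  expect_equal(forward_score(p1, s), forward_score(p2, s))
})

test_that("the single-state concentrated profile approaches log2(20) bits", {
  p <- build_profile(msa("r1", "A"), pseudocount = 1e-12)
  expect_equal(viterbi_score(p, "A")$bit_score, log2(20), tolerance = 1e-6)
})

test_that("a consensus outscores its shuffle and long sequences stay finite", {
  m <- msa(paste0("r", 1:4),
           c("MGAQVSTQKTGAHETGLNAS", "MGAQVSTQKTGAHETGLNAS",
             "MGAQVSSQKTGAHETGMNAS", "MGAQVSTQKTGAHESGLNAS"))
  p <- build_profile(m)
  cons <- "MGAQVSTQKTGAHETGLNAS"
  set.seed(5)
  shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
  expect_gte(viterbi_score(p, cons)$bit_score, viterbi_score(p, shuf)$bit_score)
  long <- random_protein(10000)
  expect_true(is.finite(forward_score(p, long)))
})

test_that("database scanning ranks the training consensus first, reproducibly", {
  m <- msa(paste0("r", 1:3), rep("MGAQVSTQKTGAHETGLNAS", 3))
  p <- build_profile(m)
  set.seed(88)
  db <- seq_records(c("consensus", paste0("rand", 1:20)),
                    c("MGAQVSTQKTGAHETGLNAS",
                      replicate(20, random_protein(20))), "protein")
  hits1 <- scan_proteins(p, db, n_shuffles = 100, seed = 4)
  hits2 <- scan_proteins(p, db, n_shuffles = 100, seed = 4)
  expect_identical(hits1, hits2)
  expect_equal(hits1$target_id[1], "consensus")
  expect_true(all(hits1$empirical_p >= 1 / 101 & hits1$empirical_p <= 1))
  expect_lte(hits1$empirical_p[1], 0.02)
})

test_that("serialization round-trips scoring bit-exactly", {
  m <- msa(c("a", "b", "c"), c("MKLVWY--AC", "MKLVWYGG-C", "MKL-WYGGAC"))
  p <- build_profile(m, name = "toy")
  f <- withr::local_tempfile(fileext = ".prof")
  write_profile(p, f)
  p2 <- read_profile(f)
  s <- "MKLVWYGGAC"
  expect_identical(forward_score(p, s), forward_score(p2, s))
  expect_identical(viterbi_score(p, s)$bit_score,
                   viterbi_score(p2, s)$bit_score)
})

test_that("profiles rebuilt from sampled sequences recover modal residues", {
  # sample 50 gapless sequences from a known match-emission profile and
  # check that >= 90% of match states recover the modal residue
  set.seed(99)
  n_states <- 12
  modal <- sample(AA20_ORACLE, n_states, replace = TRUE)
  sample_seq <- function() {
    paste(vapply(seq_len(n_states), function(i) {
      if (runif(1) < 0.8) modal[i] else sample(AA20_ORACLE, 1)
    }, ""), collapse = "")
  }
  rows <- replicate(50, sample_seq())
  p <- build_profile(msa(paste0("s", 1:50), rows))
  expect_equal(p$n_match, n_states)
  got <- vapply(seq_len(n_states), function(i) {
    names(which.max(p$match_emissions[i, ]))
  }, "")
  expect_gte(mean(got == modal), 0.9)
})
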