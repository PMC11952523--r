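kd <- hydropathy_scale("kyte_doolittle")
eis <- hydropathy_scale("eisenberg_consensus")

test_that("windowed hydropathy equals direct re-summation", {
  # constant sequence and window = 1 limits
  expect_equal(hydropathy_profile(strrep("L", 25), kd, 5),
               rep(kd[["L"]], 21))
  p <- "MKWLVA"
  expect_equal(hydropathy_profile(p, kd, 1),
               unname(kd[strsplit(p, "")[[1]]]))
  expect_length(hydropathy_profile("MKL", kd, 19), 0)
  # random proteins against the oracle
  set.seed(21)
  for (rep in 1:20) {
    pr <- random_protein(40)
    expect_equal(hydropathy_profile(pr, kd, 19),
                 hydropathy_oracle(pr, kd, 19), tolerance = 1e-12)
  }
})

test_that("transmembrane detection finds a planted hydrophobic stretch", {
  p <- paste0(strrep("K", 4), strrep("L", 21), strrep("K", 4))
  seg <- detect_tm(p, kd)
  expect_equal(nrow(seg), 1)
  # derived by hand from the windowed means: every center passes, the
  # covered span is the whole 29-mer (within max_len so no clipping)
  expect_equal(seg$start_aa, 0L)
  expect_equal(seg$end_aa, 29L)
  expect_equal(seg$mean_hydropathy,
               (21 * kd[["L"]] + 8 * kd[["K"]]) / 29)

  expect_equal(nrow(detect_tm(strrep("K", 60), kd)), 0)
  expect_equal(nrow(detect_tm(strrep("L", 10), kd)), 0)  # window can't fit
})

test_that("poly-Ala exceeds the hydropathy threshold while poly-Gly does not", {
  # pins the threshold semantics: KD(A) = 1.8 >= 1.6, KD(G) = -0.4 < 1.6
  expect_equal(nrow(detect_tm(strrep("A", 30), kd)), 1)
  expect_equal(nrow(detect_tm(strrep("G", 30), kd)), 0)
})

test_that("long hydrophobic runs are clipped around the windowed maximum", {
  p <- paste0(strrep("S", 10), strrep("L", 45), strrep("S", 10))
  seg <- detect_tm(p, kd)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$end_aa - seg$start_aa, 30L)
})

test_that("detection is monotone in the threshold", {
  set.seed(31)
  hydrophilic <- c("K", "R", "D", "E", "S", "T", "N", "Q", "G", "P")
  for (rep in 1:20) {
    pr <- paste0(random_protein(20, hydrophilic),
                 strrep("I", sample(12:30, 1)),
                 random_protein(20, hydrophilic))
    lo <- detect_tm(pr, kd, threshold = 1.2)
    hi <- detect_tm(pr, kd, threshold = 2.0)
    expect_lte(nrow(hi), nrow(lo))
    expect_lte(sum(hi$end_aa - hi$start_aa), sum(lo$end_aa - lo$start_aa))
  }
})

test_that("topology follows the positive-inside rule", {
  tm <- list(start_aa = 4L, end_aa = 25L)
  p1 <- paste0("AAAA", strrep("L", 21), "KRKRAAAAA")
  expect_equal(infer_topology(p1, tm), "N_out_C_in")
  p2 <- paste0("KRKR", strrep("L", 21), "AAAAAAAAA")
  expect_equal(infer_topology(p2, tm), "N_in_C_out")
  p3 <- paste0("KRAA", strrep("L", 21), "AAKRAAAAA")
  expect_equal(infer_topology(p3, tm), "undetermined")
  # segment at the protein start: decided by the C side alone
  p4 <- paste0(strrep("L", 21), "KAAAA")
  expect_equal(infer_topology(p4, list(start_aa = 0L, end_aa = 21L)),
               "N_out_C_in")
})

test_that("myristoylation motif is the literal MGxxxS/T pattern", {
  expect_true(has_myristoylation_motif("MGAAASKLL"))
  expect_true(has_myristoylation_motif("MGAAATKLL"))
  expect_false(has_myristoylation_motif("MAGAAS"))
  expect_false(has_myristoylation_motif("MGAAAV"))
  expect_false(has_myristoylation_motif("MGAAA"))   # too short
  expect_false(has_myristoylation_motif("MGAAAX"))  # X never satisfies S/T
})

test_that("polybasic search matches the exhaustive window oracle", {
  hit <- find_polybasic("AAKRKAAA", 0L, 8L, window = 5)
  expect_equal(hit$kr_count, 3L)
  expect_true(hit$start <= 2 && hit$end >= 5)
  expect_null(find_polybasic("AAAAAA", 0L, 6L))
  # tie-break: earlier window wins
  two <- find_polybasic("KRKAAAAKRK", 0L, 10L, window = 3)
  expect_equal(two$start, 0L)
  set.seed(41)
  for (rep in 1:50) {
    pr <- random_protein(30, c("K", "R", "A", "S", "L", "E"))
    got <- find_polybasic(pr, 0L, 30L)
    want <- polybasic_oracle(pr, 0, 30)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$kr_count, want$kr_count)
      expect_equal(got$start, want$start)
    }
  }
})

test_that("hydrophobic moment matches the complex-exponential oracle", {
  zero <- setNames(rep(0, 20), AA20_ORACLE)
  zero["X"] <- 0
  expect_equal(hydrophobic_moment("MKWLV", zero), 0)
  expect_equal(hydrophobic_moment("W", eis), abs(eis[["W"]]))
  # periodic hydrophobics every 3-4 positions -> strong moment
  amphi <- "LSSALTTISSLNNVSSLA"
  expect_equal(hydrophobic_moment(amphi, eis),
               moment_oracle(amphi, eis), tolerance = 1e-9)
  set.seed(51)
  for (rep in 1:50) {
    pr <- random_protein(sample(1:25, 1))
    expect_equal(hydrophobic_moment(pr, eis), moment_oracle(pr, eis),
                 tolerance = 1e-9)
  }
})

test_that("moment is invariant to the window's offset in the protein", {
  set.seed(61)
  pr <- random_protein(11)
  host <- paste0(random_protein(13), pr, random_protein(9))
  expect_equal(hydrophobic_moment(substr(host, 14, 24), eis),
               hydrophobic_moment(pr, eis), tolerance = 1e-12)
})

test_that("max windowed moment matches the all-windows oracle", {
  expect_equal(max_window_moment("MKWLV", 0L, 5L, eis, window = 11), 0)
  homo <- strrep("L", 20)
  expect_equal(max_window_moment(homo, 0L, 20L, eis),
               hydrophobic_moment(strrep("L", 11), eis))
  set.seed(71)
  for (rep in 1:20) {
    pr <- random_protein(40)
    expect_equal(max_window_moment(pr, 0L, 40L, eis),
                 max_moment_oracle(pr, 0, 40, eis, 11), tolerance = 1e-9)
    s0 <- sample(0:10, 1); s1 <- sample(25:40, 1)
    expect_equal(max_window_moment(pr, s0, s1, eis),
                 max_moment_oracle(pr, s0, s1, eis, 11), tolerance = 1e-9)
  }
})

test_that("aromatic-belt Tyr is sought just downstream of the segment", {
  tm <- list(start_aa = 0L, end_aa = 21L)
  expect_true(aromatic_belt_tyr(paste0(strrep("L", 21), "YKKR"), tm))
  expect_false(aromatic_belt_tyr(paste0(strrep("L", 21), "KKRAAF"), tm))
  expect_false(aromatic_belt_tyr(strrep("L", 21), tm))  # nothing after
})

test_that("feature profiling partitions domains and is a pure function", {
  pl <- make_sorf2_protein(seed = 7)
  f1 <- profile_features(pl$protein)
  f2 <- profile_features(pl$protein)
  expect_identical(f1, f2)
  expect_true(f1$has_myristoylation)
  expect_equal(f1$tm_count, 1L)
  expect_equal(f1$topology, "N_out_C_in")
  expect_false(is.null(f1$polybasic))
  expect_equal(f1$ecto_len + (f1$tm$end_aa - f1$tm$start_aa) + f1$endo_len,
               nchar(pl$protein))
  expect_gte(f1$mu_h_ecto, 0)
  expect_gte(f1$mu_h_endo, 0)
  # no-TM convention: full-length ectodomain, flagged
  f3 <- profile_features(strrep("K", 60))
  expect_equal(f3$tm_count, 0L)
  expect_false(f3$partition_defined)
  expect_equal(f3$ecto_len, 60L)
  expect_equal(f3$endo_len, 0L)
})
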