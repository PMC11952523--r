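test_that("tiling arithmetic: full tiles plus a flagged remainder", {
  t1 <- tile_genome(c(chrA = 250000))
  expect_equal(nrow(t1), 3)
  expect_equal(t1$start, c(0, 100000, 200000))
  expect_equal(t1$end, c(100000, 200000, 250000))
  expect_equal(t1$remainder, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(tile_genome(c(chrB = 100000))), 1)
  t3 <- tile_genome(c(chrC = 50000))
  expect_equal(nrow(t3), 1)
  expect_true(t3$remainder)
})

test_that("composition counts merged, clipped coverage without double counting", {
  tiles <- tile_genome(c(chr1 = 200000))
  one <- data.frame(chrom = "chr1", start = 20000L, end = 80000L,
                    strand = ".", name = "a", group = "G1")
  comp <- compute_composition(tiles, one)
  expect_equal(comp$tiles$te_content, c(0.6, 0))
  # identical overlapping intervals, same group: counted once
  comp2 <- compute_composition(tiles, rbind(one, one))
  expect_equal(comp2$tiles$te_bp, comp$tiles$te_bp)
  expect_equal(comp2$group_bp, comp$group_bp)
  # interval spanning a tile boundary: bp split, total conserved
  span <- data.frame(chrom = "chr1", start = 90000L, end = 130000L,
                     strand = ".", name = "b", group = "G1")
  comp3 <- compute_composition(tiles, span)
  expect_equal(unname(comp3$group_bp[, "G1"]), c(10000, 30000))
  expect_equal(sum(comp3$group_bp), 40000)
})

test_that("clipped per-tile coverage conserves total merged coverage", {
  set.seed(123)
  tiles <- tile_genome(c(chr1 = 500000))
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    s <- sample.int(480000, n)
    iv <- data.frame(chrom = "chr1", start = s,
                     end = s + sample.int(30000, n), strand = ".",
                     name = paste0("iv", 1:n), group = "G")
    iv$end <- pmin(iv$end, 500000L)
    comp <- compute_composition(tiles, iv)
    # oracle: merged genomic coverage via sorted sweep
    o <- iv[order(iv$start), ]
    merged <- 0; cur_s <- o$start[1]; cur_e <- o$end[1]
    for (i in seq_len(nrow(o))[-1]) {
      if (o$start[i] <= cur_e) cur_e <- max(cur_e, o$end[i])
      else { merged <- merged + cur_e - cur_s; cur_s <- o$start[i]; cur_e <- o$end[i] }
    }
    merged <- merged + cur_e - cur_s
    expect_equal(sum(comp$group_bp[, "G"]), merged)
    expect_equal(sum(comp$tiles$te_bp), merged)
  }
})

test_that("exhaustive enrichment matches independent enumeration", {
  fx <- make_tile_fixture(
    list(G1 = c(80000, rep(10000, 7)), G2 = c(0, rep(60000, 7))),
    n_tiles = 8, target_tiles = 1)
  comp <- compute_composition(fx$tiles, fx$te_intervals)
  expect_equal(comp$tiles$te_content, fx$expected$te_content)
  er <- enrichment_test(comp, "G1", fx$target_tile_ids)
  expect_true(er$exhaustive)
  expect_equal(er$observed_stat, fx$expected$observed_stat)
  expect_equal(er$empirical_p, fx$expected$p_exhaustive)
  # dominant group in the single target tile, 8 background tiles: only the
  # target itself ties the observed statistic
  expect_equal(er$empirical_p, 2 / 9)
})

test_that("degenerate fixtures give p = 1", {
  # identical composition everywhere: every permuted value ties
  fx <- make_tile_fixture(list(G1 = rep(30000, 6), G2 = rep(40000, 6)),
                          n_tiles = 6, target_tiles = 2)
  comp <- compute_composition(fx$tiles, fx$te_intervals)
  er <- enrichment_test(comp, "G1", fx$target_tile_ids)
  expect_equal(er$empirical_p, 1)
  # group absent from the target tiles (one-sided): observed 0, p = 1
  fx2 <- make_tile_fixture(list(G1 = c(0, rep(20000, 5)),
                                G2 = rep(60000, 6)),
                           n_tiles = 6, target_tiles = 1)
  comp2 <- compute_composition(fx2$tiles, fx2$te_intervals)
  er2 <- enrichment_test(comp2, "G1", fx2$target_tile_ids)
  expect_equal(er2$observed_stat, 0)
  expect_equal(er2$empirical_p, 1)
  # group absent everywhere
  er3 <- enrichment_test(comp2, "NOPE", fx2$target_tile_ids)
  expect_equal(er3$observed_stat, 0)
  expect_equal(er3$empirical_p, 1)
})

test_that("background thresholds and errors behave as specified", {
  fx <- make_tile_fixture(list(G1 = c(80000, 10000, 70000, 60000)),
                          n_tiles = 4, target_tiles = 1)
  comp <- compute_composition(fx$tiles, fx$te_intervals)
  # tile 2 (10% content) is not background: targeting it must error
  expect_error(enrichment_test(comp, "G1", comp$tiles$tile_id[2]),
               "outside the background")
  expect_error(enrichment_test(comp, "G1", comp$tiles$tile_id[1],
                               min_content = 0.99), "no background")
})

test_that("sampled and exhaustive modes agree within Monte Carlo error", {
  set.seed(9)
  g1 <- sample(10000:60000, 12)
  fx <- make_tile_fixture(list(G1 = g1, G2 = 70000 - g1),
                          n_tiles = 12, target_tiles = c(1, 2, 3))
  comp <- compute_composition(fx$tiles, fx$te_intervals)
  # choose(12, 3) = 220 distinct target sets
  ex <- enrichment_test(comp, "G1", fx$target_tile_ids, n_perm = 500)
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 220L)
  sa <- enrichment_test(comp, "G1", fx$target_tile_ids, n_perm = 150,
                        seed = 2)
  expect_false(sa$exhaustive)
  se <- sqrt(ex$empirical_p * (1 - ex$empirical_p) / 150)
  expect_lt(abs(sa$empirical_p - ex$empirical_p), 3 * se + 2 / 150)
})

test_that("null-drawn targets give super-uniform empirical p", {
  # background of 12 equally TE-rich tiles with heterogeneous composition;
  # targets drawn from the background by the null mechanism itself
  set.seed(314)
  g1 <- sample(5000:55000, 12)
  fx <- make_tile_fixture(list(G1 = g1, G2 = 60000 - g1 + 10000),
                          n_tiles = 12, target_tiles = 1)
  comp <- compute_composition(fx$tiles, fx$te_intervals)
  bg_ids <- comp$tiles$tile_id
  ps <- vapply(1:300, function(i) {
    tgt <- sample(bg_ids, 2)
    enrichment_test(comp, "G1", tgt, n_perm = 200, seed = i)$empirical_p
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.05)
  expect_lte(mean(ps <= 0.10), 0.10)
})
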