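#' Partition chromosomes into fixed-width tiles
#'
#' Consecutive, non-overlapping windows of `tile_len` bp (100 kb by
#' default). A terminal remainder shorter than `tile_len` is kept but
#' flagged, and excluded from enrichment statistics by default.
#'
#' @param chrom_sizes two-column data frame (`chrom`, `size`) or named
#'   numeric vector of chromosome lengths.
#' @param tile_len tile width in bp.
#' @return data frame: `tile_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `remainder` (logical).
#' @export
tile_genome <- function(chrom_sizes, tile_len = 100000L) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- data.frame(chrom = names(chrom_sizes),
                              size = unname(chrom_sizes))
  }
  stopifnot(all(chrom_sizes$size > 0))
  rows <- list()
  for (i in seq_len(nrow(chrom_sizes))) {
    ch <- chrom_sizes$chrom[i]; sz <- chrom_sizes$size[i]
    starts <- seq(0L, sz - 1L, by = tile_len)
    ends <- pmin(starts + tile_len, sz)
    rows[[i]] <- data.frame(
      chrom = ch, start = as.integer(starts), end = as.integer(ends),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start
  out$remainder <- out$length < tile_len
  out$tile_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  rownames(out) <- NULL
  out[, c("tile_id", "chrom", "start", "end", "length", "remainder")]
}

# merged coverage (bp) of intervals clipped to [start, end), one chrom
.clipped_coverage <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo); e <- pmin(ends, hi)
  keep <- s < e
  if (!any(keep)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = s[keep] + 1L, end = e[keep]))
  sum(IRanges::width(ir))
}

#' Compute per-tile transposon composition
#'
#' Fills per-tile total TE coverage and per-group coverage. Overlapping
#' intervals of the same group are merged before counting (no double
#' counting within a group); groups are counted independently; total
#' coverage (`te_bp`) is the merged union over all intervals, so it can
#' never exceed the tile length. Intervals are clipped at tile boundaries
#' and the clipped pieces sum to the genomic coverage.
#'
#' @param tiles output of [tile_genome()].
#' @param te_intervals interval data frame with non-empty `group` labels.
#' @return list of class `tile_composition`: `tiles` (input plus `te_bp`,
#'   `te_content`) and `group_bp` (matrix, tiles x groups).
#' @export
compute_composition <- function(tiles, te_intervals) {
  groups <- sort(unique(te_intervals$group[nzchar(te_intervals$group)]))
  gm <- matrix(0L, nrow(tiles), length(groups),
               dimnames = list(tiles$tile_id, groups))
  te_bp <- integer(nrow(tiles))
  by_chrom <- split(te_intervals, te_intervals$chrom)
  for (i in seq_len(nrow(tiles))) {
    iv <- by_chrom[[tiles$chrom[i]]]
    if (is.null(iv) || nrow(iv) == 0) next
    te_bp[i] <- .clipped_coverage(iv$start, iv$end, tiles$start[i], tiles$end[i])
    for (g in unique(iv$group[nzchar(iv$group)])) {
      sub <- iv[iv$group == g, ]
      gm[i, g] <- .clipped_coverage(sub$start, sub$end,
                                    tiles$start[i], tiles$end[i])
    }
  }
  tiles$te_bp <- te_bp
  tiles$te_content <- te_bp / tiles$length
  structure(list(tiles = tiles, group_bp = gm), class = "tile_composition")
}

#' Permutation test for group enrichment in designated tiles
#'
#' Tests whether a TE group is over-represented in a designated set of
#' TE-rich tiles (e.g. the tiles of a piRNA master locus) relative to all
#' TE-rich tiles. The statistic is the group's fraction of total TE bp
#' aggregated over the target tiles. The null redraws `|targets|` tiles
#' uniformly without replacement from the background (all non-remainder
#' tiles with `te_content > min_content`) and recomputes the statistic;
#' `empirical_p = (1 + #{null >= observed}) / (n + 1)`, one-sided. When the
#' number of distinct target sets is at most `n_perm`, the null is
#' enumerated exhaustively instead of sampled.
#'
#' @param composition a [compute_composition()] result.
#' @param group group (column of `group_bp`) to test.
#' @param target_tile_ids tile ids of the designated tiles; must all pass
#'   the background content threshold.
#' @param min_content minimum `te_content` for the background (default 0.5,
#'   i.e. >50% transposon content).
#' @param n_perm permutations when sampling.
#' @param seed integer seed for the sampled mode.
#' @return list of class `enrichment_result`: `group`, `target_tile_ids`,
#'   `observed_stat`, `null_mean`, `null_sd`, `n_perm` (draws actually
#'   used), `exhaustive`, `empirical_p`.
#' @export
enrichment_test <- function(composition, group, target_tile_ids,
                            min_content = 0.5, n_perm = 10000L, seed = 1L) {
  tiles <- composition$tiles
  gm <- composition$group_bp
  bg_idx <- which(tiles$te_content > min_content & !tiles$remainder)
  if (!length(bg_idx)) stop("no background tiles exceed te_content ", min_content)
  bg_ids <- tiles$tile_id[bg_idx]
  if (!all(target_tile_ids %in% bg_ids)) {
    stop("target tiles outside the background: ",
         paste(setdiff(target_tile_ids, bg_ids), collapse = ", "))
  }
  g_bp <- if (group %in% colnames(gm)) gm[, group] else rep(0, nrow(tiles))
  t_bp <- tiles$te_bp
  names(g_bp) <- names(t_bp) <- tiles$tile_id
  stat <- function(ids) {
    tot <- sum(t_bp[ids])
    if (tot == 0) 0 else sum(g_bp[ids]) / tot
  }
  observed <- stat(target_tile_ids)
  k <- length(target_tile_ids)
  n_sets <- choose(length(bg_ids), k)
  if (is.finite(n_sets) && n_sets <= n_perm) {
    combos <- utils::combn(bg_ids, k, simplify = FALSE)
    null_stats <- vapply(combos, stat, numeric(1))
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    null_stats <- vapply(seq_len(n_perm), function(i) {
      stat(sample(bg_ids, k))
    }, numeric(1))
    exhaustive <- FALSE
  }
  n_used <- length(null_stats)
  p <- (1 + sum(null_stats >= observed)) / (n_used + 1)
  structure(list(group = group, target_tile_ids = target_tile_ids,
                 observed_stat = observed,
                 null_mean = mean(null_stats), null_sd = stats::sd(null_stats),
                 n_perm = n_used, exhaustive = exhaustive,
                 empirical_p = p), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: group %s, observed %.4f vs null %.4f +/- %.4f (%s n=%d), p = %.4g\n",
    x$group, x$observed_stat, x$null_mean, x$null_sd,
    if (x$exhaustive) "exhaustive" else "sampled", x$n_perm, x$empirical_p))
  invisible(x)
}
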