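# Seeded generators that emulate the statistical structure the pipeline
# assumes: planted short-fusogen ORFs with the canonical domain layout,
# feature-ablated decoys, TE-like nucleotide backbones with stop-codon
# seeding, toy genomes with insertion annotations, and tile fixtures with
# known group compositions. Every generator emits machine-readable ground
# truth next to the data and self-checks its own output.

HYDROPHOBIC_POOL <- c("L", "I", "V", "F", "A", "M")
POLAR_POOL <- c("S", "T", "N", "Q", "D", "E", "G")

#' Specification of a planted short-fusogen protein
#'
#' Encodes the canonical architecture: myristoylation-tagged ectodomain
#' (near-constant ~30 residues in known short fusogens), hydrophobic
#' single-pass transmembrane segment, interfacial Tyr, juxtamembrane
#' polybasic patch, and an amphipathic cytoplasmic tail. Amphipathicity is
#' emulated by placing a hydrophobic residue every 3-4 positions of the
#' ecto and tail segments (one helical face).
#'
#' @param ecto_len ectodomain length (default 30).
#' @param tm_len transmembrane length (default 21).
#' @param tm_residue_pool hydrophobic residues for the membrane span.
#' @param polybasic_len number of K/R residues after the Tyr (default 6).
#' @param tail_len cytoplasmic tail length after the polybasic patch.
#' @param myristoylation plant the MGxxxS/T motif (default `TRUE`).
#' @param amphipathic_period hydrophobic spacing pattern in ecto/tail,
#'   integer gaps cycled (default `c(3, 4)`).
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(ecto_len = 30L, tm_len = 21L,
                       tm_residue_pool = HYDROPHOBIC_POOL,
                       polybasic_len = 6L, tail_len = 20L,
                       myristoylation = TRUE,
                       amphipathic_period = c(3L, 4L)) {
  spec <- list(ecto_len = as.integer(ecto_len), tm_len = as.integer(tm_len),
               tm_residue_pool = tm_residue_pool,
               polybasic_len = as.integer(polybasic_len),
               tail_len = as.integer(tail_len),
               myristoylation = isTRUE(myristoylation),
               amphipathic_period = as.integer(amphipathic_period))
  total <- spec$ecto_len + spec$tm_len + 1L + spec$polybasic_len + spec$tail_len
  if (total < 50L || total > 250L) {
    stop("planted protein length ", total,
         " falls outside the pipeline's default 50-250 aa window")
  }
  spec$total_len <- total
  structure(spec, class = "plant_spec")
}

# amphipathic face positions (0-based) within a segment of length n
.amphi_positions <- function(n, period) {
  pos <- 0L; out <- integer(0); k <- 1L
  while (pos < n) {
    out <- c(out, pos)
    pos <- pos + period[(k - 1L) %% length(period) + 1L]
    k <- k + 1L
  }
  out
}

.amphi_segment <- function(n, period, polar_pool = POLAR_POOL,
                           hydro_pool = c("L", "I", "F", "V")) {
  res <- sample(polar_pool, n, replace = TRUE)
  hp <- .amphi_positions(n, period) + 1L
  res[hp] <- sample(hydro_pool, length(hp), replace = TRUE)
  res
}

#' Generate a planted short-fusogen protein
#'
#' Draws a protein realizing the [plant_spec()] architecture and
#' self-checks at generation time that it carries the features it claims
#' (single transmembrane segment, N-outside/C-inside topology, polybasic
#' patch, and the myristoylation motif when requested), redrawing up to
#' `max_tries` times.
#'
#' @param spec a [plant_spec()].
#' @param seed optional integer seed (uses the current RNG stream if
#'   `NULL`).
#' @param max_tries redraw budget for the self-check.
#' @return list with `protein` and `truth` (0-based half-open coordinates
#'   of `ecto`, `tm`, `tyr`, `polybasic`, `tail`, plus `myristoylation`).
#' @export
make_sorf2_protein <- function(spec = plant_spec(), seed = NULL,
                               max_tries = 50L) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    ecto <- .amphi_segment(spec$ecto_len, spec$amphipathic_period)
    ecto[1] <- "M"
    ecto[2] <- if (spec$myristoylation) "G" else "A"
    if (spec$ecto_len >= 6) {
      ecto[3:5] <- sample(c(POLAR_POOL, "A", "L"), 3, replace = TRUE)
      ecto[6] <- sample(c("S", "T"), 1)
    }
    tm <- sample(spec$tm_residue_pool, spec$tm_len, replace = TRUE)
    pb <- sample(c("K", "R"), spec$polybasic_len, replace = TRUE)
    tail <- .amphi_segment(spec$tail_len, spec$amphipathic_period,
                           polar_pool = c(POLAR_POOL, "K", "R"))
    protein <- paste(c(ecto, tm, "Y", pb, tail), collapse = "")
    f <- profile_features(protein)
    ok <- f$tm_count == 1 &&
      identical(f$topology, "N_out_C_in") &&
      !is.null(f$polybasic) &&
      f$has_myristoylation == spec$myristoylation
    if (ok) {
      e <- spec$ecto_len; t2 <- e + spec$tm_len
      truth <- list(ecto = c(0L, e), tm = c(e, t2), tyr = t2,
                    polybasic = c(t2 + 1L, t2 + 1L + spec$polybasic_len),
                    tail = c(t2 + 1L + spec$polybasic_len, spec$total_len),
                    myristoylation = spec$myristoylation)
      return(list(protein = protein, truth = truth))
    }
  }
  stop("could not generate a self-consistent planted protein in ",
       max_tries, " tries")
}

#' Generate a feature-ablated decoy protein
#'
#' Starts from a planted positive and ablates exactly one feature:
#' `tm_scrambled` replaces the membrane span with draws from the full
#' residue alphabet, rejection-sampled until no transmembrane segment is
#' detected; `no_myristoylation` mutates the position-2 Gly to Ala;
#' `no_polybasic` neutralises every K/R in the juxtamembrane window;
#' `topology_flipped` moves the polybasic patch to the N-terminal side of
#' the membrane span.
#'
#' @param spec a [plant_spec()] for the base protein.
#' @param ablate one of `"tm_scrambled"`, `"no_myristoylation"`,
#'   `"no_polybasic"`, `"topology_flipped"`.
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling budget.
#' @return list with `protein`, `truth` of the base, and `ablate`.
#' @export
make_decoy <- function(spec = plant_spec(), ablate = c(
                         "tm_scrambled", "no_myristoylation",
                         "no_polybasic", "topology_flipped"),
                       seed = NULL, max_tries = 1000L) {
  ablate <- match.arg(ablate)
  if (!is.null(seed)) set.seed(seed)
  base <- make_sorf2_protein(spec)
  res <- strsplit(base$protein, "")[[1]]
  tm0 <- base$truth$tm[1] + 1L; tm1 <- base$truth$tm[2]  # 1-based inclusive
  if (ablate == "tm_scrambled") {
    neutral <- setdiff(AA20, c("C"))
    for (try in seq_len(max_tries)) {
      cand <- res
      cand[tm0:tm1] <- sample(neutral, tm1 - tm0 + 1L, replace = TRUE)
      p <- paste(cand, collapse = "")
      if (nrow(detect_tm(p)) == 0) {
        return(list(protein = p, truth = base$truth, ablate = ablate))
      }
    }
    stop("rejection sampling failed after ", max_tries, " tries")
  }
  if (ablate == "no_myristoylation") {
    res[2] <- "A"
    p <- paste(res, collapse = "")
    stopifnot(!has_myristoylation_motif(p))
    return(list(protein = p, truth = base$truth, ablate = ablate))
  }
  n <- length(res)
  if (ablate == "no_polybasic") {
    # neutralise every basic residue C-terminal of the membrane span, then
    # restore two isolated lysines so the positive-inside topology is kept
    # while no window can ever reach the min_kr threshold (the detected
    # segment boundary may sit a few residues off the planted one, so the
    # whole tail is treated, not just the planted patch)
    cside <- (tm1 + 1L):n
    kr <- cside[res[cside] %in% c("K", "R")]
    res[kr] <- sample(POLAR_POOL, length(kr), replace = TRUE)
    keep_k <- c(tm1 + 3L, tm1 + 12L)
    res[keep_k[keep_k <= n]] <- "K"
    p <- paste(res, collapse = "")
    f <- profile_features(p)
    stopifnot(is.null(f$polybasic))
    return(list(protein = p, truth = base$truth, ablate = ablate))
  }
  # topology_flipped: basic patch moved to the N-side of the membrane span,
  # and the whole C-side stripped of K/R so the positive-inside rule cannot
  # call N-outside whatever boundary the detector settles on
  npb <- spec$polybasic_len
  res[(tm0 - npb):(tm0 - 1L)] <- sample(c("K", "R"), npb, replace = TRUE)
  cside <- (tm1 + 1L):n
  kr <- cside[res[cside] %in% c("K", "R")]
  res[kr] <- sample(POLAR_POOL, length(kr), replace = TRUE)
  p <- paste(res, collapse = "")
  f <- profile_features(p)
  stopifnot(!identical(f$topology, "N_out_C_in"))
  list(protein = p, truth = base$truth, ablate = ablate)
}

# uniform synonymous reverse translation (stop excluded)
.encode_protein <- function(protein) {
  tab <- codon_table()
  by_aa <- split(names(tab), tab)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    if (!a %in% names(by_aa) || a == "*") stop("cannot encode residue ", a)
    sample(by_aa[[a]], 1)
  }, ""), collapse = "")
}

# random backbone with stop codons seeded in all 3 frames at least every
# `stop_every` nt so spurious ORFs stay short; stop positions sit on a
# fixed non-overlapping lattice (offsets 0/7/14 within each period) so the
# three frames never clobber each other's stops
.make_backbone <- function(len, stop_every = 90L) {
  nt <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    offset <- frame * 7L  # 0, 7, 14: in frame (mod 3) and >= 3 nt apart
    at <- seq(offset, len - 3L, by = stop_every)
    at <- at[at + 3L <= len]
    for (s in at) {
      nt[(s + 1L):(s + 3L)] <- strsplit(sample(stops, 1), "")[[1]]
    }
  }
  nt
}

#' Embed an encoded protein ORF in a synthetic backbone
#'
#' Reverse-translates the protein with uniform synonymous codon choice
#' (ATG start by construction, TAA stop appended) and plants it at the
#' requested position in a random nucleotide backbone whose other frames
#' are interrupted by seeded stop codons, so no spurious ORF reaches the
#' pipeline's length window. Optionally appends a long downstream pol-like
#' ORF so hits can be placed relative to it. Self-checks that a default
#' scan recovers exactly the planted ORF, redrawing the backbone if not.
#'
#' @param protein protein string to plant.
#' @param backbone_len total backbone length (>= ORF span + position).
#' @param position 0-based start of the planted ORF.
#' @param seed optional integer seed.
#' @param with_pol also plant a long (301-codon) downstream pol-like ORF.
#' @param id record id.
#' @param self_check verify recovery by [scan_consensus()] (default
#'   `TRUE`).
#' @param max_tries backbone redraw budget for the self-check.
#' @return list with `record` (nucleotide sequence-record row),
#'   `orf_interval` (`c(start, end)`, 0-based half-open, stop included),
#'   `pol_interval` (or `NULL`), and `protein`.
#' @export
embed_orf <- function(protein, backbone_len = 2000L, position = 300L,
                      seed = NULL, with_pol = FALSE, id = "synthetic",
                      self_check = TRUE, max_tries = 20L) {
  if (!is.null(seed)) set.seed(seed)
  orf_len <- 3L * (nchar(protein) + 1L)
  pol_codons <- 301L
  pol_len <- 3L * (pol_codons + 1L)
  pol_gap <- 60L
  need <- position + orf_len + if (with_pol) pol_gap + pol_len else 0L
  if (need > backbone_len) {
    stop("backbone of ", backbone_len, " nt cannot hold the planted ORF(s) (need ",
         need, ")")
  }
  for (try in seq_len(max_tries)) {
    nt <- .make_backbone(backbone_len)
    orf_nt <- paste0(.encode_protein(protein), "TAA")
    nt[(position + 1L):(position + orf_len)] <- strsplit(orf_nt, "")[[1]]
    if (position >= 3L) {
      # in-frame stop just upstream so no backbone ATG can absorb the plant
      nt[(position - 2L):position] <- c("T", "A", "A")
    }
    pol_interval <- NULL
    if (with_pol) {
      pol_start <- position + orf_len + pol_gap
      # long ORF: ATG + non-stop random codons + TAA; length > max_aa so it
      # can never pass the short-ORF length filter
      tab <- codon_table()
      non_stop <- names(tab)[tab != "*"]
      pol_nt <- paste0("ATG", paste(sample(non_stop, pol_codons - 1L,
                                           replace = TRUE), collapse = ""), "TAA")
      nt[(pol_start + 1L):(pol_start + pol_len)] <- strsplit(pol_nt, "")[[1]]
      pol_interval <- c(pol_start, pol_start + pol_len)
    }
    rec <- seq_records(id, paste(nt, collapse = ""), "nucleotide")
    if (!self_check) {
      return(list(record = rec, orf_interval = c(position, position + orf_len),
                  pol_interval = pol_interval, protein = protein))
    }
    hits <- scan_consensus(rec)
    if (nrow(hits) == 1 && hits$nt_start == position &&
        hits$nt_end == position + orf_len && hits$protein == protein) {
      return(list(record = rec, orf_interval = c(position, position + orf_len),
                  pol_interval = pol_interval, protein = protein))
    }
  }
  stop("could not embed the ORF with clean recovery in ", max_tries, " tries")
}

#' Seeded benchmark of planted consensus sequences
#'
#' One planted positive per backbone at a random position, defaults per
#' [plant_spec()]. The ground truth records the planted interval and
#' protein for each record.
#'
#' @param n_backbones number of synthetic consensus sequences.
#' @param seed integer seed.
#' @param backbone_len backbone length.
#' @param spec a [plant_spec()].
#' @param self_check passed to [embed_orf()] (default `TRUE`).
#' @return list with `records` (sequence-record data frame) and `truth`
#'   (data frame `id`, `nt_start`, `nt_end`, `protein`).
#' @export
make_benchmark <- function(n_backbones = 300L, seed = 1L,
                           backbone_len = 1500L, spec = plant_spec(),
                           self_check = FALSE) {
  set.seed(seed)
  recs <- vector("list", n_backbones)
  truth <- vector("list", n_backbones)
  for (i in seq_len(n_backbones)) {
    pl <- make_sorf2_protein(spec)
    orf_len <- 3L * (nchar(pl$protein) + 1L)
    pos <- 3L * sample.int((backbone_len - orf_len - 60L) %/% 3L, 1)
    emb <- embed_orf(pl$protein, backbone_len, pos, id = sprintf("bb%04d", i),
                     self_check = self_check)
    recs[[i]] <- emb$record
    truth[[i]] <- data.frame(id = emb$record$id,
                             nt_start = emb$orf_interval[1],
                             nt_end = emb$orf_interval[2],
                             protein = pl$protein, stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
}

#' Generate a toy genome with annotated insertions
#'
#' Random chromosomes carrying non-overlapping TE-like insertions on both
#' strands; a configurable fraction of insertions carry a planted
#' short-fusogen ORF. Minus-strand insertions are placed as the reverse
#' complement of the element, so extraction must re-orient them.
#'
#' @param n_chroms number of chromosomes.
#' @param n_insertions total insertions.
#' @param fraction_positive fraction carrying a planted ORF.
#' @param seed integer seed.
#' @param spec a [plant_spec()].
#' @return list with `genome` (sequence records), `intervals` (interval
#'   data frame with `group` = family), and `truth` (data frame with
#'   `name`, `positive`).
#' @export
make_toy_genome <- function(n_chroms = 2L, n_insertions = 10L,
                            fraction_positive = 0.5, seed = 1L,
                            spec = plant_spec()) {
  set.seed(seed)
  element_len <- 1200L
  gap <- 200L
  per_chrom <- ceiling(n_insertions / n_chroms)
  chrom_len <- per_chrom * (element_len + gap) + gap
  genome <- lapply(seq_len(n_chroms), function(c) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  })
  families <- c("FamA", "FamB", "FamC")
  n_pos <- round(fraction_positive * n_insertions)
  positive <- sample(rep(c(TRUE, FALSE),
                         c(n_pos, n_insertions - n_pos)))
  ivs <- list(); truth <- list()
  for (k in seq_len(n_insertions)) {
    ci <- ((k - 1L) %% n_chroms) + 1L
    slot <- (k - 1L) %/% n_chroms
    start <- gap + slot * (element_len + gap)
    if (positive[k]) {
      pl <- make_sorf2_protein(spec)
      emb <- embed_orf(pl$protein, element_len, 300L, id = "tmp",
                       self_check = TRUE)
      element <- emb$record$seq
    } else {
      element <- paste(.make_backbone(element_len), collapse = "")
    }
    strand <- sample(c("+", "-"), 1)
    placed <- if (strand == "-") reverse_complement(element) else element
    g <- genome[[ci]]
    genome[[ci]] <- paste0(substr(g, 1, start),
                           placed,
                           substr(g, start + element_len + 1L, nchar(g)))
    nm <- sprintf("ins%03d", k)
    ivs[[k]] <- data.frame(chrom = paste0("chr", ci), start = start,
                           end = start + element_len, strand = strand,
                           name = nm, group = sample(families, 1),
                           stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(name = nm, positive = positive[k],
                             stringsAsFactors = FALSE)
  }
  list(genome = seq_records(paste0("chr", seq_len(n_chroms)),
                            unlist(genome), "nucleotide"),
       intervals = do.call(rbind, ivs),
       truth = do.call(rbind, truth))
}

#' Generate a tile fixture with known group composition
#'
#' Emits a chromosome-size table and TE intervals realizing the requested
#' per-tile per-group coverage exactly (groups stacked without overlap
#' within each tile), a designated target-tile set, and the analytic
#' expectation for the exhaustive-mode enrichment test computed by direct
#' enumeration over all target-set choices, independent of the package's
#' test implementation.
#'
#' @param compositions named list: one numeric vector of bp per group,
#'   each of length `n_tiles`.
#' @param n_tiles number of tiles (one chromosome).
#' @param target_tiles integer indices of the designated tiles.
#' @param test_group group for the analytic expectation (default: first).
#' @param tile_len tile width.
#' @return list with `chrom_sizes`, `te_intervals`, `tiles` (via
#'   [tile_genome()]), `target_tile_ids`, and `expected`
#'   (`te_content`, `observed_stat`, `p_exhaustive`).
#' @export
make_tile_fixture <- function(compositions, n_tiles = 8L,
                              target_tiles = 1L, test_group = NULL,
                              tile_len = 100000L) {
  groups <- names(compositions)
  stopifnot(length(groups) >= 1,
            all(vapply(compositions, length, 0L) == n_tiles))
  tot <- Reduce(`+`, compositions)
  stopifnot(all(tot <= tile_len))
  if (is.null(test_group)) test_group <- groups[1]
  ivs <- list()
  for (t in seq_len(n_tiles)) {
    offset <- (t - 1L) * tile_len
    for (g in groups) {
      bp <- compositions[[g]][t]
      if (bp > 0) {
        ivs[[length(ivs) + 1L]] <- data.frame(
          chrom = "chr1", start = offset, end = offset + bp,
          strand = ".", name = paste0(g, "_t", t), group = g,
          stringsAsFactors = FALSE)
        offset <- offset + bp
      }
    }
  }
  chrom_sizes <- data.frame(chrom = "chr1", size = n_tiles * tile_len)
  tiles <- tile_genome(chrom_sizes, tile_len)
  target_ids <- tiles$tile_id[target_tiles]
  # analytic expectation by direct enumeration over target-set choices,
  # computed from the requested numbers (not via compute_composition)
  g_bp <- compositions[[test_group]]
  t_bp <- tot
  stat <- function(idx) {
    s <- sum(t_bp[idx]); if (s == 0) 0 else sum(g_bp[idx]) / s
  }
  obs <- stat(target_tiles)
  bg <- which(t_bp / tile_len > 0.5)
  p_exh <- NA_real_
  if (all(target_tiles %in% bg)) {
    combos <- utils::combn(bg, length(target_tiles), simplify = FALSE)
    nulls <- vapply(combos, stat, numeric(1))
    p_exh <- (1 + sum(nulls >= obs)) / (length(nulls) + 1)
  }
  list(chrom_sizes = chrom_sizes, te_intervals = do.call(rbind, ivs),
       tiles = tiles, target_tile_ids = target_ids,
       expected = list(te_content = tot / tile_len, observed_stat = obs,
                       p_exhaustive = p_exh))
}
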