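#' Extract annotated insertions from a genome
#'
#' Sub-sequences are taken with the internal 0-based half-open convention;
#' minus-strand insertions are reverse-complemented so every element reads
#' 5' to 3' before scanning. The TE family comes from the interval group
#' label.
#'
#' @param genome nucleotide sequence-record data frame (chromosomes).
#' @param intervals interval data frame (`chrom`, `start`, `end`, `strand`,
#'   `name`, `group`).
#' @return sequence-record data frame with one row per insertion
#'   (`id = name`, or `chrom:start-end` when the name is empty) and extra
#'   columns `chrom`, `start`, `end`, `strand`, `family`.
#' @export
extract_insertions <- function(genome, intervals) {
  chrom_seq <- setNames(genome$seq, genome$id)
  n <- nrow(intervals)
  seqs <- character(n); ids <- character(n)
  for (i in seq_len(n)) {
    iv <- intervals[i, ]
    if (!iv$chrom %in% names(chrom_seq)) {
      stop("interval ", iv$chrom, ":", iv$start, "-", iv$end,
           " references an unknown chromosome")
    }
    L <- nchar(chrom_seq[[iv$chrom]])
    if (iv$start < 0 || iv$end > L) {
      stop("interval ", iv$chrom, ":", iv$start, "-", iv$end,
           " exceeds chromosome length ", L)
    }
    s <- substr(chrom_seq[[iv$chrom]], iv$start + 1L, iv$end)
    if (identical(iv$strand, "-")) s <- reverse_complement(s)
    seqs[i] <- s
    ids[i] <- if (nzchar(iv$name)) iv$name
              else paste0(iv$chrom, ":", iv$start, "-", iv$end)
  }
  out <- seq_records(make.unique(ids), seqs, "nucleotide")
  out$chrom <- intervals$chrom
  out$start <- intervals$start
  out$end <- intervals$end
  out$strand <- intervals$strand
  out$family <- intervals$group
  out
}

#' Scan genome insertions for short-fusogen candidates
#'
#' Runs [scan_consensus()] on each extracted insertion in the forward
#' orientation of the element. The counting unit is the insertion: one
#' insertion with several passing ORFs counts once (a per-ORF count is
#' also reported). Duplicate loci (same chrom/start/end) can be collapsed
#' before counting.
#'
#' @param insertions output of [extract_insertions()].
#' @param config a [filter_config()].
#' @param dedupe collapse duplicate (chrom, start, end) loci first.
#' @return list of class `scan_summary`: `total_insertions`,
#'   `insertions_with_hits`, `total_passing_orfs`, `per_family` (data
#'   frame `family`, `n_insertions`, `n_with_hits`), and `hits` (per-ORF
#'   hit table with insertion metadata).
#' @export
scan_insertions <- function(insertions, config = filter_config(),
                            dedupe = TRUE) {
  ins <- insertions
  if (dedupe && nrow(ins) > 0) {
    key <- paste(ins$chrom, ins$start, ins$end)
    ins <- ins[!duplicated(key), , drop = FALSE]
  }
  hit_tabs <- list()
  has_hit <- logical(nrow(ins))
  for (i in seq_len(nrow(ins))) {
    h <- scan_consensus(ins[i, c("id", "desc", "alphabet", "seq"), drop = FALSE],
                        config)
    has_hit[i] <- nrow(h) > 0
    if (nrow(h) > 0) {
      h$chrom <- ins$chrom[i]; h$insertion_start <- ins$start[i]
      h$insertion_end <- ins$end[i]; h$insertion_strand <- ins$strand[i]
      h$family <- ins$family[i]
      hit_tabs[[length(hit_tabs) + 1L]] <- h
    }
  }
  hits <- if (length(hit_tabs)) do.call(rbind, hit_tabs) else NULL
  fam <- if (nrow(ins) > 0) {
    agg <- aggregate(cbind(n_insertions = rep(1L, nrow(ins)),
                           n_with_hits = as.integer(has_hit)),
                     by = list(family = ins$family), FUN = sum)
    agg[order(agg$family), , drop = FALSE]
  } else {
    data.frame(family = character(0), n_insertions = integer(0),
               n_with_hits = integer(0))
  }
  structure(list(
    total_insertions = nrow(ins),
    insertions_with_hits = sum(has_hit),
    total_passing_orfs = if (is.null(hits)) 0L else nrow(hits),
    per_family = fam, hits = hits), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("scan_summary:", x$insertions_with_hits, "of", x$total_insertions,
      "insertions carry candidate ORFs (", x$total_passing_orfs,
      "passing ORFs )\n")
  invisible(x)
}

#' @importFrom stats aggregate
NULL
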