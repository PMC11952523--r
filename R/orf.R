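# Standard genetic code (NCBI table 1), taken from Biostrings at load time.
.codon_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$tab <- setNames(as.character(gc), names(gc))
  }
  .codon_env$tab
}

#' Translate an in-frame nucleotide string
#'
#' Standard genetic code; stop codons become `*`; any codon containing a
#' letter other than A/C/G/T (e.g. the ambiguity letter N) becomes `X`.
#'
#' @param codons nucleotide string whose length is divisible by 3.
#' @return protein string of length `nchar(codons)/3`.
#' @export
translate_codons <- function(codons) {
  codons <- toupper(codons)
  n <- nchar(codons)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  if (n == 0) return("")
  starts <- seq(1L, n, by = 3L)
  cods <- substring(codons, starts, starts + 2L)
  tab <- codon_table()
  aa <- tab[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.as_record <- function(record, need = c("nucleotide", "protein")) {
  need <- match.arg(need)
  if (is.character(record) && length(record) == 1) {
    return(list(id = "seq", seq = toupper(record), alphabet = need))
  }
  rec <- as.list(record[1, , drop = FALSE])
  if (!is.null(rec$alphabet) && rec$alphabet != need) {
    stop("expected a ", need, " record, got ", rec$alphabet)
  }
  rec$seq <- toupper(rec$seq[[1]])
  rec$id <- rec$id[[1]]
  rec
}

# ORFs on the forward strand of one oriented sequence. Returns 0-based
# half-open coordinates on that orientation.
.orfs_one_strand <- function(seq, min_aa, max_aa, overlap_policy) {
  n <- nchar(seq)
  out <- list()
  tab <- codon_table()
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3L
    if (n_cod < 1) next
    starts <- frame + 3L * (seq_len(n_cod) - 1L) + 1L  # 1-based substring starts
    cods <- substring(seq, starts, starts + 2L)
    aa <- tab[cods]
    aa[is.na(aa)] <- "X"
    is_stop <- aa == "*"
    is_start <- cods == "ATG"
    # segment id: index of the stop codon (or n_cod+1 for the open tail)
    stop_idx <- which(is_stop)
    seg_end <- c(stop_idx, if (length(stop_idx) == 0 || stop_idx[length(stop_idx)] < n_cod) n_cod + 1L)
    seg_begin <- c(1L, head(stop_idx, -1) + 1L)[seq_along(seg_end)]
    if (length(seg_end) > length(stop_idx)) {
      seg_begin[length(seg_end)] <- if (length(stop_idx)) stop_idx[length(stop_idx)] + 1L else 1L
    }
    for (si in seq_along(seg_end)) {
      e <- seg_end[si]; b <- seg_begin[si]
      open_ended <- e > n_cod || !is_stop[e]
      last_aa <- if (open_ended) n_cod else e - 1L
      if (last_aa < b) next
      m_pos <- which(is_start[b:last_aa]) + b - 1L
      if (!length(m_pos)) next
      if (overlap_policy == "longest_per_stop") m_pos <- m_pos[1]
      for (m in m_pos) {
        len_aa <- last_aa - m + 1L
        if (len_aa < min_aa || len_aa > max_aa) next
        nt_start <- frame + 3L * (m - 1L)
        nt_end <- if (open_ended) frame + 3L * last_aa else frame + 3L * e
        out[[length(out) + 1L]] <- list(
          frame = frame, nt_start = nt_start, nt_end = nt_end,
          open_ended = open_ended,
          protein = paste(aa[m:last_aa], collapse = ""),
          length_aa = len_aa)
      }
    }
  }
  out
}

#' Enumerate ATG-initiated open reading frames
#'
#' Every ORF starts at an ATG and runs to the first in-frame stop codon
#' (TAA/TAG/TGA) or, if none occurs before the sequence end, to the last
#' full codon (then flagged `open_ended`, since consensus sequences may be
#' truncated). Coordinates are 0-based half-open on the forward strand of
#' the parent and include the stop codon when present.
#'
#' @param record nucleotide sequence record (string or one-row record data
#'   frame).
#' @param strand_mode `"forward"` (default; candidate small ORFs lie in the
#'   forward orientation of the element) or `"both"`.
#' @param min_aa,max_aa length window in amino acids (defaults 50 and 250,
#'   spanning the known short-fusogen range with margin).
#' @param start_policy only `"atg_only"` is supported (canonical starts).
#' @param overlap_policy `"longest_per_stop"` keeps the 5'-most ATG per
#'   (strand, stop) pair; `"all"` keeps every ATG.
#' @return data frame of ORF candidates: `parent_id`, `strand`, `frame`,
#'   `nt_start`, `nt_end`, `open_ended`, `protein` (no stop symbol),
#'   `length_aa`; sorted by (strand, nt_start).
#' @export
find_orfs <- function(record, strand_mode = c("forward", "both"),
                      min_aa = 50L, max_aa = 250L,
                      start_policy = "atg_only",
                      overlap_policy = c("longest_per_stop", "all")) {
  strand_mode <- match.arg(strand_mode)
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(identical(start_policy, "atg_only"), min_aa >= 1, min_aa <= max_aa)
  rec <- .as_record(record, "nucleotide")
  n <- nchar(rec$seq)

  rows <- list()
  fwd <- .orfs_one_strand(rec$seq, min_aa, max_aa, overlap_policy)
  for (o in fwd) rows[[length(rows) + 1L]] <- c(o, strand = "+")
  if (strand_mode == "both") {
    rev <- .orfs_one_strand(reverse_complement(rec$seq), min_aa, max_aa,
                            overlap_policy)
    for (o in rev) {
      # map back to forward-strand coordinates of the parent
      s <- n - o$nt_end; e <- n - o$nt_start
      o$nt_start <- s; o$nt_end <- e
      rows[[length(rows) + 1L]] <- c(o, strand = "-")
    }
  }
  if (!length(rows)) {
    return(data.frame(parent_id = character(0), strand = character(0),
                      frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), open_ended = logical(0),
                      protein = character(0), length_aa = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    parent_id = rec$id,
    strand = vapply(rows, `[[`, "", "strand"),
    frame = vapply(rows, `[[`, 0L, "frame"),
    nt_start = vapply(rows, `[[`, 0L, "nt_start"),
    nt_end = vapply(rows, `[[`, 0L, "nt_end"),
    open_ended = vapply(rows, `[[`, FALSE, "open_ended"),
    protein = vapply(rows, `[[`, "", "protein"),
    length_aa = vapply(rows, `[[`, 0L, "length_aa"),
    stringsAsFactors = FALSE)
  df <- df[order(df$strand, df$nt_start, df$nt_end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
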