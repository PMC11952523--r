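#' @importFrom utils read.table write.table
#' @importFrom stats setNames
NULL

NUC_LETTERS  <- strsplit("ACGTUNRYSWKMBDHV", "")[[1]]
PROT_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYXBZJUO*", "")[[1]]
AA20         <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a set of sequence records
#'
#' The common container for nucleotide and protein sequences throughout the
#' package: a data frame with one row per sequence and columns `id`, `desc`,
#' `alphabet`, `seq`. Residues are upper-cased; an `alphabet_ok` column flags
#' records whose letters are inconsistent with the declared alphabet
#' (flagged, never silently coerced).
#'
#' @param id character vector of non-empty, unique identifiers.
#' @param seq character vector of residue strings.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param desc optional description strings (text after the first whitespace
#'   of a FASTA header).
#' @return data frame with columns `id`, `desc`, `alphabet`, `seq`,
#'   `alphabet_ok`.
#' @export
seq_records <- function(id, seq, alphabet = c("nucleotide", "protein"),
                        desc = "") {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seq <- toupper(as.character(seq))
  allowed <- if (alphabet == "nucleotide") NUC_LETTERS else PROT_LETTERS
  ok <- vapply(seq, function(s) {
    all(strsplit(s, "")[[1]] %in% allowed)
  }, logical(1), USE.NAMES = FALSE)
  if (any(!ok)) {
    warning("record(s) with letters outside the ", alphabet, " alphabet: ",
            paste(id[!ok], collapse = ", "))
  }
  data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
             alphabet = rep(alphabet, length(id)), seq = seq,
             alphabet_ok = ok, stringsAsFactors = FALSE)
}

#' Read a FASTA file
#'
#' Order is preserved, residues are upper-cased, and the description after
#' the first whitespace of each header is kept in `desc`.
#'
#' @param path path to a FASTA file.
#' @param alphabet declared alphabet of the file, `"nucleotide"` or
#'   `"protein"`.
#' @return a sequence-record data frame (see [seq_records()]); empty (zero
#'   rows) with a warning if the file holds no records.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- function() {
    warning("no sequences in ", path)
    seq_records(character(0), character(0), alphabet)
  }
  if (file.size(path) == 0) return(empty())
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) return(empty())
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(ss), alphabet, desc)
}

#' Write sequence records as FASTA
#'
#' @param records a sequence-record data frame.
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i])) paste(records$id[i], records$desc[i])
           else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq nucleotide string (IUPAC letters allowed).
#' @return reverse complement, upper case.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Read genomic intervals from BED6 or GFF3
#'
#' Internal coordinates are 0-based half-open everywhere in the package;
#' conversion happens only here. BED is taken verbatim; GFF3 starts are
#' decremented by one (GFF3 is 1-based inclusive). The transposon
#' group/family label is taken from a configurable GFF3 attribute key, or,
#' for BED, from the suffix after the last `#` in the name column
#' (RepeatMasker-style `name#family`), else left empty.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"gff3"`.
#' @param group_attr GFF3 attribute key naming the TE group (default
#'   `"group"`); ignored for BED.
#' @return data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `group` (0-based half-open coordinates).
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3"),
                           group_attr = "group") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0), group = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "bed") {
    out <- data.frame(
      chrom  = vapply(fields, `[`, "", 1),
      start  = as.integer(vapply(fields, `[`, "", 2)),
      end    = as.integer(vapply(fields, `[`, "", 3)),
      strand = vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", ""),
      name   = vapply(fields, function(f) if (length(f) >= 4) f[4] else "", ""),
      stringsAsFactors = FALSE)
    out$group <- ifelse(grepl("#", out$name),
                        sub("^.*#", "", out$name), "")
  } else {
    attrs <- vapply(fields, function(f) if (length(f) >= 9) f[9] else "", "")
    pick_attr <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)\\s*", key, "=([^;]*)"), a))[[1]]
      if (length(m) == 2) m[2] else ""
    }
    out <- data.frame(
      chrom  = vapply(fields, `[`, "", 1),
      start  = as.integer(vapply(fields, `[`, "", 4)) - 1L,
      end    = as.integer(vapply(fields, `[`, "", 5)),
      strand = vapply(fields, function(f) if (length(f) >= 7) f[7] else ".", ""),
      name   = vapply(attrs, pick_attr, "", key = "ID", USE.NAMES = FALSE),
      group  = vapply(attrs, pick_attr, "", key = group_attr, USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  }
  bad <- which(!(out$start < out$end) | out$start < 0L | is.na(out$start) | is.na(out$end))
  if (length(bad)) {
    stop("invalid interval (start >= end after conversion) at line ",
         lineno[bad[1]], " of ", path)
  }
  out$strand[!out$strand %in% c("+", "-")] <- "."
  rownames(out) <- NULL
  out
}

#' Write intervals as BED6
#'
#' Internal 0-based half-open coordinates are emitted verbatim (BED shares
#' the convention).
#'
#' @param intervals interval data frame as from [read_intervals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- intervals$name
  if (!is.null(intervals$group)) {
    name <- ifelse(nzchar(intervals$group),
                   paste0(name, "#", intervals$group), name)
  }
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   name, 0L,
                   ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "."))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tab-separated report
#'
#' Deterministic TSV with a header line and stable column order. Coordinate
#' columns named `start` or ending in `_start` are converted from the
#' internal 0-based half-open convention to 1-based inclusive for the
#' report (end columns are numerically identical in both conventions).
#'
#' @param rows data frame sharing one schema.
#' @param path output path.
#' @param convert_coords convert start columns to 1-based (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, convert_coords = TRUE) {
  rows <- as.data.frame(rows)
  if (convert_coords) {
    for (cn in names(rows)) {
      if (cn == "start" || grepl("_start$", cn)) {
        rows[[cn]] <- rows[[cn]] + 1L
      }
    }
  }
  ok <- tryCatch({
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to ", path)
  invisible(path)
}

#' Read a protein multiple sequence alignment
#'
#' Aligned FASTA or Stockholm. All rows must share one length; only protein
#' letters, `.` and `-` are accepted (`.` is normalised to `-`).
#'
#' @param path file path.
#' @param format `"fasta"` or `"stockholm"`; default guesses from the first
#'   line (`# STOCKHOLM` header).
#' @return an `msa` object: list with `id` (character) and `rows`
#'   (character, aligned, equal length).
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    return(msa(ids, gsub("\\.", "-", toupper(as.character(ss)))))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines)) & !grepl("^//", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[`, "", 1)
  seqs <- vapply(parts, `[`, "", 2)
  agg <- tapply(seqs, factor(ids, levels = unique(ids)), paste, collapse = "")
  msa(names(agg), gsub("\\.", "-", toupper(unname(agg))))
}

#' Construct a multiple sequence alignment object
#'
#' @param id row identifiers.
#' @param rows aligned residue strings with `-` gaps, equal length.
#' @return object of class `msa`.
#' @export
msa <- function(id, rows) {
  rows <- toupper(as.character(rows))
  if (!length(rows)) stop("empty MSA")
  w <- unique(nchar(rows))
  if (length(w) != 1 || w == 0) stop("MSA rows must share one positive length")
  letters_ok <- all(strsplit(paste(rows, collapse = ""), "")[[1]] %in% c(AA20, "X", "-"))
  if (!letters_ok) stop("MSA rows contain non-protein letters")
  structure(list(id = as.character(id), rows = rows, width = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$rows), "rows x", x$width, "columns\n")
  invisible(x)
}
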