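#' Composite filter configuration
#'
#' Mirrors the published search criteria by default: a candidate must fall
#' in the length window and carry exactly one predicted transmembrane
#' segment plus the N-myristoylation motif. Topology, polybasic patch and
#' ectodomain-length checks are always computed and reported but are
#' non-filtering by default; `strict = TRUE` enables them all (the
#' ectodomain length check then uses `ecto_len_range`, motivated by the
#' near-constant ~30-residue ectodomain of known short fusogens).
#'
#' @param min_aa,max_aa ORF length window in amino acids.
#' @param require_myristoylation,require_tm,require_topology,
#'   require_polybasic logical filter switches.
#' @param ecto_len_range integer length-2 vector or `NULL` (disabled).
#' @param strand_mode passed to [find_orfs()].
#' @param overlap_policy passed to [find_orfs()].
#' @param features a [feature_config()].
#' @param strict enable every check at once.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_aa = 50L, max_aa = 250L,
                          require_myristoylation = TRUE,
                          require_tm = TRUE,
                          require_topology = FALSE,
                          require_polybasic = FALSE,
                          ecto_len_range = NULL,
                          strand_mode = "forward",
                          overlap_policy = "longest_per_stop",
                          features = feature_config(),
                          strict = FALSE) {
  if (strict) {
    require_topology <- TRUE
    require_polybasic <- TRUE
    if (is.null(ecto_len_range)) ecto_len_range <- c(15L, 45L)
  }
  cfg <- list(min_aa = as.integer(min_aa), max_aa = as.integer(max_aa),
              require_myristoylation = require_myristoylation,
              require_tm = require_tm,
              require_topology = require_topology,
              require_polybasic = require_polybasic,
              ecto_len_range = ecto_len_range,
              strand_mode = strand_mode,
              overlap_policy = overlap_policy,
              features = features)
  stopifnot(cfg$min_aa <= cfg$max_aa)
  enabled <- c(TRUE, require_myristoylation, require_tm, require_topology,
               require_polybasic, !is.null(ecto_len_range))
  if (!any(enabled)) stop("at least one filter must be enabled")
  structure(cfg, class = "filter_config")
}

.filter_order <- c("length", "myristoylation", "tm", "topology",
                   "polybasic", "ecto_len")

#' Classify one ORF against the composite filter
#'
#' Filters are evaluated in a fixed order (length, myristoylation, single
#' transmembrane segment, topology, polybasic, ectodomain length); the
#' trace records the outcome of every enabled filter even after the first
#' failure, so decoys can be attributed to the feature they lack.
#'
#' @param orf one ORF candidate row from [find_orfs()].
#' @param config a [filter_config()].
#' @return list of class `sorf_hit`: `orf`, `features`
#'   ([profile_features()] output), `passed`, `filter_trace` (named logical
#'   over enabled filters, in evaluation order), `position_class`,
#'   `orientation` (both placeholders until [locate_relative()]).
#' @export
classify_orf <- function(orf, config = filter_config()) {
  protein <- orf$protein[[1]]
  stopifnot(nchar(protein) > 0)
  feats <- profile_features(protein, config$features)
  trace <- c(length = orf$length_aa[[1]] >= config$min_aa &&
                      orf$length_aa[[1]] <= config$max_aa)
  if (config$require_myristoylation) {
    trace["myristoylation"] <- feats$has_myristoylation
  }
  if (config$require_tm) {
    trace["tm"] <- feats$tm_count == 1
  }
  if (config$require_topology) {
    trace["topology"] <- identical(feats$topology, "N_out_C_in")
  }
  if (config$require_polybasic) {
    trace["polybasic"] <- !is.null(feats$polybasic)
  }
  if (!is.null(config$ecto_len_range)) {
    trace["ecto_len"] <- feats$partition_defined &&
      feats$ecto_len >= config$ecto_len_range[1] &&
      feats$ecto_len <= config$ecto_len_range[2]
  }
  trace <- trace[intersect(.filter_order, names(trace))]
  structure(list(orf = orf, features = feats, passed = all(trace),
                 filter_trace = trace,
                 position_class = "unplaced", orientation = "unknown"),
            class = "sorf_hit")
}

.hit_row <- function(hit) {
  o <- hit$orf; f <- hit$features
  row <- data.frame(
    parent_id = o$parent_id[[1]], strand = o$strand[[1]],
    frame = o$frame[[1]], nt_start = o$nt_start[[1]], nt_end = o$nt_end[[1]],
    open_ended = o$open_ended[[1]], length_aa = o$length_aa[[1]],
    passed = hit$passed,
    has_myristoylation = f$has_myristoylation,
    tm_count = f$tm_count,
    tm_start = if (f$tm_count > 0) f$tm$start_aa else NA_integer_,
    tm_end = if (f$tm_count > 0) f$tm$end_aa else NA_integer_,
    tm_mean_hydropathy = if (f$tm_count > 0) f$tm$mean_hydropathy else NA_real_,
    topology = f$topology,
    polybasic_kr = if (!is.null(f$polybasic)) f$polybasic$kr_count else 0L,
    ecto_len = f$ecto_len, endo_len = f$endo_len,
    mu_h_ecto = f$mu_h_ecto, mu_h_endo = f$mu_h_endo,
    aromatic_belt_tyr = f$aromatic_belt_tyr,
    position_class = hit$position_class, orientation = hit$orientation,
    protein = o$protein[[1]],
    stringsAsFactors = FALSE)
  for (fn in .filter_order) {
    row[[paste0("pass_", fn)]] <-
      if (fn %in% names(hit$filter_trace)) hit$filter_trace[[fn]] else NA
  }
  row
}

#' Scan one nucleotide sequence for short-fusogen candidates
#'
#' Runs [find_orfs()] under the configured length window and strand mode,
#' then [classify_orf()] on every candidate. Ordering is deterministic
#' (strand, then coordinates).
#'
#' @param record nucleotide sequence record (string or one-row record data
#'   frame).
#' @param config a [filter_config()].
#' @param keep_failed also return candidates that failed the filter, for
#'   audit (default `FALSE`).
#' @return data frame with one row per candidate: ORF coordinates, feature
#'   summary, `passed`, and `pass_*` columns holding the full filter trace.
#' @export
scan_consensus <- function(record, config = filter_config(),
                           keep_failed = FALSE) {
  orfs <- find_orfs(record, strand_mode = config$strand_mode,
                    min_aa = config$min_aa, max_aa = config$max_aa,
                    overlap_policy = config$overlap_policy)
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    .hit_row(classify_orf(orfs[i, , drop = FALSE], config))
  })
  out <- if (length(rows)) do.call(rbind, rows) else .hit_row_schema()
  if (!keep_failed) out <- out[out$passed, , drop = FALSE]
  out <- out[order(out$strand, out$nt_start, out$nt_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.hit_row_schema <- function() {
  dummy_orf <- data.frame(parent_id = "x", strand = "+", frame = 0L,
                          nt_start = 0L, nt_end = 153L, open_ended = FALSE,
                          protein = paste(rep("A", 50), collapse = ""),
                          length_aa = 50L, stringsAsFactors = FALSE)
  .hit_row(classify_orf(dummy_orf))[0, , drop = FALSE]
}

#' Classify a bare protein against the composite filter
#'
#' Convenience wrapper for protein-level inputs (e.g. translated viral
#' ORFs): wraps the protein in a synthetic ORF record and calls
#' [classify_orf()].
#'
#' @param protein protein string.
#' @param config a [filter_config()].
#' @param id identifier for the wrapper record.
#' @return a `sorf_hit` (see [classify_orf()]).
#' @export
classify_protein <- function(protein, config = filter_config(), id = "protein") {
  n <- nchar(protein)
  orf <- data.frame(parent_id = id, strand = "+", frame = 0L,
                    nt_start = 0L, nt_end = 3L * (n + 1L),
                    open_ended = FALSE, protein = protein, length_aa = n,
                    stringsAsFactors = FALSE)
  classify_orf(orf, config)
}

#' Place a hit relative to the element's gag/pol ORFs
#'
#' Candidate fusogen ORFs of MDG1-group elements sit upstream of *gag*;
#' some lepidopteran elements carry them downstream of *pol* instead. The
#' orientation is forward iff the hit shares the *pol* (or *gag*) strand.
#'
#' @param hit a `sorf_hit` or one hit row from [scan_consensus()].
#' @param annotation interval data frame on the same parent with `name`
#'   values containing `gag` and/or `pol` (case-insensitive).
#' @return list with `position_class`
#'   (`upstream_of_gag`/`downstream_of_pol`/`unplaced`) and `orientation`
#'   (`forward`/`reverse`/`unknown`).
#' @export
locate_relative <- function(hit, annotation) {
  if (inherits(hit, "sorf_hit")) {
    h_start <- hit$orf$nt_start[[1]]; h_end <- hit$orf$nt_end[[1]]
    h_strand <- hit$orf$strand[[1]]
  } else {
    h_start <- hit$nt_start[[1]]; h_end <- hit$nt_end[[1]]
    h_strand <- hit$strand[[1]]
  }
  res <- list(position_class = "unplaced", orientation = "unknown")
  if (is.null(annotation) || nrow(annotation) == 0) return(res)
  nm <- tolower(annotation$name)
  gag <- annotation[grepl("gag", nm), , drop = FALSE]
  pol <- annotation[grepl("pol", nm), , drop = FALSE]
  ref <- if (nrow(pol)) pol[1, ] else if (nrow(gag)) gag[1, ] else NULL
  if (!is.null(ref) && ref$strand %in% c("+", "-")) {
    res$orientation <- if (h_strand == ref$strand) "forward" else "reverse"
  }
  if (nrow(gag) && h_end <= gag$start[1]) {
    res$position_class <- "upstream_of_gag"
  } else if (nrow(pol) && h_start >= pol$end[1]) {
    res$position_class <- "downstream_of_pol"
  }
  res
}
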