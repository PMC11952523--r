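#' Load a hydropathy scale
#'
#' Scales ship as plain-text residue/value tables so alternatives can be
#' substituted bit-exactly. The 20 canonical residues must all be present;
#' `X` (unknown residue, e.g. from ambiguous codons) scores 0 so it can
#' never satisfy a residue-specific feature.
#'
#' @param name `"kyte_doolittle"` (transmembrane detection default) or
#'   `"eisenberg_consensus"` (amphipathicity default), or a path to a
#'   two-column TSV with header `residue`/`value`.
#' @return named numeric vector over the 20 residues plus `X = 0`, with a
#'   `"scale_name"` attribute.
#' @export
hydropathy_scale <- function(name = "kyte_doolittle") {
  path <- if (file.exists(name)) name
          else system.file("extdata", paste0(name, ".tsv"), package = "sorfscan")
  if (!nzchar(path) || !file.exists(path)) stop("unknown hydropathy scale: ", name)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  vals <- setNames(tab$value, tab$residue)
  if (!all(AA20 %in% names(vals))) {
    stop("scale is missing canonical residues: ",
         paste(setdiff(AA20, names(vals)), collapse = ", "))
  }
  vals["X"] <- 0
  attr(vals, "scale_name") <- basename(name)
  vals
}

.scale_values <- function(protein, scale) {
  v <- scale[strsplit(protein, "")[[1]]]
  v[is.na(v)] <- 0  # non-canonical letters behave like X
  unname(v)
}

#' Sliding-window hydropathy profile
#'
#' Centered arithmetic mean of the scale values in a window of odd width;
#' one value per position where the full window fits.
#'
#' @param protein protein string.
#' @param scale named numeric vector from [hydropathy_scale()].
#' @param window odd window width (>= 1).
#' @return numeric vector of length `nchar(protein) - window + 1` (empty if
#'   the window does not fit), where element `i` is centered on residue
#'   `i + (window-1)/2` (1-based).
#' @export
hydropathy_profile <- function(protein, scale, window = 19L) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- nchar(protein)
  if (window > n) return(numeric(0))
  v <- .scale_values(protein, scale)
  cs <- c(0, cumsum(v))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Detect transmembrane segments by windowed hydropathy
#'
#' Maximal runs of window centers whose mean hydropathy reaches `threshold`
#' are taken as candidate segments; each run is expanded to the full
#' residue span covered by its windows, clipped to `max_len` residues
#' around the run's maximum, and discarded if shorter than `min_len`.
#' Defaults (Kyte-Doolittle scale, window 19, mean >= 1.6) are the classic
#' single-pass transmembrane setting.
#'
#' @param protein protein string.
#' @param scale hydropathy scale (default Kyte-Doolittle).
#' @param window odd window width.
#' @param threshold minimum windowed mean hydropathy.
#' @param min_len,max_len segment length bounds in residues.
#' @return data frame of segments sorted by start: `start_aa`, `end_aa`
#'   (0-based half-open protein coordinates), `mean_hydropathy` (over the
#'   reported span).
#' @export
detect_tm <- function(protein, scale = hydropathy_scale(), window = 19L,
                      threshold = 1.6, min_len = 15L, max_len = 30L) {
  prof <- hydropathy_profile(protein, scale, window)
  empty <- data.frame(start_aa = integer(0), end_aa = integer(0),
                      mean_hydropathy = numeric(0))
  if (!length(prof)) return(empty)
  half <- (window - 1L) %/% 2L
  pass <- prof >= threshold
  if (!any(pass)) return(empty)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  v <- .scale_values(protein, scale)
  segs <- list()
  for (k in which(r$values)) {
    c0 <- begins[k]; c1 <- ends[k]          # profile indices (1-based)
    # residue span covered by the passing windows, 0-based half-open
    s <- c0 - 1L
    e <- c1 - 1L + window
    if (e - s > max_len) {
      peak <- c0 - 1L + which.max(prof[c0:c1]) - 1L + half  # 0-based residue of peak center
      s2 <- max(s, peak - max_len %/% 2L)
      e2 <- s2 + max_len
      if (e2 > e) { e2 <- e; s2 <- e2 - max_len }
      s <- s2; e <- e2
    }
    if (e - s < min_len) next
    segs[[length(segs) + 1L]] <- data.frame(
      start_aa = s, end_aa = e,
      mean_hydropathy = mean(v[(s + 1L):e]))
  }
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  out[order(out$start_aa), , drop = FALSE]
}

#' Infer membrane topology by the positive-inside rule
#'
#' Counts K+R in up to `flank` residues on each side of the transmembrane
#' segment; the more basic flank is called cytoplasmic ("inside").
#'
#' @param protein protein string.
#' @param tm one-row segment (list/data frame with `start_aa`, `end_aa`).
#' @param flank flank width in residues.
#' @return `"N_out_C_in"`, `"N_in_C_out"`, or `"undetermined"` on a tie.
#' @export
infer_topology <- function(protein, tm, flank = 15L) {
  n <- nchar(protein)
  s <- tm$start_aa[[1]]; e <- tm$end_aa[[1]]
  stopifnot(s >= 0, e <= n, s < e)
  count_kr <- function(str) sum(strsplit(str, "")[[1]] %in% c("K", "R"))
  n_side <- if (s > 0) count_kr(substr(protein, max(1L, s - flank + 1L), s)) else 0L
  c_side <- if (e < n) count_kr(substr(protein, e + 1L, min(n, e + flank))) else 0L
  if (c_side > n_side) "N_out_C_in"
  else if (c_side < n_side) "N_in_C_out"
  else "undetermined"
}

#' Test for the N-terminal glycine myristoylation motif
#'
#' The canonical co-translational myristoylation context M-G-x-x-x-S/T,
#' evaluated on the primary translate with the initiator Met retained
#' (positions 1-based: residue 1 = M, residue 2 = G, residue 6 = S or T).
#' `X` at position 6 fails; the x positions are unconstrained.
#'
#' @param protein protein string.
#' @return `TRUE` iff the motif is present.
#' @export
has_myristoylation_motif <- function(protein) {
  nchar(protein) >= 6 &&
    substr(protein, 1, 1) == "M" &&
    substr(protein, 2, 2) == "G" &&
    substr(protein, 6, 6) %in% c("S", "T")
}

#' Find the juxtamembrane polybasic patch
#'
#' Scans every window of up to `window` residues inside
#' `[region_start, region_end)` (0-based half-open) and returns the one
#' with the most K+R residues, provided that count reaches `min_kr`; ties
#' break to the smallest start.
#'
#' @param protein protein string.
#' @param region_start,region_end search region, 0-based half-open.
#' @param window maximum window width.
#' @param min_kr minimum K+R count to report a patch.
#' @return list with `start`, `end` (0-based half-open), `kr_count`, or
#'   `NULL` if no window qualifies.
#' @export
find_polybasic <- function(protein, region_start, region_end,
                           window = 10L, min_kr = 3L) {
  n <- nchar(protein)
  region_start <- max(0L, region_start)
  region_end <- min(n, region_end)
  if (region_end <= region_start) return(NULL)
  res <- strsplit(substr(protein, region_start + 1L, region_end), "")[[1]]
  is_kr <- as.integer(res %in% c("K", "R"))
  len <- length(is_kr)
  w <- min(window, len)
  cs <- c(0L, cumsum(is_kr))
  counts <- cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]
  best <- which.max(counts)  # earliest max
  if (counts[best] < min_kr) return(NULL)
  list(start = region_start + best - 1L,
       end = region_start + best - 1L + w,
       kr_count = as.integer(counts[best]))
}

#' Hydrophobic moment of a window
#'
#' Magnitude of the helical-wheel vector sum,
#' \eqn{\mu_H = |\sum_k H_k (\cos k\delta, \sin k\delta)| / N}, with
#' \eqn{\delta} the per-residue helical rotation (100 degrees for an ideal
#' alpha helix). Independent of where the window sits in the protein.
#'
#' @param window_protein residue string of the window.
#' @param scale hydropathy scale (default Eisenberg consensus).
#' @param delta_deg helical rotation per residue, degrees.
#' @return nonnegative mean moment per residue.
#' @export
hydrophobic_moment <- function(window_protein,
                               scale = hydropathy_scale("eisenberg_consensus"),
                               delta_deg = 100) {
  h <- .scale_values(window_protein, scale)
  n <- length(h)
  if (n == 0) stop("empty window")
  k <- seq_len(n) - 1
  d <- delta_deg * pi / 180
  sqrt(sum(h * cos(k * d))^2 + sum(h * sin(k * d))^2) / n
}

#' Maximum windowed hydrophobic moment over a span
#'
#' Reduces "has an amphipathic motif somewhere in this domain" to one
#' score: the maximum of [hydrophobic_moment()] over all full windows in
#' `[span_start, span_end)`; 0 when no full window fits.
#'
#' @param protein protein string.
#' @param span_start,span_end 0-based half-open span.
#' @param scale hydropathy scale.
#' @param window window width.
#' @param delta_deg helical rotation per residue, degrees.
#' @return maximum moment, or 0.
#' @export
max_window_moment <- function(protein, span_start, span_end,
                              scale = hydropathy_scale("eisenberg_consensus"),
                              window = 11L, delta_deg = 100) {
  n <- nchar(protein)
  span_start <- max(0L, span_start)
  span_end <- min(n, span_end)
  len <- span_end - span_start
  if (len < window) return(0)
  h <- .scale_values(substr(protein, span_start + 1L, span_end), scale)
  d <- delta_deg * pi / 180
  k <- 0:(length(h) - 1)
  cx <- c(0, cumsum(h * cos(k * d)))
  sx <- c(0, cumsum(h * sin(k * d)))
  starts <- 1:(len - window + 1)
  # moment magnitude is invariant to the phase offset of the window start,
  # so cumulative sums over a fixed global phase are exact
  mags <- sqrt((cx[starts + window] - cx[starts])^2 +
               (sx[starts + window] - sx[starts])^2) / window
  max(mags)
}

#' Aromatic-belt tyrosine just downstream of the transmembrane segment
#'
#' Interfacial Tyr at the cytoplasmic membrane boundary. Report-only in the
#' default pipeline (never a filter).
#'
#' @param protein protein string.
#' @param tm transmembrane segment (`start_aa`, `end_aa`).
#' @param lookahead residues to inspect after the segment end.
#' @return `TRUE` iff a `Y` occurs within `lookahead` residues after the
#'   segment.
#' @export
aromatic_belt_tyr <- function(protein, tm, lookahead = 5L) {
  n <- nchar(protein)
  e <- tm$end_aa[[1]]
  if (e >= n) return(FALSE)
  grepl("Y", substr(protein, e + 1L, min(n, e + lookahead)), fixed = TRUE)
}

#' Default feature configuration
#'
#' Bundles every threshold of the feature stage. Transmembrane detection
#' uses the Kyte-Doolittle scale (window 19, mean >= 1.6, 15-30 residues);
#' amphipathicity uses the Eisenberg consensus scale at 100 degrees per
#' residue, window 11; the polybasic patch is sought in the 15-residue
#' juxtamembrane endodomain window (>= 3 K/R in <= 10 residues).
#'
#' @param tm_scale,mu_scale hydropathy scales.
#' @param tm_window,tm_threshold,tm_min_len,tm_max_len transmembrane
#'   detection parameters.
#' @param topology_flank flank width for the positive-inside rule.
#' @param polybasic_region,polybasic_window,polybasic_min_kr polybasic
#'   search parameters.
#' @param mu_window,mu_delta_deg hydrophobic-moment parameters.
#' @param tyr_lookahead aromatic-belt window after the segment.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(tm_scale = hydropathy_scale("kyte_doolittle"),
                           mu_scale = hydropathy_scale("eisenberg_consensus"),
                           tm_window = 19L, tm_threshold = 1.6,
                           tm_min_len = 15L, tm_max_len = 30L,
                           topology_flank = 15L,
                           polybasic_region = 15L, polybasic_window = 10L,
                           polybasic_min_kr = 3L,
                           mu_window = 11L, mu_delta_deg = 100,
                           tyr_lookahead = 5L) {
  structure(as.list(environment()), class = "feature_config")
}

#' Profile a protein for short-fusogen hallmark features
#'
#' Aggregates every hallmark of the FAST-like architecture: myristoylation
#' motif, transmembrane segment (the highest-mean segment when several are
#' detected; `tm_count` records how many), topology by the positive-inside
#' rule, ecto/endodomain partition (N-terminal side is the ectodomain under
#' the expected N-outside/C-inside topology), juxtamembrane polybasic
#' patch, per-domain maximum hydrophobic moment, and the aromatic-belt Tyr.
#' With no transmembrane segment the ectodomain is set to the full length
#' by convention and `partition_defined` is `FALSE`.
#'
#' @param protein protein string (non-empty).
#' @param config a [feature_config()].
#' @return list of class `feature_profile`.
#' @export
profile_features <- function(protein, config = feature_config()) {
  stopifnot(nchar(protein) > 0)
  n <- nchar(protein)
  tms <- detect_tm(protein, config$tm_scale, config$tm_window,
                   config$tm_threshold, config$tm_min_len, config$tm_max_len)
  tm_count <- nrow(tms)
  tm <- if (tm_count > 0) as.list(tms[which.max(tms$mean_hydropathy), ]) else NULL
  out <- list(
    has_myristoylation = has_myristoylation_motif(protein),
    tm = tm, tm_count = tm_count,
    topology = "undetermined", polybasic = NULL,
    ecto_len = n, endo_len = 0L, partition_defined = FALSE,
    mu_h_ecto = 0, mu_h_endo = 0, aromatic_belt_tyr = FALSE,
    protein_length = n)
  if (!is.null(tm)) {
    out$topology <- infer_topology(protein, tm, config$topology_flank)
    out$ecto_len <- tm$start_aa
    out$endo_len <- n - tm$end_aa
    out$partition_defined <- TRUE
    out$polybasic <- find_polybasic(protein, tm$end_aa,
                                    tm$end_aa + config$polybasic_region,
                                    config$polybasic_window,
                                    config$polybasic_min_kr)
    out$mu_h_ecto <- max_window_moment(protein, 0L, tm$start_aa,
                                       config$mu_scale, config$mu_window,
                                       config$mu_delta_deg)
    out$mu_h_endo <- max_window_moment(protein, tm$end_aa, n,
                                       config$mu_scale, config$mu_window,
                                       config$mu_delta_deg)
    out$aromatic_belt_tyr <- aromatic_belt_tyr(protein, tm,
                                               config$tyr_lookahead)
  }
  structure(out, class = "feature_profile")
}

#' @export
print.feature_profile <- function(x, ...) {
  cat("feature_profile:", x$protein_length, "aa;",
      if (x$has_myristoylation) "myr+" else "myr-",
      if (x$tm_count > 0) sprintf("TM[%d,%d) x%d", x$tm$start_aa, x$tm$end_aa,
                                  x$tm_count) else "no-TM",
      x$topology,
      if (!is.null(x$polybasic)) sprintf("polybasic(KR=%d)", x$polybasic$kr_count)
      else "no-polybasic", "\n")
  invisible(x)
}
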