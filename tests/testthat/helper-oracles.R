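# Independent oracles used to pin the package's numerical operations.
# These deliberately avoid the package's own code paths: direct summation,
# exhaustive scans, explicit path enumeration, hand-typed tables.

AA20_ORACLE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle values typed here independently of inst/extdata
KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2, X = 0)

# A second, hand-entered standard genetic code (independent of Biostrings)
CODE_ORACLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- paste0("FFLLSSSSYY**CC*W",   # TTT..TGG
                "LLLLPPPPHHQQRRRR",   # CTT..CGG
                "IIIMTTTTNNKKSSRR",   # ATT..AGG
                "VVVVAAAADDEEGGGG")   # GTT..GGG
  # enumerate codons in the classic table order (first base slowest)
  cods <- character(64); k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1; cods[k] <- paste0(b1, b2, b3)
  }
  setNames(strsplit(aas, "")[[1]], cods)
})

random_protein <- function(n, letters = AA20_ORACLE) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# position-by-position ORF scanner: tests every position for ATG and walks
# codon by codon; returns all ORFs (overlap policy "all"), forward strand
orf_oracle_forward <- function(seq, min_aa, max_aa) {
  n <- nchar(seq)
  res <- list()
  for (s in 0:(n - 3)) {
    if (substr(seq, s + 1, s + 3) != "ATG") next
    pos <- s; prot <- character(0); stopped <- FALSE
    while (pos + 3 <= n) {
      cod <- substr(seq, pos + 1, pos + 3)
      aa <- CODE_ORACLE[[cod]]
      if (is.null(aa) || is.na(aa)) aa <- "X"
      if (aa == "*") { stopped <- TRUE; pos <- pos + 3; break }
      prot <- c(prot, aa)
      pos <- pos + 3
    }
    len <- length(prot)
    if (len >= min_aa && len <= max_aa) {
      res[[length(res) + 1]] <- data.frame(
        nt_start = s, nt_end = pos, frame = s %% 3,
        open_ended = !stopped, protein = paste(prot, collapse = ""),
        length_aa = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(nt_start = integer(0), nt_end = integer(0),
                      frame = integer(0), open_ended = logical(0),
                      protein = character(0), length_aa = integer(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$nt_start, out$nt_end), , drop = FALSE]
}

# direct re-summation oracle for windowed hydropathy
hydropathy_oracle <- function(protein, scale, window) {
  res <- strsplit(protein, "")[[1]]
  v <- unname(scale[res]); v[is.na(v)] <- 0
  n <- length(v)
  if (window > n) return(numeric(0))
  sapply(1:(n - window + 1), function(i) sum(v[i:(i + window - 1)]) / window)
}

# direct complex-exponential oracle for the hydrophobic moment
moment_oracle <- function(window_protein, scale, delta_deg = 100) {
  res <- strsplit(window_protein, "")[[1]]
  h <- unname(scale[res]); h[is.na(h)] <- 0
  d <- delta_deg * pi / 180
  z <- sum(h * exp(1i * d * (seq_along(h) - 1)))
  Mod(z) / length(h)
}

max_moment_oracle <- function(protein, s0, s1, scale, window, delta_deg = 100) {
  span <- substr(protein, s0 + 1, s1)
  n <- nchar(span)
  if (n < window) return(0)
  max(sapply(1:(n - window + 1), function(i) {
    moment_oracle(substr(span, i, i + window - 1), scale, delta_deg)
  }))
}

# exhaustive window scan oracle for the polybasic patch
polybasic_oracle <- function(protein, r0, r1, window = 10, min_kr = 3) {
  res <- strsplit(substr(protein, r0 + 1, r1), "")[[1]]
  len <- length(res)
  if (!len) return(NULL)
  w <- min(window, len)
  best <- NULL
  for (i in 1:(len - w + 1)) {
    cnt <- sum(res[i:(i + w - 1)] %in% c("K", "R"))
    if (is.null(best) || cnt > best$kr_count) {
      best <- list(start = r0 + i - 1, end = r0 + i - 1 + w, kr_count = cnt)
    }
  }
  if (best$kr_count < min_kr) NULL else best
}

# exhaustive state-path enumeration oracle for the profile HMM (log2 space).
# Walks every begin-to-end path, multiplying transition and emission
# probabilities; returns the max (Viterbi) and log-sum (forward) bit score.
hmm_enum_oracle <- function(profile, protein) {
  x <- match(strsplit(protein, "")[[1]], AA20_ORACLE)
  L <- length(x); n <- profile$n_match
  lME <- log2(profile$match_emissions)
  lIE <- log2(profile$insert_emissions)
  lTM <- log2(profile$trans_m); lTI <- log2(profile$trans_i)
  lTD <- log2(profile$trans_d)
  scores <- numeric(0)
  rec <- function(type, i, j, logp) {
    # transitions out of (type, i): row in the relevant table
    tr <- switch(type, M = lTM[i + 1, ], I = lTI[i + 1, ], D = lTD[i, ])
    # to M_{i+1} (end when i == n)
    if (i == n) {
      if (j == L) scores[[length(scores) + 1]] <<- logp + tr[["M"]]
    } else if (j < L) {
      rec("M", i + 1, j + 1, logp + tr[["M"]] + lME[i + 1, x[j + 1]])
    }
    # to I_i (emits)
    if (j < L && is.finite(tr[["I"]])) {
      rec("I", i, j + 1, logp + tr[["I"]] + lIE[i + 1, x[j + 1]])
    }
    # to D_{i+1}
    if (i < n && is.finite(tr[["D"]])) {
      rec("D", i + 1, j, logp + tr[["D"]])
    }
    invisible(NULL)
  }
  rec("M", 0, 0, 0)
  null <- sum(log2(profile$background[x]))
  lse <- function(v) { m <- max(v); m + log2(sum(2^(v - m))) }
  list(viterbi = max(scores) - null, forward = lse(scores) - null,
       n_paths = length(scores))
}

# random small profile for oracle tests: built from a random gappy MSA
random_small_profile <- function(max_match = 4) {
  repeat {
    nr <- sample(2:4, 1)
    w <- sample(2:5, 1)
    rows <- replicate(nr, {
      r <- sample(AA20_ORACLE, w, replace = TRUE)
      gaps <- which(runif(w) < 0.25)
      r[gaps] <- "-"
      paste(r, collapse = "")
    })
    if (any(vapply(gregexpr("-", rows), function(g) sum(g > 0), 0) == nchar(rows[1]))) next
    p <- tryCatch(build_profile(msa(paste0("r", 1:nr), rows)),
                  error = function(e) NULL)
    if (!is.null(p) && p$n_match >= 1 && p$n_match <= max_match) return(p)
  }
}
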