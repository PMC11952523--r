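# Lightweight profile HMM with match/insert/delete states and global
# (begin-to-end) alignment; a `glocal` scoring flag makes the flanking
# insert states free so partial-context targets are not penalised.
# Everything is computed in log2 space.

.logsumexp2 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log2(sum(2^(x - m)))
}

#' Build a profile HMM from a protein alignment
#'
#' Columns whose gap fraction is at most `gap_threshold` become match
#' states; the rest feed insert states. Emissions are maximum-posterior
#' estimates with a Dirichlet-style pseudocount proportional to the
#' background: `(counts + pseudocount * background) / (n + pseudocount)`.
#' Transitions are estimated from the observed per-row state paths with
#' the same pseudocounting (uniform over the valid successors). All-gap
#' columns are insert columns by construction.
#'
#' @param msa an [msa()] object (>= 1 row; >= 2 recommended).
#' @param gap_threshold maximum gap fraction for a match column.
#' @param pseudocount pseudocount mass.
#' @param background residue background frequencies (named over the 20
#'   residues, summing to 1); default uniform 1/20.
#' @param name model name.
#' @return object of class `profile_hmm` with `n_match`,
#'   `match_emissions` (n x 20), `insert_emissions` ((n+1) x 20, states
#'   I0..In), `trans_m`/`trans_i` ((n+1) x 3, rows for M0=begin..Mn and
#'   I0..In, columns to-M/to-I/to-D), `trans_d` (n x 3, rows D1..Dn),
#'   `background`.
#' @export
build_profile <- function(msa, gap_threshold = 0.5, pseudocount = 1.0,
                          background = NULL, name = "profile") {
  if (!inherits(msa, "msa")) stop("build_profile needs an msa object")
  rows <- strsplit(msa$rows, "")
  nrows <- length(rows)
  ncol <- msa$width
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20]
  stopifnot(abs(sum(background) - 1) < 1e-9)

  gap_frac <- vapply(seq_len(ncol), function(j) {
    mean(vapply(rows, function(r) r[j] == "-", logical(1)))
  }, numeric(1))
  is_match <- gap_frac <= gap_threshold
  n <- sum(is_match)
  if (n < 1) stop("no match columns under gap_threshold = ", gap_threshold)
  match_of_col <- cumsum(is_match)  # match index reached at/after column j

  # emission counts
  m_counts <- matrix(0, n, 20, dimnames = list(NULL, AA20))
  i_counts <- matrix(0, n + 1, 20, dimnames = list(NULL, AA20))
  # transition counts: rows are source index 0..n (M,I) or 1..n (D)
  t_m <- matrix(0, n + 1, 3, dimnames = list(NULL, c("M", "I", "D")))
  t_i <- matrix(0, n + 1, 3, dimnames = list(NULL, c("M", "I", "D")))
  t_d <- matrix(0, n, 3, dimnames = list(NULL, c("M", "I", "D")))

  for (r in rows) {
    # state path of this row: begin = ("M", 0); end = ("M", n+1)
    path_type <- "M"; path_idx <- 0L
    states_t <- character(0); states_i <- integer(0)
    for (j in seq_len(ncol)) {
      if (is_match[j]) {
        i <- match_of_col[j]
        if (r[j] == "-") {
          states_t <- c(states_t, "D"); states_i <- c(states_i, i)
        } else {
          states_t <- c(states_t, "M"); states_i <- c(states_i, i)
          if (r[j] %in% AA20) m_counts[i, r[j]] <- m_counts[i, r[j]] + 1
        }
      } else if (r[j] != "-") {
        i <- match_of_col[j]  # insert state between match i and i+1
        states_t <- c(states_t, "I"); states_i <- c(states_i, i)
        if (r[j] %in% AA20) i_counts[i + 1, r[j]] <- i_counts[i + 1, r[j]] + 1
      }
    }
    st <- c("M", states_t, "M"); si <- c(0L, states_i, n + 1L)
    for (k in seq_len(length(st) - 1)) {
      from_t <- st[k]; from_i <- si[k]; to_t <- st[k + 1]
      if (from_t == "M") t_m[from_i + 1, to_t] <- t_m[from_i + 1, to_t] + 1
      else if (from_t == "I") t_i[from_i + 1, to_t] <- t_i[from_i + 1, to_t] + 1
      else t_d[from_i, to_t] <- t_d[from_i, to_t] + 1
    }
  }

  norm_em <- function(counts) {
    nobs <- rowSums(counts)
    sweep(counts + pseudocount * matrix(background, nrow(counts), 20,
                                        byrow = TRUE),
          1, nobs + pseudocount, "/")
  }
  norm_tr <- function(counts, last_has_d) {
    out <- counts
    for (i in seq_len(nrow(counts))) {
      valid <- c(TRUE, TRUE, if (i == nrow(counts) && !last_has_d) FALSE else TRUE)
      k <- sum(valid)
      tot <- sum(counts[i, valid])
      out[i, valid] <- (counts[i, valid] + pseudocount / k) / (tot + pseudocount)
      out[i, !valid] <- 0
    }
    out
  }
  structure(list(
    name = name, n_match = n,
    match_emissions = norm_em(m_counts),
    insert_emissions = norm_em(i_counts),
    trans_m = norm_tr(t_m, last_has_d = FALSE),
    trans_i = norm_tr(t_i, last_has_d = FALSE),
    trans_d = if (n >= 1) norm_tr(t_d, last_has_d = FALSE) else t_d,
    background = background,
    match_columns = which(is_match)), class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$name, "': ", x$n_match, " match states\n", sep = "")
  invisible(x)
}

# log2 parameter matrices, optionally with free flanking inserts
.log_params <- function(profile, glocal = FALSE) {
  p <- profile
  lm <- log2(p$match_emissions)
  li <- log2(p$insert_emissions)
  tm <- log2(p$trans_m); ti <- log2(p$trans_i); td <- log2(p$trans_d)
  lbg <- log2(p$background)
  if (glocal) {
    n <- p$n_match
    # flanking insert states emit at background and cost nothing
    li[1, ] <- lbg; li[n + 1, ] <- lbg
    tm[1, c("M", "I")] <- 0; ti[1, c("M", "I")] <- 0
    tm[n + 1, c("M", "I")] <- 0; ti[n + 1, c("M", "I")] <- 0
  }
  list(lm = lm, li = li, tm = tm, ti = ti, td = td, lbg = lbg,
       n = p$n_match)
}

.seq_idx <- function(protein) {
  res <- strsplit(toupper(protein), "")[[1]]
  idx <- match(res, AA20)
  if (anyNA(idx)) stop("protein contains letters outside the 20-residue alphabet: ",
                       paste(unique(res[is.na(idx)]), collapse = ""))
  idx
}

.hmm_dp <- function(profile, protein, mode = c("viterbi", "forward"),
                    glocal = FALSE) {
  mode <- match.arg(mode)
  q <- .log_params(profile, glocal)
  x <- .seq_idx(protein)
  L <- length(x); n <- q$n
  viterbi <- mode == "viterbi"
  # transition vectors by source row (M/I: sources 0..n; D: sources 1..n)
  tmM <- q$tm[, 1]; tmI <- q$tm[, 2]; tmD <- q$tm[, 3]
  tiM <- q$ti[, 1]; tiI <- q$ti[, 2]; tiD <- q$ti[, 3]
  tdM <- q$td[, 1]; tdI <- q$td[, 2]; tdD <- q$td[, 3]
  # vectorized 3-way combine: max with argmax (Viterbi) or log-sum (forward)
  vmax3 <- function(a, b, c) {
    v <- a; p <- rep.int(1L, length(a))
    i <- b > v; v[i] <- b[i]; p[i] <- 2L
    i <- c > v; v[i] <- c[i]; p[i] <- 3L
    list(v = v, p = p)
  }
  fsum3 <- function(a, b, c) {
    m <- pmax(a, b, c)
    r <- m + log2(2^(a - m) + 2^(b - m) + 2^(c - m))
    r[!is.finite(m)] <- -Inf
    list(v = r, p = rep.int(NA_integer_, length(a)))
  }
  comb <- if (viterbi) vmax3 else fsum3
  # V*[i+1, j+1]: state index i = 0..n, emitted prefix length j = 0..L
  VM <- matrix(-Inf, n + 1, L + 1)
  VI <- matrix(-Inf, n + 1, L + 1)
  VD <- matrix(-Inf, n + 1, L + 1)
  PM <- PI <- PD <- matrix(NA_integer_, n + 1, L + 1)
  VM[1, 1] <- 0  # begin
  d_chain <- function(jj) {
    # delete states depend on the current column: lean scalar sweep
    for (i in 1:n) {
      c1 <- VM[i, jj] + tmD[i]
      c2 <- VI[i, jj] + tiD[i]
      c3 <- if (i >= 2) VD[i, jj] + tdD[i - 1] else -Inf
      if (viterbi) {
        if (c1 >= c2 && c1 >= c3) { VD[i + 1, jj] <<- c1; PD[i + 1, jj] <<- 1L }
        else if (c2 >= c3)        { VD[i + 1, jj] <<- c2; PD[i + 1, jj] <<- 2L }
        else                      { VD[i + 1, jj] <<- c3; PD[i + 1, jj] <<- 3L }
      } else {
        m <- max(c1, c2, c3)
        VD[i + 1, jj] <<- if (is.finite(m)) {
          m + log2(2^(c1 - m) + 2^(c2 - m) + 2^(c3 - m))
        } else -Inf
      }
    }
  }
  d_chain(1L)
  if (L >= 1) {
    for (j in 1:L) {
      jj <- j + 1L; xj <- x[j]
      # match states i = 1..n (predecessors at column j-1, state i-1)
      a3 <- if (n >= 2) c(-Inf, VD[2:n, jj - 1] + tdM[1:(n - 1)]) else -Inf
      rm <- comb(VM[1:n, jj - 1] + tmM[1:n],
                 VI[1:n, jj - 1] + tiM[1:n], a3)
      VM[2:(n + 1), jj] <- q$lm[, xj] + rm$v
      PM[2:(n + 1), jj] <- rm$p
      # insert states i = 0..n (predecessors at column j-1, same state)
      b3 <- c(-Inf, VD[2:(n + 1), jj - 1] + tdI[1:n])
      ri <- comb(VM[, jj - 1] + tmI, VI[, jj - 1] + tiI, b3)
      VI[, jj] <- q$li[, xj] + ri$v
      PI[, jj] <- ri$p
      d_chain(jj)
    }
  }
  f3 <- if (n >= 1) VD[n + 1, L + 1] + tdM[n] else -Inf
  fin <- comb(VM[n + 1, L + 1] + tmM[n + 1],
              VI[n + 1, L + 1] + tiM[n + 1], f3)
  null <- sum(q$lbg[x])
  list(score = fin$v, bit_score = fin$v - null,
       last = c("M", "I", "D")[fin$p], PM = PM, PI = PI, PD = PD,
       x = x, n = n)
}

#' Viterbi score of a protein against a profile
#'
#' Best-path log-odds of a global alignment of the whole sequence to the
#' whole profile, in bits: log2 of the best joint path probability minus
#' log2 of the background probability of the sequence.
#'
#' @param profile a `profile_hmm`.
#' @param protein protein string (canonical residues).
#' @param glocal score flanking insert states as free background emitters.
#' @return list with `bit_score` and `path` (character vector of visited
#'   emitting/delete states, e.g. `"M1"`, `"I0"`, `"D2"`).
#' @export
viterbi_score <- function(profile, protein, glocal = FALSE) {
  d <- .hmm_dp(profile, protein, "viterbi", glocal)
  n <- d$n; L <- length(d$x)
  lab <- c("M", "I", "D")
  typ <- d$last; i <- n; j <- L
  path <- character(0)
  while (!(typ == "M" && i == 0)) {
    path <- c(paste0(typ, i), path)
    if (typ == "M") {
      typ <- lab[d$PM[i + 1, j + 1]]; i <- i - 1; j <- j - 1
    } else if (typ == "I") {
      typ <- lab[d$PI[i + 1, j + 1]]; j <- j - 1
    } else {
      typ <- lab[d$PD[i + 1, j + 1]]; i <- i - 1
    }
    stopifnot(!is.na(typ))
  }
  list(bit_score = d$bit_score, path = path)
}

#' Forward score of a protein against a profile
#'
#' As [viterbi_score()] but summing over all paths (log-space); always at
#' least the Viterbi score.
#'
#' @inheritParams viterbi_score
#' @return bit score (numeric scalar).
#' @export
forward_score <- function(profile, protein, glocal = FALSE) {
  .hmm_dp(profile, protein, "forward", glocal)$bit_score
}

#' Scan a protein database with a profile
#'
#' Scores every target with [forward_score()] and calibrates an empirical
#' p-value against a per-target residue-shuffle null: `empirical_p =
#' (1 + #{shuffled scores >= observed}) / (n_shuffles + 1)`. Shuffles come
#' from a seeded generator, so the scan is reproducible.
#'
#' @param profile a `profile_hmm`.
#' @param db protein sequence-record data frame.
#' @param n_shuffles shuffles per target.
#' @param seed integer seed.
#' @param glocal passed to the scorer.
#' @return data frame sorted by decreasing `bit_score`: `target_id`,
#'   `bit_score`, `empirical_p`, `ali_start`, `ali_end` (0-based half-open
#'   span on the target; global alignment spans the whole sequence).
#' @export
scan_proteins <- function(profile, db, n_shuffles = 200L, seed = 1L,
                          glocal = FALSE) {
  stopifnot(nrow(db) >= 1)
  set.seed(seed)
  res <- lapply(seq_len(nrow(db)), function(i) {
    s <- db$seq[i]
    obs <- forward_score(profile, s, glocal)
    ge <- 0L
    chars <- strsplit(s, "")[[1]]
    for (k in seq_len(n_shuffles)) {
      shuf <- paste(sample(chars), collapse = "")
      if (forward_score(profile, shuf, glocal) >= obs) ge <- ge + 1L
    }
    data.frame(target_id = db$id[i], bit_score = obs,
               empirical_p = (1 + ge) / (n_shuffles + 1),
               ali_start = 0L, ali_end = nchar(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$bit_score, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a profile HMM to a plain-text file
#'
#' Versioned header, then per-state emission and transition tables in a
#' fixed column order, full precision.
#'
#' @param profile a `profile_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c("# sorfscan profile v1",
               paste("name", profile$name),
               paste("n_match", profile$n_match),
               paste("alphabet", paste(AA20, collapse = "")),
               paste("background", fmt(profile$background))), con)
  wmat <- function(tag, m) {
    writeLines(paste(tag, nrow(m)), con)
    for (i in seq_len(nrow(m))) writeLines(fmt(m[i, ]), con)
  }
  wmat("match_emissions", profile$match_emissions)
  wmat("insert_emissions", profile$insert_emissions)
  wmat("trans_m", profile$trans_m)
  wmat("trans_i", profile$trans_i)
  wmat("trans_d", profile$trans_d)
  invisible(path)
}

#' Read a serialized profile HMM
#'
#' @param path file written by [write_profile()].
#' @return a `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# sorfscan profile v1", lines[1])) {
    stop("not a sorfscan profile file: ", path)
  }
  kv <- function(key) sub(paste0("^", key, " "), "", grep(paste0("^", key, " "),
                                                          lines, value = TRUE)[1])
  name <- kv("name")
  n <- as.integer(kv("n_match"))
  background <- setNames(as.numeric(strsplit(kv("background"), " +")[[1]]), AA20)
  rmat <- function(tag, ncol, colnm) {
    at <- grep(paste0("^", tag, " "), lines)[1]
    nr <- as.integer(sub(paste0("^", tag, " "), "", lines[at]))
    m <- matrix(NA_real_, nr, ncol, dimnames = list(NULL, colnm))
    for (i in seq_len(nr)) {
      m[i, ] <- as.numeric(strsplit(trimws(lines[at + i]), " +")[[1]])
    }
    m
  }
  structure(list(
    name = name, n_match = n,
    match_emissions = rmat("match_emissions", 20, AA20),
    insert_emissions = rmat("insert_emissions", 20, AA20),
    trans_m = rmat("trans_m", 3, c("M", "I", "D")),
    trans_i = rmat("trans_i", 3, c("M", "I", "D")),
    trans_d = rmat("trans_d", 3, c("M", "I", "D")),
    background = background, match_columns = NULL), class = "profile_hmm")
}
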