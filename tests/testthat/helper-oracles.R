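# Independent oracles and fixture builders used across the suite.
# The oracles re-derive expected values from first principles (plain-R
# dynamic programming, exhaustive window scans) so the optimised code paths
# are checked against a second, separately written implementation.

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")

rc <- function(x) as.character(venomest:::revcomp_cpp(x))

comp1 <- function(x) chartr("ACGT", "TGCA", x)

# plain-R affine-gap local alignment, score only (gap of length L costs
# gap_open + L * gap_extend; N never matches)
oracle_local_score <- function(q, s, match, mismatch, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  Fm <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      Fm[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                      Fm[i - 1, j] + gap_extend)
      sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N") match else
        mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], Fm[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# exhaustive quality-trim oracle: enumerate every segment and keep the
# longest whose every internal window (or the whole segment when shorter
# than the window) has mean quality >= threshold
oracle_quality_trim <- function(qual, window, threshold) {
  n <- length(qual)
  best <- c(0L, 0L)
  for (a in seq_len(n)) {
    for (b in a:n) {
      len <- b - a + 1
      w <- min(window, len)
      ok <- TRUE
      for (st in a:(b - w + 1)) {
        if (mean(qual[st:(st + w - 1)]) < threshold - 1e-9) {
          ok <- FALSE; break
        }
      }
      if (ok && len > best[2] - best[1])
        best <- c(a - 1L, b)
    }
  }
  best
}

# brute-force exact tandem scanner: maximal period-m runs by direct
# character comparison, thresholds in copies, primitive motifs, nested
# reports dropped in favour of the smaller period
oracle_microsats <- function(seq, min_copies = c(12L, 7L, 5L, 4L, 4L, 4L)) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  rows <- list()
  for (m in 1:6) {
    i <- 1
    while (i + 2 * m - 1 <= n) {
      k <- i + m
      while (k <= n && ch[k] == ch[k - m]) k <- k + 1
      runlen <- k - i
      motif <- paste(ch[i:(i + m - 1)], collapse = "")
      prim <- TRUE
      for (d in seq_len(m - 1))
        if (m %% d == 0 &&
            strrep(substr(motif, 1, d), m / d) == motif) prim <- FALSE
      if (runlen >= m * min_copies[m] && runlen >= 2 * m && prim) {
        rows[[length(rows) + 1]] <-
          data.frame(start = i - 1L, end = i - 1L + runlen, period = m)
        i <- k - m + 1
      } else i <- i + 1
    }
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer(),
                                       period = integer()))
  df <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(df))
  for (r in seq_len(nrow(df))) {
    contained <- df$start <= df$start[r] & df$end >= df$end[r] &
      seq_len(nrow(df)) != r
    if (any(contained & (df$period < df$period[r] |
                           (df$period == df$period[r] &
                              seq_len(nrow(df)) < r))))
      keep[r] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$period), , drop = FALSE]
}

# quadratic brute-force inverted-repeat scanner: every anti-diagonal of the
# sequence against its own complement; per anti-diagonal the valid window
# (endpoints match, length >= min_arm, mismatches <= floor(frac * len))
# with the highest match/mismatch score, shorter on ties
oracle_ir_scan <- function(seq, min_arm, frac, match = 1, mismatch = -3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  cc <- comp1(ch)
  rows <- list()
  for (cdiag in 0:(2 * n - 2)) {
    lo <- max(0, cdiag - n + 1)
    hi <- (cdiag - 1) %/% 2
    if (hi - lo + 1 < min_arm) next
    u <- lo:hi
    mvec <- ch[u + 1] == cc[cdiag - u + 1]
    if (!any(mvec)) next
    best <- NULL
    for (ai in which(mvec)) {
      misc <- cumsum(!mvec[ai:length(mvec)])
      L <- seq_along(misc)
      valid <- mvec[ai:length(mvec)] & L >= min_arm &
        misc <= floor(frac * L + 1e-9)
      if (!any(valid)) next
      sc <- (L - misc) * match + misc * mismatch
      sc[!valid] <- -Inf
      bi <- which.max(sc)
      cand <- c(sc[bi], L[bi], ai)
      if (is.null(best) || cand[1] > best[1] ||
          (cand[1] == best[1] && (cand[2] < best[2] ||
                                    (cand[2] == best[2] &&
                                       cand[3] < best[3]))))
        best <- cand
    }
    if (!is.null(best)) {
      a <- lo + best[3] - 1
      b <- a + best[2] - 1
      rows[[length(rows) + 1]] <- data.frame(
        left_start = a, right_start = cdiag - b, arm_length = best[2],
        score = best[1])
    }
  }
  if (!length(rows)) return(data.frame(left_start = integer(),
                                       right_start = integer(),
                                       arm_length = integer(),
                                       score = numeric()))
  do.call(rbind, rows)
}

# insert an exact copy of `donor`'s prefix into `host` at 0-based position
# `at`, mutating the junction bases so the copy cannot be extended by
# chance matches (keeps planted alignment boundaries deterministic)
plant_exact_copy <- function(host, donor, at, len) {
  seg <- substr(donor, 1, len)
  out <- paste0(substr(host, 1, at), seg,
                substr(host, at + 1, nchar(host)))
  after <- at + len + 1
  if (after <= nchar(out) && len + 1 <= nchar(donor)) {
    while (substr(out, after, after) == substr(donor, len + 1, len + 1))
      substr(out, after, after) <- sample(c("A", "C", "G", "T"), 1)
  }
  out
}

# an est_set of identical reads with controlled per-read substitutions
# (list of position -> base) on a shared 0-based template slice
make_column_reads <- function(template, n, subs = list(), quals = NULL,
                              plates = NULL) {
  len <- nchar(template)
  seqs <- character(n)
  qs <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- strsplit(template, "")[[1]]
    qv <- if (is.null(quals)) rep(30L, len) else quals[[i]]
    if (length(subs) >= i && length(subs[[i]]))
      for (p in names(subs[[i]]))
        ch[as.integer(p) + 1] <- subs[[i]][[p]]
    seqs[i] <- paste(ch, collapse = "")
    qs[[i]] <- qv
  }
  est_set(sprintf("r%02d", seq_len(n)), seqs, qs,
          if (is.null(plates)) rep(1L, n) else plates)
}

default_scheme <- function() scoring_scheme()
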