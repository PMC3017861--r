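# EST pre-processing: vector screening, sliding-window quality trimming,
# terminal polyA/polyT trimming, slippage flagging and the 100-bp minimum
# length filter.  Cleaning only ever removes bases: every output read is a
# contiguous interval of its input.

#' Cleaning parameters
#'
#' @param quality_window sliding window (bases) for quality trimming.
#' @param quality_threshold minimum mean PHRED score per window.
#' @param vector_min_score minimum local-alignment score for a read interval
#'   to be excised as vector.
#' @param polyA_min_run minimum number of terminal A's (or 5' T's) to trim.
#' @param polyA_max_mismatch interior non-matching bases tolerated in the
#'   terminal run.
#' @param slippage_window,slippage_dominance window and dominance fraction
#'   of the slippage rule: a read is flagged when a window is dominated by a
#'   single nucleotide or dinucleotide unit.
#' @param min_length reads shorter than this after cleaning are discarded.
#' @return an object of class `cleaning_params`.
#' @export
cleaning_params <- function(quality_window = 20L, quality_threshold = 16,
                            vector_min_score = 20L, polyA_min_run = 10L,
                            polyA_max_mismatch = 1L, slippage_window = 50L,
                            slippage_dominance = 0.8, min_length = 100L) {
  stopifnot(quality_window >= 1, slippage_window >= 1,
            slippage_dominance > 0, slippage_dominance <= 1)
  structure(list(quality_window = as.integer(quality_window),
                 quality_threshold = quality_threshold,
                 vector_min_score = as.integer(vector_min_score),
                 polyA_min_run = as.integer(polyA_min_run),
                 polyA_max_mismatch = as.integer(polyA_max_mismatch),
                 slippage_window = as.integer(slippage_window),
                 slippage_dominance = slippage_dominance,
                 min_length = as.integer(min_length)),
            class = "cleaning_params")
}

#' Quality trimming of a single read
#'
#' Retains the longest contiguous segment in which every sliding window of
#' `quality_window` bases has mean PHRED quality at or above
#' `quality_threshold`.  Reads shorter than the window are assessed as one
#' whole-read window.  A zero-length result is allowed.
#'
#' @param seq DNA string.
#' @param qual integer PHRED vector, same length.
#' @param params a [cleaning_params()].
#' @return list with `start`, `end` (0-based half-open retained interval),
#'   `seq` and `qual` of the retained segment.
#' @export
trim_quality <- function(seq, qual, params = cleaning_params()) {
  len <- nchar(seq)
  if (len != length(qual))
    stop("input error: quality/sequence length mismatch")
  if (len == 0)
    return(list(start = 0L, end = 0L, seq = "", qual = integer()))
  w <- min(params$quality_window, len)
  cs <- c(0, cumsum(qual))
  nwin <- len - w + 1
  means <- (cs[(w + 1):(w + nwin)] - cs[1:nwin]) / w
  ok <- means >= params$quality_threshold - 1e-9
  if (!any(ok))
    return(list(start = 0L, end = 0L, seq = "", qual = integer()))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  seg_len <- r$lengths[runs] + w - 1
  best <- runs[which.max(seg_len)]
  a <- starts[best]; b <- ends[best] + w - 1
  list(start = a - 1L, end = b,
       seq = substr(seq, a, b), qual = qual[a:b])
}

#' Vector screening of a single read
#'
#' Every read interval aligning to a vector-library record with score at
#' least `vector_min_score` (either strand) is excised.  Remaining fragments
#' are joined only when contiguous; otherwise the longest fragment is kept.
#'
#' @param seq,qual read bases and qualities.
#' @param vector_library named character vector of vector/adapter sequences.
#' @param scheme a [scoring_scheme()].
#' @param params a [cleaning_params()].
#' @return list with `start`, `end`, `seq`, `qual` of the kept fragment and
#'   `all_vector` (TRUE when nothing remains).
#' @export
screen_vector <- function(seq, qual, vector_library, scheme,
                          params = cleaning_params()) {
  if (length(vector_library) == 0)
    stop("config error: empty vector library")
  len <- nchar(seq)
  mask <- rep(FALSE, len)
  for (v in seq_along(vector_library)) {
    hits <- search_both_strands(seq, vector_library[[v]], scheme,
                                min_score = params$vector_min_score,
                                max_hits = 8L)
    for (r in seq_len(nrow(hits)))
      mask[(hits$q_start[r] + 1):hits$q_end[r]] <- TRUE
  }
  if (!any(mask))
    return(list(start = 0L, end = len, seq = seq, qual = qual,
                all_vector = FALSE))
  if (all(mask))
    return(list(start = 0L, end = 0L, seq = "", qual = integer(),
                all_vector = TRUE))
  r <- rle(!mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  best <- keep[which.max(r$lengths[keep])]
  a <- starts[best]; b <- ends[best]
  list(start = a - 1L, end = b, seq = substr(seq, a, b), qual = qual[a:b],
       all_vector = FALSE)
}

polya_run_start <- function(chars, min_run, max_mismatch) {
  # index (1-based) where the terminal 3' A-run starts, or NA
  len <- length(chars)
  if (len == 0 || chars[len] != "A") return(NA_integer_)
  mism <- 0L; best <- NA_integer_; n_a <- 0L
  for (j in len:1) {
    if (chars[j] == "A") {
      n_a <- n_a + 1L
      if (n_a >= min_run) best <- j
    } else {
      mism <- mism + 1L
      if (mism > max_mismatch) break
    }
  }
  # run must start with an A; `best` only ever points at A positions
  best
}

#' Terminal polyA / polyT trimming of a single read
#'
#' Removes a terminal run of at least `polyA_min_run` A's at the 3' end (or
#' T's at the 5' end) allowing at most `polyA_max_mismatch` interior
#' non-matching bases.  Interior runs are untouched.
#'
#' @inheritParams trim_quality
#' @return list with `start`, `end`, `seq`, `qual`.
#' @export
trim_polyA_polyT <- function(seq, qual, params = cleaning_params()) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  a <- 1L; b <- len
  st <- polya_run_start(chars, params$polyA_min_run, params$polyA_max_mismatch)
  if (!is.na(st)) b <- st - 1L
  # 5' polyT: same rule on the reversed complemented-sense strand; a
  # leading T-run is the tail seen in the other orientation.
  if (b >= a) {
    lead <- chars[a:b]
    tt <- polya_run_start(rev(chartr("T", "A", chartr("A", "X", lead))),
                          params$polyA_min_run, params$polyA_max_mismatch)
    if (!is.na(tt)) a <- a + (length(lead) - tt + 1L)
  }
  if (a > b)
    return(list(start = 0L, end = 0L, seq = "", qual = integer()))
  list(start = a - 1L, end = b, seq = substr(seq, a, b), qual = qual[a:b])
}

#' Slippage flag for a single read
#'
#' TRUE when some window of `slippage_window` bases is dominated (fraction
#' at or above `slippage_dominance`) by a single nucleotide, or when the
#' read carries an exact dinucleotide-unit tandem run covering that fraction
#' of a window.  Flagged reads are discarded by [clean_pipeline()].
#'
#' @param seq DNA string.
#' @param params a [cleaning_params()].
#' @export
flag_slippage <- function(seq, params = cleaning_params()) {
  slippage_flag_cpp(seq, params$slippage_window, params$slippage_dominance)
}

#' Full cleaning pipeline
#'
#' Applies vector screening, quality trimming, polyA/polyT trimming and the
#' slippage filter, in that order (vector removal precedes the quality
#' windows it would otherwise distort), then discards reads shorter than
#' `min_length`.
#'
#' @param reads an [est_set()].
#' @param vector_library named character vector of vector sequences.
#' @param scheme a [scoring_scheme()].
#' @param params a [cleaning_params()].
#' @return list with `reads` (cleaned, kept reads only) and `report` (one
#'   row per input read: outcome and per-stage trimmed base counts).
#' @export
clean_pipeline <- function(reads, vector_library, scheme,
                           params = cleaning_params()) {
  n <- length(reads)
  outcome <- character(n)
  trimmed_vec <- integer(n); trimmed_q <- integer(n); trimmed_pa <- integer(n)
  final_len <- integer(n)
  out_seq <- character(n); out_qual <- vector("list", n)

  # k-mer prefilter: only reads sharing exact 12-mers with the vector
  # library are aligned against it
  cand <- kmer_candidates_cpp(reads$seq, unlist(vector_library), 12L, 2L)
  has_vec_cand <- lengths(cand) > 0

  for (i in seq_len(n)) {
    s <- reads$seq[i]; q <- reads$qual[[i]]
    len0 <- nchar(s)
    if (has_vec_cand[i]) {
      sv <- screen_vector(s, q, vector_library, scheme, params)
      if (sv$all_vector) {
        outcome[i] <- "discarded_all_vector"
        trimmed_vec[i] <- len0; final_len[i] <- 0L
        next
      }
      trimmed_vec[i] <- len0 - nchar(sv$seq)
      s <- sv$seq; q <- sv$qual
    }
    tq <- trim_quality(s, q, params)
    trimmed_q[i] <- nchar(s) - nchar(tq$seq)
    s <- tq$seq; q <- tq$qual
    if (nchar(s)) {
      tp <- trim_polyA_polyT(s, q, params)
      trimmed_pa[i] <- nchar(s) - nchar(tp$seq)
      s <- tp$seq; q <- tp$qual
    }
    final_len[i] <- nchar(s)
    if (nchar(s) && flag_slippage(s, params)) {
      outcome[i] <- "discarded_slippage"
    } else if (nchar(s) < params$min_length) {
      outcome[i] <- "discarded_short"
    } else {
      outcome[i] <- "kept"
      out_seq[i] <- s; out_qual[[i]] <- q
    }
  }
  keep <- outcome == "kept"
  report <- data.frame(id = reads$id, outcome = outcome,
                       trimmed_vector = trimmed_vec,
                       trimmed_quality = trimmed_q,
                       trimmed_polya = trimmed_pa,
                       final_length = final_len,
                       stringsAsFactors = FALSE)
  cleaned <- est_set(reads$id[keep], out_seq[keep], out_qual[keep],
                     reads$plate[keep])
  list(reads = cleaned, report = report)
}

#' Write a cleaning report as TSV
#' @param report the `report` element of [clean_pipeline()] output.
#' @param path output file.
#' @export
write_cleaning_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
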