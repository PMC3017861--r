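# Local alignment engine shared by cleaning, annotation, repeat mining and
# inverted-repeat discovery.  Alignments are returned as data frames with
# 0-based half-open coordinates on the forward strand of the query.

empty_alignments <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), aligned_length = integer(),
             matches = integer(), mismatches = integer(),
             gap_columns = integer(), identity = numeric(),
             score = integer(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

hits_to_df <- function(hits, query_id, subject_id, strand, qlen) {
  if (length(hits) == 0) return(empty_alignments())
  rows <- lapply(hits, function(h) {
    qs <- h$q_start; qe <- h$q_end
    if (strand == "reverse") { # map back to forward-strand query coordinates
      tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp
    }
    data.frame(query_id = query_id, subject_id = subject_id,
               q_start = qs, q_end = qe,
               s_start = h$s_start, s_end = h$s_end, strand = strand,
               aligned_length = h$aligned_length, matches = h$matches,
               mismatches = h$mismatches, gap_columns = h$gap_columns,
               identity = h$matches / h$aligned_length,
               score = h$score, evalue = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Returns the best-scoring local alignment between `query` and `subject`
#' plus all further local alignments that do not overlap already-reported
#' query intervals and score at least `min_score`, sorted by descending
#' score.  N never counts as a match.  Ties in the dynamic programming are
#' broken deterministically (earliest endpoint in query-then-subject scan
#' order, diagonal moves preferred in the traceback).
#'
#' @param query,subject non-empty DNA strings over A, C, G, T, N.
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum reported score (> 0).
#' @param max_hits cap on the number of reported non-overlapping alignments.
#' @param query_id,subject_id labels carried into the result.
#' @return a data frame of local alignments (possibly zero rows) with
#'   0-based half-open coordinates; `evalue` is `NA` until a search space is
#'   applied by a caller.
#' @examples
#' sc <- scoring_scheme(match = 1, mismatch = -1, gap_open = 0, gap_extend = -2)
#' smith_waterman("ACGT", "TACGTA", sc, min_score = 4)
#' @export
smith_waterman <- function(query, subject, scheme, min_score = 1L,
                           max_hits = 16L, query_id = "query",
                           subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject))
    stop("input error: empty sequence")
  stopifnot(inherits(scheme, "scoring_scheme"), min_score > 0)
  hits <- sw_align_cpp(toupper(query), toupper(subject), scheme$match,
                       scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                       as.integer(min_score), as.integer(max_hits), FALSE)
  df <- hits_to_df(hits, query_id, subject_id, "forward", nchar(query))
  df[order(-df$score, df$q_start, df$s_start), , drop = FALSE]
}

# Internal: best single hit, statistics only (no path; cheaper).
sw_best_stats <- function(query, subject, scheme, min_score = 1L) {
  hits <- sw_align_cpp(toupper(query), toupper(subject), scheme$match,
                       scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                       as.integer(min_score), 1L, FALSE)
  if (length(hits) == 0) NULL else hits[[1]]
}

# Internal: best single hit with alignment path, one orientation.
sw_best_path <- function(query, subject, scheme, min_score = 1L) {
  hits <- sw_align_cpp(toupper(query), toupper(subject), scheme$match,
                       scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                       as.integer(min_score), 1L, TRUE)
  if (length(hits) == 0) NULL else hits[[1]]
}

#' Local alignment of both query strands
#'
#' Runs [smith_waterman()] on the query and on its reverse complement.
#' Reverse-strand hits report query coordinates on the forward strand with
#' `strand = "reverse"`.
#'
#' @inheritParams smith_waterman
#' @return a data frame of local alignments sorted by descending score.
#' @export
search_both_strands <- function(query, subject, scheme, min_score = 1L,
                                max_hits = 16L, query_id = "query",
                                subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject))
    stop("input error: empty sequence")
  fwd <- smith_waterman(query, subject, scheme, min_score, max_hits,
                        query_id, subject_id)
  rc <- revcomp(query)
  hits <- sw_align_cpp(toupper(rc), toupper(subject), scheme$match,
                       scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                       as.integer(min_score), as.integer(max_hits), FALSE)
  rev <- hits_to_df(hits, query_id, subject_id, "reverse", nchar(query))
  out <- rbind(fwd, rev)
  out <- out[order(-out$score, out$q_start, out$s_start), , drop = FALSE]
  # never double-report the same query/subject interval on both strands
  key <- paste(out$q_start, out$q_end, out$s_start, out$s_end)
  out[!duplicated(key), , drop = FALSE]
}

#' Write alignments as BLAST-style 12-column tabular TSV
#'
#' Columns: qid, sid, \%identity, length, mismatches, gapopen, qstart, qend,
#' sstart, send, evalue, score.  Coordinates are 1-based inclusive in this
#' human-readable report (internal objects are 0-based half-open).
#'
#' @param alignments a data frame as produced by the search functions.
#' @param path output file.
#' @export
write_alignment_tsv <- function(alignments, path) {
  a <- alignments
  out <- data.frame(qid = a$query_id, sid = a$subject_id,
                    pident = round(100 * a$identity, 2),
                    length = a$aligned_length, mismatches = a$mismatches,
                    gapopen = a$gap_columns,
                    qstart = a$q_start + 1L, qend = a$q_end,
                    sstart = a$s_start + 1L, send = a$s_end,
                    evalue = signif(a$evalue, 3), score = a$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
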