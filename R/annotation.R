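# Similarity-based annotation of unisequences against a labeled reference
# collection: hit/no-hit status at an E-value cutoff, toxin class of the
# best hit, coding vs 3'UTR-only hit region, reading-frame inference for
# downstream SNP classification, and EST-level abundance summaries with the
# two denominators (all ESTs; toxin ESTs).

# minimum score that can still reach the E-value cutoff in this space
min_score_for_cutoff <- function(cutoff, space, scheme) {
  s <- ceiling(log(scheme$k_const * space$m * space$n / cutoff) /
                 scheme$lambda)
  max(1L, as.integer(s))
}

#' Search a unisequence against a labeled reference collection
#'
#' Both-strand local alignment of the query against every reference record;
#' E-values use the Karlin-Altschul statistics of `scheme` with search
#' space m = query length, n = total reference length.  Hits with E-value
#' at most `evalue_cutoff` are returned ranked by ascending E-value, then
#' descending score, then reference id.
#'
#' @param query DNA string.
#' @param references list with `seq` (named list of reference sequences)
#'   and `info` (data frame with `id`, `class_label`, `cds_start`,
#'   `cds_end`).
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff maximum E-value of a reported hit.
#' @param query_id label carried into the result.
#' @param candidates optional integer vector restricting the reference
#'   records searched (k-mer prefilter output); `NULL` searches all.
#' @return a data frame of qualifying alignments.
#' @export
search_references <- function(query, references, scheme,
                              evalue_cutoff = 1e-5, query_id = "query",
                              candidates = NULL) {
  if (length(references$seq) == 0)
    stop("config error: empty reference collection")
  n_total <- sum(nchar(unlist(references$seq)))
  space <- search_space(nchar(query), n_total)
  smin <- min_score_for_cutoff(evalue_cutoff, space, scheme)
  idx <- if (is.null(candidates)) seq_along(references$seq) else candidates
  hits <- list()
  for (i in idx) {
    rid <- names(references$seq)[i]
    h <- search_both_strands(query, references$seq[[i]], scheme,
                             min_score = smin, max_hits = 4L,
                             query_id = query_id, subject_id = rid)
    if (nrow(h)) hits[[length(hits) + 1]] <- h
  }
  if (!length(hits)) return(empty_alignments())
  out <- do.call(rbind, hits)
  out$evalue <- evalue_of(out$score, space, scheme)
  out <- out[out$evalue <= evalue_cutoff, , drop = FALSE]
  out[order(out$evalue, -out$score, out$subject_id), , drop = FALSE]
}

#' Classify the hit region of an alignment relative to a reference CDS
#'
#' `utr_only` iff the subject interval of the hit is disjoint from the CDS
#' interval; references without CDS annotation yield `coding_unknown`.
#'
#' @param s_start,s_end 0-based half-open subject interval of the hit.
#' @param cds_start,cds_end 0-based half-open CDS interval (NA when
#'   unannotated).
#' @return one of `"coding"`, `"utr_only"`, `"coding_unknown"`.
#' @export
classify_hit_region <- function(s_start, s_end, cds_start, cds_end) {
  if (is.na(cds_start) || is.na(cds_end)) return("coding_unknown")
  if (s_end <= cds_start || s_start >= cds_end) "utr_only" else "coding"
}

#' Infer the reading frame of a unisequence from its best coding hit
#'
#' Maps the aligned interval into codon coordinates of the reference CDS.
#' The frame record carries the strand, the codon phase of oriented query
#' position 0 (`offset`), and a per-position map from oriented query
#' coordinates to subject coordinates (NA inside alignment gaps, where the
#' frame is unknown).  For reverse-strand hits the oriented coordinates are
#' those of the reverse complement of the unisequence.
#'
#' @param query the unisequence.
#' @param ref_seq the best-hit reference sequence.
#' @param strand strand of the best hit.
#' @param cds_start,cds_end reference CDS interval (0-based half-open).
#' @param scheme a [scoring_scheme()].
#' @return list with `strand`, `offset` and `qmap`, or `NULL` when no
#'   coding alignment exists.
#' @export
infer_frame <- function(query, ref_seq, strand, cds_start, cds_end, scheme) {
  if (is.na(cds_start)) return(NULL)
  oriented <- if (strand == "reverse") revcomp(query) else query
  h <- sw_best_path(oriented, ref_seq, scheme)
  if (is.null(h)) return(NULL)
  qmap <- rep(NA_integer_, nchar(query))
  sel <- h$qpath >= 0 & h$spath >= 0
  qmap[h$qpath[sel] + 1] <- h$spath[sel]
  first <- which(sel)[1]
  q0 <- h$qpath[first]; s0 <- h$spath[first]
  offset <- ((s0 - cds_start - q0) %% 3 + 3) %% 3
  list(strand = strand, offset = as.integer(offset), qmap = qmap,
       cds_start = cds_start, cds_end = cds_end)
}

#' Annotate unisequences against a reference collection
#'
#' For each unisequence: hit/no-hit status at the E-value cutoff, the best
#' hit and its class label, the hit region (coding vs 3'UTR-only) and, for
#' coding hits, the inferred reading frame.  A shared-k-mer prefilter skips
#' reference records with no exact 14-mer in common with the query.
#'
#' @param unis the `unisequences` data frame of [build_unisequences()].
#' @param references a labeled reference collection
#'   ([make_reference_collections()] format).
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff hit threshold (default 1e-5).
#' @return list with `table` (one row per unisequence) and `frames` (named
#'   list of frame records for coding hits).
#' @export
annotate_unisequences <- function(unis, references, scheme,
                                  evalue_cutoff = 1e-5) {
  if (length(references$seq) == 0)
    stop("config error: empty reference collection")
  n <- nrow(unis)
  cand <- kmer_candidates_cpp(unis$sequence,
                              unlist(lapply(references$seq, identity)),
                              14L, 1L)
  rows <- vector("list", n)
  frames <- list()
  info <- references$info
  for (i in seq_len(n)) {
    hits <- if (length(cand[[i]]) == 0) empty_alignments() else
      search_references(unis$sequence[i], references, scheme,
                        evalue_cutoff, query_id = unis$id[i],
                        candidates = cand[[i]])
    if (nrow(hits) == 0) {
      rows[[i]] <- data.frame(
        unisequence_id = unis$id[i], status = "no_hit",
        class_label = NA_character_, best_ref = NA_character_,
        evalue = NA_real_, score = NA_integer_, identity = NA_real_,
        strand = NA_character_, hit_region = NA_character_,
        frame_offset = NA_integer_, est_count = unis$member_count[i],
        stringsAsFactors = FALSE)
      next
    }
    best <- hits[1, ]
    ri <- match(best$subject_id, info$id)
    region <- classify_hit_region(best$s_start, best$s_end,
                                  info$cds_start[ri], info$cds_end[ri])
    fr <- NULL
    if (region == "coding") {
      fr <- infer_frame(unis$sequence[i], references$seq[[best$subject_id]],
                        best$strand, info$cds_start[ri], info$cds_end[ri],
                        scheme)
      if (!is.null(fr)) frames[[unis$id[i]]] <- fr
    }
    rows[[i]] <- data.frame(
      unisequence_id = unis$id[i], status = "hit",
      class_label = info$class_label[ri], best_ref = best$subject_id,
      evalue = best$evalue, score = best$score, identity = best$identity,
      strand = best$strand, hit_region = region,
      frame_offset = if (is.null(fr)) NA_integer_ else fr$offset,
      est_count = unis$member_count[i], stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), frames = frames)
}

#' EST-level abundance summary with the two denominators
#'
#' All percentages are computed over ESTs (reads): a contig contributes its
#' member count.  Class percentages are reported both against the total
#' number of ESTs and against the number of toxin ESTs.
#'
#' @param annotations the `table` element of [annotate_unisequences()].
#' @return an object of class `class_abundance`.
#' @export
summarize_abundance <- function(annotations) {
  a <- annotations
  total <- sum(a$est_count)
  hit_est <- sum(a$est_count[a$status == "hit"])
  is_toxin <- a$status == "hit" & a$class_label %in% toxin_classes
  toxin_est <- sum(a$est_count[is_toxin])
  per_class <- vapply(est_classes, function(cl)
    sum(a$est_count[a$status == "hit" &
                      !is.na(a$class_label) & a$class_label == cl]), 1)
  per_class["unknown"] <- sum(a$est_count[a$status == "no_hit"])
  class_pct_of_toxin <- if (toxin_est > 0)
    100 * per_class[toxin_classes] / toxin_est else
    setNames(rep(NA_real_, length(toxin_classes)), toxin_classes)
  structure(list(
    est_total = total, est_hits = hit_est, est_toxin = toxin_est,
    per_class = per_class,
    class_pct_of_total = 100 * per_class / total,
    class_pct_of_toxin = class_pct_of_toxin,
    toxin_pct_of_total = 100 * toxin_est / total,
    hit_pct_of_total = 100 * hit_est / total,
    toxin_pct_of_hits = if (hit_est > 0) 100 * toxin_est / hit_est
                        else NA_real_),
    class = "class_abundance")
}

#' @export
print.class_abundance <- function(x, ...) {
  cat(sprintf("ESTs: %d total, %d hits (%.1f%%), %d toxin (%.1f%% of total, %.1f%% of hits)\n",
              x$est_total, x$est_hits, x$hit_pct_of_total, x$est_toxin,
              x$toxin_pct_of_total, x$toxin_pct_of_hits))
  tox <- x$class_pct_of_toxin
  for (cl in names(tox))
    cat(sprintf("  %-18s %6.1f%% of toxin ESTs\n", cl, tox[[cl]]))
  invisible(x)
}
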