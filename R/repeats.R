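# Transposable-element detection against a repeat library, TE-host chimera
# classification by mask-and-requery, and long inverted-repeat discovery by
# opposite-strand self-comparison.

#' Repeat-search parameters
#'
#' TE annotation gates: E-value at most `te_evalue_cutoff`, alignment
#' length at least `te_min_alignment`, identity strictly above
#' `te_min_identity`, and coverage of at least `te_min_coverage` of the
#' unisequence length.  Chimera classification: eligible when total TE
#' coverage lies strictly inside (`chimera_coverage_min`,
#' `chimera_coverage_max`); after masking, the best host hit must cover at
#' least `chimera_min_host_fraction` of the unmasked length with identity
#' at least `chimera_min_host_identity`.
#'
#' @param te_evalue_cutoff,te_min_alignment,te_min_identity,te_min_coverage
#'   TE annotation gates.
#' @param chimera_coverage_min,chimera_coverage_max open eligibility
#'   interval for total TE coverage.
#' @param chimera_min_host_fraction,chimera_min_host_identity host-hit
#'   gates of the masked re-query.
#' @return an object of class `repeat_search_params`.
#' @export
repeat_search_params <- function(te_evalue_cutoff = 1e-10,
                                 te_min_alignment = 50L,
                                 te_min_identity = 0.80,
                                 te_min_coverage = 0.10,
                                 chimera_coverage_min = 0.10,
                                 chimera_coverage_max = 0.90,
                                 chimera_min_host_fraction = 0.50,
                                 chimera_min_host_identity = 0.70) {
  stopifnot(chimera_coverage_min > 0, chimera_coverage_max < 1,
            chimera_coverage_min < chimera_coverage_max)
  structure(list(te_evalue_cutoff = te_evalue_cutoff,
                 te_min_alignment = as.integer(te_min_alignment),
                 te_min_identity = te_min_identity,
                 te_min_coverage = te_min_coverage,
                 chimera_coverage_min = chimera_coverage_min,
                 chimera_coverage_max = chimera_coverage_max,
                 chimera_min_host_fraction = chimera_min_host_fraction,
                 chimera_min_host_identity = chimera_min_host_identity),
            class = "repeat_search_params")
}

#' Inverted-repeat parameters
#'
#' @param min_arm_length minimum arm length defining a "long" inverted
#'   repeat.
#' @param max_mismatch_fraction upper limit on mismatches between the two
#'   arms (inclusive; 10\% by default).
#' @param self_alignment_evalue_cutoff E-value gate of the arm-pair
#'   self-alignment.
#' @return an object of class `ir_params`.
#' @export
ir_params <- function(min_arm_length = 30L, max_mismatch_fraction = 0.10,
                      self_alignment_evalue_cutoff = 1e-5) {
  structure(list(min_arm_length = as.integer(min_arm_length),
                 max_mismatch_fraction = max_mismatch_fraction,
                 self_alignment_evalue_cutoff = self_alignment_evalue_cutoff),
            class = "ir_params")
}

empty_te_annotations <- function() {
  data.frame(unisequence_id = character(), repeat_id = character(),
             family = character(), q_start = integer(), q_end = integer(),
             strand = character(), identity = numeric(), evalue = numeric(),
             coverage = numeric(), score = integer(),
             stringsAsFactors = FALSE)
}

#' Detect transposable elements in a unisequence
#'
#' Both-strand search against every repeat-library record; reported
#' annotations pass all four gates (E-value, alignment length, identity,
#' coverage of the unisequence), one per non-overlapping query interval,
#' best score first.
#'
#' @param seq unisequence DNA string.
#' @param repeat_library list with `seq` (named list) and `info` (data
#'   frame with `id`, `family`).
#' @param scheme a [scoring_scheme()].
#' @param params a [repeat_search_params()].
#' @param unisequence_id label carried into the result.
#' @param candidates optional indices of repeat records to search.
#' @return data frame of TE annotations.
#' @export
detect_tes <- function(seq, repeat_library, scheme,
                       params = repeat_search_params(),
                       unisequence_id = "seq", candidates = NULL) {
  if (length(repeat_library$seq) == 0)
    stop("config error: empty repeat library")
  qlen <- nchar(seq)
  n_total <- sum(nchar(unlist(repeat_library$seq)))
  space <- search_space(qlen, n_total)
  smin <- min_score_for_cutoff(params$te_evalue_cutoff, space, scheme)
  idx <- if (is.null(candidates)) seq_along(repeat_library$seq) else
    candidates
  hits <- list()
  for (i in idx) {
    rid <- names(repeat_library$seq)[i]
    h <- search_both_strands(seq, repeat_library$seq[[i]], scheme,
                             min_score = smin, max_hits = 4L,
                             query_id = unisequence_id, subject_id = rid)
    if (nrow(h)) hits[[length(hits) + 1]] <- h
  }
  if (!length(hits)) return(empty_te_annotations())
  h <- do.call(rbind, hits)
  h$evalue <- evalue_of(h$score, space, scheme)
  h$coverage <- (h$q_end - h$q_start) / qlen
  pass <- h$evalue <= params$te_evalue_cutoff &
    h$aligned_length >= params$te_min_alignment &
    h$identity > params$te_min_identity &
    h$coverage >= params$te_min_coverage - 1e-12
  h <- h[pass, , drop = FALSE]
  if (nrow(h) == 0) return(empty_te_annotations())
  h <- h[order(-h$score, h$q_start, h$subject_id), , drop = FALSE]
  keep <- logical(nrow(h))
  used <- logical(qlen)
  for (r in seq_len(nrow(h))) {
    span <- (h$q_start[r] + 1):h$q_end[r]
    if (!any(used[span])) { keep[r] <- TRUE; used[span] <- TRUE }
  }
  h <- h[keep, , drop = FALSE]
  fam <- repeat_library$info$family[match(h$subject_id,
                                          repeat_library$info$id)]
  data.frame(unisequence_id = unisequence_id, repeat_id = h$subject_id,
             family = fam, q_start = h$q_start, q_end = h$q_end,
             strand = h$strand, identity = h$identity, evalue = h$evalue,
             coverage = h$coverage, score = h$score,
             stringsAsFactors = FALSE)
}

#' Mask a TE interval with N's
#'
#' @param seq DNA string.
#' @param q_start,q_end 0-based half-open interval to mask.
#' @return the masked sequence (same length).
#' @export
mask_te <- function(seq, q_start, q_end) {
  stopifnot(q_start >= 0, q_end <= nchar(seq), q_end > q_start)
  paste0(substr(seq, 1, q_start), strrep("N", q_end - q_start),
         substr(seq, q_end + 1, nchar(seq)))
}

#' Classify a TE-bearing unisequence as a TE-host chimera
#'
#' Eligible when the total TE coverage lies strictly inside the configured
#' open interval; the TE intervals are then masked and the remainder is
#' re-queried against the host reference collection.  The call is chimeric
#' when the best host hit covers at least the configured fraction of the
#' unmasked length at the configured identity.
#'
#' @param seq unisequence DNA string.
#' @param te_annotations TE annotations of this unisequence
#'   ([detect_tes()]).
#' @param host_references labeled reference collection
#'   ([make_reference_collections()] format).
#' @param scheme a [scoring_scheme()].
#' @param params a [repeat_search_params()].
#' @param unisequence_id label carried into the result.
#' @return list with `call` (`"chimeric"`, `"not_chimeric"` or
#'   `"ineligible"`), a `reason` code, the TE coverage and - when aligned -
#'   host id, fraction and identity.
#' @export
classify_chimera <- function(seq, te_annotations, host_references, scheme,
                             params = repeat_search_params(),
                             unisequence_id = "seq") {
  qlen <- nchar(seq)
  if (is.null(te_annotations) || nrow(te_annotations) == 0)
    return(list(call = "ineligible", reason = "no_te", te_coverage = 0))
  covered <- logical(qlen)
  for (r in seq_len(nrow(te_annotations)))
    covered[(te_annotations$q_start[r] + 1):te_annotations$q_end[r]] <- TRUE
  te_cov <- mean(covered)
  if (te_cov <= params$chimera_coverage_min ||
      te_cov >= params$chimera_coverage_max)
    return(list(call = "ineligible", reason = "coverage_out_of_range",
                te_coverage = te_cov))
  masked <- seq
  for (r in seq_len(nrow(te_annotations)))
    masked <- mask_te(masked, te_annotations$q_start[r],
                      te_annotations$q_end[r])
  unmasked_len <- sum(!covered)
  best <- NULL
  for (i in seq_along(host_references$seq)) {
    rid <- names(host_references$seq)[i]
    h <- search_both_strands(masked, host_references$seq[[i]], scheme,
                             min_score = 20L, max_hits = 1L,
                             query_id = unisequence_id, subject_id = rid)
    if (nrow(h) && (is.null(best) || h$score[1] > best$score))
      best <- h[1, ]
  }
  if (is.null(best))
    return(list(call = "not_chimeric", reason = "no_host_hit",
                te_coverage = te_cov))
  host_fraction <- (best$q_end - best$q_start) / unmasked_len
  chim <- host_fraction >= params$chimera_min_host_fraction - 1e-12 &&
    best$identity >= params$chimera_min_host_identity - 1e-12
  list(call = if (chim) "chimeric" else "not_chimeric",
       reason = if (chim) "host_hit" else "host_hit_below_thresholds",
       te_coverage = te_cov, host_id = best$subject_id,
       host_fraction = host_fraction, host_identity = best$identity,
       masked = masked)
}

#' Detect long inverted repeats by opposite-strand self-comparison
#'
#' Finds gap-free arm pairs in which the right arm is the reverse
#' complement of the left arm up to the mismatch budget: arm length at
#' least `min_arm_length`, mismatch fraction at most
#' `max_mismatch_fraction` (inclusive), and an ungapped self-alignment
#' E-value (search space = sequence length squared) at most the cutoff.
#' Arm pairs never overlap; reported pairs are selected greedily by
#' descending arm length.  The inter-IR length is the gap between the arms.
#'
#' @param seq DNA string.
#' @param scheme a [scoring_scheme()].
#' @param params an [ir_params()].
#' @param unisequence_id label carried into the result.
#' @return data frame of inverted repeats (0-based half-open arm
#'   intervals).
#' @export
detect_inverted_repeats <- function(seq, scheme, params = ir_params(),
                                    unisequence_id = "seq") {
  empty <- data.frame(unisequence_id = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), arm_length = integer(),
                      mismatches = integer(), mismatch_fraction = numeric(),
                      inter_ir_length = integer(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < 2 * params$min_arm_length) return(empty)
  m <- ir_scan_cpp(toupper(seq), params$min_arm_length,
                   params$max_mismatch_fraction, scheme$match,
                   scheme$mismatch)
  if (nrow(m) == 0) return(empty)
  ev <- evalue_of(m[, "score"], search_space(n, n), scheme)
  sel <- ev <= params$self_alignment_evalue_cutoff
  m <- m[sel, , drop = FALSE]; ev <- ev[sel]
  if (nrow(m) == 0) return(empty)
  ord <- order(-m[, "score"], m[, "left_start"])
  m <- m[ord, , drop = FALSE]; ev <- ev[ord]
  used <- logical(n)
  keep <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    span <- c((m[r, "left_start"] + 1):(m[r, "left_start"] +
                                          m[r, "arm_length"]),
              (m[r, "right_start"] + 1):(m[r, "right_start"] +
                                           m[r, "arm_length"]))
    if (!any(used[span])) { keep[r] <- TRUE; used[span] <- TRUE }
  }
  m <- m[keep, , drop = FALSE]; ev <- ev[keep]
  out <- data.frame(
    unisequence_id = unisequence_id,
    left_start = m[, "left_start"],
    left_end = m[, "left_start"] + m[, "arm_length"],
    right_start = m[, "right_start"],
    right_end = m[, "right_start"] + m[, "arm_length"],
    arm_length = m[, "arm_length"], mismatches = m[, "mismatches"],
    mismatch_fraction = m[, "mismatches"] / m[, "arm_length"],
    inter_ir_length = m[, "right_start"] -
      (m[, "left_start"] + m[, "arm_length"]),
    evalue = ev, stringsAsFactors = FALSE)
  out[order(out$left_start), , drop = FALSE]
}

#' Tabulate TE families across unisequences
#'
#' @param annotations combined TE annotations over all unisequences.
#' @return data frame of unisequence counts per family/repeat name,
#'   descending; a unisequence with TEs of two families counts once per
#'   family.
#' @export
summarize_te_families <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0)
    return(data.frame(family = character(), repeat_id = character(),
                      unisequences = integer(), stringsAsFactors = FALSE))
  key <- unique(annotations[, c("unisequence_id", "family", "repeat_id")])
  agg <- aggregate(key$unisequence_id,
                   by = list(family = key$family, repeat_id = key$repeat_id),
                   FUN = function(x) length(unique(x)))
  names(agg)[3] <- "unisequences"
  agg[order(-agg$unisequences, agg$family), , drop = FALSE]
}
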