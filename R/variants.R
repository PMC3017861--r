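# SNP and indel calling from padded contig layouts under read-count,
# allele-support, base-quality, plate-of-origin and gap-free-flank controls,
# synonymous/non-synonymous classification through the annotation frame,
# and exact tandem-repeat (microsatellite) detection with TE exclusion.

#' SNP calling parameters
#'
#' The artifact controls: a contig is eligible only with at least
#' `min_reads_per_contig` reads, every allele needs
#' `min_allele_support` reads of quality at least `min_base_quality`,
#' supporting reads must jointly span at least `min_distinct_plates`
#' sequencing plates, and the flanking `gap_free_flank` layout columns of
#' every supporting read must be pad-free.
#'
#' @param min_reads_per_contig minimum reads per contig (default 3).
#' @param min_distinct_plates minimum plates spanned by supporting reads.
#' @param min_allele_support minimum reads per allele.
#' @param min_base_quality minimum PHRED quality of a supporting base.
#' @param gap_free_flank pad-free flank width in layout columns.
#' @return an object of class `snp_params`.
#' @export
snp_params <- function(min_reads_per_contig = 3L, min_distinct_plates = 2L,
                       min_allele_support = 2L, min_base_quality = 20L,
                       gap_free_flank = 5L) {
  structure(list(min_reads_per_contig = as.integer(min_reads_per_contig),
                 min_distinct_plates = as.integer(min_distinct_plates),
                 min_allele_support = as.integer(min_allele_support),
                 min_base_quality = as.integer(min_base_quality),
                 gap_free_flank = as.integer(gap_free_flank)),
            class = "snp_params")
}

contig_plates <- function(contig) {
  vapply(contig$members, function(m)
    if (is.null(m$plate)) NA_integer_ else as.integer(m$plate), 1L)
}

flank_gap_free <- function(charm, row, col, flank) {
  covered <- which(charm[row, ] != "")
  lo <- max(min(covered), col - flank)
  hi <- min(max(covered), col + flank)
  cols <- setdiff(lo:hi, col)
  !any(charm[row, cols] == "-")
}

#' Call SNPs from a contig layout
#'
#' A layout column yields a SNP iff the contig has at least
#' `min_reads_per_contig` reads; at least two alleles are each supported by
#' `min_allele_support` reads with base quality at or above
#' `min_base_quality`; the supporting reads jointly span
#' `min_distinct_plates` plates; and the flanking columns of every
#' supporting read are pad-free.
#'
#' @param contig a contig object from [build_unisequences()].
#' @param params an [snp_params()].
#' @return data frame of SNP calls (possibly empty): contig id, layout
#'   column, consensus position (0-based), allele summary and support.
#' @export
call_snps <- function(contig, params = snp_params()) {
  empty <- data.frame(contig_id = character(), column = integer(),
                      consensus_pos = integer(), alleles = character(),
                      n_plates = integer(), depth = integer(),
                      stringsAsFactors = FALSE)
  plates <- contig_plates(contig)
  if (any(is.na(plates)))
    stop("eligibility error: contig members lack plate tags")
  if (length(contig$members) < params$min_reads_per_contig) return(empty)
  lay <- contig$layout
  charm <- lay$charm; qualm <- lay$qualm
  out <- list()
  cons_lookup <- match(seq_along(lay$keys), lay$cons_col)
  for (col in seq_along(lay$keys)) {
    base_rows <- which(charm[, col] %in% c("A", "C", "G", "T") &
                         !is.na(qualm[, col]) &
                         qualm[, col] >= params$min_base_quality)
    if (length(base_rows) < 2 * params$min_allele_support) next
    tab <- table(charm[base_rows, col])
    good <- names(tab)[tab >= params$min_allele_support]
    if (length(good) < 2) next
    sup_rows <- base_rows[charm[base_rows, col] %in% good]
    if (length(unique(plates[sup_rows])) < params$min_distinct_plates) next
    if (!all(vapply(sup_rows, function(r)
      flank_gap_free(charm, r, col, params$gap_free_flank), TRUE))) next
    tab <- sort(tab[good], decreasing = TRUE)
    out[[length(out) + 1]] <- data.frame(
      contig_id = contig$contig_id, column = col - 1L,
      consensus_pos = cons_lookup[col] - 1L,
      alleles = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                      collapse = "|"),
      n_plates = length(unique(plates[sup_rows])),
      depth = sum(charm[, col] != ""), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Call indels from a contig layout
#'
#' A maximal run of adjacent pad-containing layout columns in which both
#' the padded and the unpadded allele meet the SNP support, quality and
#' plate rules yields one indel call.
#'
#' @inheritParams call_snps
#' @return data frame of indel calls.
#' @export
call_indels <- function(contig, params = snp_params()) {
  empty <- data.frame(contig_id = character(), col_start = integer(),
                      col_end = integer(), bases = character(),
                      n_pad = integer(), n_base = integer(),
                      stringsAsFactors = FALSE)
  plates <- contig_plates(contig)
  if (any(is.na(plates)))
    stop("eligibility error: contig members lack plate tags")
  if (length(contig$members) < params$min_reads_per_contig) return(empty)
  lay <- contig$layout
  charm <- lay$charm; qualm <- lay$qualm
  ncol <- length(lay$keys)
  ok <- logical(ncol)
  for (col in seq_len(ncol)) {
    pad_rows <- which(charm[, col] == "-" & !is.na(qualm[, col]) &
                        qualm[, col] >= params$min_base_quality)
    base_rows <- which(charm[, col] %in% c("A", "C", "G", "T") &
                         !is.na(qualm[, col]) &
                         qualm[, col] >= params$min_base_quality)
    if (length(pad_rows) < params$min_allele_support ||
        length(base_rows) < params$min_allele_support) next
    sup <- c(pad_rows, base_rows)
    if (length(unique(plates[sup])) < params$min_distinct_plates) next
    ok[col] <- TRUE
  }
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    cols <- starts[k]:ends[k]
    bases <- vapply(cols, function(col) {
      b <- charm[charm[, col] %in% c("A", "C", "G", "T"), col]
      names(sort(table(b), decreasing = TRUE))[1]
    }, "")
    data.frame(contig_id = contig$contig_id, col_start = starts[k] - 1L,
               col_end = ends[k], bases = paste(bases, collapse = ""),
               n_pad = sum(charm[, cols[1]] == "-"),
               n_base = sum(charm[, cols[1]] %in% c("A", "C", "G", "T")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify a SNP as synonymous, non-synonymous, noncoding or frame-unknown
#'
#' Substitutes each allele into its codon (through the annotation frame of
#' the contig) and compares the encoded residues under the standard genetic
#' code.  The result does not depend on which allele is taken as reference.
#'
#' @param consensus contig consensus sequence.
#' @param position 0-based consensus position of the SNP.
#' @param alleles character vector of two (or more) allele bases, as they
#'   appear in the consensus orientation.
#' @param frame a frame record from [infer_frame()], or `NULL` when the
#'   contig's hit is 3'UTR-only (yields `"noncoding"`).
#' @return list with `classification` and, when coding, the codons and
#'   residues per allele.
#' @export
classify_snp <- function(consensus, position, alleles, frame) {
  if (is.null(frame))
    return(list(classification = "noncoding"))
  len <- nchar(consensus)
  oriented <- consensus; p <- position
  if (frame$strand == "reverse") {
    oriented <- revcomp(consensus)
    p <- len - 1L - position
    alleles <- vapply(alleles, function(a) revcomp(a), "")
  }
  s <- frame$qmap[p + 1]
  if (is.na(s)) return(list(classification = "frame_unknown"))
  if (s < frame$cds_start || s >= frame$cds_end)
    return(list(classification = "noncoding"))
  phase <- ((p + frame$offset) %% 3 + 3) %% 3
  c0 <- p - phase
  if (c0 < 0 || c0 + 2 >= len)
    return(list(classification = "frame_unknown"))
  # all three codon positions must map gaplessly inside the CDS
  smap <- frame$qmap[(c0 + 1):(c0 + 3)]
  if (any(is.na(smap)) || any(diff(smap) != 1) ||
      smap[1] < frame$cds_start || smap[3] >= frame$cds_end)
    return(list(classification = "frame_unknown"))
  codon <- substr(oriented, c0 + 1, c0 + 3)
  codons <- vapply(alleles, function(a) {
    cc <- strsplit(codon, "")[[1]]; cc[phase + 1] <- a
    paste(cc, collapse = "")
  }, "")
  residues <- vapply(codons, translate_codon, "")
  cls <- if (length(unique(residues)) == 1) "synonymous" else "nonsynonymous"
  list(classification = cls, codons = codons, residues = residues)
}

#' Exact microsatellite detection
#'
#' Maximal exact tandem arrays of primitive motifs of length 1-6 meeting
#' per-class minimum copy numbers.  Motifs are reported in their canonical
#' rotation (lexicographically smallest); nested reports (an array wholly
#' contained in another) are suppressed, preferring the shorter period.
#'
#' @param seq DNA string.
#' @param unisequence_id label carried into the result.
#' @param min_copies integer vector of minimum (full) copy numbers for
#'   motif lengths 1 to 6.
#' @return data frame: unisequence_id, motif, period, copies, start, end
#'   (0-based half-open).
#' @export
find_microsatellites <- function(seq, unisequence_id = "seq",
                                 min_copies = c(12L, 7L, 5L, 4L, 4L, 4L)) {
  m <- microsat_scan_cpp(toupper(seq), as.integer(min_copies))
  empty <- data.frame(unisequence_id = character(), motif = character(),
                      period = integer(), copies = numeric(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(m) == 0) return(empty)
  motif <- substr(rep(seq, nrow(m)), m[, "start"] + 1,
                  m[, "start"] + m[, "period"])
  prim <- vapply(seq_len(nrow(m)), function(r)
    is_primitive_motif(motif[r]), TRUE)
  m <- m[prim, , drop = FALSE]; motif <- motif[prim]
  if (nrow(m) == 0) return(empty)
  canon <- vapply(motif, canonical_rotation, "")
  df <- data.frame(unisequence_id = unisequence_id, motif = canon,
                   period = m[, "period"],
                   copies = m[, "run_length"] / m[, "period"],
                   start = m[, "start"],
                   end = m[, "start"] + m[, "run_length"],
                   stringsAsFactors = FALSE)
  # suppress nested arrays: keep the report with the smaller period
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

is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1) return(TRUE)
  for (d in seq_len(m - 1)) {
    if (m %% d != 0) next
    if (strrep(substr(motif, 1, d), m / d) == motif) return(FALSE)
  }
  TRUE
}

canonical_rotation <- function(motif) {
  m <- nchar(motif)
  if (m == 1) return(motif)
  rots <- vapply(seq_len(m), function(i)
    paste0(substr(motif, i, m), substr(motif, 1, i - 1)), "")
  min(rots)
}

#' Remove microsatellites on TE-annotated unisequences
#'
#' Sequence-level exclusion: any microsatellite on a unisequence carrying a
#' transposable-element annotation is dropped.
#'
#' @param repeats microsatellite data frame ([find_microsatellites()]).
#' @param te_annotations TE annotation data frame ([detect_tes()]).
#' @return the filtered microsatellite data frame.
#' @export
exclude_te_overlaps <- function(repeats, te_annotations) {
  if (is.null(te_annotations) || nrow(te_annotations) == 0) return(repeats)
  repeats[!(repeats$unisequence_id %in% te_annotations$unisequence_id), ,
          drop = FALSE]
}
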