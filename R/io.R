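# FASTA + PHRED .qual sidecar IO and the EST read container.
# FASTA goes through Biostrings; the .qual sidecar (">id" header lines
# followed by whitespace-separated PHRED integers) has no reader in the
# installed stack, so a small one lives here.

#' Container for single-pass EST reads
#'
#' Holds read ids, bases, per-base PHRED qualities and the plate (sequencing
#' batch) of origin.
#'
#' @param id character vector of unique read ids.
#' @param seq character vector of DNA sequences.
#' @param qual list of integer vectors, one per read, same lengths as `seq`.
#' @param plate integer vector of plate-of-origin tags.
#' @return an object of class `est_set`.
#' @export
est_set <- function(id, seq, qual, plate) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  plate <- as.integer(plate)
  stopifnot(length(seq) == length(id), length(qual) == length(id),
            length(plate) == length(id), !anyDuplicated(id))
  if (any(nchar(seq) != lengths(qual)))
    stop("input error: quality/sequence length mismatch")
  structure(list(id = id, seq = seq, qual = qual, plate = plate),
            class = "est_set")
}

#' @export
length.est_set <- function(x) length(x$id)

#' @export
`[.est_set` <- function(x, i) {
  est_set(x$id[i], x$seq[i], x$qual[i], x$plate[i])
}

#' @export
print.est_set <- function(x, ...) {
  cat(sprintf("est_set: %d reads, %d plates, length %d-%d (mean %.1f)\n",
              length(x), length(unique(x$plate)),
              if (length(x)) min(nchar(x$seq)) else 0L,
              if (length(x)) max(nchar(x$seq)) else 0L,
              if (length(x)) mean(nchar(x$seq)) else 0))
  invisible(x)
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings returning / accepting named character
#' vectors.
#' @param x named character vector of sequences.
#' @param path file path.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(unname(x))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Read and write PHRED .qual sidecar files
#'
#' @param quals named list of integer vectors.
#' @param path file path.
#' @export
write_qual <- function(quals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(quals)) {
    writeLines(paste0(">", names(quals)[i]), con)
    q <- quals[[i]]
    if (length(q))
      writeLines(vapply(split(q, ceiling(seq_along(q) / 20)),
                        paste, collapse = " ", FUN.VALUE = ""), con)
  }
  invisible(path)
}

#' @rdname write_qual
#' @export
read_qual <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  body <- split(lines[!hdr], idx[!hdr])
  out <- lapply(body, function(b)
    as.integer(unlist(strsplit(paste(b, collapse = " "), "\\s+"))[
      nzchar(unlist(strsplit(paste(b, collapse = " "), "\\s+")))]))
  # headers with no quality lines (empty reads)
  full <- setNames(vector("list", length(ids)), ids)
  present <- as.integer(names(body))
  for (k in seq_along(body)) full[[present[k]]] <- out[[k]]
  full[vapply(full, is.null, TRUE)] <- list(integer())
  full
}

#' Write / read an `est_set` as FASTA plus .qual sidecar
#'
#' The plate tag is stored in the FASTA description as `plate=<n>`.
#'
#' @param reads an [est_set()].
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.fasta.qual`.
#' @export
write_est_set <- function(reads, prefix) {
  seqs <- setNames(reads$seq, paste0(reads$id, " plate=", reads$plate))
  write_fasta(seqs, paste0(prefix, ".fasta"))
  write_qual(setNames(reads$qual, reads$id), paste0(prefix, ".fasta.qual"))
  invisible(prefix)
}

#' @rdname write_est_set
#' @export
read_est_set <- function(prefix) {
  set <- Biostrings::readDNAStringSet(paste0(prefix, ".fasta"))
  full_names <- names(set)
  ids <- sub("\\s.*$", "", full_names)
  plate <- suppressWarnings(as.integer(sub(".*plate=(\\d+).*", "\\1",
                                           full_names)))
  plate[is.na(plate)] <- 1L
  quals <- read_qual(paste0(prefix, ".fasta.qual"))
  est_set(ids, as.character(set), quals[ids], plate)
}
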