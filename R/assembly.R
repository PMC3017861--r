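# Overlap clustering and consensus assembly.  Cleaned reads are clustered by
# the transitive closure of accepted pairwise overlaps (>= 100 bp and >= 95%
# identity over the overlap alignment) and each cluster is assembled by a
# greedy progressive layout with a quality-weighted consensus.  This is a
# deliberately simple assembler, not a CAP3 re-implementation.

#' Assembly parameters
#'
#' @param min_overlap minimum accepted overlap length (alignment columns).
#' @param min_identity minimum identity over the overlap alignment
#'   (inclusive boundary: exactly 95\% is accepted).
#' @param kmer,kmer_stride,kmer_min_shared candidate-pair prefilter: only
#'   read pairs sharing at least `kmer_min_shared` sampled canonical k-mers
#'   are aligned.
#' @return an object of class `assembly_params`.
#' @export
assembly_params <- function(min_overlap = 100L, min_identity = 0.95,
                            kmer = 16L, kmer_stride = 5L,
                            kmer_min_shared = 3L) {
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity, kmer = as.integer(kmer),
                 kmer_stride = as.integer(kmer_stride),
                 kmer_min_shared = as.integer(kmer_min_shared)),
            class = "assembly_params")
}

#' Pairwise overlap detection
#'
#' Best local alignment between two reads (both orientations of `b`);
#' accepted iff the alignment spans at least `min_overlap` columns with
#' identity at least `min_identity`.
#'
#' @param a,b DNA strings.
#' @param scheme a [scoring_scheme()].
#' @param params an [assembly_params()].
#' @return `NULL` when rejected, otherwise a list with the alignment
#'   statistics, `strand` of `b` relative to `a` and the implied relative
#'   offset.
#' @export
detect_overlap <- function(a, b, scheme, params = assembly_params()) {
  fh <- sw_best_stats(a, b, scheme)
  rh <- sw_best_stats(a, revcomp(b), scheme)
  best <- NULL; strand <- "forward"
  if (!is.null(fh)) best <- fh
  if (!is.null(rh) && (is.null(best) || rh$score > best$score)) {
    best <- rh; strand <- "reverse"
  }
  if (is.null(best)) return(NULL)
  identity <- best$matches / best$aligned_length
  if (best$aligned_length < params$min_overlap ||
      identity < params$min_identity - 1e-12)
    return(NULL)
  list(score = best$score, strand = strand, identity = identity,
       aligned_length = best$aligned_length,
       a_start = best$q_start, a_end = best$q_end,
       b_start = best$s_start, b_end = best$s_end,
       offset = best$q_start - best$s_start)
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster reads by accepted overlaps
#'
#' Transitive closure (union-find) over accepted pairwise overlaps.
#' Candidate pairs come from the shared-k-mer prefilter; pairs already in
#' the same component are skipped without alignment, which leaves the
#' closure unchanged.  Clusters are ordered by their smallest member read
#' id, making the partition independent of input order.
#'
#' @param reads an [est_set()].
#' @param scheme a [scoring_scheme()].
#' @param params an [assembly_params()].
#' @return list with `clusters` (list of integer index vectors into
#'   `reads`, only components of size >= 2), `singletons` (integer vector),
#'   and `edges` (accepted overlaps: i, j, score, strand).
#' @export
cluster_reads <- function(reads, scheme, params = assembly_params()) {
  n <- length(reads)
  ord <- order(reads$id)
  reads <- reads[ord]
  cand <- kmer_pair_counts_cpp(reads$seq, params$kmer, params$kmer_stride,
                               params$kmer_min_shared, 100000L)
  parent <- seq_len(n)
  edges <- list()
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri == rj) next
      ov <- detect_overlap(reads$seq[i], reads$seq[j], scheme, params)
      if (is.null(ov)) next
      parent[max(ri, rj)] <- min(ri, rj)
      edges[[length(edges) + 1]] <-
        data.frame(i = i, j = j, score = ov$score, strand = ov$strand,
                   stringsAsFactors = FALSE)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  comp <- split(seq_len(n), roots)
  sizes <- lengths(comp)
  first_id <- vapply(comp, function(ix) min(reads$id[ix]), "")
  comp <- comp[order(first_id)]
  sizes <- lengths(comp)
  list(reads = reads,
       clusters = unname(comp[sizes >= 2]),
       singletons = sort(unlist(unname(comp[sizes == 1]))),
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(i = integer(), j = integer(), score = integer(),
                    strand = character()))
}

# fill NA pad qualities with the nearest covered base quality of the read
fill_pad_quals <- function(q) {
  na <- which(is.na(q))
  if (!length(na)) return(q)
  ok <- which(!is.na(q))
  if (!length(ok)) return(rep(0L, length(q)))
  near <- ok[pmax(1L, findInterval(na, ok))]
  q[na] <- q[near]
  q
}

place_read <- function(state, rid, seq, qual, plate, scheme, params) {
  fh <- sw_best_path(seq, state$ref, scheme)
  rseq <- revcomp(seq)
  rh <- sw_best_path(rseq, state$ref, scheme)
  strand <- "forward"; h <- fh; r <- seq; rq <- qual
  if (!is.null(rh) && (is.null(fh) || rh$score > fh$score)) {
    strand <- "reverse"; h <- rh; r <- rseq; rq <- rev(qual)
  }
  if (is.null(h)) return(NULL)
  min_ov <- min(params$min_overlap, nchar(state$ref), nchar(seq))
  if (h$aligned_length < min_ov ||
      h$matches / h$aligned_length < params$min_identity - 1e-12)
    return(NULL)

  qlen <- nchar(r)
  reflen <- nchar(state$ref)
  gref <- state$g  # key of backbone position 0 as seen by this alignment
  keys <- numeric(0); chars <- character(0); quals <- integer(0)
  rb <- strsplit(r, "")[[1]]

  # left unaligned read prefix: incorporate only if it overhangs the
  # backbone start (internal clipped prefixes are dropped)
  if (h$q_start > 0 && h$s_start == 0) {
    ext <- rb[1:h$q_start]
    state$ref <- paste0(paste(ext, collapse = ""), state$ref)
    state$g <- state$g - h$q_start
    keys <- c(keys, state$g + 0:(h$q_start - 1))
    chars <- c(chars, ext); quals <- c(quals, rq[1:h$q_start])
  }
  # aligned columns: keys are gref + backbone position; read insertions
  # relative to the backbone take fractional keys after their anchor
  qp <- h$qpath; sp <- h$spath
  is_ins <- sp < 0
  idx <- seq_along(sp)
  anchor <- cummax(ifelse(is_ins, -1L, sp))        # last backbone position
  run_pos <- idx - cummax(ifelse(is_ins, 0L, idx)) # index within ins run
  akeys <- ifelse(is_ins, gref + anchor + run_pos / 1000, gref + sp)
  achars <- ifelse(qp >= 0, rb[pmax(qp, 0L) + 1], "-")
  aquals <- ifelse(qp >= 0, rq[pmax(qp, 0L) + 1], NA_integer_)
  keys <- c(keys, akeys); chars <- c(chars, achars)
  quals <- c(quals, aquals)
  # right unaligned read suffix: incorporate only if it overhangs the
  # backbone end
  if (h$q_end < qlen && h$s_end == reflen) {
    ext <- rb[(h$q_end + 1):qlen]
    keys <- c(keys, gref + reflen + 0:(length(ext) - 1))
    chars <- c(chars, ext); quals <- c(quals, rq[(h$q_end + 1):qlen])
    state$ref <- paste0(state$ref, paste(ext, collapse = ""))
  }
  state$placements[[length(state$placements) + 1]] <-
    list(read_id = rid, strand = strand, keys = keys, chars = chars,
         quals = fill_pad_quals(quals), plate = plate)
  state
}

consensus_from_placements <- function(placements) {
  all_keys <- sort(unique(unlist(lapply(placements, `[[`, "keys"))))
  ncol <- length(all_keys)
  nm <- length(placements)
  charm <- matrix("", nm, ncol)
  qualm <- matrix(NA_integer_, nm, ncol)
  for (m in seq_len(nm)) {
    p <- placements[[m]]
    ix <- match(p$keys, all_keys)
    charm[m, ix] <- p$chars
    qualm[m, ix] <- p$quals
    # a read spans its full placed range: mark uncovered internal columns
    # (columns introduced by other reads' insertions) as pads
    rng <- range(ix)
    inside <- setdiff(seq(rng[1], rng[2]), ix)
    if (length(inside)) {
      charm[m, inside] <- "-"
      qualm[m, inside] <- fill_pad_quals(qualm[m, seq(rng[1], rng[2])])[
        inside - rng[1] + 1]
    }
  }
  symbols <- c("A", "C", "G", "T", "N", "-")
  wt <- matrix(0, length(symbols), ncol)
  for (s in seq_along(symbols)) {
    sel <- charm == symbols[s]
    sel[is.na(qualm)] <- FALSE
    wt[s, ] <- colSums(qualm * sel, na.rm = TRUE)
  }
  # quality-weighted majority; ties by symbol order (bases before pad)
  win <- apply(wt, 2, which.max)
  cons_char <- symbols[win]
  depth <- colSums(charm != "")
  is_base <- cons_char != "-"
  consensus <- paste(cons_char[is_base], collapse = "")
  list(keys = all_keys, charm = charm, qualm = qualm,
       cons_char = cons_char, consensus = consensus,
       cons_col = which(is_base), depth = depth)
}

#' Assemble one cluster into a contig (or several consistent sub-contigs)
#'
#' Greedy progressive layout: the seed is an endpoint of the highest-scoring
#' accepted overlap (falling back to the longest read) and members join in
#' Prim order over the overlap graph, each placed by its best local
#' alignment to the growing backbone; reverse-strand members are stored
#' reverse-complemented.  The consensus takes, per layout column, the
#' quality-weighted majority symbol (ties broken by base order, pads last);
#' pad-majority columns are dropped from the consensus.  Members that
#' cannot be placed consistently seed additional sub-contigs rather than
#' being force-merged.
#'
#' @param reads an [est_set()] holding exactly the cluster members.
#' @param scheme a [scoring_scheme()].
#' @param params an [assembly_params()].
#' @param edges optional accepted-overlap edges (local indices) used for
#'   the placement order.
#' @return a list of contig objects (usually one), each with `consensus`,
#'   `members` (placements with padded columns, qualities, plates) and the
#'   padded layout matrices.
#' @export
assemble_cluster <- function(reads, scheme, params = assembly_params(),
                             edges = NULL) {
  n <- length(reads)
  stopifnot(n >= 1)
  remaining <- seq_len(n)
  out <- list()

  order_next <- function(placed, remaining) {
    # Prim order on the overlap edge list; fall back to length
    if (!is.null(edges) && nrow(edges)) {
      sel <- (edges$i %in% placed & edges$j %in% remaining) |
             (edges$j %in% placed & edges$i %in% remaining)
      if (any(sel)) {
        e <- edges[sel, , drop = FALSE]
        e <- e[which.max(e$score), ]
        return(if (e$i %in% remaining) e$i else e$j)
      }
    }
    remaining[which.max(nchar(reads$seq[remaining]))]
  }

  while (length(remaining)) {
    # seed: endpoint of the best remaining edge, else the longest read
    seed <- NULL
    if (!is.null(edges) && nrow(edges)) {
      sel <- edges$i %in% remaining & edges$j %in% remaining
      if (any(sel)) {
        e <- edges[sel, , drop = FALSE]
        seed <- e$i[which.max(e$score)]
      }
    }
    if (is.null(seed))
      seed <- remaining[which.max(nchar(reads$seq[remaining]))]
    state <- list(ref = reads$seq[seed], g = 0L,
                  placements = list(
                    list(read_id = reads$id[seed], strand = "forward",
                         keys = 0:(nchar(reads$seq[seed]) - 1),
                         chars = strsplit(reads$seq[seed], "")[[1]],
                         quals = reads$qual[[seed]],
                         plate = reads$plate[seed])))
    placed <- seed
    remaining <- setdiff(remaining, seed)
    failed <- integer(0)
    while (length(remaining)) {
      i <- order_next(placed, remaining)
      st2 <- place_read(state, reads$id[i], reads$seq[i], reads$qual[[i]],
                        reads$plate[i], scheme, params)
      remaining <- setdiff(remaining, i)
      if (is.null(st2)) failed <- c(failed, i)
      else { state <- st2; placed <- c(placed, i) }
    }
    lay <- consensus_from_placements(state$placements)
    out[[length(out) + 1]] <-
      structure(list(contig_id = NA_character_,
                     consensus = lay$consensus,
                     members = state$placements,
                     layout = lay,
                     member_ids = vapply(state$placements, `[[`, "",
                                         "read_id")),
                class = "contig")
    remaining <- failed   # inconsistent members start a new sub-contig
  }
  out
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig %s: %d members, consensus %d bp\n",
              x$contig_id, length(x$members), nchar(x$consensus)))
  invisible(x)
}

#' Cluster and assemble cleaned reads into unisequences
#'
#' Every read ends up in exactly one unisequence: a contig (>= 2 members)
#' or a singleton.  Contigs come first with stable ids in cluster order.
#'
#' @param reads an [est_set()] of cleaned reads.
#' @param scheme a [scoring_scheme()].
#' @param params an [assembly_params()].
#' @return list with `unisequences` (data frame: id, kind, sequence,
#'   member_count, plus a `members` list column of read ids) and `contigs`
#'   (named list of contig objects with layouts).
#' @export
build_unisequences <- function(reads, scheme, params = assembly_params()) {
  cl <- cluster_reads(reads, scheme, params)
  reads <- cl$reads
  contigs <- list()
  uni_rows <- list()
  members_col <- list()
  cn <- 0L
  for (cluster in cl$clusters) {
    sub <- reads[cluster]
    loc_edges <- cl$edges[cl$edges$i %in% cluster & cl$edges$j %in% cluster, ,
                          drop = FALSE]
    if (nrow(loc_edges)) {
      loc_edges$i <- match(loc_edges$i, cluster)
      loc_edges$j <- match(loc_edges$j, cluster)
    }
    parts <- assemble_cluster(sub, scheme, params, edges = loc_edges)
    for (ctg in parts) {
      if (length(ctg$members) >= 2) {
        cn <- cn + 1L
        ctg$contig_id <- sprintf("CTG%04d", cn)
        contigs[[ctg$contig_id]] <- ctg
        uni_rows[[length(uni_rows) + 1]] <- data.frame(
          id = ctg$contig_id, kind = "contig", sequence = ctg$consensus,
          member_count = length(ctg$members), stringsAsFactors = FALSE)
        members_col[[length(members_col) + 1]] <- ctg$member_ids
      } else {
        # sub-contig of one: emit as singleton below
        cl$singletons <- c(cl$singletons,
                           which(reads$id == ctg$member_ids[1]))
      }
    }
  }
  sg <- sort(unique(cl$singletons))
  for (k in seq_along(sg)) {
    i <- sg[k]
    uni_rows[[length(uni_rows) + 1]] <- data.frame(
      id = sprintf("SGT%05d", k), kind = "singleton",
      sequence = reads$seq[i], member_count = 1L, stringsAsFactors = FALSE)
    members_col[[length(members_col) + 1]] <- reads$id[i]
  }
  unis <- do.call(rbind, uni_rows)
  if (is.null(unis))
    unis <- data.frame(id = character(), kind = character(),
                       sequence = character(), member_count = integer(),
                       stringsAsFactors = FALSE)
  unis$members <- I(members_col)
  list(unisequences = unis, contigs = contigs)
}
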