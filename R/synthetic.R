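# Synthetic EST library generator.  Emulates a three-plate single-pass
# venom-gland cDNA library: a toxin-dominated class mixture, a truncated
# normal post-cleaning length model, 5' vector and 3' polyA decorations with
# quality decay, per-base miscalls, and planted SNPs, indels,
# microsatellites, transposable elements and inverted repeats with a full
# ground-truth registry.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generator configuration
#'
#' Defaults encode the study conditions the rest of the package is exercised
#' under: 30\% of ESTs annotatable of which roughly three quarters are
#' toxin-related (toxin reads are 23\% of all reads), a toxin-class mixture
#' dominated by metalloproteinases (81\% of toxin reads) ahead of BPP/CNP
#' precursors (8.8\%), phospholipases A2 (5.6\%), serine proteinases (1.9\%)
#' and C-type lectins (1.5\%), and post-cleaning read lengths on
#' [100, 848] bp with mean 562 bp.
#'
#' @param n_reads number of reads to generate.
#' @param n_plates number of sequencing plates (libraries of origin).
#' @param toxin_fraction_of_total probability a read is toxin-derived.
#' @param hit_fraction_of_total probability a read derives from an
#'   annotatable (reference-represented) template; must be >= the toxin
#'   fraction.
#' @param toxin_class_mixture named probabilities over [toxin_classes],
#'   summing to 1.
#' @param length_model list (`mean`, `sd`, `min`, `max`): truncated normal
#'   model of the post-cleaning read length in bp.
#' @param decoration_model list with 5' vector prefix probability and length
#'   model (`vector_prob`, `vector_mean`, `vector_sd`), 3' polyA tail
#'   (`polya_prob`, `polya_length`), core base quality (`q_mean`, `q_sd`,
#'   `q_min`, `q_max`), and the linear PHRED decay over the tail
#'   (`decay_start`, `decay_slope`).
#' @param per_base_error substitution miscall probability; miscalled bases
#'   get low PHRED scores (idealised base-caller calibration).
#' @param n_templates named integer vector: number of distinct transcript
#'   species per class.
#' @param snp_loci,indel_loci,microsat_loci,te_insertions,ir_insertions
#'   `"auto"` for the default planting (a small set of each feature type),
#'   `NULL` for none, or a data frame as produced by the planting helpers.
#' @param seed integer seed; all generator output is a deterministic
#'   function of the configuration including the seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(
    n_reads = 5000L,
    n_plates = 3L,
    toxin_fraction_of_total = 0.23,
    hit_fraction_of_total = 0.30,
    toxin_class_mixture = c(metalloproteinase = 0.81, BPP_CNP = 0.088,
                            PLA2 = 0.056, serine_proteinase = 0.019,
                            C_type_lectin = 0.015, other_toxin = 0.012),
    length_model = list(mean = 573, sd = 150, min = 100, max = 848),
    decoration_model = list(vector_prob = 0.5, vector_mean = 40,
                            vector_sd = 8, polya_prob = 0.85,
                            polya_length = 25L, q_mean = 35, q_sd = 3,
                            q_min = 25, q_max = 45, decay_start = 28,
                            decay_slope = -1),
    per_base_error = 0.005,
    n_templates = c(metalloproteinase = 22L, BPP_CNP = 4L, PLA2 = 4L,
                    serine_proteinase = 5L, C_type_lectin = 5L,
                    other_toxin = 6L, non_toxin = 40L, unknown = 2000L),
    snp_loci = "auto", indel_loci = "auto", microsat_loci = "auto",
    te_insertions = "auto", ir_insertions = "auto",
    seed = 1L) {
  stopifnot(n_reads > 0, n_plates >= 1,
            toxin_fraction_of_total >= 0, toxin_fraction_of_total <= 1,
            hit_fraction_of_total >= toxin_fraction_of_total,
            hit_fraction_of_total <= 1,
            length_model$min <= length_model$max,
            per_base_error >= 0, per_base_error <= 1)
  if (abs(sum(toxin_class_mixture) - 1) > 1e-9)
    stop("config error: toxin_class_mixture must sum to 1")
  if (!all(names(toxin_class_mixture) %in% toxin_classes))
    stop("config error: unknown toxin class in mixture")
  structure(list(n_reads = as.integer(n_reads),
                 n_plates = as.integer(n_plates),
                 toxin_fraction_of_total = toxin_fraction_of_total,
                 hit_fraction_of_total = hit_fraction_of_total,
                 toxin_class_mixture = toxin_class_mixture,
                 length_model = length_model,
                 decoration_model = decoration_model,
                 per_base_error = per_base_error,
                 n_templates = n_templates,
                 snp_loci = snp_loci, indel_loci = indel_loci,
                 microsat_loci = microsat_loci,
                 te_insertions = te_insertions,
                 ir_insertions = ir_insertions,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Per-class read sampling probabilities implied by a configuration
#' @param config a [generator_config()].
#' @return named numeric over [est_classes], summing to 1.
#' @export
class_probabilities <- function(config) {
  p <- setNames(numeric(length(est_classes)), est_classes)
  p[names(config$toxin_class_mixture)] <-
    config$toxin_fraction_of_total * config$toxin_class_mixture
  p["non_toxin"] <- config$hit_fraction_of_total -
    config$toxin_fraction_of_total
  p["unknown"] <- 1 - config$hit_fraction_of_total
  p
}

empty_feature_registry <- function() {
  data.frame(template_id = character(), type = character(),
             start = integer(), end = integer(), detail = character(),
             maf = numeric(), stringsAsFactors = FALSE)
}

feature_row <- function(template_id, type, start, end, detail, maf = NA_real_) {
  data.frame(template_id = template_id, type = type,
             start = as.integer(start), end = as.integer(end),
             detail = detail, maf = maf, stringsAsFactors = FALSE)
}

# --- planting operations ----------------------------------------------------

#' Plant a long inverted repeat into a template
#'
#' Inserts, at `position`, a block consisting of a fresh segment A of
#' `arm_length` bases, a random spacer of `inter_ir_length` bases (the
#' inter-IR domain), and the reverse complement of A with each base mutated
#' independently at `arm_mismatch_rate`.  With rate 0 the two arms form a
#' perfect palindrome.
#'
#' @param template a template list (fields `sequence`, `features`, ...).
#' @param arm_length arm length in bases.
#' @param inter_ir_length spacer length between the arms.
#' @param arm_mismatch_rate per-base mutation rate of the right arm.
#' @param position 0-based insertion point; defaults to just after the CDS
#'   (the 3'UTR) or the template midpoint when there is no CDS.
#' @return the modified template; the feature registry gains an
#'   `inverted_repeat` row whose detail records arm coordinates, the inter-IR
#'   length and the realised mismatch count.
#' @export
plant_inverted_repeat <- function(template, arm_length, inter_ir_length,
                                  arm_mismatch_rate = 0, position = NULL) {
  n <- nchar(template$sequence)
  if (n < 2 * arm_length + inter_ir_length)
    stop("planting error: template too short to host the inverted repeat")
  if (is.null(position))
    position <- if (!is.na(template$cds_end)) template$cds_end + 10L
                else n %/% 2L
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  arm <- rand_dna(arm_length)
  spacer <- if (inter_ir_length > 0) rand_dna(inter_ir_length) else ""
  # keep the planted arms maximal: the spacer ends must not extend the
  # palindrome inward by chance
  if (inter_ir_length >= 2) {
    while (substr(spacer, 1, 1) ==
             comp1(substr(spacer, inter_ir_length, inter_ir_length)))
      substr(spacer, 1, 1) <- sample(c("A", "C", "G", "T"), 1)
  }
  right <- revcomp(arm)
  if (arm_mismatch_rate > 0) {
    rb <- strsplit(right, "")[[1]]
    mut <- runif(arm_length) < arm_mismatch_rate
    for (i in which(mut))
      rb[i] <- sample(setdiff(c("A", "C", "G", "T"), rb[i]), 1)
    right <- paste(rb, collapse = "")
  }
  mism <- sum(strsplit(right, "")[[1]] != strsplit(revcomp(arm), "")[[1]])
  block <- paste0(arm, spacer, right)
  s <- template$sequence
  template <- shift_features(template, position, nchar(block))
  newseq <- paste0(substr(s, 1, position), block, substr(s, position + 1, n))
  # block outward extension: the template bases flanking the block must not
  # complement each other
  bl <- nchar(block)
  if (position >= 1 && position + bl < nchar(newseq)) {
    while (substr(newseq, position, position) ==
             comp1(substr(newseq, position + bl + 1, position + bl + 1)))
      substr(newseq, position + bl + 1, position + bl + 1) <-
        sample(c("A", "C", "G", "T"), 1)
  }
  template$sequence <- newseq
  template$features <- rbind(
    template$features,
    feature_row(template$template_id, "inverted_repeat",
                position, position + nchar(block),
                sprintf("arm_length=%d;inter_ir_length=%d;mismatches=%d",
                        arm_length, inter_ir_length, mism)))
  template
}

# insertions shift the coordinates of previously planted features that sit
# at or beyond the insertion point
shift_features <- function(template, position, inserted) {
  f <- template$features
  if (nrow(f)) {
    sel <- f$start >= position
    f$start[sel] <- f$start[sel] + inserted
    f$end[sel] <- f$end[sel] + inserted
    template$features <- f
  }
  template
}

plant_te <- function(template, position, repeat_library, repeat_id, length) {
  te_full <- repeat_library$seq[[repeat_id]]
  stopifnot(!is.null(te_full))
  length <- min(length, nchar(te_full))
  seg <- substr(te_full, 1, length)
  s <- template$sequence
  template <- shift_features(template, position, length)
  template$sequence <- paste0(substr(s, 1, position), seg,
                              substr(s, position + 1, nchar(s)))
  template$features <- rbind(
    template$features,
    feature_row(template$template_id, "te", position, position + length,
                sprintf("repeat_id=%s", repeat_id)))
  template
}

plant_microsat <- function(template, position, motif, copies) {
  block <- strrep(motif, copies)
  s <- template$sequence
  template <- shift_features(template, position, nchar(block))
  template$sequence <- paste0(substr(s, 1, position), block,
                              substr(s, position + 1, nchar(s)))
  template$features <- rbind(
    template$features,
    feature_row(template$template_id, "microsatellite",
                position, position + nchar(block),
                sprintf("motif=%s;copies=%d", motif, copies)))
  template
}

plant_snp <- function(template, position, alt = NULL, maf = 0.5) {
  ref <- substr(template$sequence, position + 1, position + 1)
  if (is.null(alt)) alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  template$features <- rbind(
    template$features,
    feature_row(template$template_id, "snp", position, position + 1L,
                sprintf("ref=%s;alt=%s", ref, alt), maf))
  template
}

plant_indel <- function(template, position, bases, kind = c("ins", "del"),
                        maf = 0.5) {
  kind <- match.arg(kind)
  template$features <- rbind(
    template$features,
    feature_row(template$template_id, "indel", position,
                position + if (kind == "del") nchar(bases) else 0L,
                sprintf("kind=%s;bases=%s", kind, bases), maf))
  template
}

feature_detail <- function(detail, key) {
  m <- regmatches(detail, regexec(paste0("(^|;)", key, "=([^;]*)"), detail))
  vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
}

# --- template set ------------------------------------------------------------

new_template <- function(id, class_label, len, with_cds) {
  seq <- rand_dna(len)
  if (with_cds) {
    cds_start <- sample(30:90, 1)
    cds_len <- ((floor(0.7 * len) - cds_start) %/% 3) * 3
    cds_end <- cds_start + cds_len
  } else {
    cds_start <- NA_integer_; cds_end <- NA_integer_
  }
  list(template_id = id, class_label = class_label, sequence = seq,
       cds_start = cds_start, cds_end = cds_end, abundance_weight = 1,
       features = empty_feature_registry())
}

default_repeat_library <- function() {
  info <- data.frame(
    id = c("BovB_synthetic", "CR1_synthetic", "L2_synthetic",
           "hAT_synthetic", "Tc1_synthetic"),
    family = c("RTE", "CR1", "L2", "hAT", "TcMar-Tc1"),
    stringsAsFactors = FALSE)
  lens <- c(900, 700, 650, 500, 450)
  seqs <- setNames(vapply(lens, rand_dna, ""), info$id)
  list(seq = as.list(seqs), info = info)
}

#' Build the synthetic template set, repeat library and vector library
#'
#' Creates the transcript species underlying a library: per-class template
#' counts and Zipf-like within-class abundance weights, CDS coordinates for
#' every annotatable class, and the default planted features (when the
#' corresponding config entries are `"auto"`): SNP and indel loci on abundant
#' metalloproteinase templates, microsatellite arrays, transposable-element
#' insertions (including chimera-eligible fusions and one TE-dominated
#' transcript) and two inverted repeats, one with the 132-nt arm /183-nt
#' spacer architecture.
#'
#' @param config a [generator_config()].
#' @return a list with `templates` (list of template records),
#'   `repeat_library` and `vector_library`; deterministic given
#'   `config$seed`.
#' @export
make_templates <- function(config) {
  set.seed(config$seed)
  templates <- list()
  for (cls in est_classes) {
    k <- config$n_templates[[cls]]
    if (is.null(k) || k == 0) next
    for (i in seq_len(k)) {
      id <- sprintf("%s_t%03d", cls, i)
      len <- sample(900:1800, 1)
      tp <- new_template(id, cls, len, with_cds = (cls != "unknown"))
      tp$abundance_weight <- 1 / i   # Zipf-like within-class ranks
      templates[[id]] <- tp
    }
  }
  repeat_library <- default_repeat_library()
  vector_library <- c(pVEC_synthetic = rand_dna(600))

  tox_ids <- names(templates)[startsWith(names(templates),
                                         "metalloproteinase")]
  # default plants sit in the well-covered 5' ~500 bp of their templates
  # (single-pass 5' reads rarely reach far 3' positions)
  if (identical(config$snp_loci, "auto")) {
    for (id in head(tox_ids, 4)) {
      tp <- templates[[id]]
      hi <- min(tp$cds_end - 30, 500)
      for (pos in sort(sample((tp$cds_start + 30):hi, 2)))
        tp <- plant_snp(tp, pos, maf = 0.5)
      templates[[id]] <- tp
    }
  } else if (is.data.frame(config$snp_loci)) {
    for (r in seq_len(nrow(config$snp_loci))) {
      x <- config$snp_loci[r, ]
      templates[[x$template_id]] <-
        plant_snp(templates[[x$template_id]], x$position,
                  alt = x$alt, maf = x$maf)
    }
  }
  if (identical(config$indel_loci, "auto")) {
    indel_hosts <- if (length(tox_ids) >= 5)
      tox_ids[5:min(6, length(tox_ids))] else character(0)
    for (id in indel_hosts) {
      tp <- templates[[id]]
      pos <- sample((tp$cds_start + 30):min(tp$cds_end - 30, 500), 1)
      tp <- plant_indel(tp, pos, bases = sample(c("A", "C", "G", "T"), 1),
                        kind = sample(c("ins", "del"), 1), maf = 0.5)
      templates[[id]] <- tp
    }
  }
  if (identical(config$microsat_loci, "auto")) {
    plan <- list(list("non_toxin_t001", "AGC", 7L),
                 list("non_toxin_t002", "AT", 9L),
                 list("non_toxin_t003", "A", 14L),
                 list("PLA2_t001", "AG", 8L),
                 list("non_toxin_t004", "TTAGG", 5L))
    for (p in plan) {
      tp <- templates[[p[[1]]]]
      if (is.null(tp)) next
      templates[[p[[1]]]] <- plant_microsat(tp, 300L, p[[2]], p[[3]])
    }
  }
  if (identical(config$te_insertions, "auto")) {
    # chimera-eligible fusions: TE near the 5' end of annotatable templates,
    # coverage inside (0.10, 0.90)
    plan <- list(list("non_toxin_t005", "BovB_synthetic", 400L),
                 list("non_toxin_t006", "CR1_synthetic", 300L),
                 list("non_toxin_t003", "L2_synthetic", 150L))
    for (p in plan) {
      tp <- templates[[p[[1]]]]
      if (is.null(tp)) next
      templates[[p[[1]]]] <- plant_te(tp, 20L, repeat_library,
                                      p[[2]], p[[3]])
    }
    # one TE-dominated transcript (not chimera-eligible, coverage > 0.9);
    # rare, as TE-only transcripts are in real libraries
    te_dom <- new_template("unknown_te01", "unknown", 40, with_cds = FALSE)
    te_dom <- plant_te(te_dom, 20L, repeat_library, "BovB_synthetic", 850L)
    te_dom$abundance_weight <- 0.02
    templates[["unknown_te01"]] <- te_dom
  }
  if (identical(config$ir_insertions, "auto")) {
    ids <- c("BPP_CNP_t001", "non_toxin_t007")
    if (!is.null(templates[[ids[1]]]))
      templates[[ids[1]]] <- plant_inverted_repeat(templates[[ids[1]]],
                                                   132L, 183L, 0,
                                                   position = 160L)
    if (!is.null(templates[[ids[2]]]))
      templates[[ids[2]]] <- plant_inverted_repeat(templates[[ids[2]]],
                                                   40L, 20L, 0,
                                                   position = 160L)
  }
  list(templates = templates, repeat_library = repeat_library,
       vector_library = vector_library)
}

#' Reference, repeat and vector collections for a template set
#'
#' The labeled reference collection contains every template except those of
#' class `unknown` (which must yield no-hits), together with class labels
#' and CDS coordinates.  Optionally writes the three collections as FASTA
#' (plus a TSV of reference annotations) under `dir`.
#'
#' @param world output of [make_templates()].
#' @param dir optional output directory.
#' @return list with `references` (list: `seq` named list, `info` data
#'   frame), `repeat_library`, `vector_library`.
#' @export
make_reference_collections <- function(world, dir = NULL) {
  tl <- world$templates
  keep <- vapply(tl, function(t) t$class_label != "unknown", TRUE)
  refs <- tl[keep]
  info <- data.frame(
    id = vapply(refs, `[[`, "", "template_id"),
    class_label = vapply(refs, `[[`, "", "class_label"),
    cds_start = vapply(refs, function(t) as.integer(t$cds_start), 1L),
    cds_end = vapply(refs, function(t) as.integer(t$cds_end), 1L),
    length = vapply(refs, function(t) nchar(t$sequence), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  seqs <- lapply(refs, `[[`, "sequence")
  names(seqs) <- info$id
  out <- list(references = list(seq = seqs, info = info),
              repeat_library = world$repeat_library,
              vector_library = world$vector_library)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(unlist(seqs), file.path(dir, "references.fasta"))
    write.table(info, file.path(dir, "references.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(unlist(world$repeat_library$seq),
                file.path(dir, "repeats.fasta"))
    write_fasta(world$vector_library, file.path(dir, "vector.fasta"))
  }
  out
}

#' The combined planted-feature registry of a template set
#' @param world output of [make_templates()].
#' @return data frame of all planted features with template coordinates.
#' @export
feature_registry <- function(world) {
  do.call(rbind, c(list(empty_feature_registry()),
                   lapply(world$templates, `[[`, "features")))
}

rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(as.integer(round(qnorm(u, mean, sd))), lo), hi)
}

apply_read_alleles <- function(core_chars, feats, slice_start, maf_draws) {
  # feats: features of the template; coordinates are template 0-based.
  # core_chars covers template positions [slice_start, slice_start + len).
  # Substitutions first, then indels right-to-left so coordinates stay valid.
  if (nrow(feats) == 0) return(core_chars)
  len <- length(core_chars)
  snps <- feats[feats$type == "snp", , drop = FALSE]
  for (r in seq_len(nrow(snps))) {
    pos <- snps$start[r] - slice_start
    if (pos >= 0 && pos < len && maf_draws[[paste0("f", rownames(snps)[r])]])
      core_chars[pos + 1] <- feature_detail(snps$detail[r], "alt")
  }
  indels <- feats[feats$type == "indel", , drop = FALSE]
  if (nrow(indels)) {
    ord <- order(-indels$start)
    for (r in ord) {
      if (!maf_draws[[paste0("f", rownames(indels)[r])]]) next
      pos <- indels$start[r] - slice_start
      if (pos < 5 || pos > len - 5) next  # keep read ends intact
      kind <- feature_detail(indels$detail[r], "kind")
      bases <- feature_detail(indels$detail[r], "bases")
      if (kind == "ins") {
        core_chars <- append(core_chars, strsplit(bases, "")[[1]],
                             after = pos)
      } else {
        drop <- seq(pos + 1, min(pos + nchar(bases), length(core_chars)))
        core_chars <- core_chars[-drop]
      }
      len <- length(core_chars)
    }
  }
  core_chars
}

#' Generate a synthetic EST library with ground truth
#'
#' For each read: a class is sampled from the configured mixture, a template
#' by abundance weight, a post-cleaning target length from the truncated
#' normal length model and a 5' start offset; planted SNP/indel alleles are
#' sampled at their minor-allele frequencies; substitution miscalls are
#' applied at `per_base_error` (with low PHRED scores); the deposition
#' strand is randomised; and the read is decorated with an optional 5'
#' vector prefix and a 3' polyA tail over which quality decays linearly.
#' Plates are assigned uniformly.
#'
#' @param config a [generator_config()].
#' @param world output of [make_templates()] (must come from a compatible
#'   configuration).
#' @param seed seed for the read-level randomness; defaults to
#'   `config$seed`.
#' @return list with `reads` (an [est_set()]) and `truth` (class
#'   `ground_truth`: per-read table, planted-feature registry, expected
#'   mixture).
#' @export
generate_library <- function(config, world, seed = config$seed) {
  stopifnot(config$n_reads > 0, length(world$templates) > 0)
  set.seed(seed)
  probs <- class_probabilities(config)
  tmpl_class <- vapply(world$templates, `[[`, "", "class_label")
  by_class <- split(names(world$templates), tmpl_class)
  for (cls in names(probs)[probs > 0])
    if (is.null(by_class[[cls]]) || length(by_class[[cls]]) == 0)
      stop("config error: no templates available for class ", cls)
  weights <- lapply(by_class, function(ids)
    vapply(world$templates[ids], `[[`, 1, "abundance_weight"))

  n <- config$n_reads
  lm <- config$length_model
  dm <- config$decoration_model
  cls_draw <- sample(names(probs), n, replace = TRUE, prob = probs)
  lens <- rtruncnorm_int(n, lm$mean, lm$sd, lm$min, lm$max)
  plates <- sample.int(config$n_plates, n, replace = TRUE)
  strands <- ifelse(runif(n) < 0.5, "forward", "reverse")
  has_vec <- runif(n) < dm$vector_prob
  has_pa <- runif(n) < dm$polya_prob
  vlen_all <- pmin(pmax(as.integer(round(rnorm(n, dm$vector_mean,
                                               dm$vector_sd))), 25L), 80L)
  vec_seq <- world$vector_library[[1]]

  ids <- sprintf("EST%06d", seq_len(n))
  seqs <- character(n); quals <- vector("list", n)
  tpl_ids <- character(n); tpl_starts <- integer(n); core_lens <- integer(n)

  for (i in seq_len(n)) {
    cls <- cls_draw[i]
    ids_cls <- by_class[[cls]]
    tid <- if (length(ids_cls) == 1) ids_cls else
      sample(ids_cls, 1, prob = weights[[cls]])
    tp <- world$templates[[tid]]
    tlen <- nchar(tp$sequence)
    L <- min(lens[i], tlen)
    off <- min(rgeom(1, 0.03), tlen - L)
    core <- strsplit(substr(tp$sequence, off + 1, off + L), "")[[1]]

    feats <- tp$features
    poly <- feats[feats$type %in% c("snp", "indel"), , drop = FALSE]
    if (nrow(poly)) {
      draws <- setNames(as.list(runif(nrow(poly)) < poly$maf),
                        paste0("f", rownames(poly)))
      core <- apply_read_alleles(core, feats, off, draws)
    }
    ncore <- length(core)
    q <- pmin(pmax(as.integer(round(rnorm(ncore, dm$q_mean, dm$q_sd))),
                   dm$q_min), dm$q_max)
    err <- which(runif(ncore) < config$per_base_error)
    if (length(err)) {
      for (e in err)
        core[e] <- sample(setdiff(c("A", "C", "G", "T"), core[e]), 1)
      q[err] <- pmin(pmax(as.integer(round(rnorm(length(err), 12, 3))),
                          5L), 19L)
    }
    if (strands[i] == "reverse") {
      core <- strsplit(revcomp(paste(core, collapse = "")), "")[[1]]
      q <- rev(q)
    }
    seqc <- core; qv <- q
    if (has_vec[i]) {
      vl <- vlen_all[i]
      vstart <- sample.int(nchar(vec_seq) - vl, 1)
      vfrag <- strsplit(substr(vec_seq, vstart, vstart + vl - 1), "")[[1]]
      vq <- pmin(pmax(as.integer(round(rnorm(vl, dm$q_mean, dm$q_sd))),
                      dm$q_min), dm$q_max)
      seqc <- c(vfrag, seqc); qv <- c(vq, qv)
    }
    if (has_pa[i]) {
      pl <- dm$polya_length
      paq <- pmax(as.integer(round(dm$decay_start +
                                     dm$decay_slope * (seq_len(pl) - 1))), 2L)
      seqc <- c(seqc, rep("A", pl)); qv <- c(qv, paq)
    }
    seqs[i] <- paste(seqc, collapse = "")
    quals[[i]] <- qv
    tpl_ids[i] <- tid; tpl_starts[i] <- off; core_lens[i] <- ncore
  }

  reads <- est_set(ids, seqs, quals, plates)
  truth_reads <- data.frame(
    id = ids, template_id = tpl_ids, class = tmpl_class[tpl_ids],
    plate = plates, strand = strands, tpl_start = tpl_starts,
    clean_length = core_lens, has_vector = has_vec, has_polya = has_pa,
    row.names = NULL, stringsAsFactors = FALSE)
  truth <- structure(list(reads = truth_reads,
                          features = feature_registry(world),
                          class_probabilities = probs,
                          config = config, seed = seed),
                     class = "ground_truth")
  list(reads = reads, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d reads, %d planted features\n",
              nrow(x$reads), nrow(x$features)))
  invisible(x)
}

#' Write ground truth as JSON
#' @param truth a `ground_truth` object.
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(reads = truth$reads, features = truth$features,
                            class_probabilities =
                              as.list(truth$class_probabilities),
                            seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
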