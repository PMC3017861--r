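# End-to-end orchestration: simulate -> clean -> assemble -> annotate ->
# mine, plus the evaluation harness against planted ground truth and the
# report writers.  Every stage works from plain R objects and standard
# formats so it can be re-run and tested in isolation.

#' Pipeline configuration
#'
#' Bundles all stage parameter blocks with the scoring scheme, annotation
#' cutoff and global seed.
#'
#' @param generator a [generator_config()].
#' @param cleaning a [cleaning_params()].
#' @param assembly an [assembly_params()].
#' @param snp an [snp_params()].
#' @param repeats a [repeat_search_params()].
#' @param ir an [ir_params()].
#' @param scheme a [scoring_scheme()].
#' @param evalue_cutoff annotation hit threshold.
#' @param seed global seed (overrides the generator seed when given).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            cleaning = cleaning_params(),
                            assembly = assembly_params(),
                            snp = snp_params(),
                            repeats = repeat_search_params(),
                            ir = ir_params(),
                            scheme = scoring_scheme(),
                            evalue_cutoff = 1e-5,
                            seed = NULL) {
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(generator = generator, cleaning = cleaning,
                 assembly = assembly, snp = snp, repeats = repeats,
                 ir = ir, scheme = scheme, evalue_cutoff = evalue_cutoff),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

parse_alleles <- function(s) {
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  sub(":.*", "", parts)
}

#' Run the full pipeline on a synthetic library
#'
#' Stages run in order; `stages` restricts the run (later stages need the
#' earlier ones' outputs in the same call).  With `reads` supplied the
#' simulate stage is skipped and cleaning starts from the given reads.
#' Identical configuration and seed give identical results.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("simulate", "clean", "assemble", "annotate", "mine")`.
#' @param reads optional pre-made [est_set()]; requires `world` (the
#'   matching template set) for evaluation, or `NULL` to skip truth-based
#'   steps.
#' @param outdir optional directory; intermediate artifacts are persisted
#'   as FASTA/TSV/JSON.
#' @param verbose print stage progress.
#' @return a result bundle (list) with all stage outputs, the template
#'   world and the ground truth.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "clean", "assemble",
                                    "annotate", "mine"),
                         reads = NULL, outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list(config = config)
  scheme <- config$scheme

  if ("simulate" %in% stages && is.null(reads)) {
    say("simulate: %d reads", config$generator$n_reads)
    res$world <- make_templates(config$generator)
    res$collections <- make_reference_collections(res$world)
    lib <- generate_library(config$generator, res$world)
    res$reads <- lib$reads
    res$truth <- lib$truth
  } else if (!is.null(reads)) {
    res$reads <- reads
  }

  if ("clean" %in% stages) {
    say("clean: %d reads in", length(res$reads))
    vl <- if (!is.null(res$collections)) res$collections$vector_library
          else c(none = "")
    cl <- if (is.null(res$collections))
      list(reads = res$reads,
           report = data.frame(id = res$reads$id, outcome = "kept"))
    else clean_pipeline(res$reads, vl, scheme, config$cleaning)
    res$cleaned <- cl$reads
    res$cleaning_report <- cl$report
  } else res$cleaned <- res$reads

  if ("assemble" %in% stages) {
    say("assemble: %d cleaned reads", length(res$cleaned))
    asm <- build_unisequences(res$cleaned, scheme, config$assembly)
    res$unisequences <- asm$unisequences
    res$contigs <- asm$contigs
  }

  if ("annotate" %in% stages) {
    say("annotate: %d unisequences", nrow(res$unisequences))
    ann <- annotate_unisequences(res$unisequences, res$collections$references,
                                 scheme, config$evalue_cutoff)
    res$annotations <- ann$table
    res$frames <- ann$frames
    res$abundance <- summarize_abundance(ann$table)
  }

  if ("mine" %in% stages) {
    say("mine: variants and repeats")
    res <- mine_features(res, config)
  }

  if (!is.null(outdir)) persist_results(res, outdir)
  res
}

mine_features <- function(res, config) {
  scheme <- config$scheme
  unis <- res$unisequences
  # SNPs and indels per contig, classified through the annotation frame
  snps <- list(); indels <- list()
  for (cid in names(res$contigs)) {
    ctg <- res$contigs[[cid]]
    s <- call_snps(ctg, config$snp)
    if (nrow(s)) {
      arow <- res$annotations[res$annotations$unisequence_id == cid, ]
      s$classification <- vapply(seq_len(nrow(s)), function(r) {
        if (nrow(arow) == 0 || arow$status == "no_hit")
          return("unannotated")
        if (!is.na(arow$hit_region) && arow$hit_region != "coding")
          return("noncoding")
        fr <- res$frames[[cid]]
        classify_snp(ctg$consensus, s$consensus_pos[r],
                     parse_alleles(s$alleles[r]), fr)$classification
      }, "")
      snps[[cid]] <- s
    }
    ind <- call_indels(ctg, config$snp)
    if (nrow(ind)) indels[[cid]] <- ind
  }
  res$snps <- if (length(snps)) do.call(rbind, snps) else
    call_snps(structure(list(members = list(), layout = list(keys = numeric()),
                             contig_id = "none"), class = "contig"),
              config$snp)[0, ]
  res$indels <- if (length(indels)) do.call(rbind, indels) else NULL

  # microsatellites on all unisequences
  ms <- lapply(seq_len(nrow(unis)), function(i)
    find_microsatellites(unis$sequence[i], unis$id[i]))
  res$microsatellites <- do.call(rbind, ms)

  # transposable elements (k-mer prefiltered), chimeras
  rl <- res$collections$repeat_library
  cand <- kmer_candidates_cpp(unis$sequence, unlist(rl$seq), 14L, 1L)
  tes <- list(); chims <- list()
  for (i in seq_len(nrow(unis))) {
    if (length(cand[[i]]) == 0) next
    te <- detect_tes(unis$sequence[i], rl, scheme, config$repeats,
                     unisequence_id = unis$id[i],
                     candidates = cand[[i]])
    if (nrow(te) == 0) next
    tes[[length(tes) + 1]] <- te
    ch <- classify_chimera(unis$sequence[i], te,
                           res$collections$references, scheme,
                           config$repeats, unisequence_id = unis$id[i])
    chims[[unis$id[i]]] <- c(list(unisequence_id = unis$id[i]),
                             ch[setdiff(names(ch), "masked")])
  }
  res$te_annotations <- if (length(tes)) do.call(rbind, tes) else
    empty_te_annotations()
  res$chimeras <- if (length(chims))
    do.call(rbind, lapply(chims, function(x)
      data.frame(unisequence_id = x$unisequence_id, call = x$call,
                 reason = x$reason, te_coverage = x$te_coverage,
                 host_id = if (is.null(x$host_id)) NA_character_ else
                   x$host_id,
                 host_fraction = if (is.null(x$host_fraction)) NA_real_
                   else x$host_fraction,
                 host_identity = if (is.null(x$host_identity)) NA_real_
                   else x$host_identity,
                 stringsAsFactors = FALSE)))
  else data.frame(unisequence_id = character(), call = character(),
                  reason = character(), te_coverage = numeric(),
                  host_id = character(), host_fraction = numeric(),
                  host_identity = numeric(), stringsAsFactors = FALSE)
  res$microsatellites_te_excluded <-
    exclude_te_overlaps(res$microsatellites, res$te_annotations)

  # inverted repeats
  irs <- lapply(seq_len(nrow(unis)), function(i)
    detect_inverted_repeats(unis$sequence[i], scheme, config$ir,
                            unisequence_id = unis$id[i]))
  res$inverted_repeats <- do.call(rbind, irs)
  res$te_family_table <- summarize_te_families(res$te_annotations)
  res
}

# ---------------------------------------------------------------------------
# evaluation against planted ground truth
# ---------------------------------------------------------------------------

majority_template <- function(member_ids, truth) {
  tpl <- truth$reads$template_id[match(member_ids, truth$reads$id)]
  names(sort(table(tpl), decreasing = TRUE))[1]
}

# map unisequence coordinates to template coordinates via best local
# alignment (either strand); returns integer vector, NA where unaligned
uniseq_to_template_map <- function(useq, tseq, scheme) {
  fh <- sw_best_path(useq, tseq, scheme)
  rh <- sw_best_path(revcomp(useq), tseq, scheme)
  n <- nchar(useq)
  tmap <- rep(NA_integer_, n)
  if (!is.null(fh) && (is.null(rh) || fh$score >= rh$score)) {
    sel <- fh$qpath >= 0 & fh$spath >= 0
    tmap[fh$qpath[sel] + 1] <- fh$spath[sel]
  } else if (!is.null(rh)) {
    sel <- rh$qpath >= 0 & rh$spath >= 0
    tmap[n - rh$qpath[sel]] <- rh$spath[sel]
  }
  tmap
}

match_features <- function(called, planted, tol) {
  # called/planted: data.frames with template_id, start, end
  matched_planted <- rep(FALSE, nrow(planted))
  matched_called <- rep(FALSE, nrow(called))
  for (i in seq_len(nrow(called))) {
    if (is.na(called$start[i])) next
    cand <- which(!matched_planted &
                    planted$template_id == called$template_id[i] &
                    abs(planted$start - called$start[i]) <= tol &
                    abs(planted$end - called$end[i]) <= tol)
    if (length(cand)) {
      matched_planted[cand[1]] <- TRUE
      matched_called[i] <- TRUE
    }
  }
  list(sensitivity = if (nrow(planted)) mean(matched_planted) else NA_real_,
       precision = if (nrow(called)) mean(matched_called) else NA_real_,
       n_called = nrow(called), n_planted = nrow(planted))
}

#' Evaluate pipeline calls against planted ground truth
#'
#' Maps every called feature back to template coordinates through a local
#' alignment of its unisequence to the majority template of its member
#' reads, then matches calls to planted features of the same type on the
#' same template within `tol` (0 for SNPs, +/-5 for interval features by
#' default).  Sensitivity = matched/planted, precision = matched/called.
#'
#' @param res a [run_pipeline()] result bundle (with mine stage).
#' @param truth the ground truth of the same run.
#' @param snp_tol,interval_tol matching tolerances in bases.
#' @return list of per-feature-type sensitivity/precision records plus
#'   assembly consensus accuracy.
#' @export
evaluate_against_truth <- function(res, truth, snp_tol = 0L,
                                   interval_tol = 5L) {
  scheme <- res$config$scheme
  unis <- res$unisequences
  templates <- res$world$templates
  utpl <- vapply(seq_len(nrow(unis)), function(i)
    majority_template(unis$members[[i]], truth), "")
  names(utpl) <- unis$id
  tmap_cache <- new.env()
  get_tmap <- function(uid) {
    if (!is.null(tmap_cache[[uid]])) return(tmap_cache[[uid]])
    i <- match(uid, unis$id)
    tm <- uniseq_to_template_map(unis$sequence[i],
                                 templates[[utpl[[uid]]]]$sequence, scheme)
    tmap_cache[[uid]] <- tm
    tm
  }
  map_call <- function(uid, a, b) {
    # 0-based half-open unisequence interval -> template interval
    tm <- get_tmap(uid)
    lo <- tm[a + 1]; hi <- tm[b]
    if (is.na(lo) || is.na(hi)) return(c(NA_integer_, NA_integer_))
    c(min(lo, hi), max(lo, hi) + 1L)
  }
  feats <- truth$features
  out <- list()

  # SNPs
  called <- res$snps
  if (!is.null(called) && nrow(called)) {
    mapped <- t(vapply(seq_len(nrow(called)), function(r)
      map_call(called$contig_id[r], called$consensus_pos[r],
               called$consensus_pos[r] + 1L), c(1L, 1L)))
    cd <- data.frame(template_id = utpl[called$contig_id],
                     start = mapped[, 1],
                     end = mapped[, 2], stringsAsFactors = FALSE)
  } else cd <- data.frame(template_id = character(), start = integer(),
                          end = integer())
  pf <- feats[feats$type == "snp", c("template_id", "start", "end")]
  out$snp <- match_features(cd, pf, snp_tol)

  # indels (interval features from here on)
  interval_eval <- function(called_df, uid_col, a_col, b_col, type) {
    if (!is.null(called_df) && nrow(called_df)) {
      mapped <- t(vapply(seq_len(nrow(called_df)), function(r)
        map_call(called_df[[uid_col]][r], called_df[[a_col]][r],
                 called_df[[b_col]][r]), c(1L, 1L)))
      cd <- data.frame(template_id = utpl[called_df[[uid_col]]],
                       start = mapped[, 1], end = mapped[, 2],
                       stringsAsFactors = FALSE)
    } else cd <- data.frame(template_id = character(), start = integer(),
                            end = integer())
    pf <- feats[feats$type == type, c("template_id", "start", "end")]
    match_features(cd, pf, interval_tol)
  }
  out$microsatellite <- interval_eval(res$microsatellites,
                                      "unisequence_id", "start", "end",
                                      "microsatellite")
  out$te <- interval_eval(res$te_annotations, "unisequence_id",
                          "q_start", "q_end", "te")

  # chimeras: truth = annotatable templates whose TE coverage is inside
  # the open eligibility window
  chim_truth <- character(0)
  for (tid in names(templates)) {
    tp <- templates[[tid]]
    tef <- tp$features[tp$features$type == "te", , drop = FALSE]
    if (nrow(tef) == 0 || tp$class_label == "unknown") next
    cov <- sum(tef$end - tef$start) / nchar(tp$sequence)
    if (cov > res$config$repeats$chimera_coverage_min &&
        cov < res$config$repeats$chimera_coverage_max)
      chim_truth <- c(chim_truth, tid)
  }
  called_chim <- unique(utpl[res$chimeras$unisequence_id[
    res$chimeras$call == "chimeric"]])
  out$chimera <- list(
    sensitivity = if (length(chim_truth))
      mean(chim_truth %in% called_chim) else NA_real_,
    precision = if (length(called_chim))
      mean(called_chim %in% chim_truth) else NA_real_,
    n_called = length(called_chim), n_planted = length(chim_truth))

  # inverted repeats: planted block is arm+spacer+arm; the called left arm
  # start should map to the block start and right arm end to the block end
  out$inverted_repeat <- local({
    called_df <- res$inverted_repeats
    if (!is.null(called_df) && nrow(called_df)) {
      mapped <- t(vapply(seq_len(nrow(called_df)), function(r)
        map_call(called_df$unisequence_id[r], called_df$left_start[r],
                 called_df$right_end[r]), c(1L, 1L)))
      cd <- data.frame(template_id = utpl[called_df$unisequence_id],
                       start = mapped[, 1], end = mapped[, 2],
                       stringsAsFactors = FALSE)
    } else cd <- data.frame(template_id = character(), start = integer(),
                            end = integer())
    pf <- feats[feats$type == "inverted_repeat",
                c("template_id", "start", "end")]
    match_features(cd, pf, interval_tol)
  })

  # assembly: consensus identity to the true template
  cons_ident <- vapply(names(res$contigs), function(cid) {
    ctg <- res$contigs[[cid]]
    tid <- utpl[[cid]]
    h1 <- sw_best_path(ctg$consensus, templates[[tid]]$sequence,
                       res$config$scheme)
    h2 <- sw_best_path(revcomp(ctg$consensus), templates[[tid]]$sequence,
                       res$config$scheme)
    h <- if (is.null(h2) || (!is.null(h1) && h1$score >= h2$score)) h1 else h2
    if (is.null(h)) 0 else h$matches / h$aligned_length
  }, 1)
  out$assembly <- list(
    mean_consensus_identity = if (length(cons_ident)) mean(cons_ident)
                              else NA_real_,
    reads_per_unisequence = mean(unis$member_count))
  out
}

# ---------------------------------------------------------------------------
# report writers
# ---------------------------------------------------------------------------

persist_results <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$reads)) write_est_set(res$reads, file.path(outdir, "reads"))
  if (!is.null(res$cleaned))
    write_est_set(res$cleaned, file.path(outdir, "cleaned"))
  if (!is.null(res$cleaning_report))
    write_cleaning_report(res$cleaning_report,
                          file.path(outdir, "cleaning_report.tsv"))
  if (!is.null(res$unisequences)) {
    write_fasta(setNames(res$unisequences$sequence, res$unisequences$id),
                file.path(outdir, "unisequences.fasta"))
    memb <- data.frame(
      unisequence_id = rep(res$unisequences$id,
                           lengths(res$unisequences$members)),
      read_id = unlist(res$unisequences$members))
    write.table(memb, file.path(outdir, "membership.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$truth))
    write_ground_truth(res$truth, file.path(outdir, "ground_truth.json"))
  write_reports(res, outdir)
  invisible(outdir)
}

#' Composition study: simulate, clean, assemble and annotate a library
#'
#' Runs the default-configured generator at the study conditions (toxin
#' class mixture dominated by metalloproteinases, 30\% annotatable reads,
#' truncated-normal length model) through cleaning, assembly and
#' annotation, and returns the recovered composition: the per-class
#' percentages of toxin ESTs, the toxin percentages under both
#' denominators, the hit percentage, and the mean post-cleaning read
#' length.
#'
#' @param n_reads library size (default 5000).
#' @param seed integer seed driving all randomness.
#' @return list with `abundance` (a `class_abundance`), `mean_length`,
#'   `n_kept` and the result bundle.
#' @export
run_composition_study <- function(n_reads = 5000L, seed = 1L) {
  cfg <- pipeline_config(generator = generator_config(n_reads = n_reads,
                                                      seed = seed))
  res <- run_pipeline(cfg, stages = c("simulate", "clean", "assemble",
                                      "annotate"))
  list(abundance = res$abundance,
       mean_length = mean(nchar(res$cleaned$seq)),
       n_kept = length(res$cleaned),
       result = res)
}

#' Write the paper-style report tables
#'
#' Emits the abundance summary (both denominators, percentages to one
#' decimal), the SNP-per-contig table with the first-hit column, the TE
#' family table, chimera and inverted-repeat tables, and a run summary
#' JSON.  Regeneration from the same result bundle is idempotent.
#'
#' @param res a [run_pipeline()] result bundle.
#' @param outdir output directory.
#' @export
write_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(res$abundance)) {
    ab <- res$abundance
    tab <- data.frame(
      class = names(ab$per_class),
      est_count = as.integer(ab$per_class),
      pct_of_total = round(ab$class_pct_of_total, 1),
      pct_of_toxin = round(ifelse(names(ab$per_class) %in% toxin_classes,
                                  100 * ab$per_class /
                                    max(ab$est_toxin, 1), NA), 1))
    tsv(tab, "abundance.tsv")
    jsonlite::write_json(
      list(est_total = ab$est_total, est_hits = ab$est_hits,
           est_toxin = ab$est_toxin,
           hit_pct_of_total = round(ab$hit_pct_of_total, 1),
           toxin_pct_of_total = round(ab$toxin_pct_of_total, 1),
           toxin_pct_of_hits = round(ab$toxin_pct_of_hits, 1),
           class_pct_of_toxin =
             as.list(round(ab$class_pct_of_toxin, 1))),
      file.path(outdir, "abundance.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$snps) && !is.null(res$annotations)) {
    per_contig <- if (nrow(res$snps))
      aggregate(res$snps$column, by = list(contig_id = res$snps$contig_id),
                FUN = length) else
      data.frame(contig_id = character(), x = integer())
    names(per_contig)[2] <- "snps"
    if (nrow(per_contig)) {
      i <- match(per_contig$contig_id, res$unisequences$id)
      per_contig$length <- nchar(res$unisequences$sequence[i])
      a <- match(per_contig$contig_id, res$annotations$unisequence_id)
      per_contig$first_hit <- res$annotations$best_ref[a]
      per_contig <- per_contig[order(-per_contig$snps),
                               c("contig_id", "length", "snps", "first_hit")]
    }
    tsv(per_contig, "snp_contigs.tsv")
    tsv(res$snps, "snps.tsv")
  }
  if (!is.null(res$indels)) tsv(res$indels, "indels.tsv")
  if (!is.null(res$microsatellites))
    tsv(res$microsatellites, "microsatellites.tsv")
  if (!is.null(res$microsatellites_te_excluded))
    tsv(res$microsatellites_te_excluded, "microsatellites_te_excluded.tsv")
  if (!is.null(res$te_family_table))
    tsv(res$te_family_table, "te_families.tsv")
  if (!is.null(res$te_annotations)) tsv(res$te_annotations, "tes.tsv")
  if (!is.null(res$chimeras)) tsv(res$chimeras, "chimeras.tsv")
  if (!is.null(res$inverted_repeats))
    tsv(res$inverted_repeats, "inverted_repeats.tsv")
  summary <- list(
    n_reads = if (!is.null(res$reads)) length(res$reads) else NA,
    n_cleaned = if (!is.null(res$cleaned)) length(res$cleaned) else NA,
    n_contigs = if (!is.null(res$contigs)) length(res$contigs) else NA,
    n_singletons = if (!is.null(res$unisequences))
      sum(res$unisequences$kind == "singleton") else NA,
    n_snps = if (!is.null(res$snps)) nrow(res$snps) else NA,
    n_te_unisequences = if (!is.null(res$te_annotations))
      length(unique(res$te_annotations$unisequence_id)) else NA,
    n_chimeric = if (!is.null(res$chimeras))
      sum(res$chimeras$call == "chimeric") else NA,
    n_inverted_repeats = if (!is.null(res$inverted_repeats))
      nrow(res$inverted_repeats) else NA)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
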