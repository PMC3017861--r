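# Read cleaning: quality windows, vector screening, polyA/polyT trimming,
# slippage flagging and the minimum-length filter.

test_that("quality trimming keeps high-quality reads and drops hopeless ones", {
  p <- cleaning_params()
  s <- strrep("ACGT", 50)
  r <- trim_quality(s, rep(40L, 200), p)
  expect_equal(r$seq, s)
  r2 <- trim_quality(s, rep(5L, 200), p)
  expect_equal(nchar(r2$seq), 0L)
  expect_error(trim_quality("ACGT", c(30L, 30L), p), "input error")
})

test_that("quality trim point equals the exhaustive window oracle", {
  p <- cleaning_params()
  set.seed(21)
  for (case in 1:12) {
    len <- sample(60:120, 1)
    # high-quality core with a linear 3' decay
    decay_at <- sample(30:(len - 10), 1)
    q <- c(rep(35L, decay_at),
           pmax(2L, as.integer(35 - 1.5 * seq_len(len - decay_at))))
    s <- rdna(len)
    got <- trim_quality(s, q, p)
    want <- oracle_quality_trim(q, p$quality_window, p$quality_threshold)
    expect_equal(c(got$start, got$end), want,
                 info = sprintf("case %d", case))
  }
})

test_that("vector screening excises planted prefixes and whole-vector reads", {
  sc <- default_scheme()
  p <- cleaning_params()
  set.seed(31)
  vec <- c(v1 = rdna(500))
  insert <- rdna(400)
  read <- plant_exact_copy(insert, vec[[1]], 0, 40)
  r <- screen_vector(read, rep(30L, nchar(read)), vec, sc, p)
  expect_equal(r$seq, insert)
  expect_false(r$all_vector)

  clean <- rdna(300)
  r2 <- screen_vector(clean, rep(30L, 300), vec, sc, p)
  expect_equal(r2$seq, clean)

  r3 <- screen_vector(substr(vec[[1]], 10, 200), rep(30L, 191), vec, sc, p)
  expect_true(r3$all_vector)

  expect_error(screen_vector(clean, rep(30L, 300), character(), sc, p),
               "config error")
})

test_that("polyA trimming obeys run-length and mismatch rules", {
  p <- cleaning_params()
  set.seed(41)
  core <- rdna(150)
  while (substr(core, 150, 150) == "A")
    substr(core, 150, 150) <- sample(c("C", "G", "T"), 1)
  while (substr(core, 1, 1) == "T")
    substr(core, 1, 1) <- sample(c("A", "C", "G"), 1)
  q <- function(s) rep(30L, nchar(s))

  tail25 <- paste0(core, strrep("A", 25))
  expect_equal(trim_polyA_polyT(tail25, q(tail25), p)$seq, core)

  tail9 <- paste0(core, strrep("A", 9))   # below min_run: untouched
  expect_equal(trim_polyA_polyT(tail9, q(tail9), p)$seq, tail9)

  one_mm <- paste0(core, strrep("A", 10), "C", strrep("A", 10))
  expect_equal(trim_polyA_polyT(one_mm, q(one_mm), p)$seq, core)

  two_mm <- paste0(core, strrep("A", 7), "C", strrep("A", 7), "C",
                   strrep("A", 7))
  # the second interior mismatch stops the run: only the final segment
  # (7 A's, below min_run together with one C) can go - here nothing is
  # long enough, so at most the trailing A+C block after the last C goes
  got <- trim_polyA_polyT(two_mm, q(two_mm), p)$seq
  expect_gte(nchar(got), nchar(core) + 7)

  # 5' polyT mirror
  lead <- paste0(strrep("T", 15), core)
  expect_equal(trim_polyA_polyT(lead, q(lead), p)$seq, core)

  # interior runs are untouched
  interior <- paste0(substr(core, 1, 70), strrep("A", 20),
                     substr(core, 71, 150))
  expect_equal(trim_polyA_polyT(interior, q(interior), p)$seq, interior)
})

test_that("slippage flagging follows the dominance rule", {
  p <- cleaning_params()
  expect_true(flag_slippage(paste0(rdna(100), strrep("GT", 30), rdna(100)),
                            p))
  # window of 50 with exactly 40 G's: boundary equality counts as flagged
  set.seed(51)
  win <- paste(sample(c(rep("G", 40), sample(c("A", "C", "T"), 10,
                                             TRUE))), collapse = "")
  expect_true(flag_slippage(win, p))
  win39 <- paste(sample(c(rep("G", 39), sample(c("A", "C", "T"), 11,
                                               TRUE))), collapse = "")
  expect_false(flag_slippage(win39, p))
  set.seed(52)
  expect_false(flag_slippage(rdna(500), p))
})

test_that("the pipeline applies the strict 100 bp minimum-length filter", {
  sc <- default_scheme()
  set.seed(61)
  vec <- c(v1 = rdna(400))
  reads <- est_set(c("short", "exact"),
                   c(rdna(99), rdna(100)),
                   list(rep(30L, 99), rep(30L, 100)),
                   c(1L, 2L))
  out <- clean_pipeline(reads, vec, sc)
  expect_equal(out$report$outcome,
               c("discarded_short", "kept"))
  expect_equal(length(out$reads), 1L)
  expect_equal(sum(table(out$report$outcome)), 2L)
})

test_that("cleaning yields subsequences, is idempotent, and matches truth", {
  sc <- default_scheme()
  cfg <- generator_config(n_reads = 80, seed = 17,
                          n_templates = c(metalloproteinase = 4L,
                                          BPP_CNP = 1L, PLA2 = 1L,
                                          serine_proteinase = 1L,
                                          C_type_lectin = 1L,
                                          other_toxin = 1L, non_toxin = 8L,
                                          unknown = 30L))
  world <- make_templates(cfg)
  lib <- generate_library(cfg, world)
  out <- clean_pipeline(lib$reads, world$vector_library, sc)

  # every cleaned read is a contiguous interval of its input
  for (i in seq_along(out$reads)) {
    raw <- lib$reads$seq[match(out$reads$id[i], lib$reads$id)]
    expect_true(grepl(out$reads$seq[i], raw, fixed = TRUE))
  }

  # idempotence
  again <- clean_pipeline(out$reads, world$vector_library, sc)
  expect_identical(again$reads$seq, out$reads$seq)
  expect_true(all(again$report$outcome == "kept"))

  # kept lengths track the generator's configured post-cleaning lengths
  # (per-base miscalls near read ends can shift the trim point slightly)
  tr <- lib$truth$reads
  lens <- nchar(out$reads$seq)
  truth_lens <- tr$clean_length[match(out$reads$id, tr$id)]
  expect_true(mean(abs(lens - truth_lens) <= 2) > 0.8)

  # error-free batch: every cleaned read is a substring of its template
  # (or reverse complement) and never longer than the configured
  # post-cleaning length (the trimmer may take template-terminal A's that
  # are indistinguishable from the tail)
  cfg0 <- cfg; cfg0$per_base_error <- 0
  lib0 <- generate_library(cfg0, world)
  out0 <- clean_pipeline(lib0$reads, world$vector_library, sc)
  tr0 <- lib0$truth$reads
  lens0 <- nchar(out0$reads$seq)
  truth0 <- tr0$clean_length[match(out0$reads$id, tr0$id)]
  expect_true(all(lens0 <= truth0))
  expect_true(all(truth0 - lens0 <= 10))
  polymorphic <- unique(lib0$truth$features$template_id[
    lib0$truth$features$type %in% c("snp", "indel")])
  for (i in seq_along(out0$reads)) {
    tid <- tr0$template_id[match(out0$reads$id[i], tr0$id)]
    if (tid %in% polymorphic) next  # reads may carry alternate alleles
    tseq <- world$templates[[tid]]$sequence
    expect_true(grepl(out0$reads$seq[i], tseq, fixed = TRUE) ||
                  grepl(out0$reads$seq[i], rc(tseq), fixed = TRUE))
  }
})

test_that("decoration-free error-free reads pass cleaning unchanged", {
  sc <- default_scheme()
  cfg <- generator_config(
    n_reads = 40, seed = 19, per_base_error = 0,
    decoration_model = list(vector_prob = 0, vector_mean = 40,
                            vector_sd = 8, polya_prob = 0,
                            polya_length = 25L, q_mean = 35, q_sd = 3,
                            q_min = 25, q_max = 45, decay_start = 28,
                            decay_slope = -1),
    n_templates = c(metalloproteinase = 2L, BPP_CNP = 1L, PLA2 = 1L,
                    serine_proteinase = 1L, C_type_lectin = 1L,
                    other_toxin = 1L, non_toxin = 2L, unknown = 10L),
    snp_loci = NULL, indel_loci = NULL, microsat_loci = NULL,
    te_insertions = NULL, ir_insertions = NULL)
  world <- make_templates(cfg)
  lib <- generate_library(cfg, world)
  out <- clean_pipeline(lib$reads, world$vector_library, sc)
  expect_identical(out$reads$seq, lib$reads$seq)
})
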