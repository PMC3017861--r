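# Overlap detection at the printed thresholds, union-find clustering,
# greedy layout and quality-weighted consensus.

test_that("overlap acceptance sits exactly at 100 bp and 95% identity", {
  sc <- default_scheme()
  p <- assembly_params()
  set.seed(71)

  # dovetail overlap of exactly 100 bp: accepted; 99 bp: rejected
  left <- rdna(300)
  ov100 <- substr(left, 201, 300)
  b100 <- paste0(ov100, rdna(300))
  expect_false(is.null(detect_overlap(left, b100, sc, p)))
  ov99 <- substr(left, 202, 300)
  b99 <- paste0(ov99, rdna(300))
  expect_null(detect_overlap(left, b99, sc, p))

  # 200-col overlap: 10 evenly spaced mismatches (identity 0.95) accepted,
  # 11 (0.945) rejected; mismatch positions keep block ends matching
  mutate_at <- function(s, pos) {
    for (p0 in pos) {
      old <- substr(s, p0, p0)
      substr(s, p0, p0) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  core <- rdna(200)
  a <- paste0(rdna(150), core)
  b10 <- paste0(mutate_at(core, seq(10, 190, by = 20)), rdna(150))
  ov <- detect_overlap(a, b10, sc, p)
  expect_false(is.null(ov))
  expect_equal(ov$identity, 0.95)
  b11 <- paste0(mutate_at(core, c(seq(10, 190, by = 20), 100)), rdna(150))
  expect_null(detect_overlap(a, b11, sc, p))

  # reverse-complement overlap is found with strand = reverse
  ovr <- detect_overlap(a, rc(b10), sc, p)
  expect_false(is.null(ovr))
  expect_equal(ovr$strand, "reverse")
})

test_that("clustering is the transitive closure of accepted overlaps", {
  sc <- default_scheme()
  set.seed(73)
  tmpl <- rdna(700)
  # A and C share no 100 bp overlap but both overlap B
  reads <- est_set(
    c("A", "B", "C"),
    c(substr(tmpl, 1, 300), substr(tmpl, 180, 520), substr(tmpl, 400, 700)),
    list(rep(30L, 300), rep(30L, 341), rep(30L, 301)),
    c(1L, 2L, 3L))
  cl <- cluster_reads(reads, sc)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(sort(cl$reads$id[cl$clusters[[1]]]), c("A", "B", "C"))

  # unrelated reads stay singletons
  reads2 <- est_set(c("X", "Y"), c(rdna(300), rdna(300)),
                    list(rep(30L, 300), rep(30L, 300)), c(1L, 1L))
  cl2 <- cluster_reads(reads2, sc)
  expect_equal(length(cl2$clusters), 0L)
  expect_equal(length(cl2$singletons), 2L)
})

test_that("tiled error-free reads assemble into the template substring", {
  sc <- default_scheme()
  set.seed(79)
  tmpl <- rdna(1200)
  starts <- seq(1, 801, by = 200)   # 8x-ish tiling, 400 bp reads
  reads <- est_set(sprintf("r%d", seq_along(starts)),
                   vapply(starts, function(s) substr(tmpl, s, s + 399), ""),
                   lapply(starts, function(s) rep(30L, 400)),
                   rep(1:3, length.out = length(starts)))
  asm <- build_unisequences(reads, sc)
  expect_equal(length(asm$contigs), 1L)
  ctg <- asm$contigs[[1]]
  expect_equal(length(ctg$members), length(starts))
  expect_equal(ctg$consensus, substr(tmpl, 1, 1200))

  # two identical reads: consensus equals the read
  r2 <- est_set(c("a", "b"), c(substr(tmpl, 1, 300), substr(tmpl, 1, 300)),
                list(rep(30L, 300), rep(30L, 300)), c(1L, 2L))
  asm2 <- build_unisequences(r2, sc)
  expect_equal(asm2$contigs[[1]]$consensus, substr(tmpl, 1, 300))
})

test_that("consensus ties resolve by cumulative quality", {
  sc <- default_scheme()
  set.seed(83)
  tmpl <- rdna(200)
  pos <- 100L
  base <- substr(tmpl, pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  # reads 1-2 carry the template base at q30/q20, read 3 the alternative
  # at q40: cumulative 50 beats 40
  quals <- list(rep(30L, 200), rep(30L, 200), rep(30L, 200))
  quals[[2]][pos + 1] <- 20L
  quals[[3]][pos + 1] <- 40L
  subs <- list(list(), list(), setNames(list(alt), as.character(pos)))
  reads <- make_column_reads(tmpl, 3, subs, quals, plates = c(1L, 2L, 3L))
  asm <- build_unisequences(reads, sc)
  expect_equal(substr(asm$contigs[[1]]$consensus, pos + 1, pos + 1), base)
})

test_that("every read lands in exactly one unisequence", {
  sc <- default_scheme()
  cfg <- generator_config(n_reads = 120, seed = 29,
                          n_templates = c(metalloproteinase = 4L,
                                          BPP_CNP = 1L, PLA2 = 1L,
                                          serine_proteinase = 1L,
                                          C_type_lectin = 1L,
                                          other_toxin = 1L, non_toxin = 6L,
                                          unknown = 40L))
  world <- make_templates(cfg)
  lib <- generate_library(cfg, world)
  cleaned <- clean_pipeline(lib$reads, world$vector_library, sc)$reads
  asm <- build_unisequences(cleaned, sc)
  all_members <- unlist(asm$unisequences$members)
  expect_equal(sort(all_members), sort(cleaned$id))
  expect_equal(sum(asm$unisequences$member_count), length(cleaned))
  expect_true(all(asm$unisequences$member_count[
    asm$unisequences$kind == "contig"] >= 2))
  expect_true(all(asm$unisequences$member_count[
    asm$unisequences$kind == "singleton"] == 1))
})

test_that("assembly output does not depend on read input order", {
  sc <- default_scheme()
  cfg <- generator_config(n_reads = 60, seed = 31,
                          n_templates = c(metalloproteinase = 2L,
                                          BPP_CNP = 1L, PLA2 = 1L,
                                          serine_proteinase = 1L,
                                          C_type_lectin = 1L,
                                          other_toxin = 1L, non_toxin = 3L,
                                          unknown = 20L))
  world <- make_templates(cfg)
  lib <- generate_library(cfg, world)
  cleaned <- clean_pipeline(lib$reads, world$vector_library, sc)$reads
  a1 <- build_unisequences(cleaned, sc)
  set.seed(1)
  shuffled <- cleaned[sample(length(cleaned))]
  a2 <- build_unisequences(shuffled, sc)
  expect_identical(a1$unisequences$sequence, a2$unisequences$sequence)
  expect_identical(a1$unisequences$member_count,
                   a2$unisequences$member_count)
})

test_that("consensus stays close to the template at 8x and 1% error", {
  sc <- default_scheme()
  set.seed(37)
  tmpl <- rdna(900)
  n <- 18  # ~8x at 400 bp reads
  starts <- sort(sample(1:500, n, replace = TRUE))
  seqs <- character(n); quals <- vector("list", n)
  for (i in seq_len(n)) {
    s <- substr(tmpl, starts[i], starts[i] + 399)
    ch <- strsplit(s, "")[[1]]
    err <- which(runif(length(ch)) < 0.01)
    for (e in err) ch[e] <- sample(setdiff(c("A", "C", "G", "T"), ch[e]), 1)
    q <- rep(35L, length(ch)); q[err] <- 12L
    seqs[i] <- paste(ch, collapse = ""); quals[[i]] <- q
  }
  reads <- est_set(sprintf("r%02d", 1:n), seqs, quals,
                   rep(1:3, length.out = n))
  asm <- build_unisequences(reads, sc)
  expect_equal(length(asm$contigs), 1L)
  h <- venomest:::sw_best_stats(asm$contigs[[1]]$consensus, tmpl, sc)
  expect_gte(h$matches / h$aligned_length, 0.99)
})
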