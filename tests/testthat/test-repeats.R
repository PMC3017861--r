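# TE detection gates, masking, chimera classification and inverted-repeat
# discovery.

make_replib <- function(seqs, families = NULL) {
  if (is.null(families)) families <- rep("RTE", length(seqs))
  list(seq = as.list(seqs),
       info = data.frame(id = names(seqs), family = families,
                         stringsAsFactors = FALSE))
}

test_that("TE annotation applies all four gates at their boundaries", {
  sc <- default_scheme()
  set.seed(111)
  rl <- make_replib(c(BovB_x = rdna(900)))

  # 60 nt exact copy in a 400 nt unisequence: length 60, identity 1,
  # coverage 0.15, tiny E-value -> annotated
  u1 <- plant_exact_copy(rdna(340), rl$seq$BovB_x, 200, 60)
  t1 <- detect_tes(u1, rl, sc, unisequence_id = "u1")
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$q_end - t1$q_start, 60L)
  expect_equal(t1$identity, 1)
  expect_lte(t1$evalue, 1e-10)

  # 45 nt exact copy fails the 50 bp length gate
  u2 <- plant_exact_copy(rdna(355), rl$seq$BovB_x, 200, 45)
  expect_equal(nrow(detect_tes(u2, rl, sc)), 0L)
  # 50 nt passes it
  u2b <- plant_exact_copy(rdna(350), rl$seq$BovB_x, 200, 50)
  expect_equal(nrow(detect_tes(u2b, rl, sc)), 1L)

  # 60 nt copy in a 700 nt unisequence: coverage 0.086 < 0.10 -> rejected
  u3 <- plant_exact_copy(rdna(640), rl$seq$BovB_x, 300, 60)
  expect_equal(nrow(detect_tes(u3, rl, sc)), 0L)

  # identity gate is strict at 80%: a 200-col alignment with 40 mismatches
  # (identity exactly 0.800) is rejected, 39 (0.805) is annotated; the
  # mirrored block pattern keeps the full-length alignment uniquely optimal
  # (no prefix or suffix trim can raise the score)
  mutate_pattern <- function(s, is_match) {
    for (p0 in which(!is_match)) {
      old <- substr(s, p0, p0)
      substr(s, p0, p0) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  seg <- substr(rl$seq$BovB_x, 1, 200)
  pat39 <- c(rep(c(rep(TRUE, 4), FALSE), 20),
             rep(c(FALSE, rep(TRUE, 4)), 19), rep(TRUE, 5))
  u4 <- paste0(rdna(100), mutate_pattern(seg, pat39), rdna(100))
  t4 <- detect_tes(u4, rl, sc)
  expect_equal(nrow(t4), 1L)
  expect_gt(t4$identity, 0.80)
  pat40 <- c(rep(c(rep(TRUE, 4), FALSE), 20),
             rep(c(FALSE, rep(TRUE, 4)), 20))
  u5 <- paste0(rdna(100), mutate_pattern(seg, pat40), rdna(100))
  expect_equal(nrow(detect_tes(u5, rl, sc)), 0L)

  expect_error(detect_tes(u1, make_replib(character()), sc),
               "config error")
})

test_that("masking replaces the interval with N and preserves flanks", {
  set.seed(113)
  s <- rdna(400)
  m <- mask_te(s, 100, 160)
  expect_equal(nchar(m), 400L)
  expect_equal(substr(m, 101, 160), strrep("N", 60))
  expect_equal(substr(m, 1, 100), substr(s, 1, 100))
  expect_equal(substr(m, 161, 400), substr(s, 161, 400))
  expect_identical(mask_te(m, 100, 160), m)  # idempotent
})

test_that("chimera classification follows the coverage and host rules", {
  sc <- default_scheme()
  p <- repeat_search_params()
  set.seed(115)
  rl <- make_replib(c(TEa = rdna(600)))
  host <- rdna(350)
  uni <- paste0(substr(rl$seq$TEa, 1, 150), host)  # 150 TE + 350 host

  te <- detect_tes(uni, rl, sc, unisequence_id = "u")
  expect_equal(nrow(te), 1L)
  expect_gt(te$coverage, 0.10); expect_lt(te$coverage, 0.90)

  # host reference holding 200 of the 350 host bases: fraction 0.57 >= 0.5
  refs200 <- list(seq = list(hostref = substr(host, 100, 299)),
                  info = data.frame(id = "hostref",
                                    class_label = "non_toxin",
                                    cds_start = 0L, cds_end = 198L,
                                    stringsAsFactors = FALSE))
  call1 <- classify_chimera(uni, te, refs200, sc, p)
  expect_equal(call1$call, "chimeric")
  expect_gte(call1$host_fraction, 0.5)

  # only 150 host bases known: fraction 0.43 < 0.5 -> not chimeric
  refs150 <- refs200
  refs150$seq <- list(hostref = substr(host, 100, 249))
  call2 <- classify_chimera(uni, te, refs150, sc, p)
  expect_equal(call2$call, "not_chimeric")

  # fabricated 95% TE coverage is ineligible
  te95 <- data.frame(unisequence_id = "u", repeat_id = "TEa",
                     family = "RTE", q_start = 0L,
                     q_end = as.integer(0.95 * nchar(uni)),
                     strand = "forward", identity = 1, evalue = 0,
                     coverage = 0.95, score = 100L,
                     stringsAsFactors = FALSE)
  call3 <- classify_chimera(uni, te95, refs200, sc, p)
  expect_equal(call3$call, "ineligible")
  expect_equal(call3$reason, "coverage_out_of_range")
})

test_that("inverted repeats are found with the 10% mismatch boundary", {
  sc <- default_scheme()
  set.seed(117)
  # S = A(40) + spacer(20) + revcomp(A): one IR with exact coordinates
  tp <- list(template_id = "t", class_label = "non_toxin",
             sequence = rdna(300), cds_start = NA_integer_,
             cds_end = NA_integer_, abundance_weight = 1,
             features = venomest:::empty_feature_registry())
  tp <- plant_inverted_repeat(tp, 40L, 20L, 0, position = 100L)
  ir <- detect_inverted_repeats(tp$sequence, sc)
  expect_equal(nrow(ir), 1L)
  expect_equal(c(ir$left_start, ir$left_end), c(100L, 140L))
  expect_equal(c(ir$right_start, ir$right_end), c(160L, 200L))
  expect_equal(ir$mismatches, 0L)
  expect_equal(ir$inter_ir_length, 20L)

  # 40-arm with 4 clustered mismatches (0.10) accepted, 5 (0.125) rejected
  mk <- function(n_mut) {
    arm <- rdna(40)
    right <- rc(arm)
    ch <- strsplit(right, "")[[1]]
    for (k in seq_len(n_mut)) {
      p0 <- 17 + k
      ch[p0] <- setdiff(c("A", "C", "G", "T"), ch[p0])[1]
    }
    host <- rdna(240)
    s <- paste0(substr(host, 1, 100), arm, rdna(20),
                paste(ch, collapse = ""), substr(host, 101, 240))
    s
  }
  ir4 <- detect_inverted_repeats(mk(4), sc)
  expect_equal(nrow(ir4), 1L)
  expect_equal(ir4$mismatches, 4L)
  expect_equal(ir4$mismatch_fraction, 0.10)
  ir5 <- detect_inverted_repeats(mk(5), sc)
  expect_equal(nrow(ir5), 0L)
})

test_that("IR detection agrees with the quadratic brute-force scanner", {
  sc <- default_scheme()
  p <- ir_params()
  set.seed(119)
  for (case in 1:6) {
    s <- rdna(250)
    if (case %% 2 == 0) {
      tp <- list(template_id = "t", class_label = "x", sequence = s,
                 cds_start = NA_integer_, cds_end = NA_integer_,
                 abundance_weight = 1,
                 features = venomest:::empty_feature_registry())
      arm <- sample(30:60, 1); gap <- sample(0:40, 1)
      tp <- plant_inverted_repeat(tp, arm, gap,
                                  sample(c(0, 0.05), 1), position = 80L)
      s <- tp$sequence
    }
    got <- venomest:::ir_scan_cpp(s, p$min_arm_length,
                                  p$max_mismatch_fraction, sc$match,
                                  sc$mismatch)
    want <- oracle_ir_scan(s, p$min_arm_length, p$max_mismatch_fraction,
                           sc$match, sc$mismatch)
    expect_equal(nrow(got), nrow(want), info = paste("case", case))
    if (nrow(got)) {
      ord1 <- order(got[, "left_start"], got[, "right_start"])
      ord2 <- order(want$left_start, want$right_start)
      expect_equal(unname(got[ord1, "left_start"]),
                   want$left_start[ord2], info = paste("case", case))
      expect_equal(unname(got[ord1, "arm_length"]),
                   want$arm_length[ord2], info = paste("case", case))
    }
  }
})

test_that("reported IR arms never overlap and respect the mismatch cap", {
  sc <- default_scheme()
  set.seed(121)
  for (case in 1:5) {
    tp <- list(template_id = "t", class_label = "x", sequence = rdna(500),
               cds_start = NA_integer_, cds_end = NA_integer_,
               abundance_weight = 1,
               features = venomest:::empty_feature_registry())
    tp <- plant_inverted_repeat(tp, 50L, 30L, 0.05, position = 100L)
    tp <- plant_inverted_repeat(tp, 35L, 10L, 0, position = 350L)
    ir <- detect_inverted_repeats(tp$sequence, sc)
    expect_true(all(ir$mismatch_fraction <= 0.10 + 1e-9))
    expect_true(all(ir$inter_ir_length >= 0))
    if (nrow(ir) >= 2) {
      ivs <- cbind(c(ir$left_start, ir$right_start),
                   c(ir$left_end, ir$right_end))
      ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
      expect_true(all(ivs[-1, 1] >= ivs[-nrow(ivs), 2]))
    }
  }
})

test_that("TE family table counts unisequences once per family", {
  ann <- data.frame(
    unisequence_id = c("u1", "u1", "u2", "u3", "u3"),
    repeat_id = c("BovB", "BovB", "BovB", "CR1", "BovB"),
    family = c("RTE", "RTE", "RTE", "CR1", "RTE"),
    stringsAsFactors = FALSE)
  tab <- summarize_te_families(ann)
  expect_equal(tab$unisequences[tab$repeat_id == "BovB"], 3L)
  expect_equal(tab$unisequences[tab$repeat_id == "CR1"], 1L)
  # per-repeat unisequence sets can exceed distinct TE-bearing unisequences
  expect_gte(sum(tab$unisequences), length(unique(ann$unisequence_id)))
})
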