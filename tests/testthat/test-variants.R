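# SNP/indel calling under the artifact-control rules, synonymy
# classification, and microsatellite detection with TE exclusion.

# contig built from n copies of a 200 bp template with controlled
# substitutions, qualities and plates
column_contig <- function(template, subs, quals = NULL, plates = NULL,
                          sc = default_scheme()) {
  n <- max(length(subs), length(quals), length(plates))
  reads <- make_column_reads(template, n, subs, quals, plates)
  asm <- build_unisequences(reads, sc)
  expect_equal(length(asm$contigs), 1L)
  asm$contigs[[1]]
}

test_that("SNP calling enforces the three-read and plate rules", {
  set.seed(101)
  tmpl <- rdna(200)
  pos <- 100L
  base <- substr(tmpl, pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  sub_alt <- setNames(list(alt), as.character(pos))

  # 4 reads, plates 1/1/2/2, column split 2/2 at q30: one SNP
  ctg <- column_contig(tmpl, list(list(), list(), sub_alt, sub_alt),
                       plates = c(1L, 1L, 2L, 2L))
  s <- call_snps(ctg)
  expect_equal(nrow(s), 1L)
  expect_equal(s$consensus_pos, pos)
  expect_equal(s$n_plates, 2L)
  expect_true(grepl(base, s$alleles) && grepl(alt, s$alleles))

  # same columns but a single plate: rejected
  ctg1p <- column_contig(tmpl, list(list(), list(), sub_alt, sub_alt),
                         plates = c(1L, 1L, 1L, 1L))
  expect_equal(nrow(call_snps(ctg1p)), 0L)

  # contigs below three reads are never eligible
  ctg2 <- column_contig(tmpl, list(list(), sub_alt), plates = c(1L, 2L))
  expect_equal(nrow(call_snps(ctg2)), 0L)

  # low-quality support does not count
  lowq <- list(rep(30L, 200), rep(30L, 200), rep(30L, 200), rep(30L, 200))
  lowq[[3]][pos + 1] <- 15L
  ctglq <- column_contig(tmpl, list(list(), list(), sub_alt, sub_alt),
                         quals = lowq, plates = c(1L, 1L, 2L, 2L))
  expect_equal(nrow(call_snps(ctglq)), 0L)

  # missing plate tags raise an eligibility error
  broken <- ctg
  broken$members[[1]]$plate <- NULL
  expect_error(call_snps(broken), "eligibility error")
})

test_that("indels are called once per maximal pad run", {
  sc <- default_scheme()
  set.seed(103)
  tmpl <- rdna(200)
  with_del <- paste0(substr(tmpl, 1, 100), substr(tmpl, 102, 200))
  reads <- est_set(c("r1", "r2", "r3", "r4"),
                   c(tmpl, tmpl, with_del, with_del),
                   list(rep(30L, 200), rep(30L, 200),
                        rep(30L, 199), rep(30L, 199)),
                   c(1L, 2L, 1L, 2L))
  asm <- build_unisequences(reads, sc)
  ctg <- asm$contigs[[1]]
  ind <- call_indels(ctg)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$bases, substr(tmpl, 101, 101))
  expect_equal(ind$n_pad, 2L)
  expect_equal(ind$n_base, 2L)

  # a pad supported by a single read is not called
  reads1 <- est_set(c("r1", "r2", "r3", "r4"),
                    c(tmpl, tmpl, tmpl, with_del),
                    list(rep(30L, 200), rep(30L, 200), rep(30L, 200),
                         rep(30L, 199)),
                    c(1L, 2L, 1L, 2L))
  asm1 <- build_unisequences(reads1, sc)
  expect_equal(nrow(call_indels(asm1$contigs[[1]])), 0L)

  # adjacent pad columns from the same reads give one call, not two
  with_del2 <- paste0(substr(tmpl, 1, 100), substr(tmpl, 103, 200))
  reads2 <- est_set(c("r1", "r2", "r3", "r4"),
                    c(tmpl, tmpl, with_del2, with_del2),
                    list(rep(30L, 200), rep(30L, 200),
                         rep(30L, 198), rep(30L, 198)),
                    c(1L, 2L, 1L, 2L))
  asm2 <- build_unisequences(reads2, sc)
  ind2 <- call_indels(asm2$contigs[[1]])
  expect_equal(nrow(ind2), 1L)
  expect_equal(ind2$col_end - ind2$col_start, 2L)
})

test_that("synonymy classification follows the genetic code symmetrically", {
  frame <- function(n) list(strand = "forward", offset = 0L,
                            qmap = 0:(n - 1), cds_start = 0L,
                            cds_end = as.integer(n %/% 3 * 3))
  # CAT -> CAC at codon position 3: His/His, synonymous
  r <- classify_snp("CATGGG", 2L, c("T", "C"), frame(6))
  expect_equal(r$classification, "synonymous")
  expect_setequal(unname(r$residues), c("H", "H"))
  # GAA -> GTA at codon position 2: Glu -> Val
  r2 <- classify_snp("GAAGGG", 1L, c("A", "T"), frame(6))
  expect_equal(r2$classification, "nonsynonymous")
  # allele order does not matter
  r2b <- classify_snp("GAAGGG", 1L, c("T", "A"), frame(6))
  expect_equal(r2b$classification, r2$classification)
  # no frame (UTR-only contig) is noncoding
  expect_equal(classify_snp("GAAGGG", 1L, c("A", "T"), NULL)$classification,
               "noncoding")
  # position outside the CDS is noncoding
  fr <- frame(9); fr$cds_end <- 3L
  expect_equal(classify_snp("GAAGGGTTT", 4L, c("G", "C"),
                            fr)$classification, "noncoding")
  # position with no subject mapping is frame-unknown
  fr2 <- frame(6); fr2$qmap[2] <- NA
  expect_equal(classify_snp("GAAGGG", 1L, c("A", "T"),
                            fr2)$classification, "frame_unknown")
})

test_that("SNP classification is reverse-strand aware", {
  sc <- default_scheme()
  set.seed(107)
  ref <- rdna(600)
  cds_start <- 0L; cds_end <- 600L
  qr <- rc(substr(ref, 1, 300))
  fr <- infer_frame(qr, ref, "reverse", cds_start, cds_end, sc)
  # pick a codon-third position in reference coordinates (synonymous for
  # many codons is not guaranteed, so check consistency with the forward
  # computation instead)
  fwd_frame <- list(strand = "forward", offset = 0L, qmap = 0:299,
                    cds_start = cds_start, cds_end = cds_end)
  q_fwd <- substr(ref, 1, 300)
  for (p_fwd in c(29L, 100L, 200L)) {
    old <- substr(q_fwd, p_fwd + 1, p_fwd + 1)
    alt <- setdiff(c("A", "C", "G", "T"), old)[1]
    want <- classify_snp(q_fwd, p_fwd, c(old, alt), fwd_frame)
    p_rev <- 300L - 1L - p_fwd
    got <- classify_snp(qr, p_rev, comp1(c(old, alt)), fr)
    expect_equal(got$classification, want$classification,
                 info = sprintf("pos %d", p_fwd))
  }
})

test_that("microsatellite detection matches the brute-force scanner", {
  set.seed(109)
  # planted examples
  s1 <- paste0(rdna(80), strrep("AGC", 7), rdna(80))
  m1 <- find_microsatellites(s1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$motif, "AGC")  # canonical (smallest) rotation of AGC
  expect_gte(m1$copies, 7)
  expect_equal(m1$end - m1$start, round(m1$copies * 3))

  # below-threshold dinucleotide array is not reported
  s2 <- paste0(rdna(80), strrep("AT", 6), rdna(80))
  expect_equal(nrow(find_microsatellites(s2)), 0L)

  # a non-primitive motif is reported as its primitive period
  s3 <- paste0(rdna(80), strrep("A", 14), rdna(80))
  m3 <- find_microsatellites(s3)
  expect_equal(m3$period, 1L)
  expect_equal(m3$motif, "A")

  # property: agreement with the independent scanner on random sequences
  # with occasional planted arrays
  for (case in 1:15) {
    s <- rdna(300)
    if (case %% 3 == 0)
      s <- paste0(s, strrep(c("TA", "CAG", "TTAGG")[case %/% 3 %% 3 + 1],
                            8), rdna(100))
    got <- find_microsatellites(s)
    want <- oracle_microsats(s)
    expect_equal(got$start, want$start, info = paste("case", case))
    expect_equal(got$end, want$end, info = paste("case", case))
    expect_equal(got$period, want$period, info = paste("case", case))
  }
})

test_that("TE exclusion removes whole unisequences, not intervals", {
  reps <- data.frame(unisequence_id = c("u1", "u1", "u2"),
                     motif = c("A", "AT", "ACG"), period = c(1L, 2L, 3L),
                     copies = c(14, 8, 7), start = c(0L, 50L, 10L),
                     end = c(14L, 66L, 31L), stringsAsFactors = FALSE)
  te <- data.frame(unisequence_id = "u1", stringsAsFactors = FALSE)
  kept <- exclude_te_overlaps(reps, te)
  expect_equal(unique(kept$unisequence_id), "u2")
  # empty TE set: identity
  expect_identical(exclude_te_overlaps(reps,
                                       te[0, , drop = FALSE]), reps)
})
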