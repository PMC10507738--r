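# Channel schemes and per-mutation classification.

test_that("channel schemes enumerate 6/96/78/83 unique labels", {
  for (nm in c("SBS6", "SBS96", "DBS78", "ID83")) {
    sc <- channel_scheme(nm)
    expected <- c(SBS6 = 6L, SBS96 = 96L, DBS78 = 78L, ID83 = 83L)[[nm]]
    expect_length(sc$channels, expected)
    expect_false(anyDuplicated(sc$channels) > 0)
  }
})

test_that("SBS classification orients on the pyrimidine strand", {
  g <- GenomeSequence(c(chr1 = "ACA", chr2 = "TGC"))
  expect_equal(classify_sbs(data.frame(chrom = "chr1", pos = 1L,
                                       ref = "C", alt = "T"), g),
               "A[C>T]A")
  # purine reference: oracle is the reverse complement of the 3-mer TGC
  # (GCA) with the allele pair complemented (G>A becomes C>T)
  expect_equal(classify_sbs(data.frame(chrom = "chr2", pos = 1L,
                                       ref = "G", alt = "A"), g),
               "G[C>T]A")
  # genome mismatch is an input error, N context is unclassifiable
  expect_error(classify_sbs(data.frame(chrom = "chr1", pos = 1L,
                                       ref = "T", alt = "G"), g),
               class = "topomut_input_error")
  gn <- GenomeSequence(c(chr1 = "NCA"))
  expect_true(is.na(classify_sbs(data.frame(chrom = "chr1", pos = 1L,
                                            ref = "C", alt = "T"), gn)))
})

test_that("strand collapse is idempotent over all 192 stranded 3-mer substitutions", {
  bases <- c("A", "C", "G", "T")
  labels <- character(0)
  for (mid in bases) {
    alts <- setdiff(bases, mid)
    for (alt in alts) for (p5 in bases) for (p3 in bases) {
      tri <- paste0(p5, mid, p3)
      g <- GenomeSequence(c(chr1 = tri))
      lab <- classify_sbs(data.frame(chrom = "chr1", pos = 1L,
                                     ref = mid, alt = alt), g)
      # the reverse-complemented mutation must map to the same label
      g_rc <- GenomeSequence(c(chr1 = revcomp(tri)))
      lab_rc <- classify_sbs(data.frame(chrom = "chr1", pos = 1L,
                                        ref = complement_base_pub(mid),
                                        alt = complement_base_pub(alt)),
                             g_rc)
      expect_equal(lab, lab_rc)
      labels <- c(labels, lab)
    }
  }
  expect_setequal(unique(labels), sbs96_channels())
  expect_length(unique(labels), 96L)
})

test_that("DBS classification collapses doublets onto the canonical 78", {
  expect_equal(classify_dbs("CC", "TT"), "CC>TT")
  expect_equal(classify_dbs("GG", "AA"), "CC>TT")  # revcomp oracle
  # exhaustive closure: all 144 stranded doublet substitutions map into
  # the catalogue, and every canonical label maps to itself under
  # reverse complement
  bases <- c("A", "C", "G", "T")
  seen <- character(0)
  for (r1 in bases) for (r2 in bases)
    for (a1 in setdiff(bases, r1)) for (a2 in setdiff(bases, r2)) {
      lab <- classify_dbs(paste0(r1, r2), paste0(a1, a2))
      expect_false(is.na(lab))
      seen <- c(seen, lab)
    }
  expect_setequal(unique(seen), dbs78_channels())
  for (lab in dbs78_channels()) {
    parts <- strsplit(lab, ">", fixed = TRUE)[[1]]
    expect_equal(classify_dbs(revcomp(parts[1]), revcomp(parts[2])), lab)
  }
})

test_that("ID classification matches the repeat-counting oracle", {
  # brute-force homopolymer run length around a 1 bp deletion
  run_len_oracle <- function(s, pos, base) {
    chars <- strsplit(s, "")[[1]]
    run <- 1L
    i <- pos  # 0-based deleted position; count left then right
    while (i - 1L >= 0L && chars[i] == base) { run <- run + 1L; i <- i - 1L }
    i <- pos + 2L
    while (i <= length(chars) && chars[i] == base) { run <- run + 1L; i <- i + 1L }
    run
  }
  s <- "CCAATTTTGCC"
  g <- GenomeSequence(c(chr1 = s))
  expect_equal(run_len_oracle(s, 5L, "T"), 4L)
  expect_equal(classify_id(data.frame(chrom = "chr1", pos = 5L,
                                      ref = "T", alt = ""), g),
               "1:Del:T:3")
  # 1 bp insertion next to a single C
  g2 <- GenomeSequence(c(chr1 = "AATGCATAA"))
  expect_equal(classify_id(data.frame(chrom = "chr1", pos = 4L,
                                      ref = "", alt = "C"), g2),
               "1:Ins:C:1")
  # deleted purine collapses to the pyrimidine label
  g3 <- GenomeSequence(c(chr1 = "CCAAAAGCC"))
  expect_equal(classify_id(data.frame(chrom = "chr1", pos = 3L,
                                      ref = "A", alt = ""), g3),
               "1:Del:T:3")
  # tandem-repeat deletion: TAG TAG -> one copy deleted, one flanking copy
  g4 <- GenomeSequence(c(chr1 = "GGTAGTAGGG"))
  expect_equal(classify_id(data.frame(chrom = "chr1", pos = 2L,
                                      ref = "TAG", alt = ""), g4),
               "3:Del:R:1")
  # microhomology: deleting TAGC leaves TAG immediately 3'
  g5 <- GenomeSequence(c(chr1 = "GGGTAGCTAGGG"))
  expect_equal(classify_id(data.frame(chrom = "chr1", pos = 3L,
                                      ref = "TAGC", alt = ""), g5),
               "4:Del:M:3")
  # every emitted label is a member of the scheme
  for (lab in c("1:Del:T:3", "1:Ins:C:1", "3:Del:R:1", "4:Del:M:3"))
    expect_true(lab %in% id83_channels())
  # context overrunning the chromosome end is unclassifiable
  g6 <- GenomeSequence(c(chr1 = "ACGT"))
  expect_true(is.na(classify_id(data.frame(chrom = "chr1", pos = 3L,
                                           ref = "TT", alt = ""), g6)))
})

test_that("signature assignment takes the argmax above the cutoff", {
  p1 <- data.frame(SBS1 = 0.9, SBS5 = 0.1)
  expect_equal(assign_signature(p1, 0.5)$signature, "SBS1")
  p2 <- data.frame(SBS1 = 0.45, SBS5 = 0.55)
  expect_equal(assign_signature(p2, 0.5)$signature, "SBS5")
  # exact tie: lexicographic winner, deterministically
  p3 <- data.frame(SBS5 = 0.5, SBS1 = 0.5)
  expect_equal(assign_signature(p3, 0.5)$signature, "SBS1")
  p4 <- data.frame(SBS1 = 0.4, SBS5 = 0.35, SBS13 = 0.25)
  expect_equal(assign_signature(p4, 0.5)$signature, "UNASSIGNED")
  expect_error(assign_signature(data.frame()), class = "topomut_input_error")
})

test_that("the minimum-attribution filter is applied at the boundary", {
  att <- data.frame(signature = rep(c("SBS1", "SBS5"), c(1000, 999)))
  out <- signature_mutation_counts(att, 1000)
  expect_equal(out$signature, "SBS1")
  expect_equal(out$count, 1000L)
  expect_equal(nrow(signature_mutation_counts(att[0, , drop = FALSE])), 0L)
})

test_that("attributable bases exclude ambiguous positions", {
  g <- GenomeSequence(c(chr1 = "ACGTNNACGT"))
  expect_equal(attributable_bases(g, "chr1", 0L, 10L), 8L)
  expect_equal(attributable_bases(g, "chr1", 4L, 6L), 0L)
  expect_equal(attributable_bases(g, "chr1", c(0L, 6L), c(4L, 10L)),
               c(4L, 4L))
  expect_error(attributable_bases(g, "chr1", 0L, 11L),
               class = "topomut_input_error")
})
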