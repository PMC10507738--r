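# Transcription and replication strand annotation.

test_that("transcription labels follow the pyrimidine/template convention", {
  genes_p <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                        strand = "+", gene_id = "g1")
  genes_m <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                        strand = "-", gene_id = "g1")
  # enumeration oracle over the four strand combinations: the pyrimidine
  # sits on the template strand iff its strand differs from the gene's
  for (case in list(list(ref = "C", alt = "T", gene = genes_p,
                         want = "UNTRANSCRIBED"),
                    list(ref = "C", alt = "T", gene = genes_m,
                         want = "TRANSCRIBED"),
                    list(ref = "G", alt = "A", gene = genes_p,
                         want = "TRANSCRIBED"),
                    list(ref = "G", alt = "A", gene = genes_m,
                         want = "UNTRANSCRIBED"))) {
    m <- data.frame(chrom = "chr1", pos = 150L, ref = case$ref,
                    alt = case$alt)
    m$pyr_strand <- pyrimidine_strand(m$ref, m$alt)
    expect_equal(annotate_transcription(m, case$gene), case$want)
  }
  # outside genes and in bidirectionally transcribed regions
  m <- data.frame(chrom = "chr1", pos = c(50L, 150L),
                  ref = "C", alt = "T")
  m$pyr_strand <- "+"
  both <- rbind(genes_p, data.frame(chrom = "chr1", start = 120L,
                                    end = 180L, strand = "-",
                                    gene_id = "g2"))
  expect_equal(annotate_transcription(m, both),
               c("NONTRANSCRIBED", "EXCLUDED_BIDIRECTIONAL"))
})

test_that("transcription labels partition the catalog", {
  fx <- small_fixture()
  muts <- uniform_catalog(fx$genome, 400, "C>T", seed = 3)
  muts$pyr_strand <- pyrimidine_strand(muts$ref, muts$alt)
  lab <- annotate_transcription(muts, fx$genes)
  expect_equal(length(lab), nrow(muts))
  expect_true(all(lab %in% c("TRANSCRIBED", "UNTRANSCRIBED",
                             "NONTRANSCRIBED",
                             "EXCLUDED_BIDIRECTIONAL")))
  expect_equal(sum(table(lab)), nrow(muts))
})

test_that("replication strand map follows the sawtooth slope with trimming", {
  # peak at 0, valley at 100 kb, peak at 200 kb
  seg <- data.frame(chrom = "chr1",
                    start = seq(0L, 199000L, by = 1000L),
                    end = seq(1000L, 200000L, by = 1000L))
  mid <- (seg$start + seg$end) / 2
  seg$value <- 100 * abs(1 - (mid %% 200000) / 100000)
  profile <- list(signal = signal_track(seg),
                  peaks = data.frame(chrom = "chr1",
                                     start = c(0L, 199500L),
                                     end = c(500L, 200000L)),
                  valleys = data.frame(chrom = "chr1", start = 99500L,
                                       end = 100500L))
  map <- derive_replication_strand_map(profile, min_len = 10000,
                                       term_trim = 25000)
  lag <- map[map$label == "LAGGING_PLUS", ]
  lead <- map[map$label == "LEADING_PLUS", ]
  expect_equal(nrow(lag), 1L)
  expect_equal(nrow(lead), 1L)
  # descending limb [peak, valley) trimmed 25 kb before the valley
  expect_equal(lag$start, 250)
  expect_equal(lag$end, 75000)
  # ascending limb [valley, peak) trimmed 25 kb after the valley
  expect_equal(lead$start, 125000)
  expect_equal(lead$end, 199750)
  # per-base slope oracle: signal differences inside labeled regions
  for (i in seq_len(nrow(map))) {
    at <- seq(map$start[i], map$end[i] - 1001L, by = 997L)
    d <- diff(track_values(profile$signal, "chr1", at))
    if (map$label[i] == "LEADING_PLUS") expect_true(all(d >= 0))
    else expect_true(all(d <= 0))
  }
})

test_that("short stretches are dropped and flat signal yields no labels", {
  seg <- data.frame(chrom = "chr1", start = seq(0L, 17000L, by = 1000L),
                    end = seq(1000L, 18000L, by = 1000L))
  seg$value <- c(seq(9, 1, length.out = 9), seq(1, 9, length.out = 9))
  profile <- list(signal = signal_track(seg),
                  peaks = data.frame(chrom = "chr1",
                                     start = c(0L, 17000L),
                                     end = c(1000L, 18000L)),
                  valleys = data.frame(chrom = "chr1", start = 8000L,
                                       end = 10000L))
  # both monotone stretches are 9 kb < 10 kb
  map <- derive_replication_strand_map(profile, min_len = 10000,
                                       term_trim = 0)
  expect_equal(nrow(map), 0L)

  flat <- list(signal = signal_track(data.frame(chrom = "chr1",
                                                start = 0L, end = 3e5,
                                                value = 5)),
               peaks = data.frame(chrom = "chr1", start = 0L, end = 1000L),
               valleys = data.frame(chrom = "chr1", start = 150000L,
                                    end = 151000L))
  expect_equal(nrow(derive_replication_strand_map(flat)), 0L)
})

test_that("replication labels combine region and pyrimidine strand", {
  map <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                    end = c(1000L, 2000L),
                    label = c("LEADING_PLUS", "LAGGING_PLUS"))
  m <- data.frame(chrom = "chr1", pos = c(500L, 500L, 1500L, 1500L, 5000L),
                  ref = c("C", "G", "C", "G", "C"),
                  alt = c("T", "A", "T", "A", "T"))
  m$pyr_strand <- pyrimidine_strand(m$ref, m$alt)
  expect_equal(annotate_replication(m, map),
               c("LEADING", "LAGGING", "LAGGING", "LEADING", "UNASSIGNED"))
})

test_that("reverse-complementing alleles flips strand labels exactly", {
  fx <- small_fixture()
  muts <- uniform_catalog(fx$genome, 300, "C>T", seed = 21)
  muts$pyr_strand <- pyrimidine_strand(muts$ref, muts$alt)
  flipped <- muts
  flipped$ref <- complement_base_pub(muts$ref)
  flipped$alt <- complement_base_pub(muts$alt)
  flipped$pyr_strand <- pyrimidine_strand(flipped$ref, flipped$alt)

  tx <- annotate_transcription(muts, fx$genes)
  tx_f <- annotate_transcription(flipped, fx$genes)
  swap_tx <- c(TRANSCRIBED = "UNTRANSCRIBED",
               UNTRANSCRIBED = "TRANSCRIBED",
               NONTRANSCRIBED = "NONTRANSCRIBED",
               EXCLUDED_BIDIRECTIONAL = "EXCLUDED_BIDIRECTIONAL")
  expect_equal(tx_f, unname(swap_tx[tx]))

  rp <- annotate_replication(muts, fx$rep_map)
  rp_f <- annotate_replication(flipped, fx$rep_map)
  swap_rp <- c(LEADING = "LAGGING", LAGGING = "LEADING",
               UNASSIGNED = "UNASSIGNED")
  expect_equal(rp_f, unname(swap_rp[rp]))
})

test_that("sawtooth fixture balances leading and lagging base totals", {
  fx <- small_fixture()
  totals <- tapply(fx$rep_map$end - fx$rep_map$start, fx$rep_map$label,
                   sum)
  expect_equal(unname(totals["LEADING_PLUS"]),
               unname(totals["LAGGING_PLUS"]))
})
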