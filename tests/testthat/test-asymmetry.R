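# Odds-ratio machinery, Fisher exact oracle agreement, BH adjustment and
# asymmetry detection thresholds.

# Independent Fisher oracle: enumerate all tables with the observed
# margins, compute each probability from binomial coefficients, and sum
# those no more probable than the observed table.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
}

test_that("odds ratios and Fisher p values match the spec arithmetic", {
  r <- strand_odds_ratio(20, 10, 15, 15)
  expect_equal(r$odds_ratio, 2)
  expect_equal(r$p, fisher_oracle(20, 10, 15, 15), tolerance = 1e-12)
  expect_equal(r$p, stats::fisher.test(matrix(c(20, 10, 15, 15), 2,
                                              byrow = TRUE))$p.value,
               tolerance = 1e-9)

  bal <- strand_odds_ratio(15, 15, 15, 15)
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p, 1)

  z <- strand_odds_ratio(0, 10, 10, 10)
  expect_equal(z$odds_ratio, 0)
  expect_equal(z$p, fisher_oracle(0, 10, 10, 10), tolerance = 1e-12)

  inf <- strand_odds_ratio(10, 0, 10, 10)
  expect_equal(inf$odds_ratio, Inf)
  expect_false(strand_odds_ratio(0, 0, 10, 10)$testable)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(404)
  for (i in 1:200) {
    tb <- matrix(rpois(4, 20), 2)
    expect_equal(fisher_exact_p(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  # brute-force step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
  }
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("asymmetry reporting applies strict OR and q thresholds", {
  counts <- data.frame(signature = "S", channel = "C>T",
                       real_a = 2000, real_b = 1000,
                       sim_a = 1500, sim_b = 1500)
  res <- detect_asymmetries(counts)
  expect_true(res$reported)
  expect_equal(res$direction, "a")
  expect_equal(res$odds_ratio, 2)

  # real equals simulated: OR 1, never reported
  eq <- detect_asymmetries(data.frame(signature = "S", channel = "C>T",
                                      real_a = 500, real_b = 500,
                                      sim_a = 500, sim_b = 500))
  expect_false(eq$reported)

  # OR exactly at the boundary is not "above 1.10"
  tab <- data.frame(signature = "S", channel = "C>T",
                    real_a = 110000, real_b = 100000,
                    sim_a = 100000, sim_b = 100000)
  res_b <- detect_asymmetries(tab)
  expect_equal(res_b$odds_ratio, 1.10)
  expect_true(res_b$q <= 0.05)
  expect_false(res_b$reported)
})

test_that("planted transcription bias is recovered from a generative fixture", {
  fx <- small_fixture()
  cata <- make_catalog(fx$spec, fx$genome,
                       list(list(name = "SBS_T", n = 3000, tx_or = 2)),
                       genes = fx$genes, catalog_seed = 31)
  att <- attribute_mutations(cata$mutations, cata$probabilities,
                             fx$genome)
  att$tx_label <- annotate_transcription(att, fx$genes)
  sims <- simulate_catalog(att, fx$genome, n_reps = 25, seed = 31)
  sims_att <- lapply(sims$replicates, annotate_replicate,
                     genes = fx$genes)
  tab <- strand_count_table(att, sims_att, "tx_label", "TRANSCRIBED",
                            "UNTRANSCRIBED")
  res <- detect_asymmetries(tab)
  cell <- res[res$channel == "C>T", ]
  expect_true(cell$reported)
  expect_equal(cell$direction, "a")
  expect_gt(cell$odds_ratio, 1.8)
  expect_lt(cell$odds_ratio, 2.2)
})

test_that("genic/intergenic correction rebuilds genic counts as twice the max", {
  r <- genic_intergenic_fold(40, 100, 50, 100, corrected = TRUE,
                             real_transcribed = 10,
                             real_untranscribed = 30)
  expect_equal(r$genic_used, 60)
  sym <- genic_intergenic_fold(40, 100, 50, 100, corrected = TRUE,
                               real_transcribed = 20,
                               real_untranscribed = 20)
  expect_equal(sym$genic_used, 40)
  expect_equal(sym$odds_ratio,
               genic_intergenic_fold(40, 100, 50, 100)$odds_ratio)
})

test_that("without strand bias the corrected and uncorrected folds agree", {
  fx <- small_fixture()
  # planted intergenic enrichment without transcription asymmetry:
  # weight intergenic candidates 1.5x by inverting a genic weight
  cata <- make_catalog(fx$spec, fx$genome,
                       list(list(name = "SBS_G", n = 3000)),
                       catalog_seed = 77)
  att <- attribute_mutations(cata$mutations, cata$probabilities,
                             fx$genome)
  att$tx_label <- annotate_transcription(att, fx$genes)
  set.seed(123)
  # thin genic mutations so intergenic density ends up ~1.5x the null
  keep <- att$tx_label == "NONTRANSCRIBED" | runif(nrow(att)) < 1 / 1.5
  att_enr <- att[keep, , drop = FALSE]
  tx <- sum(att_enr$tx_label == "TRANSCRIBED")
  utx <- sum(att_enr$tx_label == "UNTRANSCRIBED")
  genic <- sum(att_enr$tx_label != "NONTRANSCRIBED")
  inter <- sum(att_enr$tx_label == "NONTRANSCRIBED")
  sims <- simulate_catalog(att, fx$genome, n_reps = 10, seed = 7)
  sim_lab <- unlist(lapply(sims$replicates, function(s) {
    s$pyr_strand <- pyrimidine_strand(s$ref, s$alt)
    annotate_transcription(s, fx$genes)
  }))
  sim_genic <- round(sum(sim_lab != "NONTRANSCRIBED") /
                       length(sims$replicates))
  sim_inter <- round(sum(sim_lab == "NONTRANSCRIBED") /
                       length(sims$replicates))
  plain <- genic_intergenic_fold(genic, inter, sim_genic, sim_inter)
  corr <- genic_intergenic_fold(genic, inter, sim_genic, sim_inter,
                                corrected = TRUE, real_transcribed = tx,
                                real_untranscribed = utx)
  expect_lt(abs(corr$odds_ratio / plain$odds_ratio - 1), 0.05)
})
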