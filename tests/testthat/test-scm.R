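# Strand-coordinated mutagenesis: run finding and z tests against
# simulated replicates.

scm_mut <- function(pos, ref = "C", alt = "T", sample = "S1",
                    chrom = "chr1", signature = "SBS_X", prob = 0.9) {
  data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, type = "SBS",
             channel6 = classify_sbs6(ref, alt),
             pyr_strand = pyrimidine_strand(ref, alt),
             signature = signature, probability = prob)
}


test_that("runs respect the strict inter-mutational distance threshold", {
  g <- find_scm_groups(scm_mut(c(100, 5000, 9000)))
  expect_equal(nrow(g), 1L)
  expect_equal(g$length, 3L)
  # a gap of exactly 10,000 breaks the run ("less than 10,000")
  expect_equal(nrow(find_scm_groups(scm_mut(c(100, 10100)))), 0L)
  expect_equal(nrow(find_scm_groups(scm_mut(c(100, 10099)))), 1L)
})

test_that("a strand change breaks a run", {
  m <- rbind(scm_mut(c(100, 5000)), scm_mut(6000, ref = "G", alt = "A"))
  g <- find_scm_groups(m)
  expect_equal(nrow(g), 1L)
  expect_equal(g$length, 2L)
  expect_equal(g$strand, "+")
  expect_equal(g, scm_oracle(m), ignore_attr = TRUE)
})

test_that("low-probability mutations are removed before distances are measured", {
  # middle mutation filtered out; flanks remain within imd of each other
  m <- scm_mut(c(100, 5000, 9000), prob = c(0.9, 0.3, 0.9))
  g <- find_scm_groups(m)
  expect_equal(g$length, 2L)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 9000L)
  # flanking gap at least imd: no merge across the removed site
  m2 <- scm_mut(c(100, 5000, 11000), prob = c(0.9, 0.3, 0.9))
  expect_equal(nrow(find_scm_groups(m2)), 0L)
})

test_that("group finding matches the quadratic oracle on random catalogs", {
  fx <- small_fixture()
  set.seed(55)
  for (trial in 1:5) {
    n <- 400
    m <- data.frame(sample = sample(c("S1", "S2"), n, TRUE),
                    chrom = sample(c("chr1", "chr2"), n, TRUE),
                    pos = sample.int(4e5, n),
                    ref = sample(c("C", "G", "T", "A"), n, TRUE,
                                 prob = c(.4, .3, .2, .1)))
    m$alt <- ifelse(m$ref %in% c("C", "G"),
                    ifelse(m$ref == "C", "T", "A"),
                    ifelse(m$ref == "T", "C", "G"))
    m$type <- "SBS"
    m$channel6 <- classify_sbs6(m$ref, m$alt)
    m$pyr_strand <- pyrimidine_strand(m$ref, m$alt)
    m$signature <- sample(c("SBS_A", "SBS_B", "UNASSIGNED"), n, TRUE)
    m$probability <- round(runif(n), 2)
    got <- find_scm_groups(m, imd = 20000)
    want <- scm_oracle(m, imd = 20000)
    expect_equal(got, want, ignore_attr = TRUE)
    # partition invariant: group members plus singletons = retained
    retained <- m[m$signature != "UNASSIGNED" & m$probability >= 0.5, ]
    expect_lte(sum(got$length), nrow(retained))
  }
})

test_that("z tests separate observed from simulated group counts", {
  real <- scm_mut(seq(1000, by = 900, length.out = 6))
  sims <- lapply(1:50, function(r) {
    set.seed(r)
    scm_mut(sort(sample.int(3e5, 6)))
  })
  real_groups <- find_scm_groups(real)
  sim_groups <- lapply(sims, find_scm_groups)
  res <- test_scm_lengths(real_groups, sim_groups)
  cell <- res[res$length == 6, ]
  expect_equal(cell$observed, 1L)
  expect_true(cell$q <= 0.05)
  expect_true(cell$reported)
})

test_that("degenerate and closed-form z cells behave as specified", {
  h <- function(count) data.frame(signature = "S", length = 2L,
                                  count = count)
  mk_groups <- function(k) {
    if (k == 0)
      return(data.frame(sample = character(0), signature = character(0),
                        channel = character(0), strand = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), length = integer(0)))
    do.call(rbind, lapply(seq_len(k), function(i)
      data.frame(sample = "S1", signature = "S", channel = "C>T",
                 strand = "+", chrom = "chr1", start = i * 100000L,
                 end = i * 100000L + 500L, length = 2L)))
  }
  # obs equals the simulated mean: z = 0, p = 1
  res <- test_scm_lengths(mk_groups(2), list(mk_groups(2), mk_groups(2),
                                             mk_groups(2), mk_groups(1),
                                             mk_groups(3)))
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  # closed-form normal tail: obs 10, sims mean 2 sd 1 -> z = 8
  sims <- lapply(c(1, 2, 3, 2), mk_groups)  # mean 2, sd ~0.816
  obs <- mk_groups(10)
  res2 <- test_scm_lengths(obs, sims)
  expect_equal(res2$z, (10 - 2) / sd(c(1, 2, 3, 2)))
  expect_lt(res2$p, 1e-14)
  # zero variance with a different observation: degenerate sentinel
  res3 <- test_scm_lengths(mk_groups(5), list(mk_groups(2), mk_groups(2)))
  expect_true(res3$degenerate)
  expect_equal(res3$p, 0)
  expect_true(res3$reported)
})
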