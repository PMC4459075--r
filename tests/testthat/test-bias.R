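test_that("label abundances are percentages summing to 100", {
  reads <- seq_records(sprintf("r%02d", 1:100), strrep("A", 90),
                       origin_label = rep(c("g1", "g2"), c(80, 20)))
  prof <- abundance_from_labels(reads)
  expect_equal(unclass(prof)[c("g1", "g2")], c(g1 = 80, g2 = 20))
  expect_equal(sum(prof), 100)

  single <- abundance_from_labels(
    seq_records("r", "ACGT", origin_label = "g"))
  expect_equal(as.numeric(single), 100)

  set.seed(71)
  for (i in 1:5) {
    labs <- sample(letters[1:6], 500, replace = TRUE)
    p <- abundance_from_labels(
      seq_records(sprintf("r%03d", 1:500), "ACGT", origin_label = labs))
    expect_equal(sum(p), 100)
  }
  unlabeled <- seq_records("r", "ACGT")
  expect_error(abundance_from_labels(unlabeled), "origin label")
})

test_that("bias records carry fold changes and zero sentinels", {
  b <- compute_bias(c(rbromii = 7, rest = 93),
                    c(rbromii = 0.01, rest = 99.99))
  rb <- b[b$genome_id == "rbromii", ]
  expect_equal(rb$fold_change, 0.01 / 7)
  expect_equal(rb$log10_fold_change, log10(0.01 / 7))
  expect_equal(rb$sentinel, "none")

  flat <- compute_bias(c(g = 2), c(g = 2))
  expect_equal(flat$fold_change, 1)
  expect_equal(flat$log10_fold_change, 0)

  s <- compute_bias(c(a = 0, b = 50, c = 50),
                    c(a = 1.5, b = 98.5, c = 0))
  expect_equal(s$sentinel, c("CE_0", "none", "CL_0"))
  expect_true(is.na(s$fold_change[1]) && is.na(s$fold_change[3]))
  # CE_0 takes precedence when both are zero
  both0 <- compute_bias(c(x = 0, y = 100), c(x = 0, y = 100))
  expect_equal(both0$sentinel[both0$genome_id == "x"], "CE_0")
  # a genome absent from one profile counts as zero there
  miss <- compute_bias(c(p = 100), c(p = 40, q = 60))
  expect_equal(miss$sentinel[miss$genome_id == "q"], "CE_0")
})

test_that("identical profiles give fold change 1 and scaling cancels", {
  set.seed(72)
  counts_ce <- c(a = 120, b = 55, c = 320, d = 5)
  counts_cl <- c(a = 60, b = 110, c = 160, d = 20)
  as_prof <- function(x) 100 * x / sum(x)
  b1 <- compute_bias(as_prof(counts_ce), as_prof(counts_cl))
  b2 <- compute_bias(as_prof(counts_ce * 7), as_prof(counts_cl * 7))
  expect_equal(b1, b2)
  same <- compute_bias(as_prof(counts_ce), as_prof(counts_ce))
  expect_equal(same$fold_change, rep(1, 4))
})

test_that("genome profiles combine GC with both-strand rpoD density", {
  allc <- genome_profile(c(g = strrep("C", 100000)))
  expect_equal(allc$gc, 100)
  expect_equal(allc$rpoD_count, 0L)

  set.seed(73)
  g <- generate_genome(40000, 0.999, planted_rpoD = 20, genome_id = "p")
  prof <- genome_profile(g)
  expect_equal(prof$rpoD_count, 20L)
  expect_equal(prof$rpoD_per_mb, 20 / 0.04)

  rnd <- random_dna(100000, 0.35)
  prof2 <- genome_profile(c(r = rnd))
  expect_equal(prof2$rpoD_count,
               nrow(oracle_scan(rnd, builtin_motifs()$rpoD, "both")))
})

test_that("correlations use sentinel-free records and report exclusions", {
  bias <- data.frame(genome_id = letters[1:6],
                     abundance_CE = c(10, 20, 30, 20, 0, 20),
                     abundance_CL = c(5, 10, 60, 25, 1, 0),
                     fold_change = c(.5, .5, 2, 1.25, NA, NA),
                     log10_fold_change = log10(c(.5, .5, 2, 1.25, NA, NA)),
                     sentinel = c("none", "none", "none", "none",
                                  "CE_0", "CL_0"))
  profs <- data.frame(genome_id = letters[1:6],
                      genome_length = 1e6, gc = c(30, 40, 50, 60, 45, 55),
                      rpoD_count = c(40, 30, 5, 10, 20, 25),
                      rpoD_per_mb = c(40, 30, 5, 10, 20, 25))
  corr <- correlate_bias(bias, profs)
  expect_equal(corr$n_used, 4L)
  expect_equal(unname(corr$n_excluded), c(1L, 1L))
  est <- corr$estimates
  expect_setequal(est$predictor, c("gc", "rpoD_per_mb"))
  # hand-checked direction: bias rises with GC, falls with rpoD density
  expect_gt(est$r[est$predictor == "gc" & est$method == "spearman"], 0)
  expect_lt(est$r[est$predictor == "rpoD_per_mb" &
                  est$method == "spearman"], 0)
  expect_error(correlate_bias(bias[bias$sentinel != "none", ], profs),
               "at least 3")
})

test_that("a confounded design gives equal-magnitude rank correlations", {
  # gc and rpoD density perfectly rank-correlated by construction:
  # Spearman cannot tell the predictors apart
  bias <- data.frame(genome_id = letters[1:5],
                     abundance_CE = rep(20, 5),
                     abundance_CL = c(40, 25, 20, 10, 5),
                     fold_change = c(2, 1.25, 1, .5, .25),
                     log10_fold_change = log10(c(2, 1.25, 1, .5, .25)),
                     sentinel = "none")
  profs <- data.frame(genome_id = letters[1:5],
                      genome_length = 1e6,
                      gc = c(70, 60, 50, 40, 30),
                      rpoD_count = c(1, 5, 12, 30, 44),
                      rpoD_per_mb = c(1, 5, 12, 30, 44))
  est <- correlate_bias(bias, profs)$estimates
  sp <- est[est$method == "spearman", ]
  expect_equal(abs(sp$r[sp$predictor == "gc"]),
               abs(sp$r[sp$predictor == "rpoD_per_mb"]))
})

test_that("fragments-per-genome arithmetic", {
  expect_equal(fragments_per_genome(2250000, 28000), 80L)
  expect_equal(fragments_per_genome(28000, 28000), 1L)
  expect_equal(fragments_per_genome(56000, 28000), 2L)
  expect_equal(fragments_per_genome(c(1e6, 2e6), 25000), c(40L, 80L))
  expect_error(fragments_per_genome(0, 28000), "positive")
  expect_error(fragments_per_genome(1e6, -1), "positive")
})
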