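test_that("genome generation honors GC target and planted sites", {
  set.seed(51)
  g <- generate_genome(50000, 0.4, planted_rpoD = 0, genome_id = "g")
  gc_hat <- gc_percent(g$sequence) / 100
  se <- sqrt(0.4 * 0.6 / 50000)
  expect_lt(abs(gc_hat - 0.4), 3 * se)

  # inert background: planted count is exact, no chance hits possible
  planted <- generate_genome(30000, 0.999, planted_rpoD = 20)
  expect_equal(planted$rpoD_measured, 20L)
  expect_length(planted$plant_starts, 20L)
  # plants do not overlap
  expect_true(all(diff(sort(planted$plant_starts)) >= 27L))

  expect_error(generate_genome(500, 0.5), ">= 1000")
  expect_error(generate_genome(1000, 0.5, planted_rpoD = 100),
               "could not place")
})

test_that("crude extraction follows abundance and debris settings", {
  set.seed(52)
  spec <- community_spec(c("big", "small"), c(60000L, 60000L),
                        c(0.5, 0.5), 0L,
                        relative_abundance = c(0.8, 0.2))
  community <- generate_community(spec)
  params <- simulation_params(spec, n_fragments = 4000,
                              debris_fraction = 0,
                              hmw_length_range = c(2000L, 4000L),
                              seed = 52)
  frags <- extract_crude(community, params)
  share <- sum(frags$length[frags$genome_id == "big"]) /
    sum(frags$length)
  se <- sqrt(0.8 * 0.2 / 4000)
  expect_lt(abs(share - 0.8), 4 * se)
  # no debris: nothing shorter than the HMW minimum except end-truncated
  # fragments, which keep their genomic start
  expect_true(all(frags$length <= 4000L))
  expect_true(all(frags$end <= 60000L))
  expect_equal(frags$length, frags$end - frags$start)

  params_debris <- simulation_params(spec, n_fragments = 500,
                                     debris_fraction = 1,
                                     debris_length_range = c(500L, 5000L),
                                     seed = 53)
  debris <- extract_crude(community, params_debris)
  expect_true(all(debris$length <= 5000L))
})

test_that("size selection is an order-preserving partition", {
  set.seed(54)
  spec <- community_spec("g", 200000L, 0.5)
  community <- generate_community(spec)
  params <- simulation_params(spec, n_fragments = 300,
                              debris_fraction = 0.5, seed = 54)
  frags <- extract_crude(community, params)
  kept <- size_select(frags, c(40000L, 70000L))
  expect_true(all(kept$length >= 40000L & kept$length <= 70000L))
  dropped <- frags[!(frags$fragment_id %in% kept$fragment_id), ]
  expect_true(all(dropped$length < 40000L | dropped$length > 70000L))
  expect_equal(nrow(kept) + nrow(dropped), nrow(frags))
  expect_equal(kept$fragment_id,
               frags$fragment_id[frags$fragment_id %in% kept$fragment_id])
  # boundary values are retained (closed range)
  toy <- frags[1:2, ]
  toy$length <- c(40000L, 70000L)
  expect_equal(nrow(size_select(toy, c(40000L, 70000L))), 2L)
})

test_that("clone retention follows exp(-lambda k)", {
  frags <- data.frame(fragment_id = sprintf("f%04d", 1:3000),
                      genome_id = "g", start = 0L, end = 100L,
                      length = 100L, sequence = strrep("C", 100),
                      k = rep(c(0L, 1L), c(1000, 2000)))
  all_kept <- clone_library(frags, lambda = 0, seed = 55)
  expect_equal(nrow(all_kept$retained), 3000L)

  res <- clone_library(frags, lambda = 1, seed = 56)
  expect_equal(nrow(res$outcomes), 3000L)
  # k = 0 fragments always survive
  expect_true(all(res$outcomes$survived[res$outcomes$k == 0L]))
  # empirical retention at k = 1 within 3 binomial SE of exp(-1)
  p_hat <- mean(res$outcomes$survived[res$outcomes$k == 1L])
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 2000)
  expect_lt(abs(p_hat - exp(-1)), 3 * se)
  # retained + lost = input
  expect_equal(nrow(res$retained), sum(res$outcomes$survived))
})

test_that("read pairs are faithful windows of their labeled genome", {
  set.seed(57)
  spec <- community_spec(c("gA", "gB"), 40000L, c(0.45, 0.55))
  community <- generate_community(spec)
  params <- simulation_params(spec, n_fragments = 60, debris_fraction = 0,
                              hmw_length_range = c(3000L, 8000L),
                              seed = 57)
  frags <- extract_crude(community, params)
  reads <- suppressWarnings(simulate_reads(frags, 500, seed = 58))
  expect_equal(nrow(reads), 1000L)
  expect_true(all(nchar(reads$sequence) == 90L))
  expect_false(anyNA(reads$origin_label))
  genome_of <- vapply(community, `[[`, character(1), "sequence")
  for (i in sample(nrow(reads), 40)) {
    g <- genome_of[[reads$origin_label[i]]]
    found <- grepl(reads$sequence[i], g, fixed = TRUE) ||
      grepl(reverse_complement(reads$sequence[i]), g, fixed = TRUE)
    expect_true(found, info = reads$id[i])
  }
  # per-genome read share tracks base share of the fragment pool
  base_share <- tapply(frags$length, frags$genome_id, sum) /
    sum(frags$length)
  read_share <- table(reads$origin_label) / nrow(reads)
  se <- sqrt(base_share["gA"] * (1 - base_share["gA"]) / 500)
  expect_lt(abs(read_share[["gA"]] - base_share[["gA"]]), 4 * se)
})

test_that("too-short fragments are skipped with a warning", {
  frags <- data.frame(fragment_id = c("a", "b"), genome_id = "g",
                      start = 0L, end = c(200L, 5000L),
                      length = c(200L, 5000L),
                      sequence = c(strrep("A", 200), strrep("A", 5000)),
                      k = 0L)
  expect_warning(r <- simulate_reads(frags, 10, insert_size = 350,
                                     seed = 59),
                 "skipped")
  expect_equal(unique(r$origin_label), "g")
})

test_that("experiments are deterministic under a fixed seed", {
  spec <- community_spec(c("g1", "g2"), 50000L, c(0.4, 0.6),
                        planted_rpoD = c(2L, 0L))
  params <- simulation_params(spec, n_fragments = 80,
                              debris_fraction = 0.2,
                              hmw_length_range = c(3000L, 9000L),
                              size_select_range = c(4000L, 8000L),
                              retention_rate = 0.5,
                              reads_per_sample = 300, seed = 60)
  ex1 <- suppressWarnings(run_experiment(params))
  ex2 <- suppressWarnings(run_experiment(params))
  expect_equal(ex1$reads, ex2$reads)
  expect_equal(ex1$truth, ex2$truth)
  expect_equal(ex1$crude$sequence, ex2$crude$sequence)
})

test_that("with lambda 0 the library mirrors the size-selected sample", {
  set.seed(61)
  spec <- independent_community(n_genomes = 6L, genome_length = 120000L)
  params <- simulation_params(spec, n_fragments = 400,
                              debris_fraction = 0.2,
                              hmw_length_range = c(20000L, 60000L),
                              size_select_range = c(25000L, 50000L),
                              retention_rate = 0,
                              reads_per_sample = 2000, seed = 61)
  ex <- suppressWarnings(run_experiment(params))
  expect_equal(nrow(ex$clone$retained), nrow(ex$selected))
  ss <- abundance_from_labels(ex$reads$size_selected)
  cl <- abundance_from_labels(ex$reads$cosmid_library)
  shared <- intersect(names(ss), names(cl))
  # read-resampling noise only: per-genome percentages agree within a
  # few points at 2000 pairs
  expect_lt(max(abs(ss[shared] - cl[shared])), 6)
})

test_that("lambda is recovered from the fragment truth table", {
  set.seed(62)
  spec <- anticorrelated_community(n_genomes = 8L,
                                   genome_length = 150000L,
                                   max_density_per_mb = 60)
  community <- generate_community(spec)
  params <- simulation_params(spec, n_fragments = 2500,
                              debris_fraction = 0,
                              hmw_length_range = c(20000L, 50000L),
                              seed = 62)
  frags <- extract_crude(community, params)
  res <- clone_library(frags, lambda = 0.8)
  fit <- fit_retention(res$outcomes)
  expect_s3_class(fit, "retention_fit")
  expect_equal(unname(coef(fit)), fit$lambda)
  expect_lt(abs(fit$lambda - 0.8) / 0.8, 0.15)
})
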