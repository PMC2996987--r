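test_that("a deterministic training set yields a deterministic chain", {
  cds <- toy_cds(paste(rep("GCT", 120), collapse = ""))
  m <- suppressWarnings(train_periodic_markov(cds, 2))
  expect_equal(oscan:::transition_prob(m, "GC", "T", phase = 2), 1)
  out <- generate_cds(m, 5, seed = 1)
  expect_identical(out, paste(rep("GCT", 5), collapse = ""))
})

test_that("stop-completing emissions have zero probability at phase 2", {
  g <- synth_genome(n_genes = 40, lengths = 150, gc_target = 0.45, seed = 2)
  m <- train_periodic_markov(g, 2)
  expect_equal(oscan:::transition_prob(m, "TA", "A", phase = 2), 0)
  expect_equal(oscan:::transition_prob(m, "TA", "G", phase = 2), 0)
  expect_equal(oscan:::transition_prob(m, "TG", "A", phase = 2), 0)
  # rows at phase 2 still sum to 1 wherever defined
  rs <- rowSums(m$prob[[3]])
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})

test_that("generated sequences are stop-free and reproducible", {
  g <- synth_genome(n_genes = 30, lengths = 150, gc_target = 0.4, seed = 3)
  stops <- genetic_code(11)$stop_codons
  for (ord in c(2, 5)) {
    m <- train_periodic_markov(g, ord)
    lens <- rep(200L, 25L)
    s1 <- generate_cds(m, lens, seed = 11)
    s2 <- generate_cds(m, lens, seed = 11)
    expect_identical(s1, s2)
    expect_true(all(nchar(s1) == 600L))
    inframe <- vapply(s1, function(x) {
      codons <- substring(x, seq(1, nchar(x) - 2, 3), seq(3, nchar(x), 3))
      sum(codons %in% stops)
    }, numeric(1))
    expect_equal(sum(inframe), 0, label = paste("order", ord))
  }
})

test_that("order-2 training recovers the generating transition probabilities", {
  # truth: an order-2 model trained on a moderately biased synthetic genome
  base <- synth_genome(n_genes = 60, lengths = 200, gc_target = 0.45, seed = 4)
  truth <- train_periodic_markov(base, 2)
  sim <- toy_cds(generate_cds(truth, rep(250L, 700L), seed = 5),
                 ids = sprintf("s%04d", 1:700))          # ~5e5 nt
  refit <- train_periodic_markov(sim, 2)
  for (phase in 1:3) {
    expect_lt(max(abs(refit$prob[[phase]] - truth$prob[[phase]])), 0.02)
  }
})

test_that("positional nucleotide frequencies are preserved by generation", {
  g <- synth_genome(n_genes = 40, lengths = 200, gc_target = 0.35, seed = 6)
  m <- train_periodic_markov(g, 2)
  sim <- toy_cds(generate_cds(m, rep(200L, 40L), seed = 7),
                 ids = sprintf("s%03d", 1:40))
  cs_train <- composition_stats(g)
  cs_sim <- composition_stats(sim)
  expect_equal(cs_sim$gc1, cs_train$gc1, tolerance = 0.05)
  expect_equal(cs_sim$gc2, cs_train$gc2, tolerance = 0.05)
  expect_equal(cs_sim$gc3, cs_train$gc3, tolerance = 0.05)
})

test_that("codon-based models estimate toy frequencies exactly", {
  cds <- toy_cds("ATGGCTGCT")
  cu <- train_codon_based(cds, "codon_usage")
  expect_equal(unname(cu$codon_freq["GCT"]), 2 / 3)
  expect_equal(unname(cu$codon_freq["ATG"]), 1 / 3)
  dic <- train_codon_based(cds, "dicodon")
  expect_equal(dic$dicodon_trans["ATG", "GCT"], 1)
  expect_equal(dic$dicodon_trans["GCT", "GCT"], 1)
  dip <- train_codon_based(cds, "dipeptide")
  expect_equal(dip$aa_trans["M", "A"], 1)
  expect_equal(unname(dip$codon_given_aa[["A"]]["GCT"]), 1)
})

test_that("codon-based generation follows the fitted chains", {
  cds <- toy_cds("ATGGCTGCT")
  dic <- train_codon_based(cds, "dicodon")
  gene <- generate_cds(dic, 6, seed = 1)
  # from any start the chain moves to GCT and stays there
  expect_match(gene, "^(ATG|GCT)(GCT){5}$")
  cu <- train_codon_based(toy_cds("AAAAAAAAA"), "codon_usage")
  expect_identical(generate_cds(cu, 4, seed = 1), paste(rep("AAA", 4), collapse = ""))
})

test_that("empirical codon frequencies of generated genes match the model", {
  g <- synth_genome(n_genes = 30, lengths = 200, gc_target = 0.5, seed = 8)
  cu <- train_codon_based(g, "codon_usage")
  sim <- generate_cds(cu, rep(500L, 200L), seed = 9)  # 1e5 codons
  codons <- unlist(lapply(sim, function(x)
    substring(x, seq(1, nchar(x) - 2, 3), seq(3, nchar(x), 3))))
  emp <- table(factor(codons, levels = names(cu$codon_freq))) / length(codons)
  expect_lt(max(abs(as.numeric(emp) - cu$codon_freq)), 0.005)
})

test_that("dicodon fits converge to the codon marginal under i.i.d. truth", {
  g <- synth_genome(n_genes = 80, lengths = 400, gc_target = 0.5, seed = 10)
  dic <- train_codon_based(g, "dicodon")
  # data are i.i.d. codons, so every well-sampled transition row should be
  # close to the marginal codon frequencies
  common <- names(dic$codon_freq)[dic$codon_freq > 0.01]
  dev <- max(abs(dic$dicodon_trans[common, ] -
                   matrix(dic$codon_freq, length(common),
                          length(dic$codon_freq), byrow = TRUE)))
  expect_lt(dev, 0.03)
})

test_that("analytic expectation matches hand enumeration", {
  mk <- function(freq) structure(list(kind = "codon_usage", table_id = 11L,
                                      codon_freq = freq, organism = NA),
                                 class = "codon_model")
  # all-AAA genome: no codon suffix starts with T
  e0 <- analytic_osc_expectation(mk(c(AAA = 1)), 100)
  expect_equal(e0$E2 + e0$E3, 0)
  # freq(TTA) = freq(AAT) = 1/2: enumerate the four ordered pairs
  # (TTA,TTA): +2 TAT, +3 ATT | (TTA,AAT): +2 TAA*, +3 AAA
  # (AAT,TTA): +2 ATT, +3 TTT | (AAT,AAT): +2 ATA, +3 TAA*
  e1 <- analytic_osc_expectation(mk(c(TTA = 0.5, AAT = 0.5)), 11)
  expect_equal(e1$p2, 0.25)
  expect_equal(e1$p3, 0.25)
  expect_equal(e1$E2, 2.5)
  expect_equal(e1$E3, 2.5)
  # uniform over all 64 codons (diagnostic): stop chance per window is 3/64
  uni <- mk(stats::setNames(rep(1 / 64, 64), oscan:::ALL_CODONS))
  e2 <- analytic_osc_expectation(uni, 1000)
  expect_equal(e2$p2, 3 / 64)
  expect_equal(e2$p3, 3 / 64)
  dic <- train_codon_based(toy_cds("ATGGCTGCT"), "dicodon")
  expect_error(analytic_osc_expectation(dic, 10), class = "oscan_config_error")
})

test_that("dicodon forward expectation matches simulation", {
  g <- synth_genome(n_genes = 20, lengths = 150, gc_target = 0.45, seed = 11)
  dic <- train_codon_based(g, "dicodon")
  lens <- rep(150L, 20L)
  exact <- analytic_osc_expectation_dicodon(dic, lens)
  sims <- vapply(1:100, function(i) {
    sim <- toy_cds(generate_cds(dic, lens, seed = 1000 + i),
                   ids = sprintf("x%03d", seq_along(lens)))
    genome_osc_stats(sim)$density_total
  }, numeric(1))
  se <- stats::sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - exact$density_total), 4 * se)
})

test_that("model serialization round-trips through JSON", {
  g <- synth_genome(n_genes = 15, lengths = 120, gc_target = 0.5, seed = 12)
  dir <- withr::local_tempdir()
  m <- train_periodic_markov(g, 2)
  p <- file.path(dir, "m.json")
  write_model_json(m, p)
  m2 <- read_model_json(p)
  expect_equal(m2$prob, m$prob)
  expect_equal(m2$initial, m$initial)
  expect_identical(generate_cds(m2, c(100L, 100L), seed = 3),
                   generate_cds(m, c(100L, 100L), seed = 3))
  cu <- train_codon_based(g, "dicodon")
  p2 <- file.path(dir, "cu.json")
  write_model_json(cu, p2)
  cu2 <- read_model_json(p2)
  expect_equal(cu2$codon_freq, cu$codon_freq)
  expect_equal(cu2$dicodon_trans, cu$dicodon_trans)
})

test_that("generated genomes pass the CDS filters unchanged", {
  g <- synth_genome(n_genes = 20, lengths = 120, gc_target = 0.4, seed = 13)
  for (spec in list(train_periodic_markov(g, 2),
                    train_codon_based(g, "dicodon"),
                    train_codon_based(g, "dipeptide"))) {
    sim <- toy_cds(generate_cds(spec, rep(120L, 10L), seed = 14),
                   ids = sprintf("y%02d", 1:10))
    filt <- filter_cds(sim)
    expect_equal(nrow(filt), 10L)
    expect_identical(filt$sequence, sim$sequence)
  }
})
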