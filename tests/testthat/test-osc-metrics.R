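test_that("count_oscs matches hand-enumerated examples", {
  stops <- genetic_code(11)$stop_codons
  # frame +2 triplets of ATGTTAGCATGA: TGT TAG CAT -> one stop
  expect_equal(count_oscs("ATGTTAGCATGA", 1, stops), 1L)
  # frame +3 triplets: GTT AGC ATG -> none
  expect_equal(count_oscs("ATGTTAGCATGA", 2, stops), 0L)
  # ATGAATTAA frame +2: TGA ATT -> one
  expect_equal(count_oscs("ATGAATTAA", 1, stops), 1L)
  # table 4 drops TGA from the stop set but TAG still counts
  expect_equal(count_oscs("ATGTTAGCATGA", 1, genetic_code(4)$stop_codons), 1L)
  expect_error(count_oscs("ATGNNN", 1, stops), class = "oscan_input_error")
})

test_that("count_oscs agrees with a naive sliding scan on random genes", {
  stops <- genetic_code(11)$stop_codons
  for (seed in 1:10) {
    gene <- random_sense_gene(150, seed)
    expect_equal(count_oscs(gene, 1, stops), brute_count_oscs(gene, 1))
    expect_equal(count_oscs(gene, 2, stops), brute_count_oscs(gene, 2))
  }
})

test_that("genome_osc_stats aggregates per-gene counts into densities", {
  # single 3-codon gene ATG TTA GCA: frame +2 has TGT TAG -> 1; +3 GTT AGC -> 0
  st <- genome_osc_stats(toy_cds("ATGTTAGCA"))
  expect_equal(unname(st$totals), c(1, 0, 3))
  expect_equal(st$density2, 100 * 1 / 3)
  expect_equal(st$density3, 0)
  expect_equal(st$density_total, st$density2 + st$density3)
  # genomes without T cannot contain stops in any frame
  noT <- toy_cds(paste(rep("GCA", 120), collapse = ""))
  stT <- genome_osc_stats(noT)
  expect_equal(stT$density_total, 0)
  expect_error(genome_osc_stats(toy_cds(character(0))), class = "oscan_input_error")
})

test_that("junction-lookup counting equals per-sequence scanning", {
  stops <- genetic_code(11)$stop_codons
  cds <- toy_cds(vapply(1:8, function(s) random_sense_gene(200, s + 50), ""))
  st <- genome_osc_stats(cds)
  n2 <- sum(vapply(cds$sequence, count_oscs, 0L, frame_offset = 1, stop_codons = stops))
  n3 <- sum(vapply(cds$sequence, count_oscs, 0L, frame_offset = 2, stop_codons = stops))
  expect_equal(unname(st$totals[["N2"]]), n2)
  expect_equal(unname(st$totals[["N3"]]), n3)
})

test_that("totals are additive over concatenated genome sets", {
  g1 <- synth_genome(n_genes = 15, lengths = 120, gc_target = 0.4, seed = 1,
                     organism = "a")
  g2 <- synth_genome(n_genes = 10, lengths = 150, gc_target = 0.6, seed = 2,
                     organism = "b")
  both <- oscan:::as_cds_tbl(dplyr::bind_rows(g1, g2))
  both$organism <- "ab"
  st <- genome_osc_stats(both)
  s1 <- genome_osc_stats(g1); s2 <- genome_osc_stats(g2)
  expect_equal(st$totals, s1$totals + s2$totals)
})

test_that("per-gene counts respect the window-count bound", {
  for (seed in 1:5) {
    gene <- random_sense_gene(100 + seed, seed)
    stops <- genetic_code(11)$stop_codons
    total <- count_oscs(gene, 1, stops) + count_oscs(gene, 2, stops)
    codons <- nchar(gene) / 3
    expect_lte(total, 2 * (codons - 1) + 2)
  }
})

test_that("osc_usage normalises within each frame and flags empty frames", {
  # only +2 OSC is TAG (from TTA GCA junction? construct directly):
  # gene ATG TAG would be in-frame; instead ATG GTA GCA has +2 TGG TAG -> TAG
  u <- osc_usage(toy_cds("ATGGTAGCA"))
  f2 <- u[u$frame == "+2", ]
  expect_equal(f2$freq[f2$stop == "TAG"], 1)
  expect_equal(sum(f2$freq), 1)
  expect_true(all(is.na(u$freq[u$frame == "+3"])))  # no +3 OSC -> undefined
  # larger random genome: both frames normalised
  cds <- toy_cds(vapply(1:5, function(s) random_sense_gene(300, s + 80), ""))
  u2 <- osc_usage(cds)
  sums <- tapply(u2$freq, u2$frame, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})

test_that("usage ratios reflect raw counts", {
  # build a genome whose +2 OSCs are 3 TAA and 1 TGA using explicit junctions:
  # codon pair (xTA, Ayy) gives +2 window TAA; (xTG, Ayy) gives TGA
  genes <- c(
    "ATGCTAACCCTAACCCTAACCGTGACC",  # pairs CTA|ACC (x3 TAA), GTG|ACC (TGA)
    "ATGGGC")
  cds <- toy_cds(paste0(genes, collapse = ""))
  u <- osc_usage(cds)
  f2 <- u[u$frame == "+2", ]
  expect_equal(f2$freq[f2$stop == "TAA"], 0.75)
  expect_equal(f2$freq[f2$stop == "TGA"], 0.25)
})

test_that("composition statistics match direct counts", {
  atgc <- toy_cds(paste(rep("ATGC", 3), collapse = ""))  # 12 nt, 4 codons
  cs <- composition_stats(atgc)
  expect_equal(cs$gc, 0.5)
  expect_equal(cs$gc_skew, 0)
  expect_equal(cs$at_skew, 0)
  g2 <- composition_stats(toy_cds("GGGAAA"))
  expect_equal(g2$gc, 0.5)
  expect_equal(g2$gc_skew, 1)
  expect_equal(g2$at_skew, 1)
  expect_equal(g2$gc_ratio, 1)
  g3 <- composition_stats(toy_cds("ATGGCC"))
  expect_equal(g3$gc3, 1)   # third positions G, C
  expect_equal(g3$gc1, 0.5) # A, C
  expect_equal(g3$gc2, 0.5) # T, C
  # gc equals the mean of the positional fractions on complete codons
  rand <- toy_cds(random_sense_gene(200, 99))
  cr <- composition_stats(rand)
  expect_equal(cr$gc, mean(c(cr$gc1, cr$gc2, cr$gc3)))
})

test_that("frame bias is the signed log ratio with undefined N3=0", {
  st <- list(totals = c(N2 = 100, N3 = 10, total_codons = 1000))
  expect_equal(frame_bias(st), 1)
  st$totals[c("N2", "N3")] <- c(10, 100)
  expect_equal(frame_bias(st), -1)
  st$totals[c("N2", "N3")] <- c(50, 50)
  expect_equal(frame_bias(st), 0)
  st$totals[c("N2", "N3")] <- c(5, 0)
  expect_warning(fb <- frame_bias(st))
  expect_true(is.na(fb))
})

test_that("genome_metrics binds densities, composition and usage per organism", {
  cds <- dplyr::bind_rows(
    synth_genome(n_genes = 10, lengths = 120, gc_target = 0.35, seed = 5, organism = "low"),
    synth_genome(n_genes = 10, lengths = 120, gc_target = 0.65, seed = 6, organism = "high"))
  m <- genome_metrics(oscan:::as_cds_tbl(cds))
  expect_equal(nrow(m), 2L)
  expect_true(all(c("density_total", "gc", "gc3", "frame_bias", "TAA_f2",
                    "TGA_f3") %in% names(m)))
  expect_gt(m$density_total[m$organism == "low"],
            m$density_total[m$organism == "high"])
})
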