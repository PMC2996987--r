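# shared fixture builders (all fixtures are generated in code)

TABLE11_STOPS <- c("TAA", "TAG", "TGA")

# a cds_tbl from raw sequences, bypassing I/O
toy_cds <- function(sequences, table_id = 11L, organism = "toy",
                    ids = sprintf("g%03d", seq_along(sequences))) {
  oscan:::as_cds_tbl(tibble::tibble(
    gene_id = ids, organism = organism, genus = "Toygenus",
    division = "test", table_id = as.integer(table_id),
    sequence = sequences, pseudogene = FALSE, incomplete = FALSE,
    plasmid = FALSE, n_codons = nchar(sequences) %/% 3L
  ))
}

# stop-free random gene strings of n_codons codons (table 11), base R only,
# independent of the package's generators
random_sense_gene <- function(n_codons, seed) {
  set.seed(seed)
  sense <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    TABLE11_STOPS)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# brute-force OSC count by sliding over the shifted frame with substr --
# deliberately naive, used as the independent oracle for fast counters
brute_count_oscs <- function(sequence, frame_offset, stops = TABLE11_STOPS) {
  n <- nchar(sequence)
  count <- 0L
  i <- 1L + frame_offset
  while (i + 2L <= n) {
    if (substr(sequence, i, i + 2L) %in% stops) count <- count + 1L
    i <- i + 3L
  }
  count
}

# GenBank fixture: writes a small flat file with the package's writer plus a
# hand-appended pseudogene feature, returns the path
make_genbank_fixture <- function(dir = tempdir()) {
  genes <- toy_cds(c(
    paste(rep("ATGGCTTTAGCA", 30), collapse = ""),   # 120 codons
    paste(rep("ATGAAACCCGGG", 30), collapse = ""),
    paste(rep("ATGTCATCAGCA", 30), collapse = "")
  ), organism = "SynthOrg")
  path <- file.path(dir, "synthetic_fixture.gb")
  write_genbank(genes, path)
  genes_attr <- genes
  attr(path, "genes") <- genes_attr
  path
}
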