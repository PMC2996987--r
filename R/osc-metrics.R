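# ---- counting out-of-frame stops ----

#' Count out-of-frame stop codons in one sequence
#'
#' Scans non-overlapping triplets of a shifted reading frame of a coding
#' sequence. `frame_offset = 1` scans frame +2 (triplets starting one base
#' into the gene, the frame reached by a +1 ribosomal frameshift);
#' `frame_offset = 2` scans frame +3 (a -1 frameshift). Trailing one or two
#' bases that cannot form a triplet are ignored; windows never extend past
#' the gene.
#'
#' @param sequence a DNA string over A/C/G/T.
#' @param frame_offset 1 (frame +2) or 2 (frame +3).
#' @param stop_codons character vector of stop trinucleotides, e.g.
#'   `genetic_code(11)$stop_codons`.
#' @return Integer count of stop triplets in the scanned frame.
#' @examples
#' count_oscs("ATGTTAGCATGA", 1, genetic_code(11)$stop_codons)  # TGT TAG CAT -> 1
#' @export
count_oscs <- function(sequence, frame_offset, stop_codons) {
  stopifnot(frame_offset %in% c(1L, 2L))
  if (grepl("[^ACGT]", sequence)) {
    abort("sequence contains non-ACGT characters", class = "oscan_input_error")
  }
  n <- nchar(sequence)
  if (n < frame_offset + 3L) return(0L)
  starts <- seq.int(1L + frame_offset, n - 2L, by = 3L)
  sum(substring(sequence, starts, starts + 2L) %in% stop_codons)
}

# fast internal path: per-gene OSC counts from integer-coded codon vectors.
# osc windows in frames +2/+3 always straddle a codon junction, so counts are
# sums of a lookup over adjacent codon pairs.
osc_pair_masks <- function(stop_codons) {
  s <- codon_to_int(stop_codons)
  b1 <- s %/% 16L; b2 <- (s %/% 4L) %% 4L; b3 <- s %% 4L
  m2 <- matrix(0L, 64, 64)  # +2: suffix(2) of codon i + prefix(1) of codon i+1
  m3 <- matrix(0L, 64, 64)  # +3: suffix(1) of codon i + prefix(2) of codon i+1
  ci <- 0:63
  c_b1 <- ci %/% 16L; c_b2 <- (ci %/% 4L) %% 4L; c_b3 <- ci %% 4L
  for (k in seq_along(s)) {
    left2 <- which(c_b2 == b1[k] & c_b3 == b2[k])  # codon i candidates, +2
    right1 <- which(c_b1 == b3[k])                 # codon i+1 candidates, +2
    m2[left2, right1] <- m2[left2, right1] + 1L
    left3 <- which(c_b3 == b1[k])
    right2 <- which(c_b1 == b2[k] & c_b2 == b3[k])
    m3[left3, right2] <- m3[left3, right2] + 1L
  }
  list(frame2 = m2, frame3 = m3)
}

# counts per gene for integer codon vectors (list of integer vectors)
count_osc_codons <- function(codon_list, masks) {
  f <- function(x, m) {
    n <- length(x)
    if (n < 2L) return(0L)
    sum(m[cbind(x[-n] + 1L, x[-1L] + 1L)])
  }
  tibble(n2 = vapply(codon_list, f, integer(1), m = masks$frame2),
         n3 = vapply(codon_list, f, integer(1), m = masks$frame3))
}

#' Per-genome OSC counts and densities
#'
#' Counts out-of-frame stops per gene in frames +2 and +3 and summarises them
#' per genome as densities per 100 codons, using the total sense-codon count
#' as denominator.
#'
#' @param cds a filtered single-organism `cds_tbl` (see [filter_cds()]).
#' @return An object of class `osc_stats`: list with `per_gene` (tibble of
#'   `gene_id`, `n2`, `n3`, `codons`), `totals` (`N2`, `N3`, `total_codons`)
#'   and densities `density2`, `density3`, `density_total` (per 100 codons).
#' @examples
#' g <- synth_genome(n_genes = 20, gc_target = 0.4, seed = 1)
#' genome_osc_stats(g)
#' @export
genome_osc_stats <- function(cds) {
  cds <- as_cds_tbl(cds)
  if (!nrow(cds)) abort("empty CDS set", class = "oscan_input_error")
  if (length(unique(cds$table_id)) != 1L) {
    abort("CDS set mixes genetic codes", class = "oscan_input_error")
  }
  code <- genetic_code(cds$table_id[[1]])
  masks <- osc_pair_masks(code$stop_codons)
  codon_list <- lapply(cds$sequence, seq_to_codon_int)
  counts <- count_osc_codons(codon_list, masks)
  per_gene <- tibble(gene_id = cds$gene_id, n2 = counts$n2, n3 = counts$n3,
                     codons = lengths(codon_list))
  new_osc_stats(per_gene, organism = cds$organism[[1]] %||% NA_character_)
}

new_osc_stats <- function(per_gene, organism = NA_character_) {
  N2 <- sum(per_gene$n2); N3 <- sum(per_gene$n3); tc <- sum(per_gene$codons)
  structure(
    list(organism = organism, per_gene = per_gene,
         totals = c(N2 = N2, N3 = N3, total_codons = tc),
         density2 = 100 * N2 / tc, density3 = 100 * N3 / tc,
         density_total = 100 * (N2 + N3) / tc),
    class = "osc_stats"
  )
}

#' @export
print.osc_stats <- function(x, ...) {
  cat("<osc_stats>", if (!is.na(x$organism)) x$organism else "", "\n")
  cat(sprintf("  genes: %d | codons: %d | N2: %d | N3: %d\n",
              nrow(x$per_gene), x$totals[["total_codons"]],
              x$totals[["N2"]], x$totals[["N3"]]))
  cat(sprintf("  density per 100 codons: +2 %.3f | +3 %.3f | total %.3f\n",
              x$density2, x$density3, x$density_total))
  invisible(x)
}

#' @export
tidy.osc_stats <- function(x, ...) x$per_gene

#' @export
glance.osc_stats <- function(x, ...) {
  tibble(organism = x$organism,
         n_genes = nrow(x$per_gene),
         total_codons = unname(x$totals[["total_codons"]]),
         n2 = unname(x$totals[["N2"]]), n3 = unname(x$totals[["N3"]]),
         density2 = x$density2, density3 = x$density3,
         density_total = x$density_total)
}

#' Relative stop-codon usage in the alternate frames
#'
#' For each alternate frame, the relative frequency of each stop trinucleotide
#' among that frame's out-of-frame stops (each frame normalised to sum to 1).
#' Frames without any OSC are flagged undefined (`NA` frequencies).
#'
#' @param cds a filtered single-organism `cds_tbl`.
#' @return A tibble with one row per (frame, stop codon):
#'   columns `frame` (`"+2"`/`"+3"`), `stop`, `count`, `freq`.
#' @export
osc_usage <- function(cds) {
  cds <- as_cds_tbl(cds)
  code <- genetic_code(cds$table_id[[1]])
  codon_list <- lapply(cds$sequence, seq_to_codon_int)
  usage <- purrr::map(code$stop_codons, function(s) {
    cnt <- count_osc_codons(codon_list, osc_pair_masks(s))
    tibble(stop = s, f2 = sum(cnt$n2), f3 = sum(cnt$n3))
  }) |> bind_rows()
  out <- tibble(
    frame = rep(c("+2", "+3"), each = nrow(usage)),
    stop = rep(usage$stop, 2L),
    count = c(usage$f2, usage$f3)
  ) |>
    group_by(.data$frame) |>
    mutate(freq = if (sum(.data$count) > 0) .data$count / sum(.data$count)
           else NA_real_) |>
    ungroup()
  out
}

#' Nucleotide composition of a CDS set
#'
#' Pooled G+C content, positional G+C at codon positions 1-3, strand skews
#' and the GC:AT ratio of a filtered CDS set.
#'
#' @param cds a filtered single-organism `cds_tbl`.
#' @return One-row tibble: `gc`, `gc1`, `gc2`, `gc3`, `gc_skew` ((G-C)/(G+C)),
#'   `at_skew` ((A-T)/(A+T)), `gc_ratio` ((G+C)/(A+T)).
#' @export
composition_stats <- function(cds) {
  cds <- as_cds_tbl(cds)
  if (!nrow(cds)) abort("empty CDS set", class = "oscan_input_error")
  ints <- unlist(lapply(cds$sequence, nt_to_int), use.names = FALSE)
  pos <- unlist(lapply(nchar(cds$sequence), function(n) rep_len(1:3, n)),
                use.names = FALSE)
  counts <- table(factor(ints, levels = 0:3))  # A C G T
  a <- counts[[1]]; c_ <- counts[[2]]; g <- counts[[3]]; t <- counts[[4]]
  posgc <- vapply(1:3, function(p) mean(ints[pos == p] %in% c(1L, 2L)), numeric(1))
  tibble(gc = (g + c_) / length(ints),
         gc1 = posgc[1], gc2 = posgc[2], gc3 = posgc[3],
         gc_skew = (g - c_) / (g + c_),
         at_skew = (a - t) / (a + t),
         gc_ratio = (g + c_) / (a + t))
}

#' Frame bias of OSC counts
#'
#' log10 of the ratio of total OSC counts in frame +2 to frame +3. Genomes
#' with no frame +3 OSC have undefined bias (`NA`, with a warning) and are
#' excluded from frame-bias regressions.
#'
#' @param stats an `osc_stats` object from [genome_osc_stats()].
#' @return A single number, `log10(N2/N3)`.
#' @export
frame_bias <- function(stats) {
  N2 <- stats$totals[["N2"]]; N3 <- stats$totals[["N3"]]
  if (N3 == 0) {
    warn("frame +3 has zero OSCs; frame bias undefined")
    return(NA_real_)
  }
  log10(N2 / N3)
}

#' Per-genome metrics table
#'
#' One row per organism combining OSC densities, frame bias, usage vector and
#' composition statistics — the input expected by the descriptive statistics
#' layer (PCA, regressions).
#'
#' @param cds a filtered `cds_tbl`, possibly spanning many organisms.
#' @return A tibble with one row per organism.
#' @export
genome_metrics <- function(cds) {
  cds <- as_cds_tbl(cds)
  cds |>
    group_by(.data$organism) |>
    group_map(function(g, key) {
      g <- as_cds_tbl(mutate(g, organism = key$organism))
      st <- genome_osc_stats(g)
      comp <- composition_stats(g)
      us <- osc_usage(g) |>
        mutate(var = paste0(.data$stop, "_", sub("\\+", "f", .data$frame))) |>
        select("var", "freq") |>
        tidyr::pivot_wider(names_from = "var", values_from = "freq")
      bind_cols(glance(st),
                tibble(frame_bias = suppressWarnings(frame_bias(st))),
                comp, us)
    }) |>
    bind_rows()
}
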