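# ---- GenBank flat-file CDS extraction ----
#
# Minimal feature-table parser for GenBank flat files: reads LOCUS/DEFINITION,
# the FEATURES block (CDS locations, incl. complement() and join(), and a few
# qualifiers), and the ORIGIN sequence block. Only what CDS extraction needs.

parse_genbank_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[[1]])) {
    abort(paste0("not a GenBank flat file: ", path), class = "oscan_format_error")
  }
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) abort("GenBank record terminator '//' missing", class = "oscan_format_error")
  starts <- c(1L, head(ends, -1L) + 1L)
  purrr::map2(starts, ends, function(s, e) parse_genbank_one(lines[s:(e - 1L)]))
}

parse_genbank_one <- function(lines) {
  locus <- stringr::str_split(stringr::str_squish(lines[[1]]), " ")[[1]][2]
  def_i <- grep("^DEFINITION", lines)
  definition <- if (length(def_i)) stringr::str_squish(sub("^DEFINITION", "", lines[[def_i[1]]])) else ""
  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) abort("GenBank record has no ORIGIN block", class = "oscan_format_error")
  seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- list()
  if (length(feat_i)) {
    fl <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    # a feature line starts with 5 spaces + key; continuation/qualifier lines
    # start with 21 spaces
    key_i <- grep("^ {5}\\S", fl)
    bounds <- c(key_i, length(fl) + 1L)
    features <- purrr::map(seq_along(key_i), function(k) {
      block <- fl[bounds[k]:(bounds[k + 1L] - 1L)]
      key <- stringr::str_split(stringr::str_squish(block[[1]]), " ")[[1]]
      qual_i <- grep("^ {21}/", block)
      # location may wrap onto continuation lines before the first qualifier
      loc_end <- if (length(qual_i)) qual_i[1] - 1L else length(block)
      loc <- paste(stringr::str_squish(c(sub("^ {5}\\S+", "", block[[1]]),
                                         if (loc_end >= 2) block[2:loc_end])), collapse = "")
      quals <- parse_genbank_qualifiers(block[qual_i], block, qual_i)
      list(key = key[1], location = gsub(" ", "", loc), qualifiers = quals)
    })
  }
  list(locus = locus, definition = definition, sequence = sequence, features = features)
}

parse_genbank_qualifiers <- function(qlines, block, qual_i) {
  if (!length(qual_i)) return(list())
  bounds <- c(qual_i, length(block) + 1L)
  out <- list()
  for (k in seq_along(qual_i)) {
    chunk <- paste(stringr::str_squish(block[bounds[k]:(bounds[k + 1L] - 1L)]), collapse = "")
    m <- stringr::str_match(chunk, "^/([A-Za-z_0-9]+)(=(.*))?$")
    val <- m[4]
    if (!is.na(val)) val <- gsub('^"|"$', "", val) else val <- TRUE
    out[[m[2]]] <- val
  }
  out
}

# 1-based inclusive interval list from a GenBank location string; returns NULL
# for locations we treat as incomplete (<, >) or spanning external references
parse_genbank_location <- function(loc) {
  complemented <- FALSE
  incomplete <- grepl("[<>]", loc)
  x <- loc
  if (grepl("^complement\\(", x)) {
    complemented <- TRUE
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x) || grepl("^order\\(", x)) {
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  }
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  if (any(grepl(":", parts, fixed = TRUE))) return(NULL)  # external reference
  spans <- purrr::map(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      se <- rep(as.integer(p), 2L)
    }
    se
  })
  list(spans = spans, complemented = complemented, incomplete = incomplete)
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

extract_cds_from_record <- function(rec, table_id) {
  feats <- purrr::keep(rec$features, ~ .x$key == "CDS")
  if (!length(feats)) return(NULL)
  is_plasmid <- grepl("plasmid", rec$definition, ignore.case = TRUE)
  rows <- purrr::imap(feats, function(f, i) {
    loc <- parse_genbank_location(f$location)
    q <- f$qualifiers
    id <- q$locus_tag %||% q$gene %||% q$protein_id %||% paste0(rec$locus, "_CDS", i)
    pseudo <- isTRUE(q$pseudo) || isTRUE(q$pseudogene) || is.character(q$pseudogene)
    tid <- if (!is.null(q$transl_table)) as.integer(q$transl_table) else as.integer(table_id)
    seqs <- NA_character_
    incomplete <- TRUE
    if (!is.null(loc)) {
      pieces <- vapply(loc$spans, function(se)
        substr(rec$sequence, se[1], se[2]), character(1))
      seqs <- paste(pieces, collapse = "")
      if (loc$complemented) seqs <- revcomp(seqs)
      incomplete <- loc$incomplete
    }
    tibble(gene_id = id, sequence = seqs, table_id = tid,
           pseudogene = pseudo, incomplete = incomplete, plasmid = is_plasmid)
  })
  bind_rows(rows)
}

# ---- public loaders ----

#' Load coding sequences from GenBank or FASTA
#'
#' Reads one CDS record per GenBank CDS feature (minus-strand features are
#' reverse-complemented onto the coding strand) or per FASTA entry. No
#' filtering is applied at load time; see [filter_cds()].
#'
#' @param path path to a GenBank flat file (`.gb`/`.gbk`) or a multi-FASTA.
#' @param format `"genbank"` or `"fasta"`.
#' @param table_id NCBI translation-table id used for records that do not
#'   declare one (`/transl_table` qualifiers take precedence in GenBank input).
#' @param organism,genus,division optional labels attached to every record.
#' @return A `cds_tbl` tibble, one row per CDS, with columns `gene_id`,
#'   `organism`, `genus`, `division`, `table_id`, `sequence` and bookkeeping
#'   columns (`pseudogene`, `incomplete`, `plasmid`).
#' @export
load_cds <- function(path, format = c("fasta", "genbank"), table_id = 11L,
                     organism = NA_character_, genus = NA_character_,
                     division = NA_character_) {
  format <- match.arg(format)
  genetic_code(table_id)  # validate id early
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "oscan_format_error")
  if (format == "genbank") {
    recs <- parse_genbank_records(path)
    tbl <- bind_rows(purrr::map(recs, extract_cds_from_record, table_id = table_id))
    if (is.null(tbl) || !nrow(tbl)) {
      tbl <- tibble(gene_id = character(), sequence = character(),
                    table_id = integer(), pseudogene = logical(),
                    incomplete = logical(), plasmid = logical())
    }
    if (is.na(organism)) {
      org <- recs[[1]]$definition
      organism <- if (nzchar(org)) org else recs[[1]]$locus
    }
  } else {
    ss <- Biostrings::readBStringSet(path)
    tbl <- tibble(gene_id = sub("\\s.*$", "", names(ss)),
                  sequence = unname(as.character(ss)),
                  table_id = as.integer(table_id),
                  pseudogene = FALSE, incomplete = FALSE, plasmid = FALSE)
  }
  tbl <- tbl |>
    mutate(sequence = toupper(.data$sequence),
           organism = organism, genus = genus, division = division) |>
    select("gene_id", "organism", "genus", "division", "table_id",
           "sequence", "pseudogene", "incomplete", "plasmid")
  as_cds_tbl(tbl)
}

as_cds_tbl <- function(x) {
  x <- as_tibble(x)
  for (col in c("organism", "genus", "division")) {
    if (is.null(x[[col]])) x[[col]] <- NA_character_
  }
  if (is.null(x[["table_id"]])) x[["table_id"]] <- 11L
  class(x) <- unique(c("cds_tbl", class(x)))
  x
}

#' Filter coding sequences to the analysis set
#'
#' Applies the inclusion rules used throughout the analysis: drop annotated
#' pseudogenes and incomplete genes, sequences with ambiguous (non-ACGT)
#' bases, genes shorter than `min_codons`, lengths not divisible by 3, and
#' genes with an internal in-frame stop codon of their genetic code.
#' Extra-chromosomal (plasmid-flagged) records are dropped when
#' `exclude_plasmids` is `TRUE`. Terminal stop codons are stripped by default,
#' so all downstream sequences consist of sense codons only.
#'
#' @param cds a `cds_tbl` from [load_cds()] or [synth_genome()].
#' @param min_codons minimum gene length in codons after terminal-stop
#'   stripping (default 100).
#' @param keep_terminal_stop if `TRUE`, a terminal stop codon is retained
#'   rather than stripped (such genes are then excluded if the stop makes the
#'   scanned sequence contain an in-frame stop; default `FALSE`).
#' @param exclude_plasmids drop records flagged as plasmid-borne.
#' @return The kept `cds_tbl` (with an `n_codons` column) carrying an
#'   `exclusion_report` attribute: a tibble of per-reason exclusion counts.
#'   Retrieve it with `attr(x, "exclusion_report")`.
#' @export
filter_cds <- function(cds, min_codons = 100L, keep_terminal_stop = FALSE,
                       exclude_plasmids = TRUE) {
  cds <- as_cds_tbl(cds)
  if (!nrow(cds)) {
    attr(cds, "exclusion_report") <- tibble(reason = character(), n = integer())
    return(cds)
  }
  reasons <- rep(NA_character_, nrow(cds))
  mark <- function(cond, reason) {
    reasons[is.na(reasons) & cond] <<- reason
  }
  if (!is.null(cds$pseudogene)) mark(cds$pseudogene %in% TRUE, "annotated-pseudogene")
  if (!is.null(cds$incomplete)) mark(cds$incomplete %in% TRUE, "incomplete")
  if (exclude_plasmids && !is.null(cds$plasmid)) mark(cds$plasmid %in% TRUE, "extra-chromosomal")
  mark(is.na(cds$sequence) | !nzchar(cds$sequence), "incomplete")
  mark(!is.na(cds$sequence) & grepl("[^ACGT]", cds$sequence), "ambiguous-base")
  mark(nchar(cds$sequence) %% 3L != 0L, "length-not-multiple-of-3")

  seqs <- cds$sequence
  # strip terminal stop codons before length/internal-stop checks
  ok <- is.na(reasons)
  for (i in which(ok)) {
    code <- genetic_code(cds$table_id[i])
    s <- seqs[i]
    n <- nchar(s)
    last <- substr(s, n - 2L, n)
    if (!keep_terminal_stop && last %in% code$stop_codons) {
      s <- substr(s, 1L, n - 3L)
      seqs[i] <- s
    }
    if (nchar(s) < 3L * min_codons) {
      reasons[i] <- "short"
      next
    }
    ints <- seq_to_codon_int(s)
    if (any(int_to_codon(ints) %in% code$stop_codons)) reasons[i] <- "internal-stop"
  }
  kept <- cds[is.na(reasons), , drop = FALSE]
  kept$sequence <- seqs[is.na(reasons)]
  kept$n_codons <- nchar(kept$sequence) %/% 3L
  report <- tibble(reason = reasons[!is.na(reasons)]) |>
    count(.data$reason, name = "n")
  out <- as_cds_tbl(kept)
  attr(out, "exclusion_report") <- report
  out
}

#' Write coding sequences to FASTA
#'
#' @param cds a `cds_tbl`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  ss <- Biostrings::DNAStringSet(cds$sequence)
  names(ss) <- cds$gene_id
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Read a genome manifest
#'
#' A manifest is a TSV with columns `path`, `format`, `organism`, `genus`,
#' `division`, `table_id` and optionally `ogt_category`, `ogt_celsius`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest TSV path.
#' @return A tibble, one row per genome.
#' @export
read_genome_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("path", "format", "organism", "genus", "division", "table_id")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")),
          class = "oscan_format_error")
  }
  m$path <- ifelse(grepl("^/", m$path), m$path, file.path(dirname(path), m$path))
  m
}

#' Keep one genome per genus
#'
#' Reduces sampling bias from heavily sequenced genera (many *Staphylococcus
#' aureus* strains, for instance) by keeping a single genome per genus,
#' chosen uniformly at random under `seed`. Input order is preserved.
#'
#' @param genomes a tibble with one row per genome and a `genus` column
#'   (e.g. a manifest from [read_genome_manifest()]), or a multi-genome
#'   `cds_tbl` (selection is then by organism).
#' @param seed integer seed controlling the within-genus draw.
#' @return The trimmed tibble.
#' @export
select_one_per_genus <- function(genomes, seed) {
  if (inherits(genomes, "cds_tbl")) {
    key <- genomes |> distinct(.data$organism, .data$genus)
    chosen <- select_one_per_genus(key, seed)
    return(genomes |> filter(.data$organism %in% chosen$organism))
  }
  if (is.null(genomes$genus) || anyNA(genomes$genus)) {
    bad <- if (is.null(genomes$genus)) "all rows" else
      paste(genomes$organism[is.na(genomes$genus)], collapse = ", ")
    abort(paste0("missing genus label for: ", bad), class = "oscan_input_error")
  }
  idx <- withr_seed(derive_seed(seed, 101L), {
    tapply(seq_len(nrow(genomes)), genomes$genus, function(i)
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)])
  })
  genomes[sort(unlist(idx, use.names = FALSE)), , drop = FALSE]
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build an artificial metagenome
#'
#' Concatenates whole filtered CDS sets of randomly ordered genomes (drawn
#' without replacement under `seed`) until the pooled coding size reaches
#' `target_mb` megabases; the pool then stops, so the realised size exceeds
#' the target by less than one genome. All genomes must share one genetic
#' code.
#'
#' @param genomes a multi-organism `cds_tbl` (filtered).
#' @param target_mb target coding size in megabases.
#' @param seed integer seed fixing the draw order.
#' @param name organism label of the resulting set.
#' @return A single-organism `cds_tbl`.
#' @export
build_metagenome <- function(genomes, target_mb, seed, name = "metagenome") {
  stopifnot(target_mb > 0)
  genomes <- as_cds_tbl(genomes)
  if (length(unique(genomes$table_id)) != 1L) {
    abort("metagenome pool mixes genetic codes", class = "oscan_input_error")
  }
  sizes <- genomes |>
    group_by(.data$organism) |>
    summarise(nt = sum(nchar(.data$sequence)), .groups = "drop")
  total <- sum(sizes$nt)
  target_nt <- target_mb * 1e6
  if (total < target_nt) {
    abort(sprintf("pool holds %.3f MB, %.3f MB short of target", total / 1e6,
                  (target_nt - total) / 1e6), class = "oscan_input_error")
  }
  ord <- withr_seed(derive_seed(seed, 202L), sample.int(nrow(sizes)))
  cum <- cumsum(sizes$nt[ord])
  k <- which(cum >= target_nt)[1]
  chosen <- sizes$organism[ord[seq_len(k)]]
  out <- genomes |>
    filter(.data$organism %in% chosen) |>
    mutate(source_organism = .data$organism, organism = name)
  as_cds_tbl(out)
}

#' Write a CDS set as a minimal GenBank flat file
#'
#' Concatenates the genes (with short non-coding spacers) into one synthetic
#' contig and writes a LOCUS/FEATURES/ORIGIN flat file with one CDS feature
#' per gene. Genes at even positions are placed on the minus strand
#' (`complement(...)` locations) so strand resolution is exercised on
#' re-reading. Intended for building self-contained fixtures and small
#' interchange files, not for round-tripping real annotation.
#'
#' @param cds a `cds_tbl`.
#' @param path output path.
#' @param spacer non-coding spacer sequence inserted between genes.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(cds, path, spacer = "ACGTAC") {
  pieces <- character(0)
  locs <- character(nrow(cds))
  offset <- 0L
  for (i in seq_len(nrow(cds))) {
    s <- cds$sequence[i]
    minus <- i %% 2L == 0L
    placed <- if (minus) revcomp(s) else s
    start <- offset + 1L
    end <- offset + nchar(placed)
    locs[i] <- if (minus) sprintf("complement(%d..%d)", start, end)
               else sprintf("%d..%d", start, end)
    pieces <- c(pieces, placed, spacer)
    offset <- end + nchar(spacer)
  }
  genome <- paste(pieces, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2000",
                     gsub("[^A-Za-z0-9_]", "_", cds$organism[[1]] %||% "SYNTH"),
                     nchar(genome)), con)
  writeLines(sprintf("DEFINITION  %s, synthetic assembly.",
                     cds$organism[[1]] %||% "synthetic genome"), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(genome)), con)
  for (i in seq_len(nrow(cds))) {
    writeLines(sprintf("     CDS             %s", locs[i]), con)
    writeLines(sprintf('                     /locus_tag="%s"', cds$gene_id[i]), con)
    writeLines(sprintf('                     /transl_table=%d', cds$table_id[i]), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, nchar(genome), by = 60L)
  for (p in pos) {
    chunk <- substr(genome, p, min(p + 59L, nchar(genome)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
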