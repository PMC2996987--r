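#' @useDynLib oscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom utils head tail
NULL

NT <- c("A", "C", "G", "T")

# Amino-acid string of NCBI translation table 1 (standard code), codons in
# TTT, TTC, TTA, TTG, CTT, ... order (first base slowest? no: first base T,C,A,G
# outermost). We instead build codes programmatically from the standard table
# plus documented per-table reassignments, which keeps the differences explicit.
.standard_aa <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G"
)

# codon reassignments relative to the standard code, per NCBI table id
.code_patches <- list(
  `1`  = character(0),
  # vertebrate mitochondrial: AGA/AGG become stops, ATA -> Met, TGA -> Trp
  `2`  = c(AGA = "*", AGG = "*", ATA = "M", TGA = "W"),
  # yeast mitochondrial: TGA -> Trp, ATA -> Met, CTN -> Thr
  `3`  = c(TGA = "W", ATA = "M", CTT = "T", CTC = "T", CTA = "T", CTG = "T"),
  # mold/protozoan/mycoplasma: TGA -> Trp
  `4`  = c(TGA = "W"),
  # bacterial/archaeal/plant plastid: same assignments as the standard code
  `11` = character(0),
  # ascidian mitochondrial: TGA -> Trp, ATA -> Met, AGA/AGG -> Gly
  `13` = c(TGA = "W", ATA = "M", AGA = "G", AGG = "G")
)

#' Genetic-code table
#'
#' Builds the codon table for an NCBI translation-table id, exposing the set
#' of stop trinucleotides and the codon-to-amino-acid map. Stop-codon sets
#' drive all out-of-frame stop (OSC) counting; the amino-acid map drives the
#' dipeptide model. Supported ids: 1, 2, 3, 4, 11, 13 (11 is the
#' bacterial/archaeal code; 4 covers *Entomoplasmatales*/*Mycoplasmatales*
#' where TGA is tryptophan; 2, 3 and 13 are mitochondrial variants).
#'
#' @param table_id integer NCBI translation-table number.
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `stop_codons` (character vector of trinucleotides), `aa` (named map of
#'   all 64 codons to single-letter amino acids, `"*"` for stops) and
#'   `sense_codons` (the 64 minus the stops).
#' @examples
#' genetic_code(11)$stop_codons  # TAA TAG TGA
#' genetic_code(4)$stop_codons   # TAA TAG (TGA = Trp)
#' @export
genetic_code <- function(table_id) {
  key <- as.character(as.integer(table_id))
  if (!key %in% names(.code_patches)) {
    abort(paste0("unknown translation table id: ", table_id,
                 " (supported: ", paste(names(.code_patches), collapse = ", "), ")"),
          class = "oscan_config_error")
  }
  aa <- .standard_aa
  patch <- .code_patches[[key]]
  if (length(patch)) aa[names(patch)] <- patch
  stops <- names(aa)[aa == "*"]
  structure(
    list(table_id = as.integer(table_id),
         stop_codons = stops,
         aa = aa,
         sense_codons = setdiff(names(aa), stops)),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table", x$table_id,
      "| stops:", paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

# ---- nucleotide/codon integer encodings (A=0, C=1, G=2, T=3) ----

ALL_CODONS <- as.vector(outer(outer(NT, NT, paste0), NT, paste0))
ALL_CODONS <- sort(ALL_CODONS)  # index i corresponds to code i-1 (A<C<G<T base order)

codon_to_int <- function(codons) {
  m <- match(codons, ALL_CODONS)
  if (anyNA(m)) abort("invalid codon(s)", class = "oscan_input_error")
  m - 1L
}

int_to_codon <- function(codes) ALL_CODONS[codes + 1L]

nt_to_int <- function(x) {
  # x: character vector of single bases or a single string
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  m <- match(x, NT)
  if (anyNA(m)) abort("sequence contains non-ACGT characters", class = "oscan_input_error")
  m - 1L
}

int_to_nt <- function(codes) paste(NT[codes + 1L], collapse = "")

# integer codes of a string's codons (frame 0); nchar must be divisible by 3
seq_to_codon_int <- function(sequence) {
  v <- nt_to_int(sequence)
  n <- length(v) %/% 3L
  v[seq(1L, by = 3L, length.out = n)] * 16L +
    v[seq(2L, by = 3L, length.out = n)] * 4L +
    v[seq(3L, by = 3L, length.out = n)]
}

codon_int_to_seq <- function(codes) {
  b1 <- codes %/% 16L
  b2 <- (codes %/% 4L) %% 4L
  b3 <- codes %% 4L
  paste(NT[b1 + 1L], NT[b2 + 1L], NT[b3 + 1L], sep = "", collapse = "")
}

# small deterministic seed derivation; keeps every derived seed in [0, 2^31)
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(h)
}
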