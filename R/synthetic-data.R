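# ---- synthetic genomes ----

codon_gc_fraction <- function(codons) {
  vapply(strsplit(codons, "", fixed = TRUE),
         function(x) mean(x %in% c("G", "C")), numeric(1))
}

# exponentially tilt a codon distribution so its expected G+C matches target
tilt_codon_freq <- function(freq, gc_target, tol = 1e-4) {
  g <- codon_gc_fraction(names(freq))
  expected_gc <- function(theta) {
    w <- freq * exp(theta * 3 * g)
    sum(w * g) / sum(w)
  }
  lo <- expected_gc(-60); hi <- expected_gc(60)
  if (gc_target <= lo + tol / 10 || gc_target >= hi - tol / 10) {
    abort(sprintf("gc_target %.3f outside achievable range (%.4f, %.4f) for this codon support",
                  gc_target, lo, hi), class = "oscan_config_error")
  }
  theta <- stats::uniroot(function(th) expected_gc(th) - gc_target,
                          c(-60, 60), tol = 1e-10)$root
  w <- freq * exp(theta * 3 * g)
  w / sum(w)
}

#' Plant an out-of-frame stop excess in a dicodon model
#'
#' Multiplies by `1 + epsilon` every dicodon transition whose codon junction
#' spells an out-of-frame stop (in frame +2 or +3), then renormalises rows.
#' This operationalises junction-local selection for hidden stops, the
#' mechanism the Monte Carlo test is designed to detect; the reweighted
#' chain's exact expected density is available from
#' [analytic_osc_expectation_dicodon()].
#'
#' @param model a `codon_model` with `kind = "dicodon"`.
#' @param epsilon relative weight change, `>= -1` (`-1` removes all
#'   OSC-forming junctions; `0` leaves the model unchanged).
#' @return The reweighted `codon_model`.
#' @export
plant_osc_excess <- function(model, epsilon) {
  if (!inherits(model, "codon_model") || model$kind != "dicodon") {
    abort("requires a dicodon model", class = "oscan_config_error")
  }
  if (epsilon < -1) abort("epsilon must be >= -1", class = "oscan_config_error")
  masks <- sense_pair_masks(model)
  hit <- (masks$frame2 + masks$frame3) > 0
  Tm <- model$dicodon_trans
  Tm[hit] <- Tm[hit] * (1 + epsilon)
  rs <- rowSums(Tm)
  if (any(rs == 0)) {
    Tm[rs == 0, ] <- matrix(model$codon_freq, sum(rs == 0), ncol(Tm), byrow = TRUE)
    rs[rs == 0] <- 1
  }
  model$dicodon_trans <- Tm / rs
  model
}

resolve_lengths <- function(lengths, n_genes) {
  if (is.list(lengths)) {
    stopifnot(!is.null(lengths$median), !is.null(lengths$sdlog))
    out <- pmax(100L, as.integer(round(stats::rlnorm(
      n_genes, meanlog = log(lengths$median), sdlog = lengths$sdlog))))
    return(out)
  }
  if (any(lengths < 100L)) abort("gene lengths must be >= 100 codons",
                                 class = "oscan_config_error")
  rep_len(as.integer(lengths), n_genes)
}

#' Generate a synthetic genome
#'
#' Builds a stop-free CDS set with controllable composition, for exercising
#' the whole pipeline without real data. Codon frequencies start from
#' `base_model` (or uniform over the sense codons) and are exponentially
#' tilted to hit `gc_target` in expectation; genes are then drawn i.i.d.
#' from the tilted codon distribution, or, when `osc_excess_epsilon != 0`,
#' from a dicodon chain with OSC-forming junctions reweighted by
#' [plant_osc_excess()]. Output passes [filter_cds()] unchanged.
#'
#' @param n_genes number of genes.
#' @param lengths gene lengths in codons: a scalar or vector (recycled), or
#'   `list(median =, sdlog =)` for lognormal lengths (truncated at 100).
#' @param gc_target coding G+C fraction in (0, 1).
#' @param table_id NCBI translation table (default 11).
#' @param base_model optional `codon_model` supplying base codon
#'   frequencies.
#' @param osc_excess_epsilon planted relative excess of OSC-forming
#'   dicodons (default 0 = no planted signal).
#' @param seed integer seed; the genome is a deterministic function of the
#'   arguments.
#' @param organism,genus,division labels for the resulting `cds_tbl`.
#' @return A filtered-grade `cds_tbl` (sense codons only, `n_codons`
#'   column included).
#' @export
synth_genome <- function(n_genes = 100L, lengths = 300L, gc_target = 0.5,
                         table_id = 11L, base_model = NULL,
                         osc_excess_epsilon = 0, seed = 1L,
                         organism = NULL, genus = "Synthgenus",
                         division = "synthetic") {
  stopifnot(n_genes >= 1L, gc_target > 0, gc_target < 1)
  code <- genetic_code(table_id)
  base_freq <- if (!is.null(base_model)) {
    stopifnot(inherits(base_model, "codon_model"))
    base_model$codon_freq
  } else {
    stats::setNames(rep(1 / length(code$sense_codons), length(code$sense_codons)),
                    code$sense_codons)
  }
  freq <- tilt_codon_freq(base_freq, gc_target)
  organism <- organism %||%
    sprintf("synthetic_gc%02d_s%d", round(100 * gc_target), seed)

  model <- structure(list(kind = "codon_usage", table_id = code$table_id,
                          codon_freq = freq, organism = organism),
                     class = "codon_model")
  if (osc_excess_epsilon != 0) {
    S <- length(freq)
    dic <- structure(
      list(kind = "dicodon", table_id = code$table_id, codon_freq = freq,
           dicodon_trans = matrix(freq, S, S, byrow = TRUE,
                                  dimnames = list(names(freq), names(freq))),
           organism = organism),
      class = "codon_model")
    model <- plant_osc_excess(dic, osc_excess_epsilon)
  }

  withr_seed(derive_seed(seed, 23L), {
    len <- resolve_lengths(lengths, n_genes)
    seqs <- generate_cds(model, len)
    as_cds_tbl(tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      organism = organism, genus = genus, division = division,
      table_id = code$table_id, sequence = seqs,
      pseudogene = FALSE, incomplete = FALSE, plasmid = FALSE,
      n_codons = len))
  })
}

#' Synthetic dataset for the growth-temperature regression
#'
#' Draws genome-level covariates from realistic ranges (G+C in
#' `[0.25, 0.75]`, AT skew in `[-0.2, 0.2]`, optimal growth temperature from
#' the category midpoints 10/37/60/85 degrees C) and generates percentage
#' deviations from a linear model with a planted temperature slope plus
#' Gaussian noise, for testing [ogt_regression()].
#'
#' @param n_genomes number of genomes (>= 10).
#' @param planted_slope coefficient of OGT in the generating model.
#' @param seed integer seed.
#' @param gc_coef,at_coef,intercept,noise_sd remaining generating
#'   parameters; defaults place responses in the low single-digit percent
#'   range with a positive G+C association.
#' @return Tibble: `pct_deviation`, `ogt`, `ogt_category`, `gc`, `at_skew`.
#' @export
synth_ogt_dataset <- function(n_genomes = 100L, planted_slope = -0.01,
                              seed = 1L, gc_coef = 4, at_coef = 1,
                              intercept = 0.3, noise_sd = 0.3) {
  stopifnot(n_genomes >= 10L)
  midpoints <- c(psychrophile = 10, mesophile = 37,
                 thermophile = 60, hyperthermophile = 85)
  withr_seed(derive_seed(seed, 29L), {
    gc <- stats::runif(n_genomes, 0.25, 0.75)
    at_skew <- stats::runif(n_genomes, -0.2, 0.2)
    cat_idx <- sample.int(4L, n_genomes, replace = TRUE)
    ogt <- unname(midpoints[cat_idx])
    pct <- intercept + planted_slope * ogt + gc_coef * gc + at_coef * at_skew +
      stats::rnorm(n_genomes, sd = noise_sd)
    tibble(pct_deviation = pct, ogt = ogt,
           ogt_category = names(midpoints)[cat_idx],
           gc = gc, at_skew = at_skew)
  })
}
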