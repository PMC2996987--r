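# ---- Monte Carlo expectation testing ----

MODEL_SPECS <- c("periodic2", "periodic5", "codon_usage", "dicodon", "dipeptide")

normalize_model_spec <- function(spec) {
  spec <- switch(spec, codon = "codon_usage", p2 = "periodic2", p5 = "periodic5", spec)
  if (!spec %in% MODEL_SPECS) {
    abort(paste0("unknown model spec: ", spec, " (use ",
                 paste(MODEL_SPECS, collapse = ", "), ")"),
          class = "oscan_config_error")
  }
  spec
}

train_model_spec <- function(cds, spec) {
  switch(spec,
         periodic2 = train_periodic_markov(cds, 2L),
         periodic5 = train_periodic_markov(cds, 5L),
         codon_usage = train_codon_based(cds, "codon_usage"),
         dicodon = train_codon_based(cds, "dicodon"),
         dipeptide = train_codon_based(cds, "dipeptide"))
}

#' One-sample t-test against a reference value
#'
#' The comparison used for each genome: the Monte Carlo trial densities are
#' the sample, the observed density is the reference constant;
#' `t = (mean - reference) / (sd / sqrt(n))`, two-tailed p on n-1 df.
#' A zero-variance sample equal to the reference gives `t = 0, p = 1`;
#' zero variance with a different mean is flagged degenerate (`p = 0`).
#'
#' @param values numeric sample (length >= 2).
#' @param reference the reference constant.
#' @return One-row tibble: `t`, `df`, `p`, `degenerate`.
#' @export
one_sample_t_test <- function(values, reference) {
  n <- length(values)
  if (n < 2L) abort("need at least two values", class = "oscan_input_error")
  s <- stats::sd(values)
  m <- mean(values)
  if (s == 0) {
    if (m == reference) return(tibble(t = 0, df = n - 1L, p = 1, degenerate = FALSE))
    return(tibble(t = sign(m - reference) * Inf, df = n - 1L, p = 0, degenerate = TRUE))
  }
  t <- (m - reference) / (s / sqrt(n))
  tibble(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L), degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control across a family of p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Tibble with columns `p`, `q` (BH-adjusted) and `rejected`
#'   (`q < alpha`).
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "oscan_input_error")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  tibble(p = p_values, q = q, rejected = q < alpha)
}

# per-trial densities for all three frames, given gene lengths in codons
trial_densities <- function(spec, model, lengths, masks) {
  total <- sum(lengths)
  if (inherits(model, "codon_model")) {
    # generate_codon_ints yields 1-based indices into the sense alphabet;
    # count_osc_codons expects 0-based codes
    genes <- lapply(generate_codon_ints(model, lengths), function(g) g - 1L)
    cnt <- count_osc_codons(genes, masks)
  } else {
    ints <- generate_periodic_ints(model, lengths)
    genes <- split_int_genes(triplet_codes(ints, lengths), lengths)
    cnt <- count_osc_codons(genes, masks)
  }
  N2 <- sum(cnt$n2); N3 <- sum(cnt$n3)
  c(`+2` = 100 * N2 / total, `+3` = 100 * N3 / total,
    combined = 100 * (N2 + N3) / total)
}

# integer nt vector (concatenated genes, lengths in codons) -> codon codes
triplet_codes <- function(ints, lengths_codons) {
  n <- length(ints) %/% 3L
  ints[seq(1L, by = 3L, length.out = n)] * 16L +
    ints[seq(2L, by = 3L, length.out = n)] * 4L +
    ints[seq(3L, by = 3L, length.out = n)]
}

#' Monte Carlo expectation of OSC density for one genome
#'
#' The core inference. A compositional model is trained on the genome's own
#' coding sequences; `n_trials` random genomes with the same multiset of gene
#' lengths are generated from it and scored; the simulated densities are
#' compared with the observed density by [one_sample_t_test()]. Percentage
#' deviation is `100 * (observed - mean_expected) / mean_expected`, so
#' overrepresentation of out-of-frame stops is positive. Alongside the
#' t-based p-value the result carries `p_z`, a normal tail probability of
#' the observed deviation in units of the per-trial standard deviation -- a
#' calibration-honest effect-size diagnostic (see the package vignette).
#'
#' @param cds a filtered single-organism `cds_tbl`.
#' @param model_spec one of `"periodic2"`, `"periodic5"`, `"codon_usage"`,
#'   `"dicodon"`, `"dipeptide"`.
#' @param n_trials Monte Carlo trials (default 200).
#' @param seed integer seed; all trial randomness derives from it.
#' @param frames `"both"` for the per-frame and combined rows, or `"+2"` /
#'   `"+3"` / `"combined"` for a single row.
#' @param alpha significance level used for the single-genome direction call
#'   (batch runs re-derive direction from BH-adjusted q-values).
#' @return A tibble of class `expectation_result`, one row per frame:
#'   `organism`, `model`, `frame`, `n_trials`, `mean_expected`,
#'   `sd_expected`, `observed`, `t`, `p`, `p_z`, `q`, `pct_deviation`,
#'   `direction`, `degenerate`, and the per-trial densities as the
#'   list-column `sim_densities`.
#' @export
run_expectation <- function(cds, model_spec, n_trials = 200L, seed = 1L,
                            frames = "both", alpha = 0.05) {
  spec <- normalize_model_spec(model_spec)
  if (n_trials < 2L) abort("n_trials must be >= 2", class = "oscan_config_error")
  cds <- as_cds_tbl(cds)
  obs <- genome_osc_stats(cds)
  model <- train_model_spec(cds, spec)
  code <- genetic_code(cds$table_id[[1]])
  masks <- if (inherits(model, "codon_model")) sense_pair_masks(model)
           else osc_pair_masks(code$stop_codons)
  lengths <- nchar(cds$sequence) %/% 3L

  sims <- matrix(NA_real_, n_trials, 3L,
                 dimnames = list(NULL, c("+2", "+3", "combined")))
  for (trial in seq_len(n_trials)) {
    sims[trial, ] <- withr_seed(derive_seed(seed, 7L, trial),
                                trial_densities(spec, model, lengths, masks))
  }

  observed <- c(`+2` = obs$density2, `+3` = obs$density3, combined = obs$density_total)
  which_frames <- if (identical(frames, "both")) colnames(sims) else frames
  rows <- purrr::map(which_frames, function(fr) {
    x <- sims[, fr]
    obs_val <- unname(observed[[fr]])
    tt <- one_sample_t_test(x, obs_val)
    mexp <- mean(x); sdexp <- stats::sd(x)
    z <- if (sdexp > 0) (obs_val - mexp) / sdexp else NA_real_
    tibble(
      organism = cds$organism[[1]] %||% NA_character_,
      model = spec, frame = fr, n_trials = n_trials,
      mean_expected = mexp, sd_expected = sdexp,
      observed = obs_val,
      t = tt$t, p = tt$p,
      p_z = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
      pct_deviation = if (mexp > 0) 100 * (obs_val - mexp) / mexp else NA_real_,
      degenerate = tt$degenerate,
      sim_densities = list(unname(x))
    )
  })
  out <- bind_rows(rows) |>
    mutate(q = .data$p,
           direction = case_when(
             .data$q < alpha & .data$observed > .data$mean_expected ~ "over",
             .data$q < alpha & .data$observed < .data$mean_expected ~ "under",
             TRUE ~ "ns"))
  class(out) <- unique(c("expectation_result", class(out)))
  out
}

#' Batch expectation analysis across genomes
#'
#' Runs [run_expectation()] for every organism and model, then applies
#' Benjamini-Hochberg FDR control across genomes within each
#' (model, frame) family and tallies over/under/ns calls. Per-genome
#' failures are recorded and the batch continues.
#'
#' @param cds a filtered multi-organism `cds_tbl`.
#' @param model_specs character vector of model specs (see
#'   [run_expectation()]).
#' @param n_trials,seed,alpha,frames as in [run_expectation()]; per-genome
#'   seeds are derived deterministically from `seed`.
#' @return A tibble of class `osc_batch` (one row per genome x model x
#'   frame, with BH-adjusted `q` and `direction`), carrying attributes
#'   `summary` (tallies per model and frame) and `failures` (tibble of
#'   skipped genomes and reasons).
#' @export
batch_analysis <- function(cds, model_specs = c("periodic2", "codon_usage"),
                           n_trials = 200L, seed = 1L, alpha = 0.05,
                           frames = "both") {
  cds <- as_cds_tbl(cds)
  orgs <- unique(cds$organism)
  if (!length(orgs)) abort("no genomes in input", class = "oscan_input_error")
  specs <- vapply(model_specs, normalize_model_spec, character(1))
  failures <- list()
  rows <- list()
  for (oi in seq_along(orgs)) {
    g <- as_cds_tbl(cds[cds$organism == orgs[[oi]], , drop = FALSE])
    for (spec in specs) {
      res <- tryCatch(
        run_expectation(g, spec, n_trials = n_trials,
                        seed = derive_seed(seed, oi, match(spec, MODEL_SPECS)),
                        frames = frames, alpha = alpha),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble(organism = orgs[[oi]], model = spec, error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (!length(rows)) abort("no genome could be analysed", class = "oscan_input_error")
  out <- bind_rows(rows) |>
    group_by(.data$model, .data$frame) |>
    mutate(q = stats::p.adjust(.data$p, method = "BH"),
           direction = case_when(
             .data$q < alpha & .data$observed > .data$mean_expected ~ "over",
             .data$q < alpha & .data$observed < .data$mean_expected ~ "under",
             TRUE ~ "ns")) |>
    ungroup()
  summary_tbl <- out |>
    count(.data$model, .data$frame, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n", values_fill = 0L)
  for (col in c("over", "under", "ns")) {
    if (is.null(summary_tbl[[col]])) summary_tbl[[col]] <- 0L
  }
  attr(out, "summary") <- summary_tbl
  attr(out, "failures") <- bind_rows(failures)
  class(out) <- unique(c("osc_batch", class(out)))
  out
}

#' Summary tallies of a batch analysis
#'
#' @param batch an `osc_batch` tibble from [batch_analysis()].
#' @return Tibble of over/under/ns counts per model and frame.
#' @export
batch_summary <- function(batch) attr(batch, "summary")

#' @export
tidy.expectation_result <- function(x, ...) {
  as_tibble(x) |> select(-"sim_densities")
}

#' @export
glance.expectation_result <- function(x, ...) {
  as_tibble(x) |>
    filter(.data$frame == "combined") |>
    select("organism", "model", "mean_expected", "sd_expected", "observed",
           "pct_deviation", "p", "direction")
}
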