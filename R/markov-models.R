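# ---- three-periodic nucleotide Markov models ----

# order-k context/emission counts by codon phase, pooled over genes.
# Returns array dim (4^k, 4, 3): context (most recent base least significant),
# emitted base, phase (0-based codon position of the emitted base).
periodic_counts <- function(int_genes, k) {
  n_ctx <- 4L^k
  acc <- numeric(n_ctx * 4L * 3L)
  for (v in int_genes) {
    n <- length(v)
    if (n <= k) next
    i <- (k + 1L):n                       # emission positions (1-based)
    ctx <- integer(length(i))
    if (k > 0L) {
      for (j in 1:k) ctx <- ctx + v[i - j] * 4L^(j - 1L)
    }
    phase <- (i - 1L) %% 3L
    key <- phase * (n_ctx * 4L) + ctx * 4L + v[i] + 1L
    acc <- acc + tabulate(key, nbins = n_ctx * 4L * 3L)
  }
  array(acc, dim = c(4L, n_ctx, 3L))  # [emitted, ctx, phase] for fast slicing
}

#' Train a three-periodic nucleotide Markov model
#'
#' Fits maximum-likelihood phase-specific transition tables of the given
#' order from pooled within-gene counts (phase of a base = its 0-based
#' position mod 3). Counts use zero pseudocounts, so any emission whose
#' in-frame completion would form a stop codon of the training genetic code
#' has probability zero — the fitted model is stop-free by construction.
#' Sparse contexts back off to the longest shorter context with data at the
#' same phase; stop-forming completions remain masked at every order.
#'
#' @param cds a filtered single-organism `cds_tbl`.
#' @param order Markov order m >= 1 (the analysis uses 2 and 5).
#' @return An object of class `periodic_markov`: transition tables
#'   (`prob[[phase]]` is a 4^m-by-4 row-stochastic matrix), raw order-m
#'   counts, and the empirical distribution of gene-initial m-mers.
#' @export
train_periodic_markov <- function(cds, order) {
  cds <- as_cds_tbl(cds)
  if (!nrow(cds)) abort("empty CDS set", class = "oscan_input_error")
  order <- as.integer(order)
  if (is.na(order) || order < 1L) abort("order must be >= 1", class = "oscan_config_error")
  code <- genetic_code(cds$table_id[[1]])
  int_genes <- lapply(cds$sequence, nt_to_int)
  total_nt <- sum(lengths(int_genes))
  if (total_nt < 4^(order + 1)) {
    warn(sprintf("training set has %d nt; fewer than 4^(order+1) = %d recommended",
                 total_nt, 4^(order + 1)))
  }
  counts <- lapply(0:order, function(k) periodic_counts(int_genes, k))
  names(counts) <- paste0("k", 0:order)
  n_ctx <- 4L^order
  stops_int <- codon_to_int(code$stop_codons)

  prob <- lapply(0:2, function(phase) {
    m <- matrix(0, n_ctx, 4L)
    for (ctx in 0:(n_ctx - 1L)) {
      row <- NULL
      for (k in order:0) {                       # back off to shorter suffixes
        sub_ctx <- ctx %% 4L^k
        cand <- counts[[k + 1L]][, sub_ctx + 1L, phase + 1L]
        if (sum(cand) > 0) { row <- cand; break }
      }
      if (is.null(row)) row <- rep(0, 4L)
      if (phase == 2L && order >= 2L) {
        prev2 <- ctx %% 16L                      # two most recent bases
        forb <- stops_int[stops_int %/% 4L == prev2] %% 4L
        if (length(forb)) row[forb + 1L] <- 0
      }
      s <- sum(row)
      m[ctx + 1L, ] <- if (s > 0) row / s else 0
    }
    colnames(m) <- NT
    m
  })

  init_ctx <- vapply(int_genes, function(v) {
    sum(v[1:order] * 4L^((order - 1L):0L))
  }, numeric(1))
  init_tab <- table(init_ctx)
  initial <- list(ctx = as.integer(names(init_tab)),
                  prob = as.numeric(init_tab) / sum(init_tab))

  structure(
    list(order = order, table_id = code$table_id,
         prob = prob, counts = counts[[order + 1L]], initial = initial,
         n_train_nt = total_nt,
         organism = cds$organism[[1]] %||% NA_character_),
    class = "periodic_markov"
  )
}

#' @export
print.periodic_markov <- function(x, ...) {
  cat(sprintf("<periodic_markov> order %d, table %d, trained on %s nt (%s)\n",
              x$order, x$table_id, format(x$n_train_nt, big.mark = ","),
              if (is.na(x$organism)) "unnamed" else x$organism))
  invisible(x)
}

# conditional probability lookup: P(base | context string, phase of base)
transition_prob <- function(model, context, base, phase) {
  ctx_int <- sum(nt_to_int(context) * 4L^((model$order - 1L):0L))
  unname(model$prob[[phase + 1L]][ctx_int + 1L, base])
}

#' Generate coding sequences from a fitted model
#'
#' Draws stop-free random genes from a fitted compositional model: a
#' [train_periodic_markov()] chain (per-base sampling with phase-aware
#' transition tables, initial m-mer drawn from the empirical gene starts) or
#' a [train_codon_based()] model (i.i.d. codons, a dicodon chain, or an
#' amino-acid chain with synonymous-codon choice).
#'
#' @param model a `periodic_markov` or `codon_model`.
#' @param n_codons integer vector of gene lengths in codons (one gene per
#'   element).
#' @param seed optional integer; when given, output is a deterministic
#'   function of `(model, n_codons, seed)`.
#' @return Character vector of DNA sequences, one per gene.
#' @export
generate_cds <- function(model, n_codons, seed = NULL) UseMethod("generate_cds")

#' @export
generate_cds.periodic_markov <- function(model, n_codons, seed = NULL) {
  n_codons <- as.integer(n_codons)
  stopifnot(all(n_codons * 3L >= model$order))
  run <- function() {
    ints <- generate_periodic_ints(model, n_codons)
    split_int_genes(ints, n_codons * 3L, codon_units = FALSE)
  }
  if (is.null(seed)) run() else withr_seed(derive_seed(seed, 11L), run())
}

generate_periodic_ints <- function(model, n_codons) {
  init_idx <- sample.int(length(model$initial$ctx), length(n_codons),
                         replace = TRUE, prob = model$initial$prob)
  stops_int <- codon_to_int(genetic_code(model$table_id)$stop_codons)
  periodic_sample_cpp(model$order, model$prob,
                      model$initial$ctx[init_idx],
                      n_codons * 3L, stops_int)
}

split_int_genes <- function(ints, len, codon_units = TRUE) {
  ends <- cumsum(len)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (codon_units) {
    purrr::map2(starts, ends, function(s, e) ints[s:e])
  } else {
    chars <- NT[ints + 1L]
    vapply(seq_along(len), function(g)
      paste(chars[starts[g]:ends[g]], collapse = ""), character(1))
  }
}

# ---- codon-based models (codon usage, dicodon, dipeptide) ----

#' Train a codon-based compositional model
#'
#' Fits one of three nested codon-level models by maximum likelihood:
#' `codon_usage` (i.i.d. codons), `dicodon` (first-order chain over codons,
#' transitions from all adjacent within-gene codon pairs) or `dipeptide`
#' (first-order chain over amino acids plus genome-wide synonymous-codon
#' frequencies within each amino acid). Stop codons never appear in the
#' support: training sequences are sense-codon only.
#'
#' @param cds a filtered single-organism `cds_tbl`.
#' @param kind `"codon_usage"`, `"dicodon"` or `"dipeptide"`.
#' @return An object of class `codon_model`.
#' @export
train_codon_based <- function(cds, kind = c("codon_usage", "dicodon", "dipeptide")) {
  kind <- match.arg(kind)
  cds <- as_cds_tbl(cds)
  if (!nrow(cds)) abort("empty CDS set", class = "oscan_input_error")
  code <- genetic_code(cds$table_id[[1]])
  sense_int <- codon_to_int(code$sense_codons)
  genes <- lapply(cds$sequence, seq_to_codon_int)
  all_codons <- unlist(genes, use.names = FALSE)
  freq64 <- tabulate(all_codons + 1L, nbins = 64L)
  if (any(freq64[setdiff(0:63, sense_int) + 1L] > 0)) {
    abort("training sequences contain in-frame stop codons; run filter_cds first",
          class = "oscan_input_error")
  }
  codon_freq <- freq64[sense_int + 1L]
  codon_freq <- codon_freq / sum(codon_freq)
  names(codon_freq) <- code$sense_codons

  out <- list(kind = kind, table_id = code$table_id, codon_freq = codon_freq,
              organism = cds$organism[[1]] %||% NA_character_)

  if (kind == "dicodon") {
    S <- length(sense_int)
    pos <- match(all_codons, sense_int)
    gene_id <- rep(seq_along(genes), lengths(genes))
    n <- length(pos)
    keep <- gene_id[-n] == gene_id[-1L]
    trans <- matrix(0, S, S, dimnames = list(code$sense_codons, code$sense_codons))
    tab <- table(factor(pos[-n][keep], levels = 1:S),
                 factor(pos[-1L][keep], levels = 1:S))
    trans[] <- as.numeric(tab)
    rs <- rowSums(trans)
    # codons never observed with a successor fall back to the codon marginal
    empty <- rs == 0
    trans[!empty, ] <- trans[!empty, , drop = FALSE] / rs[!empty]
    if (any(empty)) trans[empty, ] <- matrix(codon_freq, sum(empty), S, byrow = TRUE)
    out$dicodon_trans <- trans
  }
  if (kind == "dipeptide") {
    aa_of <- code$aa[code$sense_codons]
    aas <- sort(unique(aa_of))
    aa_genes <- lapply(genes, function(g) aa_of[match(g, sense_int)])
    all_aa <- unlist(aa_genes, use.names = FALSE)
    gene_id <- rep(seq_along(genes), lengths(genes))
    n <- length(all_aa)
    keep <- gene_id[-n] == gene_id[-1L]
    tab <- table(factor(all_aa[-n][keep], levels = aas),
                 factor(all_aa[-1L][keep], levels = aas))
    aa_trans <- matrix(as.numeric(tab), length(aas), length(aas),
                       dimnames = list(aas, aas))
    rs <- rowSums(aa_trans)
    aa_marg <- tabulate(factor(all_aa, levels = aas), nbins = length(aas))
    aa_marg <- aa_marg / sum(aa_marg)
    empty <- rs == 0
    aa_trans[!empty, ] <- aa_trans[!empty, , drop = FALSE] / rs[!empty]
    if (any(empty)) aa_trans[empty, ] <- matrix(aa_marg, sum(empty), length(aas), byrow = TRUE)
    out$aa_trans <- aa_trans
    out$aa_initial <- aa_marg
    out$codon_given_aa <- lapply(stats::setNames(aas, aas), function(a) {
      f <- codon_freq[aa_of == a]
      if (sum(f) == 0) f[] <- 1 / length(f) else f <- f / sum(f)
      f
    })
  }
  structure(out, class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("<codon_model> kind %s, table %d (%s)\n", x$kind, x$table_id,
              if (is.na(x$organism)) "unnamed" else x$organism))
  invisible(x)
}

#' @export
generate_cds.codon_model <- function(model, n_codons, seed = NULL) {
  n_codons <- as.integer(n_codons)
  stopifnot(all(n_codons >= 1L))
  run <- function() {
    genes <- generate_codon_ints(model, n_codons)
    sense_int <- codon_to_int(names(model$codon_freq))
    vapply(genes, function(g) codon_int_to_seq(sense_int[g]), character(1))
  }
  if (is.null(seed)) run() else withr_seed(derive_seed(seed, 13L), run())
}

# internal: genes as lists of indices into the sense-codon alphabet (1-based)
generate_codon_ints <- function(model, n_codons) {
  S <- length(model$codon_freq)
  total <- sum(n_codons)
  if (model$kind == "codon_usage") {
    x <- sample.int(S, total, replace = TRUE, prob = model$codon_freq)
    return(split_index_genes(x, n_codons))
  }
  if (model$kind == "dicodon") {
    x <- chain_sample_cpp(model$dicodon_trans, model$codon_freq, n_codons) + 1L
    return(split_index_genes(x, n_codons))
  }
  # dipeptide: amino-acid chain then synonymous choice
  aa_states <- chain_sample_cpp(model$aa_trans, model$aa_initial, n_codons) + 1L
  aas <- rownames(model$aa_trans)
  x <- integer(length(aa_states))
  for (a in seq_along(aas)) {
    idx <- which(aa_states == a)
    if (!length(idx)) next
    syn <- model$codon_given_aa[[aas[a]]]
    pick <- match(names(syn), names(model$codon_freq))
    x[idx] <- pick[sample.int(length(syn), length(idx), replace = TRUE, prob = syn)]
  }
  split_index_genes(x, n_codons)
}

split_index_genes <- function(x, len) {
  ends <- cumsum(len)
  starts <- c(1L, head(ends, -1L) + 1L)
  purrr::map2(starts, ends, function(s, e) x[s:e])
}

# ---- exact expectations (verification oracles) ----

#' Exact expected OSC counts under an i.i.d. codon-usage model
#'
#' Every out-of-frame stop window in frames +2/+3 straddles exactly one
#' junction of adjacent codons, so under independent codons the expectation
#' is exact: per junction, the probability that the flanking codon fragments
#' spell a stop, enumerated by brute force over all sense-codon pairs.
#'
#' @param model a `codon_model` with `kind = "codon_usage"`.
#' @param n_codons integer vector of gene lengths in codons.
#' @return A list: per-junction probabilities `p2`, `p3`; expected counts
#'   `E2`, `E3`; expected densities per 100 codons `density2`, `density3`,
#'   `density_total`.
#' @export
analytic_osc_expectation <- function(model, n_codons) {
  if (!inherits(model, "codon_model") || model$kind != "codon_usage") {
    abort("exact expectation requires a codon_usage model (chain models use Monte Carlo)",
          class = "oscan_config_error")
  }
  masks <- sense_pair_masks(model)
  f <- model$codon_freq
  p2 <- as.numeric(t(f) %*% masks$frame2 %*% f)
  p3 <- as.numeric(t(f) %*% masks$frame3 %*% f)
  junctions <- sum(n_codons - 1L)
  total <- sum(n_codons)
  list(p2 = p2, p3 = p3, E2 = junctions * p2, E3 = junctions * p3,
       density2 = 100 * junctions * p2 / total,
       density3 = 100 * junctions * p3 / total,
       density_total = 100 * junctions * (p2 + p3) / total)
}

sense_pair_masks <- function(model) {
  code <- genetic_code(model$table_id)
  sense_int <- codon_to_int(names(model$codon_freq))
  m <- osc_pair_masks(code$stop_codons)
  list(frame2 = m$frame2[sense_int + 1L, sense_int + 1L],
       frame3 = m$frame3[sense_int + 1L, sense_int + 1L])
}

#' Exact expected OSC counts under a dicodon chain
#'
#' Forward computation over junction positions: the codon distribution at
#' each position is propagated through the transition matrix, and each
#' junction contributes the probability that the adjacent pair spells an
#' out-of-frame stop. Exact for chains started from the model's codon
#' marginal, as [generate_cds()] does.
#'
#' @param model a `codon_model` with `kind = "dicodon"`.
#' @param n_codons integer vector of gene lengths in codons.
#' @return Same shape as [analytic_osc_expectation()], with per-junction
#'   probabilities replaced by expected counts only.
#' @export
analytic_osc_expectation_dicodon <- function(model, n_codons) {
  if (!inherits(model, "codon_model") || model$kind != "dicodon") {
    abort("requires a dicodon model", class = "oscan_config_error")
  }
  masks <- sense_pair_masks(model)
  Tm <- model$dicodon_trans
  Lmax <- max(n_codons)
  d <- model$codon_freq
  e2 <- numeric(Lmax - 1L)
  e3 <- numeric(Lmax - 1L)
  for (k in seq_len(Lmax - 1L)) {
    pair_left <- d
    e2[k] <- sum(pair_left * rowSums(Tm * masks$frame2))
    e3[k] <- sum(pair_left * rowSums(Tm * masks$frame3))
    d <- as.numeric(d %*% Tm)
  }
  cum2 <- cumsum(e2); cum3 <- cumsum(e3)
  E2 <- sum(cum2[n_codons - 1L])
  E3 <- sum(cum3[n_codons - 1L])
  total <- sum(n_codons)
  list(E2 = E2, E3 = E3,
       density2 = 100 * E2 / total, density3 = 100 * E3 / total,
       density_total = 100 * (E2 + E3) / total)
}

# ---- serialization ----

#' Serialize a fitted model to JSON
#'
#' @param model a `periodic_markov` or `codon_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  x$.class <- class(model)[[1]]
  # named numeric vectors must be serialised as JSON objects, not arrays
  if (!is.null(x$codon_freq)) x$codon_freq <- as.list(x$codon_freq)
  if (!is.null(x$codon_given_aa)) x$codon_given_aa <- lapply(x$codon_given_aa, as.list)
  if (!is.null(x$aa_initial)) x$aa_initial <- as.numeric(x$aa_initial)
  if (!is.null(x$prob)) x$prob <- lapply(x$prob, as.data.frame)
  if (!is.null(x$counts)) {
    x$counts_dim <- dim(x$counts)
    x$counts <- as.numeric(x$counts)
  }
  if (!is.null(x$dicodon_trans)) x$dicodon_trans <- as.data.frame(x$dicodon_trans)
  if (!is.null(x$aa_trans)) x$aa_trans <- as.data.frame(x$aa_trans)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_model_json()].
#' @return The restored model object.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (!is.null(x$prob)) {
    x$prob <- lapply(x$prob, function(df) {
      m <- as.matrix(df); colnames(m) <- NT; rownames(m) <- NULL; m
    })
  }
  if (!is.null(x$counts)) {
    x$counts <- array(x$counts, dim = x$counts_dim)
    x$counts_dim <- NULL
  }
  for (nm in c("dicodon_trans", "aa_trans")) {
    if (!is.null(x[[nm]])) {
      m <- as.matrix(x[[nm]])
      rownames(m) <- colnames(m)
      x[[nm]] <- m
    }
  }
  for (nm in c("codon_freq")) {
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  }
  if (!is.null(x$codon_given_aa)) x$codon_given_aa <- lapply(x$codon_given_aa, unlist)
  if (!is.null(x$initial)) x$initial <- list(ctx = as.integer(x$initial$ctx),
                                             prob = as.numeric(x$initial$prob))
  structure(x, class = cls)
}
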