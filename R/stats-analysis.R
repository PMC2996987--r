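# ---- descriptive statistics layer ----

#' Paired per-gene frame comparison
#'
#' Paired t-test of per-gene OSC counts in frame +2 against frame +3 for one
#' genome, as used to ask which alternate frame carries more hidden stops.
#' Zero-variance differences are handled in closed form (`t = +/-Inf, p = 0`
#' for a constant nonzero difference).
#'
#' @param per_gene a tibble with columns `n2` and `n3` (e.g.
#'   `tidy(genome_osc_stats(x))`), one row per gene.
#' @param alpha significance level for the direction call.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff` and `direction`
#'   (`"+2"`, `"+3"` or `"none"`).
#' @export
paired_frame_test <- function(per_gene, alpha = 0.05) {
  if (nrow(per_gene) < 2L) abort("need at least two genes", class = "oscan_input_error")
  d <- per_gene$n2 - per_gene$n3
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1L)
  }
  tibble(t = t, df = n - 1L, p = p, mean_diff = m,
         direction = if (p < alpha && m > 0) "+2"
                     else if (p < alpha && m < 0) "+3" else "none")
}

#' PCA of OSC usage bias
#'
#' Principal component analysis of the per-genome stop-usage matrix (six
#' relative frequencies: three stops in each of frames +2 and +3), centred
#' but not scaled since all variables share the frequency scale. Rows with
#' undefined usage (a frame without any OSC) are dropped with a message.
#' Component signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param usage a numeric matrix or data frame, genomes x usage variables
#'   (e.g. the `TAA_f2` ... columns of [genome_metrics()]).
#' @return Object of class `pca_result`: `loadings` (variables x
#'   components), `variance_fractions`, `scores` (genomes x components),
#'   `n_dropped`.
#' @export
pca_usage <- function(usage) {
  x <- as.matrix(as.data.frame(usage))
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " genome(s) with undefined usage dropped from PCA")
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L) abort("need at least two genomes with defined usage",
                          class = "oscan_input_error")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) {
    warn("constant usage matrix; zero total variance")
    vf <- rep(NA_real_, length(pc$sdev))
  } else {
    vf <- pc$sdev^2 / tot
  }
  loadings <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = loadings, variance_fractions = vf,
                 scores = scores, n_dropped = n_dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", ncol(x$loadings), "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fractions), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  as_tibble(x$loadings, rownames = "variable")
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(component = seq_along(x$variance_fractions),
         variance_fraction = x$variance_fractions)
}

#' Ordinary least squares with optional nested comparison
#'
#' Fits `formula` by OLS; when `reduced` (a nested formula) is supplied, the
#' two fits are compared by an F-test ANOVA. Rank-deficient designs are an
#' error naming the collinear columns.
#'
#' @param data a data frame.
#' @param formula model formula for the full fit.
#' @param reduced optional nested model formula.
#' @return Object of class `osc_regression`: the `lm` fit, `r_squared`,
#'   `adj_r_squared`, coefficient table, and `anova_p` when `reduced` is
#'   given.
#' @export
fit_regression <- function(data, formula, reduced = NULL) {
  fit <- stats::lm(formula, data = data)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(names(stats::coef(fit))[aliased], collapse = ", ")),
          class = "oscan_input_error")
  }
  sm <- summary(fit)
  anova_p <- NULL
  reduced_fit <- NULL
  if (!is.null(reduced)) {
    reduced_fit <- stats::lm(reduced, data = data)
    av <- stats::anova(reduced_fit, fit)
    anova_p <- av$`Pr(>F)`[2]
  }
  structure(
    list(fit = fit, reduced_fit = reduced_fit,
         coefficients = as_tibble(sm$coefficients, rownames = "term"),
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         residuals = stats::residuals(fit), anova_p = anova_p),
    class = "osc_regression"
  )
}

#' @export
print.osc_regression <- function(x, ...) {
  cat(sprintf("<osc_regression> R^2 = %.4f (adj %.4f)\n",
              x$r_squared, x$adj_r_squared))
  if (!is.null(x$anova_p)) cat(sprintf("  vs nested model: ANOVA p = %.3g\n", x$anova_p))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.osc_regression <- function(x, ...) {
  stats::setNames(x$coefficients,
                  c("term", "estimate", "std_error", "statistic", "p_value"))
}

#' @export
glance.osc_regression <- function(x, ...) {
  tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
         df_residual = x$fit$df.residual,
         anova_p = x$anova_p %||% NA_real_)
}

# R^2 of every regressor subset (bitmask-indexed), via QR least squares
r2_all_subsets <- function(y, X) {
  p <- ncol(X)
  tss <- sum((y - mean(y))^2)
  r2 <- numeric(2^p)
  for (mask in 1:(2^p - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    Z <- cbind(1, X[, cols, drop = FALSE])
    res <- stats::.lm.fit(Z, y)$residuals
    r2[mask + 1L] <- 1 - sum(res^2) / tss
  }
  r2
}

pmvd_shares_once <- function(y, X) {
  p <- ncol(X)
  r2 <- r2_all_subsets(y, X)
  full_mask <- 2^p - 1L
  r2_full <- r2[full_mask + 1L]
  perms <- permutations_of(p)
  eps <- .Machine$double.eps
  w <- numeric(nrow(perms))
  contrib <- matrix(0, nrow(perms), p)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    mask <- 0L
    prodterm <- 1
    prev_r2 <- 0
    for (i in seq_len(p)) {
      mask <- bitwOr(mask, bitwShiftL(1L, ord[i] - 1L))
      cur <- r2[mask + 1L]
      contrib[r, ord[i]] <- cur - prev_r2
      prev_r2 <- cur
      # weight factor: remaining unexplained variance after the first i
      # regressors (Feldman's data-dependent ordering weights)
      if (i < p) prodterm <- prodterm * max(r2_full - cur, eps)
    }
    w[r] <- 1 / prodterm
  }
  w <- w / sum(w)
  shares <- as.numeric(t(contrib) %*% w)
  names(shares) <- colnames(X)
  list(shares = shares, r_squared = r2_full,
       lmg = stats::setNames(colMeans(contrib), colnames(X)))
}

permutations_of <- function(p) {
  if (p == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(p - 1L)
  do.call(rbind, lapply(1:p, function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Proportional marginal variance decomposition (PMVD)
#'
#' Apportions a regression's R-squared across correlated regressors using
#' Feldman's data-dependent ordering weights: each ordering of the
#' regressors contributes its sequence of sequential R-squared increments,
#' weighted inversely to the product of unexplained variance remaining after
#' each step. Computed by exact enumeration of all orderings (at most six
#' regressors). Confidence intervals are percentile bootstrap over case
#' resampling.
#'
#' @param data a data frame.
#' @param formula regression formula (response ~ regressors).
#' @param n_boot bootstrap replicates (default 1000; 0 skips the bootstrap).
#' @param seed integer seed for the bootstrap resampling.
#' @param method `"pmvd"` (default) or `"lmg"` (equal ordering weights).
#' @return Object of class `pmvd_result`: `shares` (non-negative, summing to
#'   the model R-squared), `r_squared`, and `ci` (per-regressor percentile
#'   intervals) when `n_boot > 0`.
#' @export
pmvd_importance <- function(data, formula, n_boot = 1000L, seed = 1L,
                            method = c("pmvd", "lmg")) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  if (p > 6L) abort("exact enumeration supports at most 6 regressors",
                    class = "oscan_config_error")
  if (any(apply(X, 2, stats::sd) == 0)) {
    abort("regressor with zero variance", class = "oscan_input_error")
  }
  base <- pmvd_shares_once(y, X)
  shares <- if (method == "pmvd") base$shares else base$lmg
  ci <- NULL
  if (n_boot > 0L) {
    boots <- withr_seed(derive_seed(seed, 17L), {
      n <- nrow(X)
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        res <- tryCatch(pmvd_shares_once(y[idx], X[idx, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(res)) rep(NA_real_, p)
        else if (method == "pmvd") res$shares else res$lmg
      }, numeric(p))
    })
    boots <- matrix(boots, nrow = p)
    ci <- tibble(
      term = colnames(X),
      share = unname(shares),
      lower = apply(boots, 1, stats::quantile, 0.025, na.rm = TRUE),
      upper = apply(boots, 1, stats::quantile, 0.975, na.rm = TRUE)
    )
  }
  structure(list(shares = shares, r_squared = base$r_squared, ci = ci,
                 method = method, n_boot = n_boot),
            class = "pmvd_result")
}

#' @export
print.pmvd_result <- function(x, ...) {
  cat(sprintf("<pmvd_result> method %s, R^2 = %.4f\n", x$method, x$r_squared))
  print(round(x$shares, 4))
  invisible(x)
}

#' @export
tidy.pmvd_result <- function(x, ...) {
  if (!is.null(x$ci)) return(x$ci)
  tibble(term = names(x$shares), share = unname(x$shares))
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties; constant input yields `NA` with a
#' warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return The correlation coefficient.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant vector; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Stepwise model selection by AIC
#'
#' Greedy add/drop selection starting from the full model, minimising the
#' Gaussian AIC (2k penalty); ties break deterministically by column order.
#'
#' @param data a data frame.
#' @param formula full model formula.
#' @return List: `selected` (character vector of retained regressors, may be
#'   empty), `fit` (an `osc_regression` for the selected model), `aic`.
#' @export
stepwise_aic <- function(data, formula) {
  tf <- stats::terms(formula, data = data)
  if (!length(attr(tf, "term.labels"))) abort("empty regressor set",
                                              class = "oscan_input_error")
  # embed the data in the call so step() can re-evaluate candidate models
  # regardless of the formula's environment
  full <- do.call(stats::lm, list(formula = formula, data = data))
  sel <- stats::step(full, scope = list(lower = ~1, upper = stats::formula(tf)),
                     direction = "both", trace = 0)
  selected <- attr(stats::terms(sel), "term.labels")
  structure(list(selected = selected,
                 fit = fit_regression(data, stats::formula(sel)),
                 aic = stats::AIC(sel)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("<stepwise_result> selected:",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else "(intercept only)",
      sprintf("| AIC %.2f\n", x$aic))
  invisible(x)
}

#' Growth-temperature regression
#'
#' The phenotype analysis: percentage deviation of observed from expected
#' OSC density regressed on optimal growth temperature, correcting for G+C
#' content and AT skew, with a stepwise-AIC check that the temperature term
#' is retained. Categorical OGT labels are mapped to representative
#' midpoints (psychrophile 10, mesophile 37, thermophile 60,
#' hyperthermophile 85 degrees C) when numeric values are absent.
#'
#' @param data a data frame with columns `pct_deviation`, `gc`, `at_skew`
#'   and either `ogt` (numeric, degrees C) or `ogt_category`.
#' @return List: `fit` (an `osc_regression` of
#'   `pct_deviation ~ ogt + gc + at_skew`), `stepwise` (a
#'   `stepwise_result`), `ogt_coefficient`, `ogt_p`.
#' @export
ogt_regression <- function(data) {
  if (!"ogt" %in% names(data)) {
    midpoints <- c(psychrophile = 10, mesophile = 37,
                   thermophile = 60, hyperthermophile = 85)
    if (!"ogt_category" %in% names(data)) {
      abort("need an ogt or ogt_category column", class = "oscan_input_error")
    }
    data$ogt <- midpoints[data$ogt_category]
  }
  fit <- fit_regression(data, pct_deviation ~ ogt + gc + at_skew,
                        reduced = pct_deviation ~ gc + at_skew)
  sw <- stepwise_aic(data, pct_deviation ~ ogt + gc + at_skew)
  co <- tidy(fit)
  list(fit = fit, stepwise = sw,
       ogt_coefficient = co$estimate[co$term == "ogt"],
       ogt_p = co$p_value[co$term == "ogt"])
}
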