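#' Random-forest surrogate for feature importance
#'
#' Trains a random forest on SNP feature vectors labeled positive
#' (prediction score > 0.5) or negative by the network, and returns the
#' Gini importance (mean decrease in node impurity) of every feature.
#' Defaults follow the surrogate's standard setting: 100 trees, 10
#' features sampled per split.
#'
#' @param snp_vectors 0/1 matrix, one row per SNP, named feature columns.
#' @param snp_labels Logical/0-1 vector; both classes must be present.
#' @param n_trees,mtry Forest size and per-split feature sample.
#' @param seed Integer seed; importances are deterministic given the seed.
#' @return Tibble `(feature, gini)` in feature-axis order.
#' @export
fit_rf_surrogate <- function(snp_vectors, snp_labels, n_trees = 100,
                             mtry = 10, seed = 1) {
  y <- factor(as.integer(snp_labels), levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2) {
    rlang::abort("surrogate needs both positive and negative SNPs",
                 class = "epifinemap_domain_error")
  }
  fit <- withr::with_seed(seed, {
    randomForest::randomForest(
      x = as.data.frame(snp_vectors), y = y, ntree = n_trees,
      mtry = min(mtry, ncol(snp_vectors)))
  })
  tibble::tibble(feature = colnames(snp_vectors),
                 gini = unname(fit$importance[, "MeanDecreaseGini"]))
}

#' Permutation p-values for Gini importances
#'
#' Shuffles the SNP labels `n_perm` times, refits the surrogate forest on
#' each shuffle, and reports for every feature the fraction of
#' permutations whose importance reached or exceeded the observed one
#' (ties count against significance):
#' `perm_p = #(permuted gini >= observed gini) / n_perm`.
#'
#' @inheritParams fit_rf_surrogate
#' @param n_perm Number of label permutations (default 1000).
#' @return Tibble `(feature, gini, perm_p)`.
#' @export
permutation_pvalues <- function(snp_vectors, snp_labels, n_perm = 1000,
                                n_trees = 100, mtry = 10, seed = 1) {
  if (!is.numeric(n_perm) || n_perm < 1) {
    rlang::abort("n_perm must be >= 1", class = "epifinemap_domain_error")
  }
  n_perm <- as.integer(n_perm)
  obs <- fit_rf_surrogate(snp_vectors, snp_labels, n_trees, mtry, seed)
  exceed <- rep(0L, nrow(obs))
  withr::with_seed(seed, {
    perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
    for (i in seq_len(n_perm)) {
      yp <- sample(snp_labels)
      gp <- fit_rf_surrogate(snp_vectors, yp, n_trees, mtry,
                             seed = perm_seeds[i])$gini
      exceed <- exceed + (gp >= obs$gini)
    }
  })
  dplyr::mutate(obs, perm_p = exceed / n_perm)
}

#' Feature importance for a scored tensor
#'
#' Convenience pipeline over the true-case blocks: joins per-SNP scores
#' to the tensor's SNP vectors, labels SNPs by `score > 0.5`, drops
#' repressive histone-mark features (H3K9me3/H3K27me3, which are not
#' specific to individual SNPs), fits the surrogate forest and computes
#' permutation p-values.
#'
#' @param tensor The filtered true-case `feature_tensor`.
#' @param scores Tibble from [predict_snp_scores()] on the same tensor.
#' @param n_trees,mtry,n_perm,seed Passed to the surrogate and the
#'   permutation test.
#' @param exclude_repressive Drop features flagged repressive?
#'   (default `TRUE`).
#' @return A `snp_importance` tibble: `(feature, category, assay, gini,
#'   perm_p, significant)` with `significant = perm_p < 0.05`.
#' @export
snp_importance <- function(tensor, scores, n_trees = 100, mtry = 10,
                           n_perm = 1000, seed = 1,
                           exclude_repressive = TRUE) {
  m <- tensor_snp_matrix(tensor)
  key <- paste(m$index$block_id, m$index$slot)
  sc <- scores$score[match(key, paste(scores$block_id, scores$slot))]
  if (anyNA(sc)) {
    rlang::abort("scores do not cover every unmasked SNP of the tensor")
  }
  info <- tensor$feature_info
  keep <- if (exclude_repressive) !info$repressive else rep(TRUE, nrow(info))
  res <- permutation_pvalues(m$x[, keep, drop = FALSE], sc > 0.5,
                             n_perm = n_perm, n_trees = n_trees,
                             mtry = mtry, seed = seed)
  out <- dplyr::left_join(res, info, by = "feature")
  out <- dplyr::mutate(out, significant = .data$perm_p < 0.05)
  out <- out[, c("feature", "category", "assay", "gini", "perm_p",
                 "significant")]
  class(out) <- c("snp_importance", class(out))
  out
}

#' Hypergeometric over-representation tail
#'
#' Upper-tail probability `P(X >= k)` for the number of significant
#' features falling in a category when `n` of `N` features are in the
#' category and `K` of the `N` are significant overall, under the
#' hypergeometric pmf
#' `P(X = k) = choose(K, k) choose(N - K, n - k) / choose(N, n)`.
#' Each pmf term is evaluated exactly in log space and the tail is the
#' sum over the support `k, ..., min(K, n)`.
#'
#' @param N Total number of features.
#' @param K Number of significant features overall.
#' @param n Number of features in the category.
#' @param k Number of significant features in the category.
#' @return The tail probability, in `(0, 1]`.
#' @examples
#' hypergeometric_enrichment(10, 4, 5, 2)
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n) ||
      k < max(0, n - (N - K))) {
    rlang::abort("inconsistent hypergeometric counts",
                 class = "epifinemap_domain_error")
  }
  support <- k:min(K, n)
  sum(exp(lchoose(K, support) + lchoose(N - K, n - support) -
            lchoose(N, n)))
}

#' Category enrichment among significant features
#'
#' For every feature category, tests over-representation of
#' permutation-significant features (`perm_p < 0.05`) with both the
#' hypergeometric tail and its binomial analogue
#' `P(X >= k)` for `X ~ Binomial(n, K / N)`.
#'
#' @param importance A `snp_importance` tibble.
#' @return Tibble `(category, N, K, n, k, p_hyper, p_binom)`.
#' @export
category_enrichment <- function(importance) {
  n_total <- nrow(importance)
  k_total <- sum(importance$significant)
  p0 <- min(max(k_total / n_total, 1 / (2 * n_total)),
            1 - 1 / (2 * n_total))
  per <- dplyr::summarise(dplyr::group_by(importance, .data$category),
                          n = dplyr::n(),
                          k = sum(.data$significant), .groups = "drop")
  out <- dplyr::mutate(
    per,
    N = n_total, K = k_total,
    p_hyper = purrr::map2_dbl(.data$n, .data$k,
                              ~hypergeometric_enrichment(n_total, k_total,
                                                         .x, .y)),
    p_binom = binomial_annotation_test(.data$k, .data$n, p0))
  out[, c("category", "N", "K", "n", "k", "p_hyper", "p_binom")]
}

#' One-sided binomial annotation test
#'
#' Upper-tail probability of seeing at least `k` annotated features in
#' `n` trials at background rate `p0`; used per SNP and per category for
#' the feature-map annotation display. `k = 0` gives 1 by convention.
#'
#' @param k Number of annotated features observed (vectorized).
#' @param n Number of trials.
#' @param p0 Background annotation fraction, in `(0, 1)`; the natural
#'   default is the category's share of all surviving features.
#' @return Upper-tail p-value(s).
#' @examples
#' binomial_annotation_test(10, 10, 0.5)  # 2^-10
#' @export
binomial_annotation_test <- function(k, n, p0) {
  if (any(p0 <= 0) || any(p0 >= 1)) {
    rlang::abort("p0 must be in (0, 1)", class = "epifinemap_domain_error")
  }
  if (any(k < 0) || any(k > n)) {
    rlang::abort("k must satisfy 0 <= k <= n",
                 class = "epifinemap_domain_error")
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Per-SNP per-category annotation enrichment
#'
#' For each unmasked SNP and each feature category, counts annotated
#' features and tests the count against the category's background
#' annotation rate with [binomial_annotation_test()]; the negative log10
#' of these p-values is the SNP feature-map annotation display.
#'
#' @param tensor A `feature_tensor`.
#' @param p0 Optional named background fraction per category; defaults to
#'   each category's overall annotation rate across all unmasked SNPs.
#' @return Tibble `(block_id, snp_id, category, k, n, p_value)`.
#' @export
annotation_enrichment <- function(tensor, p0 = NULL) {
  m <- tensor_snp_matrix(tensor)
  cats <- split(seq_len(nrow(tensor$feature_info)),
                tensor$feature_info$category)
  out <- purrr::imap(cats, function(cols, cat) {
    k <- rowSums(m$x[, cols, drop = FALSE])
    n <- length(cols)
    bg <- if (!is.null(p0)) p0[[cat]] else
      min(max(mean(m$x[, cols]), 1e-12), 1 - 1e-12)
    tibble::tibble(block_id = m$index$block_id, snp_id = m$index$snp_id,
                   category = cat, k = k, n = n,
                   p_value = binomial_annotation_test(k, n, bg))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$block_id, .data$snp_id)
}
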