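#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted SNP-scoring network
#'
#' One row per first-layer filter with its bias, combiner weight and
#' weight-vector norms — a compact view of what each pattern detector
#' contributes.
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `filter`, `combiner_weight`,
#'   `filter_bias`, `l1_norm`, `l2_norm`.
#' @export
tidy.cnn_fit <- function(x, ...) {
  fb <- x$params$filter_bank
  tibble::tibble(
    filter = seq_len(nrow(fb)),
    combiner_weight = x$params$combiner,
    filter_bias = x$params$filter_bias,
    l1_norm = rowSums(abs(fb)),
    l2_norm = sqrt(rowSums(fb^2)))
}

#' One-row summary of a fitted network
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return A tibble with `epochs_run`, `best_epoch`, `best_val_loss`,
#'   `n_filters`, `n_features`, `n_parameters`, `seed`.
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble::tibble(
    epochs_run = max(x$report$epoch),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    n_filters = x$config$n_filters,
    n_features = length(x$feature_names),
    n_parameters = length(x$params$filter_bank) +
      length(x$params$filter_bias) + length(x$params$combiner) + 1L,
    seed = x$config$seed)
}

#' Tidy a block-level evaluation
#' @param x A `cnn_eval`.
#' @param ... Unused.
#' @return The per-block score tibble (`block_id`, `score`, `label`).
#' @export
tidy.cnn_eval <- function(x, ...) x$scores

#' One-row summary of a block-level evaluation
#' @param x A `cnn_eval`.
#' @param ... Unused.
#' @return Tibble with `auc`, `f1`, `threshold` and confusion counts.
#' @export
glance.cnn_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, f1 = x$f1, threshold = x$threshold,
                 tp = x$counts[["tp"]], fp = x$counts[["fp"]],
                 fn = x$counts[["fn"]], tn = x$counts[["tn"]])
}

#' Training-loss trajectory of a fitted network
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return ggplot of train/validation loss per epoch, best epoch marked.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$report, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  d$set <- ifelse(d$set == "train_loss", "training", "validation")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Uncertainty-weighted training loss") +
    ggplot2::theme_minimal()
}

#' ROC curve for a block-level evaluation
#'
#' @param object A `cnn_eval`.
#' @param ... Unused.
#' @return ggplot of the ROC curve with the AUC in the subtitle.
#' @export
autoplot.cnn_eval <- function(object, ...) {
  s <- object$scores[order(-object$scores$score), ]
  d <- tibble::tibble(
    tpr = c(0, cumsum(s$label == 1) / max(sum(s$label == 1), 1)),
    fpr = c(0, cumsum(s$label == 0) / max(sum(s$label == 0), 1)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "Block-level ROC",
                  subtitle = paste0("AUC = ", signif(object$auc, 3),
                                    ", F1 = ", signif(object$f1, 3))) +
    ggplot2::theme_minimal()
}

#' Top-feature importance plot
#'
#' @param object A `snp_importance` tibble.
#' @param n_top Number of features to show (default 20).
#' @param ... Unused.
#' @return ggplot lollipop of Gini importance, colored by category and
#'   shaped by permutation significance.
#' @export
autoplot.snp_importance <- function(object, n_top = 20, ...) {
  d <- object[order(-object$gini), ][seq_len(min(n_top, nrow(object))), ]
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gini, y = .data$feature,
                                  colour = .data$category,
                                  shape = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature),
                          colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Gini importance", y = NULL, colour = "category",
                  shape = "perm. p < 0.05") +
    ggplot2::theme_minimal()
}

#' Per-block score overview for association blocks
#'
#' @param object An `assoc_blocks` tibble.
#' @param scores Optional tibble from [predict_snp_scores()]; when given,
#'   points are colored by whether the SNP score exceeds 0.5.
#' @param ... Unused.
#' @return ggplot of -log10 member p-values along each block.
#' @export
autoplot.assoc_blocks <- function(object, scores = NULL, ...) {
  d <- dplyr::mutate(object, neglogp = -log10(.data$p_value))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos,
                                       y = .data$neglogp))
  if (!is.null(scores)) {
    d2 <- dplyr::left_join(d, scores, by = c("block_id", "snp_id"))
    p <- ggplot2::ggplot(d2, ggplot2::aes(x = .data$pos,
                                          y = .data$neglogp,
                                          colour = .data$score > 0.5))
  }
  p + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~block_id, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p)),
                  colour = "score > 0.5") +
    ggplot2::theme_minimal()
}
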