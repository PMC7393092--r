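#' Model configuration
#'
#' Bundles the architecture and optimization settings for the two-layer
#' SNP-scoring network. The first layer applies `n_filters`
#' one-dimensional filters spanning the whole feature axis to each SNP
#' independently (ReLU activation); the second layer linearly combines the
#' filter responses and a sigmoid maps each SNP to a score in (0, 1);
#' max-pooling over the unmasked SNP slots gives the block score.
#'
#' @param n_filters Number of first-layer filters `K` (default 50).
#' @param lambda1,lambda2 Elastic-net strengths on the L1 and squared-L2
#'   norms of the two layers' weights (biases excluded).
#' @param learning_rate,momentum SGD step size and momentum coefficient.
#' @param batch_size Mini-batch size `B` (default 100).
#' @param max_epochs,patience Epoch cap and early-stopping patience on
#'   validation loss.
#' @param pretrain Initialize the filter bank with denoising-autoencoder
#'   pretraining? (default `TRUE`).
#' @param warmup_epochs Number of initial epochs during which the
#'   pretrained filter bank is held fixed and only the combiner layer is
#'   updated (default 30). Joint fine-tuning follows. With `pretrain =
#'   FALSE` the warm-up is skipped.
#' @param ae_corruption Per-element zeroing rate for the autoencoder's
#'   input corruption, in `[0, 1)`.
#' @param ae_epochs,ae_learning_rate Autoencoder training schedule.
#' @param epsilon Clamp applied to predicted probabilities inside the log
#'   likelihood (`f` is kept in `[epsilon, 1 - epsilon]`).
#' @param seed Integer seed controlling initialization, pretraining
#'   corruption and batch shuffling.
#' @return A `cnn_config` list.
#' @export
model_config <- function(n_filters = 50, lambda1 = 1e-4, lambda2 = 3e-2,
                         learning_rate = 0.01, momentum = 0.9,
                         batch_size = 100, max_epochs = 400, patience = 40,
                         pretrain = TRUE, warmup_epochs = 50,
                         ae_corruption = 0.2,
                         ae_epochs = 100, ae_learning_rate = 0.1,
                         epsilon = 1e-7, seed = 17) {
  stopifnot(n_filters >= 1, batch_size >= 1, lambda1 >= 0, lambda2 >= 0,
            learning_rate > 0, momentum >= 0, momentum < 1,
            ae_corruption >= 0, ae_corruption < 1)
  structure(list(n_filters = as.integer(n_filters), lambda1 = lambda1,
                 lambda2 = lambda2, learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), pretrain = pretrain,
                 warmup_epochs = as.integer(warmup_epochs),
                 ae_corruption = ae_corruption,
                 ae_epochs = as.integer(ae_epochs),
                 ae_learning_rate = ae_learning_rate, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Randomly initialize model parameters
#'
#' Small Gaussian weights (sd 0.01) and zero biases; deterministic given
#' the seed. When pretraining is enabled, [train_cnn()] overwrites the
#' filter bank with the autoencoder's encoder weights.
#'
#' @param feature_dim Feature axis length `M`.
#' @param config A `cnn_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A `cnn_params` list: `filter_bank` (`K x M`), `filter_bias`
#'   (`K`), `combiner` (`K`), `combiner_bias` (scalar).
#' @export
init_params <- function(feature_dim, config = model_config(),
                        seed = config$seed) {
  K <- config$n_filters
  withr::with_seed(seed, {
    p <- list(filter_bank = matrix(stats::rnorm(K * feature_dim, 0, 0.01),
                                   K, feature_dim),
              filter_bias = rep(0, K),
              combiner = stats::rnorm(K, 0, 0.01),
              combiner_bias = 0)
  })
  structure(p, class = "cnn_params")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# per-SNP forward pass on a matrix of SNP feature vectors (rows)
.forward_rows <- function(params, x) {
  a <- x %*% t(params$filter_bank) +
    matrix(params$filter_bias, nrow(x), length(params$filter_bias),
           byrow = TRUE)
  h <- pmax(a, 0)
  z <- drop(h %*% params$combiner) + params$combiner_bias
  list(a = a, h = h, z = z, s = sigmoid(z))
}

#' Score a tensor with the network
#'
#' Computes per-SNP scores
#' `sigmoid(combiner . ReLU(filter_bank x + filter_bias) + combiner_bias)`
#' for every unmasked slot, and block scores as the max-pool over each
#' block's unmasked per-SNP scores. Masked slots are inert: they get `NA`
#' and never enter the pooling.
#'
#' @param params A `cnn_params`.
#' @param tensor A `feature_tensor` whose feature axis has length `M`.
#' @return List: `per_snp` (blocks x slots matrix, `NA` where masked) and
#'   `per_block` (named numeric vector of max-pooled scores).
#' @export
forward_cnn <- function(params, tensor) {
  if (ncol(params$filter_bank) != n_features(tensor)) {
    rlang::abort(paste0("feature-dimension mismatch: params expect ",
                        ncol(params$filter_bank), ", tensor has ",
                        n_features(tensor)),
                 class = "epifinemap_shape_error")
  }
  m <- tensor_snp_matrix(tensor)
  s <- .forward_rows(params, m$x)$s
  per_snp <- matrix(NA_real_, n_blocks(tensor), dim(tensor$values)[2])
  per_snp[cbind(m$index$block_index, m$index$slot)] <- s
  per_block <- apply(per_snp, 1, max, na.rm = TRUE)
  names(per_block) <- tensor$block_ids
  list(per_snp = per_snp, per_block = per_block)
}

#' Uncertainty-weighted loss on a batch of blocks
#'
#' The negative log likelihood is the weighted mean over the batch,
#' `-(1/B) sum_m W_m (Y_m log f_m + (1 - Y_m) log(1 - f_m))`, with `f_m`
#' the max-pooled block score clamped to `[epsilon, 1 - epsilon]`, plus
#' the elastic-net penalty `lambda1 * sum|w| + lambda2 * sum w^2` over the
#' filter bank and combiner weights (biases excluded). Natural logarithms
#' throughout.
#'
#' @param params A `cnn_params`.
#' @param tensor A `feature_tensor` batch.
#' @param config A `cnn_config`.
#' @param labels,weights Block labels in `{0, 1}` and positive weights;
#'   default to those stored in the tensor.
#' @return Scalar loss.
#' @export
compute_loss <- function(params, tensor, config = model_config(),
                         labels = tensor$label, weights = tensor$weight) {
  if (n_blocks(tensor) == 0) rlang::abort("empty batch")
  f <- forward_cnn(params, tensor)$per_block
  f <- pmin(pmax(f, config$epsilon), 1 - config$epsilon)
  nll <- -mean(weights * (labels * log(f) + (1 - labels) * log(1 - f)))
  penalty <- config$lambda1 * (sum(abs(params$filter_bank)) +
                                 sum(abs(params$combiner))) +
    config$lambda2 * (sum(params$filter_bank^2) + sum(params$combiner^2))
  nll + penalty
}

#' Analytic gradient of [compute_loss()]
#'
#' Backpropagation through the max-pool (gradient flows only through each
#' block's argmax slot), the sigmoid/linear combiner, and the ReLU filter
#' layer, plus the elastic-net subgradient.
#'
#' @inheritParams compute_loss
#' @return A `cnn_params`-shaped list of gradients.
#' @export
loss_gradient <- function(params, tensor, config = model_config(),
                          labels = tensor$label, weights = tensor$weight) {
  m <- tensor_snp_matrix(tensor)
  fw <- .forward_rows(params, m$x)
  B <- n_blocks(tensor)
  # argmax slot (row of m$x) per block; first index wins on exact ties
  star <- vapply(seq_len(B), function(b) {
    rows <- which(m$index$block_index == b)
    rows[which.max(fw$s[rows])]
  }, integer(1))
  f <- fw$s[star]
  fc <- pmin(pmax(f, config$epsilon), 1 - config$epsilon)
  dz <- -(weights / B) * (labels / fc - (1 - labels) / (1 - fc)) *
    f * (1 - f)
  Hs <- fw$h[star, , drop = FALSE]
  Xs <- m$x[star, , drop = FALSE]
  dA <- (fw$a[star, , drop = FALSE] > 0) *
    outer(dz, params$combiner)
  g <- list(
    filter_bank = t(dA) %*% Xs +
      config$lambda1 * sign(params$filter_bank) +
      2 * config$lambda2 * params$filter_bank,
    filter_bias = colSums(dA),
    combiner = drop(t(Hs) %*% dz) +
      config$lambda1 * sign(params$combiner) +
      2 * config$lambda2 * params$combiner,
    combiner_bias = sum(dz))
  structure(g, class = "cnn_params")
}

#' Denoising-autoencoder pretraining of the filter bank
#'
#' A tied-weight autoencoder on binary SNP feature vectors: the encoder
#' is `h = sigmoid(W x~ + b_h)` on a corrupted input `x~` (each element
#' independently zeroed with probability `ae_corruption`), the decoder
#' `x^ = sigmoid(W' h + b_v)`, and the reconstruction loss is elementwise
#' cross-entropy against the uncorrupted input. Trained by mini-batch SGD
#' with momentum; the learned encoder provides the filter-bank starting
#' point.
#'
#' @param snp_vectors Matrix of unmasked SNP feature vectors (rows), e.g.
#'   `tensor_snp_matrix(tensor)$x`.
#' @param config A `cnn_config` (uses `n_filters`, `ae_*`, `momentum`,
#'   `batch_size`).
#' @param seed Seed (defaults to `config$seed`).
#' @return List: `filter_bank` (`K x M`), `filter_bias` (`K`), and `loss`,
#'   the per-epoch mean reconstruction loss trajectory.
#' @export
pretrain_autoencoder <- function(snp_vectors, config = model_config(),
                                 seed = config$seed) {
  if (is.null(dim(snp_vectors)) || nrow(snp_vectors) == 0) {
    rlang::abort("pretraining requires at least one SNP vector")
  }
  K <- config$n_filters
  M <- ncol(snp_vectors)
  n <- nrow(snp_vectors)
  eps <- config$epsilon
  recon_loss <- function(W, bh, bv, X) {
    H <- sigmoid(X %*% t(W) + matrix(bh, nrow(X), K, byrow = TRUE))
    Xh <- sigmoid(H %*% W + matrix(bv, nrow(X), M, byrow = TRUE))
    Xh <- pmin(pmax(Xh, eps), 1 - eps)
    -mean(rowSums(X * log(Xh) + (1 - X) * log(1 - Xh)))
  }
  withr::with_seed(seed, {
    W <- matrix(stats::runif(K * M, -0.05, 0.05), K, M)
    bh <- rep(0, K)
    bv <- rep(0, M)
    vW <- 0 * W; vbh <- 0 * bh; vbv <- 0 * bv
    traj <- numeric(config$ae_epochs)
    for (epoch in seq_len(config$ae_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (st in starts) {
        rows <- ord[st:min(st + config$batch_size - 1, n)]
        X <- snp_vectors[rows, , drop = FALSE]
        nb <- nrow(X)
        corrupt <- if (config$ae_corruption > 0) {
          X * (matrix(stats::runif(nb * M), nb, M) >= config$ae_corruption)
        } else X
        H <- sigmoid(corrupt %*% t(W) + matrix(bh, nb, K, byrow = TRUE))
        Xh <- sigmoid(H %*% W + matrix(bv, nb, M, byrow = TRUE))
        dXp <- (Xh - X) / nb              # d loss / d decoder pre-activation
        gW_dec <- t(H) %*% dXp
        dH <- (dXp %*% t(W)) * H * (1 - H)
        gW <- gW_dec + t(dH) %*% corrupt  # tied weights: both paths
        gbh <- colSums(dH)
        gbv <- colSums(dXp)
        vW <- config$momentum * vW - config$ae_learning_rate * gW
        vbh <- config$momentum * vbh - config$ae_learning_rate * gbh
        vbv <- config$momentum * vbv - config$ae_learning_rate * gbv
        W <- W + vW; bh <- bh + vbh; bv <- bv + vbv
      }
      traj[epoch] <- recon_loss(W, bh, bv, snp_vectors)
    }
  })
  list(filter_bank = W, filter_bias = bh, loss = traj)
}

#' Train the uncertainty-weighted SNP-scoring network
#'
#' Combines the true-case and control tensors, splits blocks by
#' chromosome into training/validation/test roles, optionally pretrains
#' the filter bank with the denoising autoencoder on the training-split
#' true-case SNP vectors, then runs mini-batch gradient descent with
#' momentum on [compute_loss()]. Batches are reshuffled every epoch
#' (seeded); training stops when the validation NLL has not improved for
#' `patience` epochs, and the parameters from the best validation epoch
#' are returned.
#'
#' @param true_tensor Filtered true-case `feature_tensor` (label 1, tiered
#'   weights).
#' @param control_tensor Control `feature_tensor` from
#'   [generate_control_blocks()] (label 0, weight 2).
#' @param config A `cnn_config`.
#' @param split Role assignment from [chromosome_split()].
#' @return A `cnn_fit` object with elements `params`, `config`, `report`
#'   (per-epoch train/validation loss tibble), `best_epoch`,
#'   `best_val_loss`, `feature_names`, `split` and the held-out `test`
#'   tensor indices retained for convenience.
#' @export
train_cnn <- function(true_tensor, control_tensor,
                      config = model_config(),
                      split = chromosome_split()) {
  tensor <- bind_tensors(true_tensor, control_tensor)
  role <- rep(NA_character_, n_blocks(tensor))
  for (r in names(split)) role[tensor$chrom %in% split[[r]]] <- r
  if (anyNA(role)) {
    rlang::warn(paste0(sum(is.na(role)),
                       " block(s) on unassigned chromosomes dropped"))
  }
  tr <- subset_tensor(tensor, which(role == "train"))
  va <- subset_tensor(tensor, which(role == "validation"))
  if (n_blocks(tr) == 0) rlang::abort("empty training split")

  params <- init_params(n_features(tr), config)
  ae <- NULL
  if (config$pretrain) {
    true_train <- subset_tensor(tr, tr$label == 1)
    ae <- pretrain_autoencoder(tensor_snp_matrix(true_train)$x, config)
    params$filter_bank <- ae$filter_bank
    params$filter_bias <- ae$filter_bias
  }

  val_nll <- function(p) {
    if (n_blocks(va) == 0) return(NA_real_)
    cfg0 <- config
    cfg0$lambda1 <- 0; cfg0$lambda2 <- 0
    compute_loss(p, va, cfg0)
  }
  velocity <- lapply(params, function(x) x * 0)
  best <- params
  best_val <- Inf
  best_epoch <- 0L
  since_best <- 0L
  n_tr <- n_blocks(tr)
  report <- vector("list", config$max_epochs)
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      epoch_loss <- 0
      frozen <- config$pretrain && epoch <= config$warmup_epochs
      starts <- seq(1, n_tr, by = config$batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + config$batch_size - 1, n_tr)]
        batch <- subset_tensor(tr, idx)
        g <- loss_gradient(params, batch, config)
        if (!all(vapply(g, function(x) all(is.finite(x)), logical(1)))) {
          rlang::abort("training diverged: non-finite gradient",
                       class = "epifinemap_divergence_error")
        }
        if (frozen) {
          g$filter_bank[] <- 0
          g$filter_bias[] <- 0
        }
        for (nm in names(params)) {
          velocity[[nm]] <- config$momentum * velocity[[nm]] -
            config$learning_rate * g[[nm]]
          params[[nm]] <- params[[nm]] + velocity[[nm]]
        }
        epoch_loss <- epoch_loss +
          compute_loss(params, batch, config) * length(idx)
      }
      train_loss <- epoch_loss / n_tr
      if (!is.finite(train_loss)) {
        rlang::abort("training diverged: non-finite loss",
                     class = "epifinemap_divergence_error")
      }
      vl <- val_nll(params)
      report[[epoch]] <- tibble::tibble(epoch = epoch,
                                        train_loss = train_loss,
                                        val_loss = vl)
      track <- if (is.na(vl)) train_loss else vl
      if (track < best_val - 1e-12) {
        best_val <- track
        best <- params
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })
  structure(list(params = best, config = config,
                 report = dplyr::bind_rows(report),
                 best_epoch = best_epoch, best_val_loss = best_val,
                 pretrain_loss = ae$loss,
                 feature_names = tensor$feature_info$feature,
                 split = split),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat("<cnn_fit> ", x$config$n_filters, " filters x ",
      length(x$feature_names), " features; stopped at epoch ",
      max(x$report$epoch), " (best validation loss ",
      signif(x$best_val_loss, 4), " at epoch ", x$best_epoch, ")\n",
      sep = "")
  invisible(x)
}

.fit_params <- function(object) {
  if (inherits(object, "cnn_fit")) object$params else object
}

#' Block-level evaluation: AUC and F1
#'
#' AUC is the rank-based probability that a uniformly chosen true block
#' outscores a uniformly chosen control block, with ties counting one
#' half. F1 uses the fixed block-score threshold 0.5 with true cases as
#' the positive class.
#'
#' @param object A `cnn_fit` or `cnn_params`.
#' @param tensor A labeled `feature_tensor` containing at least one true
#'   and one control block.
#' @return A `cnn_eval` object: tibble of block scores plus `auc`, `f1`,
#'   `threshold` and the confusion counts.
#' @export
evaluate_model <- function(object, tensor) {
  params <- .fit_params(object)
  y <- tensor$label
  if (length(unique(y)) < 2) {
    rlang::abort("evaluation requires both true and control blocks",
                 class = "epifinemap_domain_error")
  }
  f <- forward_cnn(params, tensor)$per_block
  r <- rank(f)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- f > 0.5
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(list(
    scores = tibble::tibble(block_id = tensor$block_ids, score = unname(f),
                            label = y),
    auc = auc, f1 = f1, threshold = 0.5,
    counts = c(tp = tp, fp = fp, fn = fn,
               tn = sum(!pred & y == 0))),
    class = "cnn_eval")
}

#' @export
print.cnn_eval <- function(x, ...) {
  cat("<cnn_eval> AUC = ", signif(x$auc, 4), ", F1 = ", signif(x$f1, 4),
      " at block-score threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Per-SNP prediction scores
#'
#' One row per unmasked SNP slot; scores identical to the per-SNP outputs
#' of [forward_cnn()]. The tensor's feature axis must match the axis the
#' model was trained on.
#'
#' @param object A `cnn_fit` (checked against its stored feature names)
#'   or bare `cnn_params`.
#' @param tensor A `feature_tensor`.
#' @return Tibble `(block_id, snp_id, slot, score)`.
#' @export
predict_snp_scores <- function(object, tensor) {
  if (inherits(object, "cnn_fit")) {
    have <- tensor$feature_info$feature
    want <- object$feature_names
    if (!identical(have, want)) {
      missing <- setdiff(want, have)
      extra <- setdiff(have, want)
      rlang::abort(paste0(
        "feature axis mismatch;",
        if (length(missing)) paste0(" missing: ",
                                    paste(missing, collapse = ", ")),
        if (length(extra)) paste0(" extra: ",
                                  paste(extra, collapse = ", "))),
        class = "epifinemap_shape_error")
    }
  }
  params <- .fit_params(object)
  m <- tensor_snp_matrix(tensor)
  if (nrow(m$x) == 0) {
    return(tibble::tibble(block_id = character(), snp_id = character(),
                          slot = integer(), score = double()))
  }
  s <- .forward_rows(params, m$x)$s
  tibble::tibble(block_id = m$index$block_id, snp_id = m$index$snp_id,
                 slot = m$index$slot, score = s)
}

#' Random hyperparameter search on the validation split
#'
#' Samples `n_configs` settings of the optimization hyperparameters
#' (learning rate, elastic-net strengths, warm-up length, autoencoder
#' epochs), trains each with [train_cnn()], and returns the fit with the
#' lowest validation loss at its best epoch — the chromosome-held-out
#' selection protocol.
#'
#' @param true_tensor,control_tensor,split As in [train_cnn()].
#' @param n_configs Number of random configurations (default 10).
#' @param base A `cnn_config` providing every non-searched setting.
#' @param seed Seed for drawing configurations.
#' @return List: `fit`, the winning `cnn_fit`; `trials`, a tibble of the
#'   sampled settings with their best validation losses.
#' @export
tune_cnn <- function(true_tensor, control_tensor, n_configs = 10,
                     base = model_config(), split = chromosome_split(),
                     seed = base$seed) {
  draws <- withr::with_seed(seed, tibble::tibble(
    learning_rate = 10^stats::runif(n_configs, -2.5, -1.5),
    lambda1 = 10^stats::runif(n_configs, -5, -3),
    lambda2 = 10^stats::runif(n_configs, -3, -1),
    warmup_epochs = sample(c(30L, 50L, 80L), n_configs, replace = TRUE),
    ae_epochs = sample(c(50L, 100L, 200L), n_configs, replace = TRUE)))
  fits <- vector("list", n_configs)
  for (i in seq_len(n_configs)) {
    cfg <- base
    for (nm in names(draws)) cfg[[nm]] <- draws[[nm]][i]
    fits[[i]] <- train_cnn(true_tensor, control_tensor, cfg, split)
  }
  val <- vapply(fits, `[[`, numeric(1), "best_val_loss")
  trials <- dplyr::mutate(draws, best_val_loss = val,
                          selected = seq_len(n_configs) == which.min(val))
  list(fit = fits[[which.min(val)]], trials = trials)
}
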