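test_that("parameter initialization is seeded and shaped by the config", {
  cfg <- model_config(n_filters = 7)
  p1 <- init_params(13, cfg, seed = 5)
  p2 <- init_params(13, cfg, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1$filter_bank,
                         init_params(13, cfg, seed = 6)$filter_bank))
  expect_equal(dim(p1$filter_bank), c(7, 13))
  expect_length(p1$filter_bias, 7)
  expect_length(p1$combiner, 7)
  expect_equal(p1$filter_bias, rep(0, 7))
})

test_that("forward pass composes filter bank, ReLU, combiner and sigmoid,
           with inert masked slots", {
  params <- make_params(rbind(c(1, 0, 0), c(0, 1, 0)), c(0, 0),
                        c(1, 1), 0)
  tensor <- make_tensor(list(matrix(c(1, 1, 0), 1, 3, byrow = TRUE)))
  out <- forward_cnn(params, tensor)
  expect_equal(out$per_block[[1]], 1 / (1 + exp(-2)), tolerance = 1e-12)

  # zero combiner: every score is sigmoid(0) = 0.5
  p0 <- make_params(rbind(c(1, 0, 0), c(0, 1, 0)), c(0, 0), c(0, 0), 0)
  expect_equal(unname(forward_cnn(p0, tensor)$per_block), 0.5)

  # adding a masked all-zero slot never changes the block score
  padded <- make_tensor(list(matrix(c(1, 1, 0), 1, 3, byrow = TRUE)),
                        n_slots = 5)
  expect_equal(unname(forward_cnn(params, padded)$per_block),
               unname(out$per_block))

  # dimension mismatch is a shape error
  expect_error(forward_cnn(params, make_tensor(list(matrix(1, 1, 2)))),
               class = "epifinemap_shape_error")
})

test_that("weighted loss reproduces hand-computed values and isolates the
           elastic-net penalty", {
  # single true case, W = 10, f = 0.5, no penalty: 10 * ln 2
  p0 <- make_params(matrix(0, 2, 3), c(0, 0), c(0, 0), 0)
  tensor <- make_tensor(list(matrix(c(1, 1, 0), 1, 3, byrow = TRUE)),
                        weight = 10, min_p = 1e-9)
  cfg0 <- model_config(lambda1 = 0, lambda2 = 0)
  expect_equal(compute_loss(p0, tensor, cfg0), 10 * log(2),
               tolerance = 1e-9)

  # f -> 1 drives a true case's loss to 0
  p1 <- make_params(matrix(0, 2, 3), c(0, 0), c(0, 0), 50)
  # bounded below by the epsilon clamp on f
  expect_lt(compute_loss(p1, tensor, cfg0), 1e-5)

  # duplicating a true block with a larger weight increases the NLL
  t4 <- make_tensor(list(matrix(c(1, 1, 0), 1, 3, byrow = TRUE)),
                    weight = 4, min_p = 1e-5)
  expect_gt(compute_loss(p0, tensor, cfg0), compute_loss(p0, t4, cfg0))

  # zero-NLL construction with lambda1 = 1: loss = sum of |weights|
  pw <- make_params(matrix(c(1, -2, 0.5, 0, 0, 0), 2, 3), c(0, 0),
                    c(0.25, -0.25), 60)
  cfg1 <- model_config(lambda1 = 1, lambda2 = 0)
  expect_equal(compute_loss(pw, tensor, cfg1),
               sum(abs(pw$filter_bank)) + sum(abs(pw$combiner)),
               tolerance = 1e-6)

  # extreme scores are clamped, never NaN
  expect_true(is.finite(compute_loss(p1, make_tensor(
    list(matrix(c(1, 1, 0), 1, 3, byrow = TRUE)), label = 0L), cfg0)))
})

test_that("analytic gradients match central finite differences on random
           small instances", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      K <- sample(1:5, 1)
      M <- sample(2:20, 1)
      nb <- sample(2:4, 1)
      mats <- lapply(seq_len(nb), function(b) {
        matrix(rbinom(3 * M, 1, 0.4), 3, M)
      })
      tensor <- make_tensor(mats, label = rbinom(nb, 1, 0.5),
                            weight = sample(c(2, 4, 6, 8, 10), nb,
                                            replace = TRUE))
      params <- make_params(matrix(rnorm(K * M, 0, 0.5), K, M),
                            rnorm(K, 0, 0.1), rnorm(K, 0, 0.5),
                            rnorm(1, 0, 0.1))
      cfg <- model_config(n_filters = K, lambda1 = runif(1, 0, 1e-3),
                          lambda2 = runif(1, 0, 1e-2))
      ga <- flatten_params(loss_gradient(params, tensor, cfg))
      gn <- numeric_gradient(params, tensor, cfg)
      expect_lt(max(abs(ga - gn)), 1e-5 * (1 + max(abs(gn))))
    }
  })
})

test_that("denoising autoencoder pretraining is deterministic, shaped
           K x M, and reduces reconstruction loss", {
  withr::with_seed(4, {
    basis <- matrix(rbinom(4 * 12, 1, 0.5), 4, 12)
    x <- basis[sample(1:4, 20, replace = TRUE), ]
  })
  cfg <- model_config(n_filters = 10, ae_corruption = 0,
                      ae_epochs = 400, ae_learning_rate = 0.5,
                      batch_size = 20)
  ae <- pretrain_autoencoder(x, cfg, seed = 2)
  expect_equal(dim(ae$filter_bank), c(10, 12))
  # uncorrupted, low-rank binary data: loss collapses by over 10x
  expect_lt(ae$loss[length(ae$loss)], ae$loss[1] / 10)
  ae2 <- pretrain_autoencoder(x, cfg, seed = 2)
  expect_identical(ae$filter_bank, ae2$filter_bank)
  expect_error(pretrain_autoencoder(x[0, , drop = FALSE], cfg))
})

test_that("training is reproducible, reduces loss on separable data, and
           respects the chromosome split", {
  # separable toy problem: feature 1 marks the causal SNP of true blocks
  withr::with_seed(6, {
    mats <- lapply(1:10, function(b) {
      m <- matrix(rbinom(4 * 6, 1, 0.15), 4, 6)
      m[2, 1:3] <- 1
      m
    })
  })
  true_t <- make_tensor(mats, label = rep(1L, 10),
                        weight = rep(10, 10), min_p = rep(1e-9, 10),
                        chrom = as.character(c(1:8, 11, 15)))
  ctrl_t <- generate_control_blocks(true_t, ratio = 5, seed = 2)
  cfg <- model_config(n_filters = 4, max_epochs = 60, patience = 60,
                      warmup_epochs = 10, ae_epochs = 30, batch_size = 20,
                      seed = 9)
  fit1 <- train_cnn(true_t, ctrl_t, cfg)
  fit2 <- train_cnn(true_t, ctrl_t, cfg)
  expect_identical(fit1$report, fit2$report)
  expect_identical(fit1$params, fit2$params)
  expect_lt(dplyr::last(fit1$report$train_loss),
            fit1$report$train_loss[1])
  expect_lte(fit1$best_epoch, cfg$max_epochs)
})

test_that("evaluation computes rank AUC with tie handling and F1 at the
           0.5 threshold", {
  # perfect separation via a single indicator feature
  params <- make_params(matrix(4, 1, 1), 0, matrix(2, 1, 1), -4)
  true_m <- list(matrix(1, 1, 1), matrix(1, 1, 1))
  ctrl_m <- list(matrix(0, 1, 1), matrix(0, 1, 1))
  tensor <- make_tensor(c(true_m, ctrl_m), label = c(1L, 1L, 0L, 0L))
  ev <- evaluate_model(params, tensor)
  expect_equal(ev$auc, 1)
  expect_equal(ev$f1, 1)
  expect_equal(ev$threshold, 0.5)

  # identical scores: AUC falls back to 0.5 by the tie convention
  p0 <- make_params(matrix(0, 1, 1), 0, matrix(0, 1, 1), 0)
  expect_equal(evaluate_model(p0, tensor)$auc, 0.5)

  # cross-check the rank AUC against an independent ROC integrator
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    mats <- lapply(1:30, function(b) matrix(rbinom(8, 1, 0.5), 2, 4))
    lab <- c(rep(1L, 10), rep(0L, 20))
  })
  rt <- make_tensor(mats, label = lab)
  pr <- make_params(matrix(rnorm(8), 2, 4), rnorm(2), rnorm(2), 0.1)
  ev2 <- evaluate_model(pr, rt)
  f <- forward_cnn(pr, rt)$per_block
  proc_auc <- as.numeric(pROC::auc(pROC::roc(lab, f, quiet = TRUE,
                                             direction = "<")))
  expect_equal(ev2$auc, proc_auc, tolerance = 1e-12)

  # single-class input is an error
  expect_error(evaluate_model(params, make_tensor(true_m)),
               class = "epifinemap_domain_error")
})

test_that("per-SNP score tables are consistent with the forward pass and
           invariant to block order", {
  rt <- random_tensor(6, 5, 7, prob = 0.4, seed = 21)
  pr <- make_params(matrix(rnorm(21), 3, 7), rnorm(3), rnorm(3), 0)
  sc <- predict_snp_scores(pr, rt)
  fw <- forward_cnn(pr, rt)
  # block score is the max of its rows
  agg <- tapply(sc$score, sc$block_id, max)
  expect_equal(as.numeric(agg[rt$block_ids]), unname(fw$per_block))

  # permuting blocks leaves per-SNP scores untouched
  perm <- c(4, 1, 6, 2, 5, 3)
  sc_p <- predict_snp_scores(pr, subset_tensor(rt, perm))
  j <- dplyr::inner_join(sc, sc_p, by = c("block_id", "snp_id"))
  expect_equal(j$score.x, j$score.y)

  # empty tensor -> empty table
  expect_equal(nrow(predict_snp_scores(pr, subset_tensor(rt, integer(0)))),
               0)

  # feature-axis mismatch against a stored fit names the offenders
  fit <- list(params = pr, feature_names = paste0("g", 1:7))
  class(fit) <- "cnn_fit"
  expect_error(predict_snp_scores(fit, rt), "missing",
               class = "epifinemap_shape_error")
})
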