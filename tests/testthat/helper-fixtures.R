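# shared builders for small in-code fixtures

make_sumstats <- function(chrom, pos, p, snp_id = NULL) {
  tibble::tibble(
    snp_id = snp_id %||% sprintf("rs%03d", seq_along(pos)),
    chrom = as.character(chrom), pos = as.numeric(pos), p_value = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force greedy clumping oracle (kept deliberately dumb:
# rescans the full table after every pick)
oracle_leads <- function(ss, p_max = 5e-4, spacing = 1e6) {
  pool <- ss[ss$p_value <= p_max, , drop = FALSE]
  picked <- ss[0, ]
  while (nrow(pool) > 0) {
    o <- order(pool$p_value, pool$chrom, pool$pos)
    ld <- pool[o[1], ]
    picked <- rbind(picked, ld)
    keep <- !(pool$chrom == ld$chrom & abs(pool$pos - ld$pos) <= spacing)
    pool <- pool[keep, , drop = FALSE]
  }
  picked
}

# write BED tracks + manifest for a named list of interval tibbles
# (chrom, start, end); returns the loaded annotation_tracks
write_toy_tracks <- function(tracks, dir = tempfile(),
                             category = "neural", assay = "DHS") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tracks)) {
    readr::write_tsv(tracks[[nm]], file.path(dir, paste0(nm, ".bed")),
                     col_names = FALSE)
  }
  man <- tibble::tibble(
    name = names(tracks),
    category = rep_len(category, length(tracks)),
    assay = rep_len(assay, length(tracks)),
    format = "bed",
    path = paste0(names(tracks), ".bed"))
  mf <- file.path(dir, "manifest.tsv")
  readr::write_tsv(man, mf)
  read_track_manifest(mf)
}

# hand-built feature tensor from a list of per-block 0/1 matrices
# (rows = SNPs, cols = features)
make_tensor <- function(block_mats, n_slots = NULL, label = NULL,
                        weight = NULL, min_p = NULL, chrom = NULL,
                        categories = "neural", assays = "DHS",
                        repressive = FALSE) {
  nb <- length(block_mats)
  nf <- ncol(block_mats[[1]])
  n_slots <- n_slots %||% max(vapply(block_mats, nrow, integer(1)))
  values <- array(0, dim = c(nb, n_slots, nf))
  mask <- matrix(FALSE, nb, n_slots)
  snp_ids <- matrix(NA_character_, nb, n_slots)
  for (b in seq_len(nb)) {
    k <- nrow(block_mats[[b]])
    values[b, seq_len(k), ] <- block_mats[[b]]
    mask[b, seq_len(k)] <- TRUE
    snp_ids[b, seq_len(k)] <- sprintf("b%02d_s%02d", b, seq_len(k))
  }
  feats <- colnames(block_mats[[1]]) %||% sprintf("f%02d", seq_len(nf))
  epifinemap:::new_feature_tensor(
    values, mask, sprintf("blk%03d", seq_len(nb)), snp_ids,
    tibble::tibble(feature = feats,
                   category = rep_len(categories, nf),
                   assay = rep_len(assays, nf),
                   repressive = rep_len(repressive, nf)),
    label = label %||% rep(1L, nb),
    weight = weight %||% rep(2, nb),
    min_p = min_p %||% rep(1e-5, nb),
    chrom = chrom %||% rep("1", nb))
}

random_tensor <- function(nb, ns, nf, prob = 0.3, seed = 1, ...) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(nb), function(b) {
      matrix(rbinom(ns * nf, 1, prob), ns, nf)
    })
  })
  make_tensor(mats, n_slots = ns, ...)
}

# parameters with known, hand-checkable structure
make_params <- function(filter_bank, filter_bias, combiner, combiner_bias) {
  structure(list(filter_bank = filter_bank, filter_bias = filter_bias,
                 combiner = combiner, combiner_bias = combiner_bias),
            class = "cnn_params")
}

flatten_params <- function(p) {
  c(as.vector(p$filter_bank), p$filter_bias, p$combiner, p$combiner_bias)
}

unflatten_params <- function(v, K, M) {
  make_params(matrix(v[seq_len(K * M)], K, M),
              v[K * M + seq_len(K)],
              v[K * M + K + seq_len(K)],
              v[K * M + 2 * K + 1])
}

numeric_gradient <- function(params, tensor, cfg, h = 1e-6) {
  K <- nrow(params$filter_bank)
  M <- ncol(params$filter_bank)
  v <- flatten_params(params)
  vapply(seq_along(v), function(i) {
    up <- v; up[i] <- up[i] + h
    dn <- v; dn[i] <- dn[i] - h
    (compute_loss(unflatten_params(up, K, M), tensor, cfg) -
       compute_loss(unflatten_params(dn, K, M), tensor, cfg)) / (2 * h)
  }, numeric(1))
}
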