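#' Construct a feature tensor object
#'
#' Internal constructor; see [build_feature_tensor()].
#'
#' @param values Numeric 0/1 array, `blocks x slots x features`.
#' @param mask Logical matrix, `blocks x slots`: which slots hold a SNP.
#' @param block_ids Character vector of block ids.
#' @param snp_ids Character matrix, `blocks x slots` (`NA` where masked).
#' @param feature_info Tibble `(feature, category, assay, repressive)`.
#' @param label Integer vector: 1 for true cases, 0 for controls.
#' @param weight Numeric vector of block uncertainty weights.
#' @param min_p Numeric vector of block minimum p-values (`NA` for
#'   controls).
#' @param chrom Character vector of block chromosomes.
#' @return A `feature_tensor` object.
#' @keywords internal
new_feature_tensor <- function(values, mask, block_ids, snp_ids,
                               feature_info, label, weight, min_p, chrom) {
  stopifnot(length(dim(values)) == 3,
            all(values %in% c(0, 1)),
            nrow(mask) == dim(values)[1],
            ncol(mask) == dim(values)[2],
            nrow(feature_info) == dim(values)[3],
            length(block_ids) == dim(values)[1])
  # enforce: masked slots carry no annotation (mask recycles across the
  # feature axis in column-major order)
  if (any(values[rep(!mask, times = dim(values)[3])] != 0)) {
    rlang::abort("masked slots must be zero-filled")
  }
  dimnames(values) <- list(block_ids, NULL, feature_info$feature)
  structure(list(values = values, mask = mask, block_ids = block_ids,
                 snp_ids = snp_ids, feature_info = feature_info,
                 label = as.integer(label), weight = as.numeric(weight),
                 min_p = as.numeric(min_p), chrom = as.character(chrom)),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("<feature_tensor> ", n_blocks(x), " blocks x ", dim(x$values)[2],
      " SNP slots x ", n_features(x), " features (",
      sum(x$label == 1), " true, ", sum(x$label == 0), " control)\n",
      sep = "")
  invisible(x)
}

n_blocks <- function(tensor) dim(tensor$values)[1]
n_features <- function(tensor) dim(tensor$values)[3]

#' Build the block x SNP x feature tensor
#'
#' Annotates every member SNP of every association block with
#' [annotate_snps()] and packs the binary vectors into a padded tensor.
#' SNPs are ordered within each block by position ascending; empty slots
#' are masked and zero-filled.
#'
#' @param blocks Tibble from [build_blocks()].
#' @param tracks An `annotation_tracks` object.
#' @param gene_map Optional SNP-to-gene map for pathway tracks.
#' @param n_slots Number of SNP slots per block (default 30). A block with
#'   more members than `n_slots` is a consistency error.
#' @return A `feature_tensor`.
#' @export
build_feature_tensor <- function(blocks, tracks, gene_map = NULL,
                                 n_slots = 30) {
  blocks <- dplyr::arrange(blocks, .data$block_id, .data$pos)
  sizes <- table(blocks$block_id)
  if (any(sizes > n_slots)) {
    rlang::abort(paste0("block(s) exceed n_slots = ", n_slots, ": ",
                        paste(names(sizes)[sizes > n_slots], collapse = ", ")),
                 class = "epifinemap_consistency_error")
  }
  ids <- unique(blocks$block_id)
  nb <- length(ids)
  ann <- annotate_snps(blocks, tracks, gene_map)
  nf <- ncol(ann)
  values <- array(0, dim = c(nb, n_slots, nf))
  mask <- matrix(FALSE, nb, n_slots)
  snp_ids <- matrix(NA_character_, nb, n_slots)
  slot <- stats::ave(seq_len(nrow(blocks)), blocks$block_id,
                     FUN = seq_along)
  bi <- match(blocks$block_id, ids)
  for (r in seq_len(nrow(blocks))) {
    values[bi[r], slot[r], ] <- ann[r, ]
    mask[bi[r], slot[r]] <- TRUE
    snp_ids[bi[r], slot[r]] <- blocks$snp_id[r]
  }
  block_level <- dplyr::distinct(
    blocks, .data$block_id, .data$chrom, .data$min_p, .data$weight)
  block_level <- block_level[match(ids, block_level$block_id), ]
  new_feature_tensor(values, mask, ids, snp_ids, tracks$info,
                     label = rep(1L, nb), weight = block_level$weight,
                     min_p = block_level$min_p, chrom = block_level$chrom)
}

#' Drop features absent from almost all blocks
#'
#' A feature is dropped when the fraction of blocks in which **no** member
#' SNP carries it is strictly greater than `absent_fraction_threshold`
#' (default 0.95, i.e. features unseen in more than 95% of blocks go).
#' Surviving features keep their original order. Apply this to the
#' true-case tensor; control blocks inherit the surviving feature axis by
#' construction.
#'
#' @param tensor A `feature_tensor` of true-case blocks.
#' @param absent_fraction_threshold Fraction in `(0, 1]`.
#' @return List with elements `tensor` (filtered) and `report`, a tibble
#'   `(feature, absent_fraction, kept)`.
#' @export
filter_features <- function(tensor, absent_fraction_threshold = 0.95) {
  if (!is.numeric(absent_fraction_threshold) ||
      absent_fraction_threshold <= 0 || absent_fraction_threshold > 1) {
    rlang::abort("absent_fraction_threshold must be in (0, 1]",
                 class = "epifinemap_domain_error")
  }
  present <- apply(tensor$values, c(1, 3), function(v) any(v > 0))
  absent_fraction <- unname(1 - colMeans(present))
  kept <- absent_fraction <= absent_fraction_threshold
  report <- tibble::tibble(feature = tensor$feature_info$feature,
                           absent_fraction = absent_fraction,
                           kept = kept)
  out <- tensor
  out$values <- tensor$values[, , kept, drop = FALSE]
  out$feature_info <- tensor$feature_info[kept, ]
  out <- new_feature_tensor(out$values, out$mask, out$block_ids,
                            out$snp_ids, out$feature_info, out$label,
                            out$weight, out$min_p, out$chrom)
  list(tensor = out, report = report)
}

#' Generate shuffled-feature control blocks
#'
#' Builds the false-case (control) training set by sampling true blocks
#' uniformly with replacement and destroying the SNP-level feature
#' co-occurrence in each copy. In the default `"column"` mode every
#' feature column is independently permuted across the unmasked SNP slots
#' of the block, which preserves each feature's per-block marginal count;
#' `"row"` mode instead permutes each SNP's values across the feature
#' axis, preserving per-SNP annotation counts.
#'
#' @param tensor The filtered true-case `feature_tensor`.
#' @param ratio Number of control blocks per true block (default 10).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param mode `"column"` (default) or `"row"`.
#' @return A `feature_tensor` of `ratio * n_blocks` control blocks with
#'   label 0 and weight 2; block ids `ctrl000001, ...`, chromosomes
#'   inherited from the source blocks.
#' @export
generate_control_blocks <- function(tensor, ratio = 10, seed = 1,
                                    mode = c("column", "row")) {
  mode <- match.arg(mode)
  if (!is.numeric(ratio) || ratio < 1) {
    rlang::abort("ratio must be >= 1", class = "epifinemap_domain_error")
  }
  ratio <- as.integer(ratio)
  nb <- n_blocks(tensor)
  nf <- n_features(tensor)
  ns <- dim(tensor$values)[2]
  n_ctrl <- ratio * nb
  withr::with_seed(seed, {
    src <- sample.int(nb, n_ctrl, replace = TRUE)
    values <- array(0, dim = c(n_ctrl, ns, nf))
    for (i in seq_len(n_ctrl)) {
      s <- src[i]
      slots <- which(tensor$mask[s, ])
      block <- tensor$values[s, slots, , drop = FALSE]
      dim(block) <- c(length(slots), nf)
      if (mode == "column") {
        for (j in seq_len(nf)) {
          block[, j] <- block[sample.int(length(slots)), j]
        }
      } else {
        for (r in seq_len(length(slots))) {
          block[r, ] <- block[r, sample.int(nf)]
        }
      }
      values[i, slots, ] <- block
    }
  })
  ft <- new_feature_tensor(
    values, tensor$mask[src, , drop = FALSE],
    sprintf("ctrl%06d", seq_len(n_ctrl)),
    tensor$snp_ids[src, , drop = FALSE], tensor$feature_info,
    label = rep(0L, n_ctrl), weight = rep(2, n_ctrl),
    min_p = rep(NA_real_, n_ctrl), chrom = tensor$chrom[src])
  ft$source_block <- tensor$block_ids[src]
  ft
}

#' Subset a feature tensor by block index
#' @param tensor A `feature_tensor`.
#' @param idx Integer or logical index over blocks.
#' @return A `feature_tensor` with the selected blocks.
#' @export
subset_tensor <- function(tensor, idx) {
  if (is.logical(idx)) idx <- which(idx)
  out <- new_feature_tensor(
    tensor$values[idx, , , drop = FALSE],
    tensor$mask[idx, , drop = FALSE],
    tensor$block_ids[idx],
    tensor$snp_ids[idx, , drop = FALSE],
    tensor$feature_info,
    tensor$label[idx], tensor$weight[idx], tensor$min_p[idx],
    tensor$chrom[idx])
  if (!is.null(tensor$source_block)) {
    out$source_block <- tensor$source_block[idx]
  }
  out
}

#' Concatenate feature tensors along the block axis
#' @param ... `feature_tensor` objects sharing slot count and feature axis.
#' @return A single `feature_tensor`.
#' @export
bind_tensors <- function(...) {
  ts <- list(...)
  f0 <- ts[[1]]$feature_info$feature
  for (t in ts[-1]) {
    if (!identical(t$feature_info$feature, f0)) {
      rlang::abort("tensors have different feature axes")
    }
  }
  nb <- vapply(ts, n_blocks, integer(1))
  values <- array(0, dim = c(sum(nb), dim(ts[[1]]$values)[2], length(f0)))
  at <- 0L
  for (t in ts) {
    values[at + seq_len(n_blocks(t)), , ] <- t$values
    at <- at + n_blocks(t)
  }
  new_feature_tensor(
    values,
    do.call(rbind, lapply(ts, `[[`, "mask")),
    unlist(lapply(ts, `[[`, "block_ids")),
    do.call(rbind, lapply(ts, `[[`, "snp_ids")),
    ts[[1]]$feature_info,
    unlist(lapply(ts, `[[`, "label")),
    unlist(lapply(ts, `[[`, "weight")),
    unlist(lapply(ts, `[[`, "min_p")),
    unlist(lapply(ts, `[[`, "chrom")))
}

#' Unmasked SNP vectors of a tensor as a matrix
#'
#' @param tensor A `feature_tensor`.
#' @return List: `x`, an `n_snps x n_features` 0/1 matrix, and `index`, a
#'   tibble `(block_index, block_id, slot, snp_id, label)` mapping rows of
#'   `x` back to blocks.
#' @export
tensor_snp_matrix <- function(tensor) {
  idx <- which(tensor$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  x <- matrix(0, nrow(idx), n_features(tensor),
              dimnames = list(NULL, tensor$feature_info$feature))
  for (r in seq_len(nrow(idx))) {
    x[r, ] <- tensor$values[idx[r, 1], idx[r, 2], ]
  }
  index <- tibble::tibble(
    block_index = as.integer(idx[, 1]),
    block_id = tensor$block_ids[idx[, 1]],
    slot = as.integer(idx[, 2]),
    snp_id = tensor$snp_ids[idx],
    label = tensor$label[idx[, 1]])
  list(x = x, index = index)
}

#' Write a feature tensor as plain-text tables
#'
#' Emits `blocks.tsv` (block-level metadata), `snps.tsv` (slot layout),
#' `features.tsv` (feature axis) and `values.tsv` (sparse 1-entries:
#' `block_id`, `snp_id`, `feature`) into `dir`.
#'
#' @param tensor A `feature_tensor`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_feature_tensor <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::tibble(
    block_id = tensor$block_ids, chrom = tensor$chrom,
    label = tensor$label, weight = tensor$weight, min_p = tensor$min_p),
    file.path(dir, "blocks.tsv"))
  m <- tensor_snp_matrix(tensor)
  readr::write_tsv(m$index[, c("block_id", "slot", "snp_id")],
                   file.path(dir, "snps.tsv"))
  readr::write_tsv(tensor$feature_info, file.path(dir, "features.tsv"))
  ones <- which(m$x == 1, arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(
    block_id = m$index$block_id[ones[, 1]],
    slot = m$index$slot[ones[, 1]],
    feature = colnames(m$x)[ones[, 2]])[order(ones[, 1], ones[, 2]), ],
    file.path(dir, "values.tsv"))
  invisible(dir)
}

#' Read a feature tensor written by [write_feature_tensor()]
#' @param dir Directory with the four tensor tables.
#' @param n_slots Slot count of the tensor (default 30).
#' @return A `feature_tensor`.
#' @export
read_feature_tensor <- function(dir, n_slots = 30) {
  blk <- readr::read_tsv(file.path(dir, "blocks.tsv"),
                         col_types = "ccidd", progress = FALSE)
  snps <- readr::read_tsv(file.path(dir, "snps.tsv"),
                          col_types = "cic", progress = FALSE)
  feats <- readr::read_tsv(file.path(dir, "features.tsv"),
                           col_types = "cccl", progress = FALSE)
  vals <- readr::read_tsv(file.path(dir, "values.tsv"),
                          col_types = "cic", progress = FALSE)
  nb <- nrow(blk)
  nf <- nrow(feats)
  values <- array(0, dim = c(nb, n_slots, nf))
  mask <- matrix(FALSE, nb, n_slots)
  snp_ids <- matrix(NA_character_, nb, n_slots)
  bi <- match(snps$block_id, blk$block_id)
  mask[cbind(bi, snps$slot)] <- TRUE
  snp_ids[cbind(bi, snps$slot)] <- snps$snp_id
  values[cbind(match(vals$block_id, blk$block_id), vals$slot,
               match(vals$feature, feats$feature))] <- 1
  new_feature_tensor(values, mask, blk$block_id, snp_ids, feats,
                     blk$label, blk$weight, blk$min_p, blk$chrom)
}
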