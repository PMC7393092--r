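#' Configuration for the synthetic benchmark generator
#'
#' Describes a synthetic post-GWAS dataset: association blocks of linked
#' SNPs laid out far apart on chromosomes 1-22, block minimum p-values
#' drawn from a mixture over the five uncertainty-weight tiers, sparse
#' binary feature vectors, and a planted causal SNP in each causal block
#' whose vector is enriched in a designated causal-feature subset.
#'
#' The defaults are the package's benchmark conditions: 25 blocks of 30
#' SNPs, 200 features of which 20 are causal, 20 causal blocks, causal
#' SNPs carrying each causal feature with probability 0.7 against a 0.05
#' background, and an equal mixture over the five p-value tiers.
#'
#' @param n_blocks Number of association blocks.
#' @param snps_per_block SNPs per block (at most 30).
#' @param n_features Number of binary features.
#' @param n_causal_features Size of the causal feature subset.
#' @param n_causal_blocks Number of blocks carrying a planted causal SNP;
#'   these are the first `n_causal_blocks` block indices, so the ground
#'   truth does not depend on the random stream.
#' @param causal_feature_prob Probability a causal SNP carries each causal
#'   feature; must exceed `background_prob`.
#' @param background_prob Probability any SNP carries any feature.
#' @param p_tier_mix Probabilities over the five weight tiers (strongest
#'   first) for block minimum p-values; normalized internally.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_blocks = 25, snps_per_block = 30,
                         n_features = 200, n_causal_features = 20,
                         n_causal_blocks = 20, causal_feature_prob = 0.7,
                         background_prob = 0.05,
                         p_tier_mix = rep(0.2, 5), seed = 17) {
  if (snps_per_block < 1 || snps_per_block > 30) {
    rlang::abort("snps_per_block must be in 1..30",
                 class = "epifinemap_domain_error")
  }
  if (n_causal_features > n_features || n_causal_blocks > n_blocks) {
    rlang::abort(paste0("causal counts cannot exceed totals"),
                 class = "epifinemap_domain_error")
  }
  if (causal_feature_prob <= background_prob) {
    rlang::abort("causal_feature_prob must exceed background_prob",
                 class = "epifinemap_domain_error")
  }
  if (length(p_tier_mix) != 5 || any(p_tier_mix < 0) ||
      sum(p_tier_mix) <= 0) {
    rlang::abort("p_tier_mix must be 5 nonnegative values",
                 class = "epifinemap_domain_error")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 snps_per_block = as.integer(snps_per_block),
                 n_features = as.integer(n_features),
                 n_causal_features = as.integer(n_causal_features),
                 n_causal_blocks = as.integer(n_causal_blocks),
                 causal_feature_prob = causal_feature_prob,
                 background_prob = background_prob,
                 p_tier_mix = p_tier_mix / sum(p_tier_mix),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# p-value bands of the five uncertainty-weight tiers, strongest first
tier_bounds <- function() {
  list(c(1e-10, 5e-8), c(5e-8, 5e-7), c(5e-7, 5e-6),
       c(5e-6, 5e-5), c(5e-5, 5e-4))
}

#' Generate a synthetic fine-mapping dataset
#'
#' Lays `n_blocks` association blocks on chromosomes 1-22 (round-robin,
#' block centers 3 Mb apart within a chromosome so that blocks never
#' interact through the 1 Mb lead-spacing rule), draws each block's
#' minimum p-value from its assigned tier and gives it to the central
#' (lead) SNP, plants one causal SNP per causal block, and materializes
#' the binary feature matrix as 1-bp BED intervals, one track per
#' feature. Also writes a per-block gene annotation (TSS placed so the
#' lead SNP falls in the promoter) and enhancer links covering each
#' causal SNP, so the gene-mapping stage is exercised end to end.
#'
#' All outputs are plain text and byte-identical across runs with the
#' same configuration.
#'
#' @param config A [synth_config()].
#' @param dir Output directory; created if needed.
#' @return Invisibly, a list: `paths` to `sumstats.tsv`, `manifest.tsv`,
#'   `genes.tsv`, `enhancers.bed`, `truth.json` and the `tracks/`
#'   directory; `truth`, the ground-truth list (`causal_snp_ids`,
#'   `causal_features`, per-block table, all SNP ids); and
#'   `feature_matrix`, the planted SNP x feature 0/1 matrix.
#' @export
generate_dataset <- function(config = synth_config(), dir = tempfile()) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE,
             recursive = TRUE)
  nb <- config$n_blocks
  ns <- config$snps_per_block
  nf <- config$n_features
  features <- sprintf("feat%03d", seq_len(nf))
  categories <- rep(c("neural", "immune", "digestive", "circulatory"),
                    length.out = nf)
  assays <- rep(c("DHS", "histone", "TFBS"), length.out = nf)
  causal_features <- features[seq_len(config$n_causal_features)]
  bounds <- tier_bounds()

  withr::with_seed(config$seed, {
    chrom <- as.character(((seq_len(nb) - 1L) %% 22L) + 1L)
    chrom_idx <- stats::ave(seq_len(nb), chrom, FUN = seq_along)
    center <- 2e7 + (chrom_idx - 1) * 3e6
    tier <- sample.int(5L, nb, replace = TRUE, prob = config$p_tier_mix)
    causal_block <- seq_len(nb) <= config$n_causal_blocks
    causal_slot <- rep(NA_integer_, nb)

    snps <- vector("list", nb)
    fmat <- vector("list", nb)
    causal_snp_ids <- character(0)
    for (b in seq_len(nb)) {
      offs <- if (ns > 1) {
        sort(c(0L, sample(setdiff(seq(-250000L, 250000L, by = 50L), 0L),
                          ns - 1L)))
      } else 0L
      lead_slot <- which(offs == 0L)
      lo <- log10(bounds[[tier[b]]][1])
      hi <- log10(bounds[[tier[b]]][2])
      min_p <- 10^stats::runif(1, lo, hi)
      p <- 10^stats::runif(ns, log10(min_p) + 1e-9, log10(5e-4))
      p[lead_slot] <- min_p
      ids <- sprintf("snp_b%02d_s%02d", b, seq_len(ns))
      snps[[b]] <- tibble::tibble(
        SNP = ids, CHR = chrom[b], BP = center[b] + offs, P = p)
      x <- matrix(stats::rbinom(ns * nf, 1, config$background_prob),
                  ns, nf, dimnames = list(ids, features))
      if (causal_block[b]) {
        cs <- sample.int(ns, 1)
        causal_slot[b] <- cs
        x[cs, causal_features] <-
          stats::rbinom(length(causal_features), 1,
                        config$causal_feature_prob)
        causal_snp_ids <- c(causal_snp_ids, ids[cs])
      }
      fmat[[b]] <- x
    }
  })
  sumstats <- dplyr::bind_rows(snps)
  sumstats <- dplyr::arrange(sumstats, as.integer(.data$CHR), .data$BP)
  x_all <- do.call(rbind, fmat)

  paths <- list(
    sumstats = file.path(dir, "sumstats.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    genes = file.path(dir, "genes.tsv"),
    enhancers = file.path(dir, "enhancers.bed"),
    truth = file.path(dir, "truth.json"),
    tracks = file.path(dir, "tracks"))
  readr::write_tsv(sumstats, paths$sumstats)

  pos_of <- stats::setNames(sumstats$BP, sumstats$SNP)
  chr_of <- stats::setNames(sumstats$CHR, sumstats$SNP)
  for (j in seq_len(nf)) {
    carriers <- rownames(x_all)[x_all[, j] == 1]
    bed <- tibble::tibble(chrom = unname(chr_of[carriers]),
                          start = unname(pos_of[carriers]) - 1,
                          end = unname(pos_of[carriers]),
                          name = features[j])
    bed <- dplyr::arrange(bed, as.integer(.data$chrom), .data$start)
    readr::write_tsv(bed, file.path(paths$tracks,
                                    paste0(features[j], ".bed")),
                     col_names = FALSE)
  }
  readr::write_tsv(tibble::tibble(
    name = features, category = categories, assay = assays,
    format = "bed", path = file.path("tracks", paste0(features, ".bed"))),
    paths$manifest)

  lead_ids <- sprintf("snp_b%02d_s%02d", seq_len(nb),
                      vapply(seq_len(nb), function(b) {
                        which(snps[[b]]$BP == center[b])
                      }, integer(1)))
  strand <- rep(c("+", "-"), length.out = nb)
  genes <- tibble::tibble(
    gene_id = sprintf("GENE%03d", seq_len(nb)),
    chrom = chrom, strand = strand,
    tss = ifelse(strand == "+", pos_of[lead_ids] + 1500,
                 pos_of[lead_ids] - 1500))
  readr::write_tsv(genes, paths$genes)

  enh <- tibble::tibble(
    chrom = chrom[causal_block],
    start = unname(pos_of[causal_snp_ids]) - 51,
    end = unname(pos_of[causal_snp_ids]) + 50,
    name = genes$gene_id[causal_block])
  enh <- dplyr::arrange(enh, as.integer(.data$chrom), .data$start)
  readr::write_tsv(enh, paths$enhancers, col_names = FALSE)

  truth <- list(
    causal_snp_ids = causal_snp_ids,
    causal_features = causal_features,
    snp_ids = sumstats$SNP,
    blocks = tibble::tibble(
      block = seq_len(nb), chrom = chrom, center = center,
      tier = tier, causal = causal_block,
      causal_snp_id = ifelse(causal_block,
                             sprintf("snp_b%02d_s%02d", seq_len(nb),
                                     causal_slot), NA_character_)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth, feature_matrix = x_all,
                 config = config))
}

#' Recovery metrics against the planted ground truth
#'
#' @param truth Ground-truth list from [generate_dataset()].
#' @param candidates Tibble of candidate calls (needs `snp_id`), e.g.
#'   from [call_candidates()].
#' @param importance Optional `snp_importance` tibble; enables
#'   `feature_recall`.
#' @param n_top Number of top-Gini features compared against the causal
#'   set (default: the number of causal features).
#' @return Tibble with one row: `snp_recall`, `snp_precision` (`NA` when
#'   nothing was called) and `feature_recall` (`NA` without importances).
#' @export
score_recovery <- function(truth, candidates, importance = NULL,
                           n_top = length(truth$causal_features)) {
  called <- unique(candidates$snp_id)
  if (length(setdiff(called, truth$snp_ids)) > 0) {
    rlang::abort("candidate SNP ids not present in the ground truth",
                 class = "epifinemap_consistency_error")
  }
  causal <- truth$causal_snp_ids
  hit <- intersect(called, causal)
  feature_recall <- NA_real_
  if (!is.null(importance)) {
    top <- importance$feature[order(-importance$gini)][seq_len(n_top)]
    feature_recall <- mean(truth$causal_features %in% top)
  }
  tibble::tibble(
    snp_recall = length(hit) / length(causal),
    snp_precision = if (length(called) == 0) NA_real_ else
      length(hit) / length(called),
    feature_recall = feature_recall)
}
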