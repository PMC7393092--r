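#' Call candidate risk SNPs from prediction scores
#'
#' Keeps SNPs with `score` strictly greater than the threshold and carries
#' their block id and lead flag.
#'
#' @param scores Tibble from [predict_snp_scores()].
#' @param blocks Tibble from [build_blocks()] (for `is_lead` and
#'   coordinates).
#' @param threshold Score cut-off (default 0.5, strict).
#' @return Tibble `(snp_id, block_id, chrom, pos, score, is_lead)`.
#' @export
call_candidates <- function(scores, blocks, threshold = 0.5) {
  hits <- dplyr::filter(scores, .data$score > threshold)
  out <- dplyr::left_join(
    hits,
    blocks[, c("block_id", "snp_id", "chrom", "pos", "is_lead")],
    by = c("block_id", "snp_id"))
  out[, c("snp_id", "block_id", "chrom", "pos", "score", "is_lead")]
}

#' Read a gene annotation table
#'
#' Tab-separated columns `gene_id`, `chrom`, `strand` (`+`/`-`), `tss`
#' (1-based transcription start site).
#'
#' @param path Path to the TSV.
#' @return Tibble of gene annotations.
#' @export
read_gene_annotation <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", strand = "c", tss = "d"),
    progress = FALSE)
  if (!all(g$strand %in% c("+", "-"))) {
    rlang::abort("gene strand must be '+' or '-'")
  }
  g
}

#' Read enhancer-to-gene links
#'
#' BED file (0-based half-open) whose name column carries the linked gene
#' id.
#'
#' @param path Path to the BED file.
#' @return Tibble `(chrom, start, end, gene_id)`.
#' @export
read_enhancer_links <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_id = S4Vectors::mcols(gr)$name)
}

#' Map SNPs to target genes via promoters and enhancers
#'
#' A SNP hits a gene's promoter when it lies in the 3 kb strictly
#' upstream of the transcription start site on the gene's strand: for a
#' `+` gene positions `[tss - promoter_bp, tss)`, for a `-` gene
#' `(tss, tss + promoter_bp]` (1-based, TSS itself excluded). A SNP hits
#' an enhancer when its position overlaps an enhancer interval linked to
#' the gene. Every mapping is kept; there is no nearest-gene fallback —
#' the closest gene is typically not the regulatory target.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos`.
#' @param genes Tibble from [read_gene_annotation()].
#' @param enhancers Optional tibble from [read_enhancer_links()].
#' @param promoter_bp Promoter length upstream of the TSS (default 3000).
#' @return Tibble `(snp_id, gene_id, via)` with `via` in
#'   `{"promoter", "enhancer"}`.
#' @export
map_snp_to_genes <- function(snps, genes, enhancers = NULL,
                             promoter_bp = 3000) {
  if (!all(genes$strand %in% c("+", "-"))) {
    rlang::abort("gene strand must be '+' or '-'")
  }
  pairs <- dplyr::inner_join(snps[, c("snp_id", "chrom", "pos")], genes,
                             by = "chrom", relationship = "many-to-many")
  prom <- dplyr::filter(pairs, ifelse(
    .data$strand == "+",
    .data$pos >= .data$tss - promoter_bp & .data$pos < .data$tss,
    .data$pos > .data$tss & .data$pos <= .data$tss + promoter_bp))
  prom <- dplyr::mutate(prom[, c("snp_id", "gene_id")], via = "promoter")
  enh <- NULL
  if (!is.null(enhancers) && nrow(enhancers) > 0) {
    ep <- dplyr::inner_join(snps[, c("snp_id", "chrom", "pos")], enhancers,
                            by = "chrom", relationship = "many-to-many")
    ep <- dplyr::filter(ep, .data$pos - 1 >= .data$start,
                        .data$pos - 1 < .data$end)
    enh <- dplyr::mutate(ep[, c("snp_id", "gene_id")], via = "enhancer")
  }
  dplyr::distinct(dplyr::bind_rows(prom, enh))
}

#' Flag blocks sharing genome-wide-significant tag-SNPs and compare gene
#' sets
#'
#' A block is flagged when any member SNP reaches genome-wide significance
#' (`p_value < gwas_threshold`). The function then mirrors the published
#' comparison of target genes: the set mapped from candidate SNPs lying in
#' flagged blocks versus the set mapped from the tag-SNPs themselves.
#'
#' @param blocks Tibble from [build_blocks()].
#' @param candidates Tibble from [call_candidates()].
#' @param genes Gene annotation tibble.
#' @param enhancers Optional enhancer-link tibble.
#' @param gwas_threshold Genome-wide significance level (default `5e-8`).
#' @param promoter_bp Promoter length for gene mapping.
#' @return List with `block_flags` (tibble `block_id`,
#'   `has_tag_snp`), `candidate_genes`, `tag_genes` (character vectors)
#'   and `comparison`, a tibble `(gene_id, in_candidate_set, in_tag_set)`.
#' @export
flag_tag_blocks <- function(blocks, candidates, genes, enhancers = NULL,
                            gwas_threshold = 5e-8, promoter_bp = 3000) {
  flags <- dplyr::summarise(
    dplyr::group_by(blocks, .data$block_id),
    has_tag_snp = any(.data$p_value < gwas_threshold), .groups = "drop")
  flagged <- flags$block_id[flags$has_tag_snp]
  cand_in_flagged <- dplyr::filter(candidates, .data$block_id %in% flagged)
  cand_map <- map_snp_to_genes(cand_in_flagged, genes, enhancers,
                               promoter_bp)
  tags <- dplyr::filter(blocks, .data$p_value < gwas_threshold)
  tag_map <- map_snp_to_genes(tags, genes, enhancers, promoter_bp)
  cand_genes <- sort(unique(cand_map$gene_id))
  tag_genes <- sort(unique(tag_map$gene_id))
  all_genes <- sort(union(cand_genes, tag_genes))
  list(block_flags = flags,
       candidate_genes = cand_genes,
       tag_genes = tag_genes,
       comparison = tibble::tibble(
         gene_id = all_genes,
         in_candidate_set = all_genes %in% cand_genes,
         in_tag_set = all_genes %in% tag_genes))
}

#' End-to-end candidate prioritization
#'
#' Calls candidates from scores, maps them to genes, and flags blocks
#' containing genome-wide-significant tag-SNPs; the per-candidate table
#' mirrors the filtering pipeline's output.
#'
#' @inheritParams flag_tag_blocks
#' @param scores Tibble from [predict_snp_scores()].
#' @param threshold Candidate score threshold (default 0.5).
#' @return List with `candidates` (tibble `snp_id, block_id, score,
#'   is_lead, gene_id, via, block_has_tag_snp`, one row per SNP-gene
#'   mapping, unmapped SNPs kept with `NA` gene) and the gene-set
#'   `comparison` from [flag_tag_blocks()].
#' @export
prioritize_variants <- function(scores, blocks, genes, enhancers = NULL,
                                threshold = 0.5, gwas_threshold = 5e-8,
                                promoter_bp = 3000) {
  calls <- call_candidates(scores, blocks, threshold)
  gmap <- map_snp_to_genes(calls, genes, enhancers, promoter_bp)
  ft <- flag_tag_blocks(blocks, calls, genes, enhancers, gwas_threshold,
                        promoter_bp)
  out <- dplyr::left_join(calls, gmap, by = "snp_id",
                          relationship = "many-to-many")
  out <- dplyr::left_join(out, ft$block_flags, by = "block_id")
  out <- dplyr::rename(out, block_has_tag_snp = "has_tag_snp")
  list(candidates = out, block_flags = ft$block_flags,
       comparison = ft$comparison,
       candidate_genes = ft$candidate_genes, tag_genes = ft$tag_genes)
}
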