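#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file with a header row and
#' returns a validated tibble of per-SNP association records. Column names
#' are configurable; the defaults match the common `SNP/CHR/BP/P` layout.
#'
#' Rows with a missing, non-numeric or out-of-range p-value (outside
#' `(0, 1]`) are rejected with an error that lists the offending line
#' numbers, counting the header as line 1. Duplicate `(chrom, pos)` pairs
#' are rejected as well: one physical position must carry one record.
#'
#' @param path Path to a tab-separated file with a header.
#' @param cols Named character vector mapping the output fields
#'   `snp_id`, `chrom`, `pos`, `p_value` to column names in the file.
#' @return A tibble with columns `snp_id` (character), `chrom` (character),
#'   `pos` (integer-valued double, 1-based) and `p_value` (double).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(
#'   tibble::tibble(SNP = c("rs1", "rs2"), CHR = "1",
#'                  BP = c(100, 200), P = c(1e-6, 2e-4)), tf)
#' read_summary_stats(tf)
#' @export
read_summary_stats <- function(path,
                               cols = c(snp_id = "SNP", chrom = "CHR",
                                        pos = "BP", p_value = "P")) {
  required <- c("snp_id", "chrom", "pos", "p_value")
  if (!all(required %in% names(cols))) {
    rlang::abort(paste0("`cols` must name all of: ",
                        paste(required, collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(unname(cols[required]), names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("summary-statistics file is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "epifinemap_format_error")
  }
  out <- tibble::tibble(
    snp_id  = as.character(raw[[cols[["snp_id"]]]]),
    chrom   = as.character(raw[[cols[["chrom"]]]]),
    pos     = suppressWarnings(as.numeric(raw[[cols[["pos"]]]])),
    p_value = suppressWarnings(as.numeric(raw[[cols[["p_value"]]]]))
  )
  # +1 for the header row, so reported numbers match the file on disk
  bad_p <- which(is.na(out$p_value) | out$p_value <= 0 | out$p_value > 1)
  if (length(bad_p) > 0) {
    rlang::abort(paste0("invalid p-value (must be in (0, 1]) on line(s): ",
                        paste(bad_p + 1L, collapse = ", ")),
                 class = "epifinemap_validation_error")
  }
  bad_pos <- which(is.na(out$pos) | out$pos < 1)
  if (length(bad_pos) > 0) {
    rlang::abort(paste0("invalid position (must be >= 1) on line(s): ",
                        paste(bad_pos + 1L, collapse = ", ")),
                 class = "epifinemap_validation_error")
  }
  dup <- duplicated(out[, c("chrom", "pos")])
  if (any(dup)) {
    rlang::abort(paste0("duplicate (chrom, pos) on line(s): ",
                        paste(which(dup) + 1L, collapse = ", ")),
                 class = "epifinemap_validation_error")
  }
  out
}

#' Select lead SNPs by greedy p-value clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as a lead
#' and removes every SNP on the same chromosome within `min_spacing` of it,
#' so that any two leads on one chromosome end up strictly more than
#' `min_spacing` apart. SNPs with `p_value > p_max` are discarded first.
#' Ties in p-value are broken by `(chrom, pos)` ascending.
#'
#' @param sumstats Tibble from [read_summary_stats()].
#' @param p_max Largest p-value a SNP may have and still be considered
#'   (default `5e-4`).
#' @param min_spacing Exclusion radius around each selected lead, in base
#'   pairs (default 1 Mb).
#' @return A tibble of lead SNPs in selection order (most significant
#'   first), same columns as the input.
#' @export
select_lead_snps <- function(sumstats, p_max = 5e-4, min_spacing = 1e6) {
  pool <- dplyr::filter(sumstats, .data$p_value <= p_max)
  pool <- dplyr::arrange(pool, .data$p_value, .data$chrom, .data$pos)
  leads <- vector("list", nrow(pool))
  n_leads <- 0L
  while (nrow(pool) > 0) {
    lead <- pool[1L, ]
    n_leads <- n_leads + 1L
    leads[[n_leads]] <- lead
    keep <- !(pool$chrom == lead$chrom &
                abs(pool$pos - lead$pos) <= min_spacing)
    pool <- pool[keep, ]
  }
  if (n_leads == 0L) {
    return(sumstats[0L, ])
  }
  dplyr::bind_rows(leads[seq_len(n_leads)])
}

#' Build association blocks around lead SNPs
#'
#' Each lead SNP seeds one block; the flanking regions up to `window` base
#' pairs on either side are searched for the most significant SNPs with
#' `p_value <= p_max`, and total block membership (lead included) is capped
#' at `max_block_size`. Blocks are non-overlapping: a SNP that qualifies
#' for several blocks is assigned to the block whose lead has the smaller
#' p-value, with ties broken by distance to the lead and then by lead
#' position.
#'
#' @param sumstats Tibble from [read_summary_stats()].
#' @param leads Tibble from [select_lead_snps()] on the same records.
#' @param max_block_size Maximum number of member SNPs per block, lead
#'   included (default 30).
#' @param window Flanking search radius around each lead in base pairs
#'   (default 1 Mb).
#' @param p_max Inclusion threshold on member p-values (default `5e-4`).
#' @return A tibble of class `assoc_blocks` with one row per block member:
#'   `block_id`, `snp_id`, `chrom`, `pos`, `p_value`, `is_lead`, plus the
#'   block-level `min_p`, `weight` (see [assign_block_weight()]) and
#'   `label` (`"true_case"`).
#' @export
build_blocks <- function(sumstats, leads, max_block_size = 30,
                         window = 1e6, p_max = 5e-4) {
  if (nrow(leads) == 0) {
    return(new_assoc_blocks(empty_blocks_tbl()))
  }
  key <- function(d) paste(d$chrom, d$pos, d$snp_id, sep = "\r")
  if (!all(key(leads) %in% key(sumstats))) {
    rlang::abort("`leads` contains SNPs absent from `sumstats`",
                 class = "epifinemap_consistency_error")
  }
  leads_tbl <- tibble::tibble(
    block_id = sprintf("blk%03d", seq_len(nrow(leads))),
    lead_snp_id = leads$snp_id, chrom = leads$chrom,
    lead_pos = leads$pos, lead_p = leads$p_value
  )
  snps <- dplyr::filter(sumstats, .data$p_value <= p_max,
                        !(key(sumstats) %in% key(leads)))
  # candidate (SNP, lead) pairs within the window, then a unique owner per SNP
  assigned <- dplyr::inner_join(snps, leads_tbl, by = "chrom",
                                relationship = "many-to-many")
  assigned <- dplyr::filter(assigned,
                            abs(.data$pos - .data$lead_pos) <= window)
  # unique owner per SNP: smaller lead p, then nearer lead, then lower
  # lead position
  assigned <- dplyr::arrange(assigned, .data$lead_p,
                             abs(.data$pos - .data$lead_pos),
                             .data$lead_pos)
  assigned <- dplyr::distinct(assigned, .data$snp_id, .data$chrom,
                              .data$pos, .keep_all = TRUE)
  # cap at max_block_size - 1 neighbors, most significant first
  assigned <- dplyr::arrange(assigned, .data$p_value, .data$chrom,
                             .data$pos)
  assigned <- dplyr::group_by(assigned, .data$block_id)
  assigned <- dplyr::slice_head(assigned, n = max_block_size - 1L)
  assigned <- dplyr::ungroup(assigned)

  members <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::rename(leads_tbl, snp_id = "lead_snp_id", pos = "lead_pos",
                    p_value = "lead_p"),
      is_lead = TRUE),
    dplyr::mutate(
      dplyr::select(assigned, "block_id", "snp_id", "chrom", "pos", "p_value"),
      is_lead = FALSE)
  )
  members <- dplyr::arrange(members, .data$block_id, .data$pos)
  members <- dplyr::group_by(members, .data$block_id)
  members <- dplyr::mutate(members, min_p = min(.data$p_value))
  members <- dplyr::ungroup(members)
  members$weight <- assign_block_weight(members$min_p)
  members$label <- "true_case"
  new_assoc_blocks(members)
}

empty_blocks_tbl <- function() {
  tibble::tibble(block_id = character(), snp_id = character(),
                 chrom = character(), pos = double(), p_value = double(),
                 is_lead = logical(), min_p = double(), weight = double(),
                 label = character())
}

new_assoc_blocks <- function(x) {
  class(x) <- c("assoc_blocks", class(tibble::tibble()))
  x
}

#' Uncertainty weight for an association block
#'
#' Maps the minimum p-value of a true-case block to a label-confidence
#' weight on a tiered step function:
#' 10 below `5e-8`, then 8, 6, 4 and 2 across successive ten-fold bands up
#' to `5e-4`. The comparisons are strict, so a minimum p-value falling
#' exactly on a tier boundary takes the weaker (higher-p) tier's weight.
#' Control (false-case) blocks always get weight 2.
#'
#' @param min_p Numeric vector of block minimum p-values (ignored where
#'   `control` is `TRUE`).
#' @param control Logical scalar or vector: is the block a shuffled-feature
#'   control?
#' @return Numeric vector of weights in `{2, 4, 6, 8, 10}`.
#' @examples
#' assign_block_weight(c(1e-9, 1e-6, 2e-5))
#' assign_block_weight(NA, control = TRUE)
#' @export
assign_block_weight <- function(min_p, control = FALSE) {
  control <- rep_len(control, length(min_p))
  true_p <- min_p[!control]
  if (any(is.na(true_p) | true_p <= 0 | true_p >= 5e-4)) {
    rlang::abort("true-case blocks require min_p in (0, 5e-4)",
                 class = "epifinemap_domain_error")
  }
  w <- rep(2, length(min_p))
  idx <- !control
  w[idx] <- dplyr::case_when(
    min_p[idx] < 5e-8 ~ 10,
    min_p[idx] < 5e-7 ~ 8,
    min_p[idx] < 5e-6 ~ 6,
    min_p[idx] < 5e-5 ~ 4,
    TRUE ~ 2
  )
  w
}

#' Chromosome-wise train/validation/test assignment
#'
#' @param train,test,validation Chromosome labels (coerced to character)
#'   for each role. Defaults: chromosomes 1-10 train, 11-14 test,
#'   15-22 validation.
#' @return A named list of three disjoint character vectors.
#' @export
chromosome_split <- function(train = 1:10, test = 11:14,
                             validation = 15:22) {
  out <- list(train = as.character(train),
              validation = as.character(validation),
              test = as.character(test))
  all_chr <- unlist(out, use.names = FALSE)
  if (anyDuplicated(all_chr)) {
    rlang::abort("split roles must have disjoint chromosome sets")
  }
  out
}

#' Partition association blocks by chromosome
#'
#' @param blocks Tibble from [build_blocks()].
#' @param assignment Role-to-chromosome map from [chromosome_split()].
#' @param unassigned What to do with blocks on chromosomes outside every
#'   role: `"drop"` (default, with a warning) or `"error"`.
#' @return Named list of three `assoc_blocks` tibbles: `train`,
#'   `validation`, `test`.
#' @export
split_by_chromosome <- function(blocks, assignment = chromosome_split(),
                                unassigned = c("drop", "error")) {
  unassigned <- match.arg(unassigned)
  known <- unlist(assignment, use.names = FALSE)
  stray <- setdiff(unique(blocks$chrom), known)
  if (length(stray) > 0) {
    msg <- paste0("blocks on unassigned chromosome(s): ",
                  paste(stray, collapse = ", "))
    if (unassigned == "error") rlang::abort(msg)
    rlang::warn(paste0(msg, " (dropped)"))
  }
  lapply(assignment[c("train", "validation", "test")], function(chr) {
    new_assoc_blocks(dplyr::filter(blocks, .data$chrom %in% chr))
  })
}

#' Write association blocks to disk
#'
#' Emits `blocks.tsv` (one row per member SNP) and `blocks.bed`
#' (0-based half-open block spans, one line per block).
#'
#' @param blocks Tibble from [build_blocks()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_blocks <- function(blocks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "blocks.tsv")
  readr::write_tsv(blocks, tsv)
  spans <- dplyr::summarise(
    dplyr::group_by(blocks, .data$block_id, .data$chrom),
    start = min(.data$pos) - 1L, end = max(.data$pos), .groups = "drop")
  bed <- file.path(dir, "blocks.bed")
  readr::write_tsv(spans[, c("chrom", "start", "end", "block_id")], bed,
                   col_names = FALSE)
  invisible(c(tsv = tsv, bed = bed))
}

#' Read association blocks written by [write_blocks()]
#' @param dir Directory containing `blocks.tsv`.
#' @return An `assoc_blocks` tibble.
#' @export
read_blocks <- function(dir) {
  x <- readr::read_tsv(file.path(dir, "blocks.tsv"),
                       col_types = readr::cols(
                         block_id = "c", snp_id = "c", chrom = "c",
                         pos = "d", p_value = "d", is_lead = "l",
                         min_p = "d", weight = "d", label = "c"),
                       progress = FALSE)
  new_assoc_blocks(x)
}
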