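#' Read a GMT-like gene-set file
#'
#' Each line: set name, a description field (ignored), then tab-separated
#' gene identifiers.
#'
#' @param path Path to the file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      rlang::abort(paste0("malformed GMT line (need name, description, ",
                          ">=1 gene): ", substr(l, 1, 40)))
    }
    stats::setNames(list(unique(parts[-(1:2)])), parts[[1]])
  })
  unlist(out, recursive = FALSE)
}

#' Load annotation tracks from a manifest
#'
#' The manifest is a tab-separated table with columns `name`, `category`
#' (tissue class: neural, immune, digestive, circulatory, other), `assay`
#' (`DHS`, `histone`, `TFBS` or `pathway`), `format` (`bed` or `gmt`) and
#' `path` (relative to the manifest unless absolute). BED tracks are
#' 0-based half-open genomic intervals; GMT tracks are gene sets, and a
#' single GMT file contributes one track per set it contains.
#'
#' Histone tracks whose name contains `H3K9me3` or `H3K27me3` are flagged
#' as repressive marks so the importance stage can exclude them; they are
#' not specific to individual SNPs.
#'
#' @param path Path to the manifest TSV.
#' @return An `annotation_tracks` object: positional tracks as a single
#'   `GRanges` keyed by track, pathway tracks as gene-id sets, and a
#'   feature info table (`feature`, `category`, `assay`, `repressive`).
#' @export
read_track_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("name", "category", "assay", "format", "path")
  if (!all(needed %in% names(man))) {
    rlang::abort(paste0("track manifest must have columns: ",
                        paste(needed, collapse = ", ")))
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  pos_rows <- man[man$format == "bed", ]
  gmt_rows <- man[man$format == "gmt", ]

  positional <- NULL
  if (nrow(pos_rows) > 0) {
    grl <- lapply(seq_len(nrow(pos_rows)), function(i) {
      gr <- rtracklayer::import(resolve(pos_rows$path[i]), format = "BED")
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        track = rep(pos_rows$name[i], length(gr)))
      gr
    })
    positional <- suppressWarnings(do.call(c, grl))
  }
  pathway <- list()
  pathway_info <- NULL
  if (nrow(gmt_rows) > 0) {
    sets <- lapply(seq_len(nrow(gmt_rows)), function(i) {
      s <- read_gmt(resolve(gmt_rows$path[i]))
      attr(s, "category") <- gmt_rows$category[i]
      s
    })
    pathway <- unlist(sets, recursive = FALSE)
    pathway_info <- tibble::tibble(
      feature = names(pathway),
      category = rep(gmt_rows$category,
                     vapply(sets, length, integer(1))),
      assay = "pathway"
    )
  }
  info <- dplyr::bind_rows(
    tibble::tibble(feature = pos_rows$name, category = pos_rows$category,
                   assay = pos_rows$assay),
    pathway_info
  )
  info$repressive <- grepl("H3K9me3|H3K27me3", info$feature)
  if (anyDuplicated(info$feature)) {
    rlang::abort("duplicate track names in manifest")
  }
  structure(list(positional = positional, pathway = pathway, info = info),
            class = "annotation_tracks")
}

#' @export
print.annotation_tracks <- function(x, ...) {
  cat("<annotation_tracks> ", nrow(x$info), " features (",
      sum(x$info$assay != "pathway"), " positional, ",
      length(x$pathway), " pathway)\n", sep = "")
  invisible(x)
}

#' Annotate SNPs with binary functional features
#'
#' Builds the binary feature matrix: entry 1 if the SNP overlaps a
#' positional track interval, or (for pathway tracks) if any gene the SNP
#' maps to belongs to the track's gene set; 0 otherwise. A SNP is a 1-bp
#' point; its 1-based position `pos` overlaps a 0-based half-open interval
#' `[start, end)` exactly when `start <= pos - 1 < end`. A SNP on a
#' chromosome absent from every track simply gets an all-zero row.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`.
#' @param tracks An `annotation_tracks` object.
#' @param gene_map Optional tibble `(snp_id, gene_id)` of SNP-to-gene
#'   assignments (from [map_snp_to_genes()]); required if any pathway
#'   tracks are present and you want them filled.
#' @return Integer 0/1 matrix, one row per SNP (rownames `snp_id`), one
#'   column per feature in `tracks$info$feature` order.
#' @export
annotate_snps <- function(snps, tracks, gene_map = NULL) {
  features <- tracks$info$feature
  mat <- matrix(0L, nrow = nrow(snps), ncol = length(features),
                dimnames = list(snps$snp_id, features))
  if (!is.null(tracks$positional) && length(tracks$positional) > 0 &&
      nrow(snps) > 0) {
    q <- GenomicRanges::GRanges(
      seqnames = snps$chrom,
      ranges = IRanges::IRanges(start = snps$pos, width = 1L))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(q, tracks$positional))
    if (length(hits) > 0) {
      trk <- S4Vectors::mcols(tracks$positional)$track[
        S4Vectors::subjectHits(hits)]
      mat[cbind(S4Vectors::queryHits(hits), match(trk, features))] <- 1L
    }
  }
  if (length(tracks$pathway) > 0 && !is.null(gene_map) && nrow(snps) > 0) {
    genes_by_snp <- split(gene_map$gene_id, gene_map$snp_id)
    for (j in seq_along(tracks$pathway)) {
      set <- tracks$pathway[[j]]
      col <- match(names(tracks$pathway)[j], features)
      hit <- vapply(snps$snp_id, function(s) {
        g <- genes_by_snp[[s]]
        !is.null(g) && any(g %in% set)
      }, logical(1))
      mat[hit, col] <- 1L
    }
  }
  mat
}
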