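# Readers and writers for the on-disk formats: CDS FASTA, BED-like tRNA
# annotation (7 columns, 0-based half-open), TSV count matrices and BED
# interval files. All writers prefix output with a '#' metadata line and all
# readers skip such lines, so write-then-read round-trips are identity.

#' Read coding sequences from a FASTA file
#'
#' Reads a CDS FASTA, keeping for each gene the longest record when several
#' share a gene id (the first whitespace-delimited token of the header).
#' Sequences are upper-cased; records whose length is not divisible by 3 or
#' that contain ambiguity codes are dropped with a warning reporting counts.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `gene_id`, `cds`, `length_nt`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stopf("empty FASTA: %s", path)
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L)
  cds <- toupper(as.character(seqs))
  len <- nchar(cds)

  # longest record wins per gene id
  ord <- order(ids, -len)
  keep <- !duplicated(ids[ord])
  ids <- ids[ord][keep]; cds <- cds[ord][keep]; len <- len[ord][keep]

  not_triplet <- len %% 3L != 0L | len == 0L
  ambiguous <- grepl("[^ACGT]", cds)
  drop <- not_triplet | ambiguous
  if (any(drop)) {
    warnf("dropped %d CDS record(s): %d with length not divisible by 3, %d with ambiguity codes",
          sum(drop), sum(not_triplet), sum(ambiguous & !not_triplet))
  }
  out <- data.frame(gene_id = ids[!drop], cds = cds[!drop],
                    length_nt = len[!drop], stringsAsFactors = FALSE)
  if (nrow(out) == 0) stopf("no usable CDS records in %s", path)
  out[order(out$gene_id), , drop = FALSE]
}

#' Write coding sequences to FASTA
#'
#' @param transcripts data.frame with `gene_id` and `cds` columns.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  x <- Biostrings::DNAStringSet(transcripts$cds)
  names(x) <- transcripts$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a tRNA gene annotation
#'
#' Tab-separated BED-like file with columns chrom, start, end, gene_id,
#' isotype, anticodon, strand (0-based half-open coordinates). Mitochondrial
#' rows (`chrM`/`MT`) are dropped; selenocysteine genes are kept but flagged
#' `excluded = TRUE` so downstream statistics can omit them.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `anticodon`, `isotype`, `family_id`, `excluded`.
#' @export
read_trna_annotation <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stopf("empty tRNA annotation: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 7L)) {
    stopf("malformed tRNA annotation row(s) at line(s): %s (expected 7 tab-separated fields)",
          paste(which(nf != 7L), collapse = ", "))
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stopf("invalid coordinates at line(s): %s", paste(bad, collapse = ", "))
  }
  anticodon <- toupper(m[, 6])
  bad_ac <- which(nchar(anticodon) != 3L | grepl("[^ACGT]", anticodon))
  if (length(bad_ac) > 0) {
    stopf("anticodon must be a DNA triplet at line(s): %s",
          paste(bad_ac, collapse = ", "))
  }
  bad_strand <- which(!m[, 7] %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    stopf("strand must be '+' or '-' at line(s): %s",
          paste(bad_strand, collapse = ", "))
  }
  out <- data.frame(
    gene_id = m[, 4], chrom = m[, 1],
    start = as.integer(start), end = as.integer(end),
    strand = m[, 7], anticodon = anticodon, isotype = m[, 5],
    stringsAsFactors = FALSE
  )
  mito <- out$chrom %in% c("chrM", "chrMT", "MT", "M")
  if (any(mito)) {
    message(sprintf("dropped %d mitochondrial tRNA gene(s)", sum(mito)))
    out <- out[!mito, , drop = FALSE]
  }
  if (anyDuplicated(out$gene_id)) stopf("duplicate tRNA gene ids")
  out$family_id <- paste0(out$isotype, "-", out$anticodon)
  out$excluded <- out$isotype %in% c("SeC", "Sec", "SelCys")
  rownames(out) <- NULL
  out
}

#' Write a tRNA gene annotation
#'
#' @param trna_genes data.frame as returned by [read_trna_annotation()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trna_annotation <- function(trna_genes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# chrom\tstart\tend\tgene_id\tisotype\tanticodon\tstrand", con)
  writeLines(paste(trna_genes$chrom, trna_genes$start, trna_genes$end,
                   trna_genes$gene_id, trna_genes$isotype,
                   trna_genes$anticodon, trna_genes$strand, sep = "\t"), con)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' First column `gene_id`; remaining column headers encode the design as
#' `tissue.stage.repN`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param stages ordered character vector of stage labels (configuration);
#'   defaults to order of first appearance in the header, with a message.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, stages = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("count table needs gene_id plus >= 1 sample column")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stopf("duplicate gene ids in %s", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(is.na(mat)) || any(mat < 0) || any(mat != round(mat))) {
    stopf("counts must be non-negative integers")
  }
  rownames(mat) <- genes
  info <- parse_sample_id(colnames(mat))
  if (is.null(stages)) {
    stages <- unique(info$stage)
    message("stage order taken from column order: ", paste(stages, collapse = " < "))
  }
  count_matrix(mat, stages = stages)
}

#' Write a count matrix to TSV
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_counts <- function(cm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# codonbalance counts; stages=",
                    paste(cm$stages, collapse = ",")), con)
  writeLines(paste(c("gene_id", colnames(cm$counts)), collapse = "\t"), con)
  body <- cbind(rownames(cm$counts),
                matrix(as.character(cm$counts), nrow = nrow(cm$counts)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Minimal 3+ column BED (chrom, start, end, optional name); 0-based
#' half-open on disk, returned as a [GenomicRanges::GRanges] (1-based).
#'
#' @param path file path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stopf("BED needs >= 3 columns")
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]])
  )
  if (ncol(df) >= 4) gr$name <- df[[4]]
  gr
}

#' Write genomic intervals to a BED file
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
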