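#' Tag barcode reference table
#'
#' Maps tag names to their DNA barcode sequences. All sequences must share a
#' common length; a warning is emitted if any pair of barcodes is closer than
#' Hamming distance 2, since such references cannot tolerate single-base
#' error correction.
#'
#' @param tag_names Character vector of unique tag names.
#' @param sequences Character vector of DNA barcodes, same length.
#' @return A `tag_reference` object (named character vector).
#' @export
tag_reference <- function(tag_names, sequences) {
  if (length(tag_names) == 0) stop("empty tag reference")
  if (length(tag_names) != length(sequences))
    stop("'tag_names' and 'sequences' lengths differ")
  if (anyDuplicated(tag_names)) stop("duplicate tag names")
  sequences <- toupper(sequences)
  if (length(unique(nchar(sequences))) != 1)
    stop("tag barcode sequences must share a common length")
  if (length(sequences) > 1) {
    d <- hamming_all_pairs(sequences)
    if (any(d < 2))
      warning("some tag barcodes are within Hamming distance 1 of each other")
  }
  structure(stats::setNames(sequences, tag_names), class = "tag_reference")
}

hamming_all_pairs <- function(seqs) {
  n <- length(seqs)
  d <- integer(0)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      d <- c(d, hamming(seqs[i], seqs[j]))
  d
}

hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Read layout for paired tag-library reads
#'
#' Describes where the cell barcode and UMI sit in read 1 and the tag barcode
#' in read 2, plus the mismatch tolerance of barcode correction. The default
#' is the 10x 3' v3 convention: a 16 bp cell barcode followed by a 12 bp UMI
#' in read 1, with the tag barcode at the start of read 2.
#'
#' @param cb_start,cb_len Cell-barcode span in read 1 (1-based start, length).
#' @param umi_start,umi_len UMI span in read 1.
#' @param tag_start,tag_len Tag-barcode span in read 2.
#' @param max_mismatch Maximum Hamming distance for tag (and whitelist)
#'   correction; a read is kept only if exactly one reference is within this
#'   distance.
#' @return A `read_layout` object.
#' @export
read_layout <- function(cb_start = 1L, cb_len = 16L,
                        umi_start = 17L, umi_len = 12L,
                        tag_start = 1L, tag_len = NULL,
                        max_mismatch = 1L) {
  stopifnot(cb_len > 0, umi_len > 0, cb_start > 0, umi_start > 0,
            tag_start > 0, max_mismatch >= 0)
  cb_end <- cb_start + cb_len - 1L
  umi_end <- umi_start + umi_len - 1L
  if (max(cb_start, umi_start) <= min(cb_end, umi_end))
    stop("cell-barcode and UMI spans overlap in read 1")
  structure(list(cb_start = cb_start, cb_len = cb_len,
                 umi_start = umi_start, umi_len = umi_len,
                 tag_start = tag_start, tag_len = tag_len,
                 max_mismatch = as.integer(max_mismatch)),
            class = "read_layout")
}

# Correct a vector of observed sequences against references: returns the
# index of the unique reference within max_mismatch, or NA (ambiguous or too
# far). Exact matches take a fast path.
correct_barcodes <- function(obs, refs, max_mismatch) {
  idx <- match(obs, refs)
  if (max_mismatch == 0 || !anyNA(idx)) return(idx)
  todo <- unique(obs[is.na(idx)])
  ref_raw <- lapply(refs, charToRaw)
  corr <- vapply(todo, function(s) {
    sr <- charToRaw(s)
    if (length(sr) != length(ref_raw[[1]])) return(NA_integer_)
    d <- vapply(ref_raw, function(r) sum(r != sr), integer(1))
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1) hit else NA_integer_
  }, integer(1))
  fix <- is.na(idx)
  idx[fix] <- corr[match(obs[fix], todo)]
  idx
}

#' Tabulate tag UMI counts from paired FASTQ files
#'
#' Reads a paired tag-library FASTQ (read 1: cell barcode + UMI; read 2: tag
#' barcode), corrects tag barcodes (and optionally cell barcodes against a
#' whitelist) allowing up to `layout$max_mismatch` mismatches to a unique
#' reference, collapses duplicate (cell barcode, UMI, tag) triplets to single
#' UMIs, and tabulates a sparse cells x tags count matrix.
#'
#' @param r1_path,r2_path Paths to the paired FASTQ(.gz) files.
#' @param tags A [tag_reference()].
#' @param whitelist Optional character vector of valid cell barcodes; reads
#'   whose barcode cannot be corrected to a unique whitelist entry are
#'   discarded.
#' @param layout A [read_layout()]; `tag_len` defaults to the reference
#'   barcode length.
#' @return List with `counts` (sparse cells x tags matrix) and `summary`
#'   (named vector: total, discarded_tag, discarded_cell, kept, umis).
#' @export
count_tags_from_fastq <- function(r1_path, r2_path, tags,
                                  whitelist = NULL,
                                  layout = read_layout()) {
  if (!inherits(tags, "tag_reference")) stop("'tags' must be a tag_reference")
  stopifnot(inherits(layout, "read_layout"))
  r1 <- as.character(Biostrings::readDNAStringSet(r1_path, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(r2_path, format = "fastq"))
  if (length(r1) != length(r2))
    stop("paired FASTQ files have different read counts")
  tag_len <- if (is.null(layout$tag_len)) nchar(tags[1]) else layout$tag_len
  n_total <- length(r1)
  smry <- c(total = n_total, discarded_tag = 0L, discarded_cell = 0L,
            kept = 0L, umis = 0L)
  tag_names <- names(tags)
  if (n_total == 0) {
    counts <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(0L, length(tags)),
      dimnames = list(character(0), tag_names))
    return(list(counts = counts, summary = smry))
  }
  if (any(nchar(r1) < layout$umi_start + layout$umi_len - 1L) ||
      any(nchar(r2) < layout$tag_start + tag_len - 1L))
    stop("layout spans exceed read lengths")

  cb <- substr(r1, layout$cb_start, layout$cb_start + layout$cb_len - 1L)
  umi <- substr(r1, layout$umi_start, layout$umi_start + layout$umi_len - 1L)
  tg <- substr(r2, layout$tag_start, layout$tag_start + tag_len - 1L)

  tag_idx <- correct_barcodes(tg, unname(unclass(tags)), layout$max_mismatch)
  keep <- !is.na(tag_idx)
  smry["discarded_tag"] <- sum(!keep)
  if (!is.null(whitelist)) {
    cb_idx <- correct_barcodes(cb, whitelist, layout$max_mismatch)
    drop_cb <- keep & is.na(cb_idx)
    smry["discarded_cell"] <- sum(drop_cb)
    keep <- keep & !is.na(cb_idx)
    cb[keep] <- whitelist[cb_idx[keep]]
  }
  smry["kept"] <- sum(keep)

  cb <- cb[keep]; umi <- umi[keep]; tag_idx <- tag_idx[keep]
  trip <- paste(cb, umi, tag_idx, sep = "\r")
  first <- !duplicated(trip)
  cb <- cb[first]; tag_idx <- tag_idx[first]
  smry["umis"] <- sum(first)

  cells <- sort(unique(cb))
  counts <- Matrix::sparseMatrix(
    i = match(cb, cells), j = tag_idx, x = rep(1, length(cb)),
    dims = c(length(cells), length(tags)),
    dimnames = list(cells, tag_names))
  list(counts = counts, summary = smry)
}
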