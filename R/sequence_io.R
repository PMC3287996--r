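#' ATG-anchored DNA sequence
#'
#' A DNA sequence carrying the position of the `A` of the translation-start
#' ATG, which defines the ATG-relative coordinate frame used throughout the
#' package: position `+1` is the `A` itself, `-1` the base immediately 5' of
#' it, and there is no position 0.  Upstream-only records anchor the ATG one
#' base past the 3' end (`atg_index = nchar + 1`).
#'
#' @param residues DNA string over `A,C,G,T,N` (lowercase accepted).
#' @param species_id short species label (e.g. `"human"`).
#' @param record_id free-text record identifier; defaults to `species_id`.
#' @param atg_index 1-based index of the `A` of the start ATG within
#'   `residues`, in `[1, nchar + 1]`; default `nchar + 1` (all positions
#'   upstream).
#' @return an object of class `anchored_seq`.
#' @examples
#' s <- anchored_seq("ccATGaa", "human", atg_index = 3)
#' atg_to_index(s, -1)   # 2
#' @export
anchored_seq <- function(residues, species_id, record_id = species_id,
                         atg_index = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty sequence for record '", record_id, "'")
  assert_dna(residues, paste0("record '", record_id, "'"))
  n <- nchar(residues)
  atg_index <- as.integer(atg_index %||% (n + 1L))
  if (is.na(atg_index) || atg_index < 1L || atg_index > n + 1L)
    stop("atg_index must be in [1, length + 1] for record '", record_id, "'")
  structure(list(species_id = as.character(species_id),
                 record_id = as.character(record_id),
                 residues = residues, atg_index = atg_index),
            class = "anchored_seq")
}

#' @export
print.anchored_seq <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<anchored_seq> %s (%s): %d bp, ATG at index %s\n",
              x$species_id, x$record_id, n,
              if (x$atg_index > n) "end (all upstream)" else x$atg_index))
  invisible(x)
}

seq_length <- function(seq) nchar(seq$residues)

#' Convert ATG-relative positions to string indices
#'
#' Position `+1` is the `A` of the start ATG, `-1` the base immediately 5'
#' of it; there is no position 0.  `index_to_atg` is the exact inverse.
#'
#' @param seq an [anchored_seq()].
#' @param pos integer vector of non-zero ATG-relative positions.
#' @param idx integer vector of 1-based string indices.
#' @return integer vector of 1-based string indices (or ATG-relative
#'   positions for `index_to_atg`).
#' @export
atg_to_index <- function(seq, pos) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) stop("ATG-relative position 0 does not exist")
  idx <- seq$atg_index + pos - as.integer(pos > 0L)
  n <- seq_length(seq)
  if (any(idx < 1L | idx > n))
    stop("ATG-relative position out of range for '", seq$species_id, "'")
  idx
}

#' @rdname atg_to_index
#' @export
index_to_atg <- function(seq, idx) {
  idx <- as.integer(idx)
  n <- seq_length(seq)
  if (any(idx < 1L | idx > n)) stop("string index out of range")
  d <- idx - seq$atg_index
  ifelse(d >= 0L, d + 1L, d)
}

# map ATG positions onto a contiguous integer axis (-k.. -1, 0, 1, ..) so
# interval arithmetic never has to special-case the missing position 0
atg_to_axis <- function(pos) ifelse(pos > 0L, pos - 1L, pos)
axis_to_atg <- function(ax) as.integer(ifelse(ax >= 0L, ax + 1L, ax))

#' ATG-relative interval
#'
#' Closed interval in ATG-relative coordinates, stored canonically as
#' `low <= high` in 5'->3' order.  Rendering follows the field's
#' downstream-end-first style: the endpoint closer to (or past) the ATG is
#' printed first, e.g. `-57 to -284` or `+97 to -259`.
#'
#' @param low,high non-zero ATG-relative endpoints, `low <= high`.
#' @return an object of class `atg_interval`.
#' @export
atg_interval <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  if (low == 0L || high == 0L) stop("ATG-relative endpoints cannot be 0")
  if (low > high) stop("interval endpoints must satisfy low <= high")
  structure(list(low = low, high = high), class = "atg_interval")
}

#' @export
format.atg_interval <- function(x, ...) {
  fmt <- function(p) if (p > 0) paste0("+", p) else as.character(p)
  paste(fmt(x$high), "to", fmt(x$low))
}

#' @export
print.atg_interval <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Length in bases of an ATG-relative interval
#'
#' @param low,high non-zero ATG-relative endpoints, `low <= high`.
#' @return integer number of bases covered (no base exists at position 0).
#' @export
atg_span_length <- function(low, high) {
  atg_to_axis(as.integer(high)) - atg_to_axis(as.integer(low)) + 1L
}

#' Read ATG-anchored sequences from FASTA
#'
#' Record headers may carry the anchor as a `atg=<int>` tag (1-based index
#' of the `A` of the start ATG), e.g. `>human atg=15001`.  Anchors can also
#' be supplied as a named integer vector; records without either use the
#' end-of-record default (all positions upstream).  Lowercase input is
#' upcased; characters outside `A,C,G,T,N` are rejected.
#'
#' @param path path to a FASTA file.
#' @param anchors optional named integer vector of per-record ATG indices
#'   (names = first header token).
#' @return named list of [anchored_seq()] objects, one per record.
#' @export
read_anchored_fasta <- function(path, anchors = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    tag <- regmatches(header, regexpr("atg=[0-9]+", header))
    atg <- if (length(tag)) as.integer(sub("atg=", "", tag))
           else if (!is.null(anchors) && id %in% names(anchors)) anchors[[id]]
           else NULL
    anchored_seq(as.character(set[[i]]), species_id = id, record_id = header,
                 atg_index = atg)
  })
  names(out) <- vapply(out, `[[`, character(1), "species_id")
  out
}

#' Write ATG-anchored sequences to FASTA
#'
#' The anchor is carried in the header as an `atg=<int>` tag so that
#' [read_anchored_fasta()] round-trips exactly.
#'
#' @param seqs list of [anchored_seq()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_anchored_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- vapply(seqs, function(s)
    sprintf("%s atg=%d", s$species_id, s$atg_index), character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' Converts ATG-relative intervals to the BED standard (0-based, half-open)
#' on the anchored sequence's own coordinate axis.  Conserved-region tables
#' put the species-support string in the name column and `identity * 1000`
#' in the score column; motif-hit tables put the matrix id in the name
#' column and the log2 likelihood ratio scaled to 0-1000 (relative to the
#' table maximum) in the score column.  Rows are sorted by start, then name.
#'
#' @param regions data frame with `low`/`high` ATG-relative columns, either
#'   a conserved-region table (columns `species`, `mean_identity`) or a
#'   motif-hit table (columns `matrix_id`, `log2_ratio`, optional `strand`).
#' @param seq the reference [anchored_seq()] the intervals live on.
#' @param path output path.
#' @param genomic_offset optional integer added to both BED coordinates
#'   (e.g. the genomic start of the extracted sequence).
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, seq, path, genomic_offset = 0L) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  start0 <- vapply(regions$low, function(p) atg_to_index(seq, p), integer(1)) - 1L
  end0 <- vapply(regions$high, function(p) atg_to_index(seq, p), integer(1))
  if (!is.null(regions$matrix_id)) {
    nm <- regions$matrix_id
    top <- max(abs(regions$log2_ratio), 1e-9)
    score <- pmax(0L, pmin(1000L, as.integer(round(1000 * regions$log2_ratio / top))))
    strand <- regions$strand %||% rep(".", nrow(regions))
  } else {
    nm <- gsub("[ \t]", "", regions$species)
    score <- pmax(0L, pmin(1000L, as.integer(round(1000 * regions$mean_identity))))
    strand <- rep(".", nrow(regions))
  }
  bed <- data.frame(chrom = seq$species_id,
                    chromStart = start0 + as.integer(genomic_offset),
                    chromEnd = end0 + as.integer(genomic_offset),
                    name = nm, score = score, strand = strand,
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$chromStart, bed$name), , drop = FALSE]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path path to a 6-column BED file (no header).
#' @return data frame with columns `chrom`, `chromStart`, `chromEnd`,
#'   `name`, `score`, `strand`; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand")
  if (file.size(path) == 0)
    return(stats::setNames(data.frame(character(), integer(), integer(),
                                      character(), integer(), character(),
                                      stringsAsFactors = FALSE), cols))
  bed <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(bed[, 1:6], cols)
}

# convert a BED row back to ATG coordinates on `seq`
bed_to_atg <- function(bed, seq, genomic_offset = 0L) {
  data.frame(low = index_to_atg(seq, bed$chromStart + 1L - genomic_offset),
             high = index_to_atg(seq, bed$chromEnd - genomic_offset),
             name = bed$name, stringsAsFactors = FALSE)
}
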