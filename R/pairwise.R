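#' Seed-and-extend gapped local alignments between two anchored sequences
#'
#' BLAST-style same-strand local search: exact-match word seeding, X-drop
#' ungapped extension, then banded affine-gap extension anchored at the
#' seed.  Retained alignments have `E <= scheme$e_max` with
#' `E = K * m * n * exp(-lambda * S)` computed on the raw sequence lengths.
#' Results are deterministic, sorted by query start then descending score.
#'
#' @param query,subject [anchored_seq()] objects; `query` is the reference
#'   species whose coordinates downstream steps use.
#' @param scheme a [scoring_scheme()].
#' @param seed_word exact-match word size for seeding (>= 4; 11 is the
#'   classic nucleotide default).
#' @param composition base composition for the E-value statistics
#'   (default uniform).
#' @param band half-width of the gapped-extension band around the seed
#'   diagonal.
#' @param xdrop X-drop for the ungapped extension stage.
#' @param xdrop_gap X-drop for the gapped extension stage.
#' @param gap_trigger minimum ungapped score to trigger gapped extension;
#'   defaults to `seed_word * match_score`.
#' @param ka optional precomputed [karlin_altschul_params()].
#' @return data frame with one row per alignment: `query_species`,
#'   `subject_species`, ATG-relative intervals `q_low`,`q_high`,`s_low`,
#'   `s_high`, `score`, `identity` (identities over all alignment columns,
#'   gaps in the denominator), `e_value`, and the gapped strings
#'   `aligned_query`, `aligned_subject`.
#' @export
find_local_alignments <- function(query, subject, scheme = scoring_scheme(),
                                  seed_word = 11L, composition = NULL,
                                  band = 40L, xdrop = 20L, xdrop_gap = 50L,
                                  gap_trigger = NULL, ka = NULL) {
  stopifnot(inherits(query, "anchored_seq"), inherits(subject, "anchored_seq"))
  seed_word <- as.integer(seed_word)
  if (seed_word < 4L) stop("seed_word must be >= 4")
  empty <- data.frame(query_species = character(), subject_species = character(),
                      q_low = integer(), q_high = integer(),
                      s_low = integer(), s_high = integer(),
                      score = integer(), identity = numeric(),
                      e_value = numeric(), aligned_query = character(),
                      aligned_subject = character(), stringsAsFactors = FALSE)
  m <- seq_length(query); n <- seq_length(subject)
  if (m < seed_word || n < seed_word) {
    message("sequence shorter than seed word; no alignments for ",
            query$species_id, " vs ", subject$species_id)
    return(empty)
  }
  composition <- composition %||% stats::setNames(rep(0.25, 4), DNA_BASES)
  ka <- ka %||% karlin_altschul_params(scheme, composition)
  gap_trigger <- as.integer(gap_trigger %||% (seed_word * scheme$match_score))
  hits <- seed_extend_cpp(query$residues, subject$residues,
                          scheme$match_score, scheme$mismatch_score,
                          scheme$gap_open, scheme$gap_extend,
                          seed_word, as.integer(xdrop), as.integer(band),
                          gap_trigger, as.integer(xdrop_gap))
  if (nrow(hits) == 0L) return(empty)
  ev <- evalue(hits$score, m, n, ka)
  keep <- ev <= scheme$e_max
  hits <- hits[keep, , drop = FALSE]
  ev <- ev[keep]
  if (nrow(hits) == 0L) return(empty)
  out <- data.frame(
    query_species = query$species_id, subject_species = subject$species_id,
    q_low = index_to_atg(query, hits$q_start),
    q_high = index_to_atg(query, hits$q_end),
    s_low = index_to_atg(subject, hits$s_start),
    s_high = index_to_atg(subject, hits$s_end),
    score = hits$score, identity = hits$n_ident / hits$n_cols,
    e_value = ev, aligned_query = hits$aligned_query,
    aligned_subject = hits$aligned_subject, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percent identity of a gapped alignment
#'
#' Identities divided by the total number of alignment columns; gap
#' columns count in the denominator, and `N` never counts as an identity.
#'
#' @param aligned_a,aligned_b gapped strings of equal length, or a data
#'   frame with `aligned_query`/`aligned_subject` columns as first
#'   argument.
#' @return numeric fraction(s) in `[0, 1]`.
#' @export
percent_identity <- function(aligned_a, aligned_b = NULL) {
  if (is.data.frame(aligned_a)) {
    return(mapply(percent_identity, aligned_a$aligned_query,
                  aligned_a$aligned_subject, USE.NAMES = FALSE))
  }
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("gapped strings must have equal length")
  if (nchar(aligned_a) == 0L) stop("empty alignment")
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  sum(a == b & a != "-" & a != "N") / length(a)
}

#' Conserved-region calling criteria
#'
#' A region is called where alignments of at least `min_identity` identity
#' stack up over at least `min_species` species (the reference counts as
#' one of them), runs separated by at most `merge_gap` bases are merged,
#' and merged runs shorter than `min_length` are discarded.  The defaults
#' are the stringent footprinting rule: >80% identity, >=100 bp, >=4 of
#' the compared species.
#'
#' @param min_identity minimum per-alignment identity fraction.
#' @param min_length minimum region length in bases.
#' @param min_species minimum number of supporting species, reference
#'   included.
#' @param merge_gap maximum gap (bases) between runs that are stitched
#'   together before the length filter.
#' @return an object of class `conservation_criteria`.
#' @export
conservation_criteria <- function(min_identity = 0.80, min_length = 100L,
                                  min_species = 4L, merge_gap = 25L) {
  if (!(min_identity > 0 && min_identity <= 1)) stop("min_identity in (0,1]")
  if (min_length < 1L) stop("min_length >= 1")
  if (min_species < 2L) stop("min_species >= 2")
  if (merge_gap < 0L) stop("merge_gap >= 0")
  structure(list(min_identity = min_identity,
                 min_length = as.integer(min_length),
                 min_species = as.integer(min_species),
                 merge_gap = as.integer(merge_gap)),
            class = "conservation_criteria")
}

#' Call conserved regions from per-species local alignments
#'
#' For every non-reference species, reference positions covered by an
#' alignment with identity at least `criteria$min_identity` are marked;
#' the per-position support is 1 (the reference itself) plus the number of
#' marked species.  Maximal runs with support `>= min_species` are
#' extracted, runs separated by at most `merge_gap` bases are merged, and
#' merged runs shorter than `min_length` are dropped.  `mean_identity` is
#' the coverage-weighted mean identity of the qualifying alignments
#' overlapping the region.
#'
#' @param reference reference species id (the query species of every
#'   alignment table).
#' @param alignments either a named list (by subject species) of alignment
#'   data frames from [find_local_alignments()], or one combined data
#'   frame with a `subject_species` column.
#' @param criteria a [conservation_criteria()].
#' @return data frame of disjoint regions sorted 5'->3': `low`, `high`
#'   (ATG-relative), `length`, `n_species`, `species` (comma-separated,
#'   reference first), `mean_identity`, `label` (NA; fill downstream).
#' @export
call_conserved_regions <- function(reference, alignments,
                                   criteria = conservation_criteria()) {
  if (is.data.frame(alignments))
    alignments <- split(alignments, alignments$subject_species)
  if (length(alignments) == 0L) stop("empty alignment map")
  aln <- do.call(rbind, c(unname(alignments), list(make.row.names = FALSE)))
  if (nrow(aln) > 0 && !all(aln$query_species == reference))
    stop("alignments do not all use reference species '", reference, "'")
  empty <- data.frame(low = integer(), high = integer(), length = integer(),
                      n_species = integer(), species = character(),
                      mean_identity = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  aln <- aln[aln$identity >= criteria$min_identity, , drop = FALSE]
  if (nrow(aln) == 0L) return(empty)

  lo <- min(atg_to_axis(aln$q_low)); hi <- max(atg_to_axis(aln$q_high))
  width <- hi - lo + 1L
  species <- sort(unique(aln$subject_species))
  support <- integer(width)
  marks <- list()
  for (sp in species) {
    rows <- aln[aln$subject_species == sp, , drop = FALSE]
    mk <- logical(width)
    for (r in seq_len(nrow(rows)))
      mk[(atg_to_axis(rows$q_low[r]) - lo + 1L):(atg_to_axis(rows$q_high[r]) - lo + 1L)] <- TRUE
    marks[[sp]] <- mk
    support <- support + mk
  }
  ok <- support + 1L >= criteria$min_species
  if (!any(ok)) return(empty)
  runs <- rle_runs(ok)
  runs <- merge_runs(runs, criteria$merge_gap)
  runs <- runs[runs$end - runs$start + 1L >= criteria$min_length, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  out <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs$start[i]; b <- runs$end[i]          # axis offsets (1-based in window)
    sup <- names(Filter(function(mk) any(mk[a:b]), marks))
    # coverage-weighted mean identity over qualifying alignments
    ax_lo <- lo + a - 1L; ax_hi <- lo + b - 1L
    ov_lo <- pmax(atg_to_axis(aln$q_low), ax_lo)
    ov_hi <- pmin(atg_to_axis(aln$q_high), ax_hi)
    w <- pmax(0L, ov_hi - ov_lo + 1L)
    mid <- sum(w * aln$identity) / sum(w)
    data.frame(low = axis_to_atg(ax_lo), high = axis_to_atg(ax_hi),
               length = b - a + 1L, n_species = length(sup) + 1L,
               species = paste(c(reference, sort(sup)), collapse = ","),
               mean_identity = mid, label = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$low), , drop = FALSE]
}

# maximal TRUE runs of a logical vector, as 1-based start/end offsets
rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# merge runs whose gap is <= merge_gap
merge_runs <- function(runs, merge_gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] - 1L <= merge_gap)
      out$end[nrow(out)] <- runs$end[i]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}
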