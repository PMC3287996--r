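# independent oracles and fixture builders used across the suite

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random pair of sequences sharing a planted exact core, so the optimal
# local alignment is guaranteed to contain a seedable exact match
rand_pair_with_core <- function(nmin = 10, nmax = 25, core_min = 6, core_max = 12) {
  core <- rand_dna(sample(core_min:core_max, 1))
  mk <- function(n) {
    l <- sample(0:max(0, n - nchar(core)), 1)
    r <- max(0, n - nchar(core) - l)
    paste0(rand_dna(l), core, rand_dna(r))
  }
  list(a = mk(sample(nmin:nmax, 1)), b = mk(sample(nmin:nmax, 1)))
}

# exhaustive affine-gap Smith-Waterman score via Biostrings (independent
# full-DP implementation; gap of length L costs gapOpening + L*gapExtension)
sw_oracle_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)))
}

# best score reported by the package aligner with search heuristics opened
# wide (full band, no X-drop truncation, no E-value filtering)
aligner_best_score <- function(a, b, seed_word = 4) {
  al <- find_local_alignments(
    anchored_seq(a, "q"), anchored_seq(b, "s"),
    scoring_scheme(e_max = 1e12, expect_threshold = 1e12),
    seed_word = seed_word, band = max(nchar(a), nchar(b)),
    xdrop = 10000, xdrop_gap = 10000, gap_trigger = seed_word)
  if (nrow(al)) max(al$score) else 0
}

# brute-force per-position conserved-region caller: an independent
# re-implementation of the support-counting rule on the ATG axis
brute_conserved_regions <- function(alignments, criteria) {
  aln <- do.call(rbind, c(unname(alignments), list(make.row.names = FALSE)))
  aln <- aln[aln$identity >= criteria$min_identity, , drop = FALSE]
  if (nrow(aln) == 0) return(data.frame(low = integer(), high = integer(),
                                        n_species = integer()))
  ax <- function(p) ifelse(p > 0, p - 1L, p)
  unax <- function(a) as.integer(ifelse(a >= 0, a + 1L, a))
  positions <- min(ax(aln$q_low)):max(ax(aln$q_high))
  support <- vapply(positions, function(p) {
    sp <- unique(aln$subject_species[ax(aln$q_low) <= p & ax(aln$q_high) >= p])
    length(sp) + 1L
  }, integer(1))
  ok <- support >= criteria$min_species
  if (!any(ok)) return(data.frame(low = integer(), high = integer(),
                                  n_species = integer()))
  # maximal runs
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge
  i <- 1
  while (i < nrow(runs)) {
    if (runs$start[i + 1] - runs$end[i] - 1L <= criteria$merge_gap) {
      runs$end[i] <- runs$end[i + 1]
      runs <- runs[-(i + 1), , drop = FALSE]
    } else i <- i + 1
  }
  runs <- runs[runs$end - runs$start + 1L >= criteria$min_length, , drop = FALSE]
  if (nrow(runs) == 0) return(data.frame(low = integer(), high = integer(),
                                         n_species = integer()))
  data.frame(low = unax(positions[runs$start]),
             high = unax(positions[runs$end]),
             n_species = vapply(seq_len(nrow(runs)), function(i) {
               span <- positions[runs$start[i]]:positions[runs$end[i]]
               sp <- unique(aln$subject_species[
                 ax(aln$q_low) <= max(span) & ax(aln$q_high) >= min(span)])
               length(sp) + 1L
             }, integer(1)))
}

# build a minimal alignment table row for region-calling tests (only the
# columns the caller consumes)
aln_row <- function(ref, sp, q_low, q_high, identity = 1) {
  data.frame(query_species = ref, subject_species = sp,
             q_low = q_low, q_high = q_high,
             s_low = q_low, s_high = q_high,
             score = q_high - q_low + 1L, identity = identity,
             e_value = 1e-10, aligned_query = "", aligned_subject = "",
             stringsAsFactors = FALSE)
}

# a sharp (near-deterministic) PWM whose sampled instances equal the
# consensus: single-site counts with zero pseudocount
sharp_pwm <- function(consensus, id = "SHARP") {
  M <- matrix(0, 4, nchar(consensus), dimnames = list(c("A", "C", "G", "T")))
  ch <- strsplit(consensus, "")[[1]]
  M[cbind(match(ch, rownames(M)), seq_along(ch))] <- 12
  pwm(M, matrix_id = id, name = id, pseudocount = 0)
}

# random count PWM (used for null-calibration tests)
rand_pwm <- function(width = 6, total = 20, id = "RND") {
  M <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_len(width)) M[, j] <- as.vector(stats::rmultinom(1, total, rep(0.25, 4)))
  pwm(M, matrix_id = id, name = id, pseudocount = 0.25)
}
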