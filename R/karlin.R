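#' Local-alignment scoring scheme
#'
#' Match/mismatch scores and affine gap penalties for the pairwise scans,
#' plus the E-value thresholds used during search and reporting.  A gap of
#' length L costs `gap_open + gap_extend * L`.  The defaults are the
#' classic nucleotide settings for cross-species non-coding scans:
#' +1/-2 with gap existence 5 and extension 2, alignments reported when
#' their E-value is at most `e_max`.
#'
#' @param match_score positive integer match score.
#' @param mismatch_score negative integer mismatch score.
#' @param gap_open non-negative gap-existence penalty.
#' @param gap_extend non-negative per-base gap-extension penalty.
#' @param e_max E-value ceiling for retained alignments.
#' @param expect_threshold E-value reporting threshold used during search;
#'   must be at least `e_max`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match_score = 1L, mismatch_score = -2L,
                           gap_open = 5L, gap_extend = 2L,
                           e_max = 0.001, expect_threshold = 10) {
  match_score <- as.integer(match_score)
  mismatch_score <- as.integer(mismatch_score)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (!(match_score > 0L && mismatch_score < 0L))
    stop("need match_score > 0 > mismatch_score")
  if (!(gap_open >= gap_extend && gap_extend >= 0L))
    stop("need gap_open >= gap_extend >= 0")
  if (!(e_max > 0 && e_max <= expect_threshold))
    stop("need 0 < e_max <= expect_threshold")
  structure(list(match_score = match_score, mismatch_score = mismatch_score,
                 gap_open = gap_open, gap_extend = gap_extend,
                 e_max = e_max, expect_threshold = expect_threshold),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> match %+d / mismatch %+d, gap %d + %d per base, E <= %g\n",
    x$match_score, x$mismatch_score, x$gap_open, x$gap_extend, x$e_max))
  invisible(x)
}

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, located by root bracketing and
#' polished by Newton steps to a residual below 1e-12.  The prefactor `K`
#' is computed numerically from the score random walk by renewal theory:
#' the density of strict descending ladder points, `theta`, times the
#' first-passage probability `h(y)` that an excursion climbs to height `y`
#' before dropping below its origin (solved as a linear system), gives
#' `K = theta * h(y) * exp(lambda * y)` in the large-`y` limit.  The method
#' assumes the ungapped regime; the same `K` is reused for gapped scores
#' (a documented simplification).
#'
#' @param scheme a [scoring_scheme()].
#' @param composition named base frequencies (`A,C,G,T`), summing to 1,
#'   all positive; the probability that two random letters match is
#'   `sum(composition^2)`.
#' @return object of class `ka_params` with elements `lambda`, `k_const`,
#'   `background`, `scheme`.
#' @export
karlin_altschul_params <- function(scheme,
                                   composition = stats::setNames(rep(0.25, 4), DNA_BASES)) {
  if (abs(sum(composition) - 1) > 1e-8 || any(composition <= 0))
    stop("composition must be positive and sum to 1")
  p_match <- sum(composition^2)
  p_mis <- 1 - p_match
  s1 <- scheme$match_score; s2 <- scheme$mismatch_score
  escore <- p_match * s1 + p_mis * s2
  if (escore >= 0)
    stop("degenerate scheme: expected score must be negative for ",
         "Karlin-Altschul statistics")
  f <- function(l) p_match * exp(l * s1) + p_mis * exp(l * s2) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  # Newton polish
  fp <- function(l) p_match * s1 * exp(l * s1) + p_mis * s2 * exp(l * s2)
  for (i in 1:8) lambda <- lambda - f(lambda) / fp(lambda)
  k_const <- ka_kconst(s1, s2, p_match, lambda)
  structure(list(lambda = lambda, k_const = k_const,
                 background = composition, scheme = scheme),
            class = "ka_params")
}

# Numeric K for the two-valued score walk (match s1 > 0 > mismatch s2):
#   theta  = P(the walk stays < 0 forever)  [ladder-point density]
#   h(y)   = P(reach height >= y before dropping below 0)
#   K      = theta * h(y) * exp(lambda * y) for large y (averaged over a
#            tail of y values; the product converges geometrically).
ka_kconst <- function(s1, s2, p_match, lambda) {
  p_mis <- 1 - p_match
  H <- 600L  # height truncation for the killed walk
  # --- theta: iterate the height distribution of the walk killed at >= 0
  d <- numeric(H)            # d[k] = P(alive, height = -k)
  if (s2 < 0) d[-s2] <- p_mis
  dead_low <- 0              # mass absorbed below -H: can de facto never return
  for (it in 1:5000) {
    dn <- numeric(H)
    # up move by s1
    up <- seq_len(H)[seq_len(H) > s1]
    dn[up - s1] <- dn[up - s1] + p_match * d[up]
    # mass moving to >= 0 is killed (returned), i.e. dropped from `dn`
    # down move by |s2|
    idx <- seq_len(H)
    tgt <- idx - s2
    ok <- tgt <= H
    dn[tgt[ok]] <- dn[tgt[ok]] + p_mis * d[idx[ok]]
    dead_low <- dead_low + p_mis * sum(d[idx[!ok]])
    if (sum(abs(dn - d)) < 1e-15) { d <- dn; break }
    d <- dn
  }
  theta <- sum(d) + dead_low
  # --- h(y): linear system over heights 0..y-1
  hvals <- vapply(40:60, function(y) {
    A <- diag(y)
    b <- numeric(y)
    for (l in 0:(y - 1)) {
      # up step
      if (l + s1 >= y) b[l + 1] <- b[l + 1] + p_match
      else A[l + 1, l + s1 + 1] <- A[l + 1, l + s1 + 1] - p_match
      # down step
      if (l + s2 >= 0) A[l + 1, l + s2 + 1] <- A[l + 1, l + s2 + 1] - p_mis
      # (below 0: failure, contributes nothing)
    }
    h <- solve(A, b)
    h[1] * exp(lambda * y)
  }, numeric(1))
  theta * mean(hvals)
}

#' @export
print.ka_params <- function(x, ...) {
  cat(sprintf("<ka_params> lambda = %.6f, K = %.4f\n", x$lambda, x$k_const))
  invisible(x)
}

#' E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between random sequences of the raw
#' (uncorrected) lengths `m` and `n`.
#'
#' @param score raw alignment score (vectorised).
#' @param m,n raw query and subject lengths.
#' @param ka a [karlin_altschul_params()] object.
#' @return numeric vector of E-values.
#' @export
evalue <- function(score, m, n, ka) {
  ka$k_const * as.numeric(m) * as.numeric(n) * exp(-ka$lambda * score)
}
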