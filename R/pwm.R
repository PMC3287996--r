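#' Position weight matrix
#'
#' Per-column base counts with a pseudocount, from which the probability
#' matrix `f_j(b) = (count + pseudocount) / (colsum + 4 * pseudocount)` is
#' derived.  `N` in a scanned sequence scores at the pseudocount floor
#' `pseudocount / (colsum + 4 * pseudocount)`, i.e. like a base never seen
#' in the motif.
#'
#' @param counts 4 x W numeric matrix of base counts (rows `A,C,G,T`) or
#'   probabilities.
#' @param matrix_id matrix identifier (e.g. a database accession).
#' @param name factor name.
#' @param pseudocount per-cell pseudocount added to counts (default 0.25).
#' @return an object of class `pwm`.
#' @export
pwm <- function(counts, matrix_id, name = matrix_id, pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 1L) stop("motif width must be >= 1")
  if (any(counts < 0)) stop("negative counts")
  rownames(counts) <- DNA_BASES
  csum <- colSums(counts)
  if (any(csum + 4 * pseudocount <= 0)) stop("zero-sum column without pseudocount")
  probs <- sweep(counts + pseudocount, 2, csum + 4 * pseudocount, "/")
  floorp <- pseudocount / (csum + 4 * pseudocount)
  structure(list(matrix_id = matrix_id, name = name,
                 width = ncol(counts), counts = counts,
                 pseudocount = pseudocount, probs = probs,
                 n_floor = floorp),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(DNA_BASES[apply(x$probs, 2, which.max)], collapse = "")
  cat(sprintf("<pwm> %s (%s), width %d, consensus %s\n",
              x$matrix_id, x$name, x$width, cons))
  invisible(x)
}

#' Load PWMs from a JASPAR-format file
#'
#' Parses the JASPAR text format: a `>ID name` header followed by four
#' count rows `A [ 1 2 3 ]` (brackets optional).
#'
#' @param path file path.
#' @param pseudocount per-cell pseudocount (default 0.25).
#' @return named list of [pwm()] objects (names = matrix ids).
#' @export
load_pwms <- function(path, pseudocount = 0.25) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no matrices found in ", path)
  out <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L) stop("malformed matrix block in ", path)
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]]
    rows <- lapply(DNA_BASES, function(b) {
      ln <- block[grepl(paste0("^\\s*", b, "\\b"), block)]
      if (length(ln) != 1L) stop("malformed matrix block for base ", b)
      stripped <- sub("^\\s*[ACGT]", "", ln)
      as.numeric(regmatches(stripped, gregexpr("[0-9.]+", stripped))[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L || w < 1L) stop("ragged matrix in ", path)
    pwm(do.call(rbind, rows), matrix_id = hdr[1],
        name = if (length(hdr) > 1L) hdr[2] else hdr[1],
        pseudocount = pseudocount)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "matrix_id"))
}

#' Write PWMs in JASPAR format
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$matrix_id, p$name), con)
    for (b in DNA_BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

#' Background model for motif statistics
#'
#' @param composition named base probabilities (`A,C,G,T`), all positive,
#'   summing to 1; default uniform.
#' @param sequences optional character vector of background DNA sequences
#'   used for length-matched fragment resampling.
#' @return an object of class `motif_background`.
#' @export
background <- function(composition = stats::setNames(rep(0.25, 4), DNA_BASES),
                       sequences = NULL) {
  composition <- composition[DNA_BASES]
  if (abs(sum(composition) - 1) > 1e-8 || any(composition <= 0))
    stop("composition must be positive over A,C,G,T and sum to 1")
  if (!is.null(sequences)) sequences <- toupper(sequences)
  structure(list(composition = composition, sequences = sequences),
            class = "motif_background")
}

# log2-odds matrix including the N floor row (5 x W)
pwm_log_odds <- function(pwm, bg) {
  q <- bg$composition
  lo <- log2(sweep(pwm$probs, 1, q, "/"))
  nrow <- log2(pwm$n_floor / 0.25)   # N: pseudocount floor over flat background
  rbind(lo, N = nrow)
}

# per-window log2 likelihood ratios of one strand
window_scores <- function(codes, LO) {
  W <- ncol(LO)
  n <- length(codes) - W + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(W)) sc <- sc + LO[cbind(codes[j:(j + n - 1L)], j)]
  sc
}

#' Scan a sequence with a PWM
#'
#' Both strands are scanned; a window is a hit when its log2-odds score is
#' at least `threshold` times the maximum achievable log2-odds (when that
#' maximum is not positive, only windows attaining it exactly are hits).
#' Minus-strand hits are reported on the same coordinates as the forward
#' window they cover.
#'
#' @param seq an [anchored_seq()] or a plain DNA string.
#' @param pwm a [pwm()].
#' @param bg a [background()].
#' @param threshold fraction of the maximum log2-odds (default 0.80).
#' @return data frame of hits sorted by position: `matrix_id`, `start`,
#'   `end` (1-based in the scanned sequence), `strand`, `log2_ratio`,
#'   `lr` (likelihood ratio), and ATG-relative `low`/`high` when the
#'   input is anchored.
#' @export
scan_pwm <- function(seq, pwm, bg = background(), threshold = 0.80) {
  anchored <- inherits(seq, "anchored_seq")
  s <- if (anchored) seq$residues else toupper(seq)
  W <- pwm$width
  empty <- data.frame(matrix_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      log2_ratio = numeric(), lr = numeric(),
                      stringsAsFactors = FALSE)
  if (anchored) { empty$low <- integer(); empty$high <- integer() }
  if (nchar(s) < W) {
    message("sequence shorter than motif width ", W, "; no hits")
    return(empty)
  }
  codes <- encode_dna_int(s)
  LO <- pwm_log_odds(pwm, bg)
  maxlo <- sum(apply(LO[1:4, , drop = FALSE], 2, max))
  cut <- if (maxlo > 0) threshold * maxlo else maxlo
  fwd <- window_scores(codes, LO)
  # minus strand: reverse-complemented matrix scanned over the forward codes
  LOrc <- LO[c(4, 3, 2, 1, 5), rev(seq_len(W)), drop = FALSE]
  rownames(LOrc) <- rownames(LO)
  rvs <- window_scores(codes, LOrc)
  tol <- 1e-9
  hit_f <- which(fwd >= cut - tol)
  hit_r <- which(rvs >= cut - tol)
  out <- data.frame(
    matrix_id = rep(pwm$matrix_id, length(hit_f) + length(hit_r)),
    start = c(hit_f, hit_r),
    end = c(hit_f, hit_r) + W - 1L,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    log2_ratio = c(fwd[hit_f], rvs[hit_r]),
    stringsAsFactors = FALSE)
  out$lr <- 2^out$log2_ratio
  out <- out[order(out$start, out$strand), , drop = FALSE]
  if (anchored) {
    out$low <- if (nrow(out)) index_to_atg(seq, out$start) else integer(0)
    out$high <- if (nrow(out)) index_to_atg(seq, out$end) else integer(0)
  }
  rownames(out) <- NULL
  out
}

# likelihood ratios of every window on both strands (natural scale)
all_window_lrs <- function(s, pwm, bg) {
  codes <- encode_dna_int(toupper(s))
  LO <- pwm_log_odds(pwm, bg)
  W <- pwm$width
  LOrc <- LO[c(4, 3, 2, 1, 5), rev(seq_len(W)), drop = FALSE]
  2^c(window_scores(codes, LO), window_scores(codes, LOrc))
}

#' Motif over-representation score of a sequence set
#'
#' For each sequence the likelihood ratio `LR = prod_j f_j(w_j)/q(w_j)` is
#' averaged over every window on both strands (`A_i`); the set-level raw
#' score is `R = sum_i ln A_i`.  Under the background model `E[LR] = 1`,
#' so `R` has zero expectation drift for background-like motifs; positive
#' `R` indicates over-representation.  This is an operationalization of
#' cis-element over-representation scoring against a background, not a
#' re-implementation of any particular published recursion.
#'
#' @param seq_set character vector (or list of [anchored_seq()]) of
#'   sequences, each at least as long as the motif.
#' @param pwm a [pwm()].
#' @param bg a [background()].
#' @return the raw score `R` (numeric scalar).
#' @export
overrepresentation_score <- function(seq_set, pwm, bg = background()) {
  strs <- seq_set_strings(seq_set)
  if (any(nchar(strs) < pwm$width))
    stop("every sequence must be at least motif width (", pwm$width, " bp)")
  sum(vapply(strs, function(s) log(mean(all_window_lrs(s, pwm, bg))),
             numeric(1)))
}

seq_set_strings <- function(seq_set) {
  if (is.character(seq_set)) return(toupper(seq_set))
  vapply(seq_set, function(s)
    if (inherits(s, "anchored_seq")) s$residues else toupper(as.character(s)),
    character(1))
}

#' Randomization p-values for a motif over-representation score
#'
#' Compares the observed raw score against null scores from one or more
#' randomization schemes: `shuffle_sequence` (per-sequence nucleotide
#' shuffles), `shuffle_matrix_columns` (random permutation of PWM
#' columns), `background_fragments` (length-matched fragments resampled
#' from the background sequence set).  p-values use the add-one estimator
#' `p = (1 + #(R_null >= R)) / (1 + n_rand)`, so they are never zero.
#' Fully reproducible given `seed`.
#'
#' @param seq_set sequences as in [overrepresentation_score()].
#' @param pwm a [pwm()].
#' @param bg a [background()]; must carry `sequences` for the
#'   `background_fragments` mode.
#' @param n_rand number of randomizations per mode (>= 100).
#' @param seed integer seed.
#' @param modes character vector of null models to run.
#' @param observed optional precomputed observed score.
#' @return object of class `overrep_result`: `matrix_id`, `raw_score`,
#'   `p_values` (named), `n_rand`, `seed`, `null_scores` (list).
#' @export
pvalues_by_randomization <- function(seq_set, pwm, bg = background(),
                                     n_rand = 1000L, seed = 1L,
                                     modes = c("shuffle_sequence",
                                               "shuffle_matrix_columns"),
                                     observed = NULL) {
  if (n_rand < 100L) stop("n_rand must be >= 100")
  modes <- match.arg(modes, c("shuffle_sequence", "shuffle_matrix_columns",
                              "background_fragments"), several.ok = TRUE)
  if ("background_fragments" %in% modes && is.null(bg$sequences))
    stop("background sequence set required for background_fragments mode")
  strs <- seq_set_strings(seq_set)
  obs <- observed %||% overrepresentation_score(strs, pwm, bg)
  nulls <- withr::with_seed(seed, {
    lapply(stats::setNames(modes, modes), function(mode) {
      vapply(seq_len(n_rand), function(i) {
        switch(mode,
          shuffle_sequence = {
            sh <- vapply(strs, function(s) {
              paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
            }, character(1))
            overrepresentation_score(sh, pwm, bg)
          },
          shuffle_matrix_columns = {
            perm <- sample(pwm$width)
            p2 <- pwm(pwm$counts[, perm, drop = FALSE], pwm$matrix_id,
                      pwm$name, pwm$pseudocount)
            overrepresentation_score(strs, p2, bg)
          },
          background_fragments = {
            frags <- vapply(nchar(strs), function(L) {
              cand <- bg$sequences[nchar(bg$sequences) >= L]
              if (length(cand) == 0L)
                stop("no background sequence of length >= ", L)
              src <- cand[[sample.int(length(cand), 1L)]]
              at <- sample.int(nchar(src) - L + 1L, 1L)
              substr(src, at, at + L - 1L)
            }, character(1))
            overrepresentation_score(frags, pwm, bg)
          })
      }, numeric(1))
    })
  })
  pv <- vapply(nulls, function(ns) (1 + sum(ns >= obs)) / (1 + n_rand),
               numeric(1))
  structure(list(matrix_id = pwm$matrix_id, raw_score = obs,
                 p_values = pv, n_rand = as.integer(n_rand),
                 seed = as.integer(seed), null_scores = nulls),
            class = "overrep_result")
}

#' @export
print.overrep_result <- function(x, ...) {
  cat(sprintf("<overrep_result> %s: R = %.4f\n", x$matrix_id, x$raw_score))
  for (m in names(x$p_values))
    cat(sprintf("  p[%s] = %.4g (n_rand = %d)\n", m, x$p_values[[m]], x$n_rand))
  invisible(x)
}

#' Check whether a point-mutated binding site loses its motif
#'
#' Scans the wild-type and mutant site with the same PWM at the same
#' threshold.  Sites shorter than the motif are padded on both sides with
#' identical uniform-random flanks drawn from a fixed seed, so wild-type
#' and mutant are compared in the same context.
#'
#' @param wt_site,mut_site DNA strings of the wild-type and mutated site.
#' @param pwm a [pwm()].
#' @param bg a [background()].
#' @param threshold hit threshold as in [scan_pwm()].
#' @param flank_seed seed for the shared padding flanks.
#' @return named logical vector `c(wt_detected =, mut_detected =)`.
#' @export
motif_lost_on_mutation <- function(wt_site, mut_site, pwm, bg = background(),
                                   threshold = 0.80, flank_seed = 42L) {
  wt_site <- toupper(wt_site); mut_site <- toupper(mut_site)
  pad <- max(0L, pwm$width - 1L)
  fl <- withr::with_seed(flank_seed, c(random_dna(pad), random_dna(pad)))
  # pad only sites shorter than the motif; longer sites are scanned as-is
  wrap <- function(s) if (nchar(s) < pwm$width) paste0(fl[1], s, fl[2]) else s
  detected <- function(s) nrow(scan_pwm(wrap(s), pwm, bg, threshold)) > 0L
  c(wt_detected = detected(wt_site), mut_detected = detected(mut_site))
}

#' Run the motif-loss check over a wild-type/mutant site table
#'
#' @param table data frame with columns `factor`, `wt`, `mut`.
#' @param pwms named list of [pwm()] objects; each row's `factor` is
#'   matched against the PWM names (case-insensitive prefix match on the
#'   factor name, e.g. `"Sp1"` matches a PWM named `"SP1"`).
#' @param bg a [background()].
#' @param threshold hit threshold as in [scan_pwm()].
#' @return the table with logical columns `wt_detected`, `mut_detected`
#'   and `motif_lost` appended.
#' @export
check_mutation_table <- function(table, pwms, bg = background(),
                                 threshold = 0.80) {
  nm <- toupper(vapply(pwms, `[[`, character(1), "name"))
  pick <- function(fac) {
    hit <- which(startsWith(nm, toupper(gsub("[^A-Za-z0-9]", "", fac))))
    if (length(hit) == 0L)
      hit <- which(startsWith(toupper(gsub("[^A-Za-z0-9]", "", nm)),
                              toupper(gsub("[^A-Za-z0-9]", "", fac))))
    if (length(hit) == 0L) return(NA_integer_)
    hit[1]
  }
  res <- lapply(seq_len(nrow(table)), function(i) {
    k <- pick(table$factor[i])
    if (is.na(k)) return(c(wt_detected = NA, mut_detected = NA))
    motif_lost_on_mutation(table$wt[i], table$mut[i], pwms[[k]], bg, threshold)
  })
  table$wt_detected <- vapply(res, `[`, logical(1), "wt_detected")
  table$mut_detected <- vapply(res, `[`, logical(1), "mut_detected")
  table$motif_lost <- table$wt_detected & !table$mut_detected
  table
}
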