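# PWM loading, scanning, the over-representation statistic, and the
# wild-type/mutant motif-loss check

test_that("PWM regularization follows the pseudocount arithmetic", {
  M <- matrix(c(10, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  expect_equal(unname(pwm(M, "m", pseudocount = 0)$probs["A", 1]), 1)
  p <- pwm(M, "m", pseudocount = 0.25)
  expect_equal(unname(p$probs["A", 1]), 10.25 / 11)
  expect_equal(unname(p$probs["C", 1]), 0.25 / 11)
  expect_equal(colSums(p$probs), 1, ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(pwm(M[1:3, , drop = FALSE], "m"), "4 rows")
  expect_error(pwm(matrix(0, 4, 2), "m", pseudocount = 0), "zero-sum")
})

test_that("JASPAR parsing round-trips and rejects malformed input", {
  pwms <- bundled_pwms()
  expect_named(pwms, c("SYN_SP1", "SYN_HNF1", "SYN_NFY", "SYN_CREB"))
  expect_equal(pwms$SYN_SP1$width, 6L)
  expect_equal(pwms$SYN_HNF1$width, 13L)
  expect_equal(unname(colSums(pwms$SYN_NFY$counts)), rep(14, 7))
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_pwms(pwms, path)
  back <- load_pwms(path)
  expect_equal(back$SYN_CREB$counts, pwms$SYN_CREB$counts)
  empty <- withr::local_tempfile(fileext = ".jaspar")
  writeLines("", empty)
  expect_error(load_pwms(empty), "no matrices")
  bad <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 x", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"), bad)
  expect_error(load_pwms(bad), "ragged|malformed")
})

test_that("scanning a forced consensus behaves like hand enumeration", {
  # delta PWM on ACGT: the only matching window is the sequence itself;
  # ACGT is self-reverse-complementary so both strands report it
  delta <- pwm(matrix(c(1, 0, 0, 0,  0, 1, 0, 0,  0, 0, 1, 0,  0, 0, 0, 1),
                      4, 4), "delta", pseudocount = 0)
  hits <- scan_pwm("ACGT", delta, background(), threshold = 0.8)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$lr, c(256, 256))
  # on TTTT there is no hit on either strand
  expect_equal(nrow(scan_pwm("TTTT", delta, background())), 0L)
  # a non-palindromic consensus hits plus-strand only, and its reverse
  # complement minus-strand only
  delta2 <- pwm(matrix(c(1, 0, 0, 0,  0, 1, 0, 0,  0, 0, 1, 0,  0, 0, 1, 0),
                       4, 4), "acgg", pseudocount = 0)
  h1 <- scan_pwm("TTACGGTT", delta2, background())
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$strand, "+")
  expect_equal(h1$start, 3L)
  h2 <- scan_pwm(revcomp("TTACGGTT"), delta2, background())
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  # threshold 1.0 keeps only exact-consensus windows
  p <- bundled_pwms()$SYN_SP1
  expect_gt(nrow(scan_pwm("AAGGGCGGAA", p, threshold = 1.0)), 0L)
  expect_equal(nrow(scan_pwm("AAGGGCGAAA", p, threshold = 1.0)), 0L)
  # too-short input: empty result with a message
  expect_message(res <- scan_pwm("AC", p), "shorter")
  expect_equal(nrow(res), 0L)
})

test_that("anchored scans report ATG-relative hit coordinates", {
  p <- bundled_pwms()$SYN_SP1
  s <- anchored_seq(paste0(strrep("T", 20), "GGGCGG", strrep("T", 10)), "hs")
  h <- scan_pwm(s, p)
  expect_equal(h$low, -16L)
  expect_equal(h$high, -11L)
})

test_that("the over-representation score matches full window enumeration", {
  # width-1 all-A motif, no pseudocount, uniform background, sequence AA:
  # windows {A,A} forward have LR 4, reverse complement {T,T} LR 0,
  # so A = 2 and R = ln 2
  aM <- matrix(c(5, 0, 0, 0), 4, 1)
  apwm <- pwm(aM, "allA", pseudocount = 0)
  expect_equal(overrepresentation_score("AA", apwm), log(2))
  # a uniform PWM equals the background: LR = 1 everywhere, R = 0
  upwm <- pwm(matrix(1, 4, 3), "unif", pseudocount = 0)
  set.seed(13)
  expect_equal(overrepresentation_score(rand_dna(200), upwm), 0)
  # R is invariant to sequence order
  set.seed(14)
  seqs <- replicate(4, rand_dna(50))
  p <- rand_pwm(5)
  expect_equal(overrepresentation_score(seqs, p),
               overrepresentation_score(rev(seqs), p))
  # strand symmetry: reverse-complementing every sequence changes nothing
  expect_equal(overrepresentation_score(revcomp(seqs), p),
               overrepresentation_score(seqs, p))
  h1 <- nrow(scan_pwm(seqs[1], p, threshold = 0.5))
  h2 <- nrow(scan_pwm(revcomp(seqs[1]), p, threshold = 0.5))
  expect_equal(h1, h2)
  expect_error(overrepresentation_score("ACG", rand_pwm(5)), "at least")
})

test_that("E[LR] is 1 under the background model", {
  set.seed(15)
  p <- rand_pwm(8)
  lrs <- footprintr:::all_window_lrs(rand_dna(50000), p, background())
  se <- stats::sd(lrs) / sqrt(length(lrs))
  expect_lt(abs(mean(lrs) - 1), 3 * se)
})

test_that("randomization p-values hit the floor for forced signal and reproduce", {
  p <- sharp_pwm("ACGTTGCA", "S")
  seqs <- rep("ACGTTGCA", 20)
  r <- pvalues_by_randomization(seqs, p, n_rand = 199, seed = 5,
                                modes = "shuffle_sequence")
  expect_equal(unname(r$p_values["shuffle_sequence"]), 1 / 200)
  r2 <- pvalues_by_randomization(seqs, p, n_rand = 199, seed = 5,
                                 modes = "shuffle_sequence")
  expect_identical(r$p_values, r2$p_values)
  expect_identical(r$null_scores, r2$null_scores)
  # all p-values live in (0, 1]
  expect_true(all(r$p_values > 0 & r$p_values <= 1))
  expect_error(pvalues_by_randomization(seqs, p, n_rand = 10), ">= 100")
  expect_error(pvalues_by_randomization(seqs, p, n_rand = 100,
                                        modes = "background_fragments"),
               "background sequence")
})

test_that("background-fragment nulls draw length-matched fragments", {
  set.seed(16)
  bgset <- background(sequences = replicate(5, rand_dna(300)))
  p <- rand_pwm(6)
  r <- pvalues_by_randomization(replicate(3, rand_dna(80)), p, bgset,
                                n_rand = 100, seed = 2,
                                modes = "background_fragments")
  expect_true(r$p_values["background_fragments"] > 0.005)
})

test_that("null p-values are approximately uniform", {
  set.seed(17)
  n_rep <- 200
  pv <- vapply(seq_len(n_rep), function(i) {
    p <- rand_pwm(6)
    seqs <- replicate(3, rand_dna(60))
    r <- pvalues_by_randomization(seqs, p, n_rand = 100, seed = i,
                                  modes = "shuffle_sequence")
    unname(r$p_values["shuffle_sequence"])
  }, numeric(1))
  frac <- mean(pv <= 0.05)
  # binomial 3-sigma band around the nominal 0.05
  band <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(frac - 0.05), band)
  # and no gross departure from uniformity overall
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("published wild-type sites are detected and their mutants are not", {
  pwms <- bundled_pwms()
  tab <- nags_mutation_sites()
  res <- check_mutation_table(tab, pwms)
  asserted <- res$factor %in% c("Sp1", "HNF-1", "NF-Y")
  expect_true(all(res$wt_detected[asserted]))
  expect_false(any(res$mut_detected[asserted]))
  expect_true(all(res$motif_lost[asserted]))
  # the CREB pair is reported but its engineered change contains a
  # canonical CRE core, so no direction is asserted
  expect_true("CREB" %in% res$factor)
  # identical wild-type and "mutant" always agree
  same <- motif_lost_on_mutation("CCGCCCCCGCC", "CCGCCCCCGCC", pwms$SYN_SP1)
  expect_equal(unname(same["wt_detected"]), unname(same["mut_detected"]))
  # sites shorter than the motif are padded identically for both alleles
  short <- motif_lost_on_mutation("GTTAAT", "GTCCAT", pwms$SYN_HNF1)
  expect_type(short, "logical")
})
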