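# phylogeny-aware sequence-evolution simulator and recovery metrics

test_that("zero branch lengths copy the root to every tip", {
  spc <- phylo_spec(tree = "((a:0,b:0):0,c:0);", root_length = 300L,
                    elements = data.frame(start = integer(), end = integer(),
                                          rate_mult = numeric()),
                    indel_rate = 0, seed = 20L)
  sim <- simulate_evolution(spc)
  res <- vapply(sim$sequences, `[[`, character(1), "residues")
  expect_equal(length(unique(res)), 1L)
  expect_equal(nchar(res[[1]]), 300L)
})

test_that("JC69 pairwise identity matches the closed form at d = 0.1", {
  spc <- phylo_spec(tree = "(a:0.05,b:0.05);", root_length = 10000L,
                    elements = data.frame(start = integer(), end = integer(),
                                          rate_mult = numeric()),
                    indel_rate = 0, seed = 21L)
  sim <- simulate_evolution(spc)
  a <- strsplit(sim$sequences$a$residues, "")[[1]]
  b <- strsplit(sim$sequences$b$residues, "")[[1]]
  expected <- 0.25 + 0.75 * exp(-4 * 0.1 / 3)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(mean(a == b) - expected), 3 * se)
})

test_that("per-branch substitution fraction matches the model expectation", {
  d <- 0.2
  spc <- phylo_spec(tree = sprintf("(a:%g,b:0);", d), root_length = 20000L,
                    elements = data.frame(start = integer(), end = integer(),
                                          rate_mult = numeric()),
                    indel_rate = 0, seed = 22L)
  sim <- simulate_evolution(spc)   # b is an unmutated copy of the root
  a <- strsplit(sim$sequences$a$residues, "")[[1]]
  b <- strsplit(sim$sequences$b$residues, "")[[1]]
  expected <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(mean(a != b) - expected), 3 * se)
  # K80 with kappa: same total substitution fraction, transition-biased
  spk <- phylo_spec(tree = sprintf("(a:%g,b:0);", d), root_length = 20000L,
                    model = "K80", kappa = 4,
                    elements = data.frame(start = integer(), end = integer(),
                                          rate_mult = numeric()),
                    indel_rate = 0, seed = 23L)
  simk <- simulate_evolution(spk)
  ak <- strsplit(simk$sequences$a$residues, "")[[1]]
  bk <- strsplit(simk$sequences$b$residues, "")[[1]]
  diffk <- which(ak != bk)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  n_ts <- sum(ts[bk[diffk]] == ak[diffk])
  expect_gt(n_ts / length(diffk), 0.5)   # transitions dominate at kappa = 4
})

test_that("rate-0 elements stay identical while neutral flanks diverge", {
  spc <- phylo_spec(root_length = 2000L,
                    elements = data.frame(start = 801L, end = 1000L,
                                          rate_mult = 0),
                    indel_rate = 0, seed = 24L)
  sim <- simulate_evolution(spc)
  el <- sim$truth$elements
  pieces <- vapply(names(sim$sequences), function(sp) {
    s <- sim$sequences[[sp]]
    row <- el[el$species == sp, ]
    substr(s$residues, atg_to_index(s, row$low), atg_to_index(s, row$high))
  }, character(1))
  expect_equal(length(unique(pieces)), 1L)
})

test_that("conserved elements out-conserve their neutral flanks", {
  worse <- 0
  for (sd in 1:20) {
    spc <- phylo_spec(tree = "(a:0.15,b:0.15);", root_length = 1200L,
                      elements = data.frame(start = 401L, end = 700L,
                                            rate_mult = 0.05),
                      indel_rate = 0, seed = 100L + sd)
    sim <- simulate_evolution(spc)
    a <- strsplit(sim$sequences$a$residues, "")[[1]]
    b <- strsplit(sim$sequences$b$residues, "")[[1]]
    inel <- mean(a[401:700] == b[401:700])
    out <- mean(a[-(401:700)] == b[-(401:700)])
    if (inel <= out) worse <- worse + 1
  }
  expect_equal(worse, 0L)
})

test_that("identical spec and seed give byte-identical FASTA output", {
  spc <- phylo_spec(seed = 25L)
  s1 <- simulate_evolution(spc)
  s2 <- simulate_evolution(spc)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_anchored_fasta(s1$sequences, f1)
  write_anchored_fasta(s2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the sequences
  s3 <- simulate_evolution(phylo_spec(seed = 26L))
  expect_false(identical(s1$sequences$human$residues,
                         s3$sequences$human$residues))
})

test_that("indels shift coordinates but truth bookkeeping stays valid", {
  spc <- phylo_spec(root_length = 3000L,
                    elements = data.frame(start = c(1001L, 2001L),
                                          end = c(1300L, 2400L),
                                          rate_mult = c(0.05, 0.05)),
                    indel_rate = 0.05, seed = 27L)
  sim <- simulate_evolution(spc)
  lens <- vapply(sim$sequences, footprintr:::seq_length, integer(1))
  expect_gt(length(unique(lens)), 1L)   # indels happened
  for (i in seq_len(nrow(sim$truth$elements))) {
    row <- sim$truth$elements[i, ]
    s <- sim$sequences[[row$species]]
    expect_true(atg_to_index(s, row$low) >= 1)
    expect_true(atg_to_index(s, row$high) <= footprintr:::seq_length(s))
    # element length is preserved (no indels inside elements)
    expect_equal(atg_span_length(row$low, row$high),
                 row$root_end - row$root_start + 1L)
  }
})

test_that("spec validation refuses inconsistent designs", {
  expect_error(phylo_spec(elements = data.frame(start = c(1L, 50L),
                                                end = c(100L, 80L),
                                                rate_mult = c(0, 0))),
               "overlapping")
  expect_error(phylo_spec(root_length = 100L,
                          elements = data.frame(start = 50L, end = 200L,
                                                rate_mult = 0)))
  p <- sharp_pwm("ACGTACGT")
  expect_error(phylo_spec(elements = data.frame(start = 1L, end = 10L,
                                                rate_mult = 0),
                          plantings = data.frame(pwm_id = "SHARP",
                                                 element = 1L, offset = 8L,
                                                 species = NA),
                          pwms = list(SHARP = p)),
               "outside element")
})

test_that("recovery metrics follow set arithmetic", {
  truth <- data.frame(species = "hs", low = -100L, high = -1L)
  # perfect call
  m <- recovery_metrics(data.frame(low = -100L, high = -1L), truth, "hs")
  expect_equal(unlist(m), c(precision = 1, recall = 1, jaccard = 1))
  # nothing called: precision 1 by convention, recall 0
  m0 <- recovery_metrics(data.frame(low = integer(), high = integer()),
                         truth, "hs")
  expect_equal(unlist(m0), c(precision = 1, recall = 0, jaccard = 0))
  # half-overlapping equal-length intervals: Jaccard 1/3
  mh <- recovery_metrics(data.frame(low = -150L, high = -51L), truth, "hs")
  expect_equal(mh$jaccard, 1 / 3)
  expect_equal(mh$precision, 0.5)
  expect_equal(mh$recall, 0.5)
})
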