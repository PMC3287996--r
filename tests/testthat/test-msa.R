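# guide-tree construction and progressive multiple alignment

test_that("pairwise distances follow the global-alignment identity", {
  expect_equal(pairwise_distance_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))["a", "b"], 0)
  expect_equal(pairwise_distance_matrix(c(a = "AAAA", b = "TTTT"))["a", "b"], 1)
  # 3x3 matrix against an independent full-DP oracle
  seqs <- c(x = "ACGTACGTAC", y = "ACGTTCGTAC", z = "ACGAACGTTC")
  D <- pairwise_distance_matrix(seqs)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), c(x = 0, y = 0, z = 0))
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
  for (p in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    al <- Biostrings::pairwiseAlignment(seqs[[p[1]]], seqs[[p[2]]],
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    id <- percent_identity(as.character(Biostrings::alignedPattern(al)),
                           as.character(Biostrings::alignedSubject(al)))
    expect_equal(D[p[1], p[2]], 1 - id, tolerance = 1e-12)
  }
})

test_that("UPGMA builds deterministic ultrametric guide trees", {
  # 2 taxa: a single cherry with branch lengths d/2
  D2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- build_guide_tree(D2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(.2, .2))
  # 3 taxa: closest pair joins first
  D3 <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- build_guide_tree(D3)
  expect_true(ape::is.monophyletic(t3, c("A", "B")))
  # agrees with hclust average linkage on a tie-free matrix
  set.seed(8)
  n <- 5
  M <- matrix(runif(n * n, .1, .9), n)
  M <- (M + t(M)) / 2; diag(M) <- 0
  dimnames(M) <- list(letters[1:n], letters[1:n])
  mine <- build_guide_tree(M)
  hc <- ape::as.phylo(stats::hclust(stats::as.dist(M), "average"))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine), ape::unroot(hc))), 0)
  # equidistant taxa: lexicographic tie-break, stable serialization
  De <- matrix(.3, 3, 3, dimnames = list(c("t3", "t1", "t2"), c("t3", "t1", "t2")))
  diag(De) <- 0
  expect_equal(attr(build_guide_tree(De), "newick"),
               attr(build_guide_tree(De[c(2, 3, 1), c(2, 3, 1)]), "newick"))
  expect_match(attr(build_guide_tree(De), "newick"), "^\\(\\(t1")
  expect_error(build_guide_tree(D2[1, 1, drop = FALSE]), "at least 2")
})

test_that("identical sequences align without gaps", {
  seqs <- c(a = "ACGTACGTAA", b = "ACGTACGTAA", c = "ACGTACGTAA")
  m <- progressive_align(seqs)
  expect_false(any(grepl("-", m$rows, fixed = TRUE)))
  expect_equal(unname(m$rows[["a"]]), "ACGTACGTAA")
})

test_that("degapping any row reproduces its input exactly", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    root <- rand_dna(sample(15:40, 1))
    seqs <- vapply(seq_len(n), function(k) {
      ch <- strsplit(root, "")[[1]]
      # substitutions
      at <- sample(length(ch), rbinom(1, length(ch), 0.1))
      ch[at] <- sample(c("A", "C", "G", "T"), length(at), TRUE)
      # an occasional deletion
      if (runif(1) < .5 && length(ch) > 8) {
        cut <- sample(length(ch) - 3, 1)
        ch <- ch[-(cut:(cut + 2))]
      }
      paste(ch, collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", seq_len(n))
    m <- progressive_align(seqs)
    expect_equal(length(unique(nchar(m$rows))), 1L)
    for (id in names(seqs)) expect_equal(msa_degap(m, id), seqs[[id]])
    # column maps are mutually inverse
    id <- names(seqs)[1]
    pos <- seq_len(nchar(seqs[[id]]))
    expect_equal(msa_col_to_pos(m, id, msa_pos_to_col(m, id, pos)), pos)
  }
})

test_that("alignment content is invariant to input order", {
  set.seed(10)
  root <- rand_dna(30)
  seqs <- vapply(1:4, function(k) {
    ch <- strsplit(root, "")[[1]]
    at <- sample(30, 4)
    ch[at] <- sample(c("A", "C", "G", "T"), 4, TRUE)
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:4)
  m1 <- progressive_align(seqs)
  m2 <- progressive_align(seqs[c(3, 1, 4, 2)])
  expect_equal(m1$rows[sort(names(m1$rows))], m2$rows[sort(names(m2$rows))])
})

test_that("progressive alignment beats random legal alignments on SP score", {
  set.seed(11)
  sch <- scoring_scheme()
  rand_msa <- function(seqs, width) {
    rows <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      slots <- sort(sample(width, length(ch)))
      out <- rep("-", width)
      out[slots] <- ch
      paste(out, collapse = "")
    }, character(1))
    footprintr:::new_msa(rows)
  }
  for (i in 1:10) {
    root <- rand_dna(12)
    seqs <- vapply(1:3, function(k) {
      ch <- strsplit(root, "")[[1]]
      at <- sample(12, 2)
      ch[at] <- sample(c("A", "C", "G", "T"), 2, TRUE)
      paste(ch[-sample(12, 1)], collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", 1:3)
    m <- progressive_align(seqs)
    sp <- footprintr:::msa_sp_score(m, sch)
    width <- max(nchar(seqs)) + 3
    best_rand <- max(vapply(1:50, function(j)
      footprintr:::msa_sp_score(rand_msa(seqs, width), sch), numeric(1)))
    expect_gte(sp, best_rand)
  }
})

test_that("aligned FASTA round-trips an MSA", {
  seqs <- c(a = "ACGTAAGT", b = "ACGTACGT", c = "ACTTACGT")
  m <- progressive_align(seqs)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_msa_fasta(m, path)
  back <- read_msa_fasta(path)
  expect_equal(back$rows, m$rows)
})

test_that("an indel-free conserved element aligns gap-free across species", {
  spc <- phylo_spec(root_length = 600L,
                    elements = data.frame(start = 201L, end = 400L,
                                          rate_mult = 0),
                    indel_rate = 0, seed = 12L)
  sim <- simulate_evolution(spc)
  el <- sim$truth$elements
  sub <- lapply(names(sim$sequences), function(sp) {
    s <- sim$sequences[[sp]]
    row <- el[el$species == sp, ]
    substr(s$residues, atg_to_index(s, row$low), atg_to_index(s, row$high))
  })
  names(sub) <- names(sim$sequences)
  # rate multiplier 0 and no indels: element is byte-identical everywhere
  expect_equal(length(unique(unlist(sub))), 1L)
  m <- progressive_align(unlist(sub))
  expect_false(any(grepl("-", m$rows, fixed = TRUE)))
})
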