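#' Pairwise distance matrix from global alignments
#'
#' Distance is `1 - identity` of a global affine-gap alignment under the
#' given scoring scheme, with gap columns in the identity denominator.
#'
#' @param seqs named list of [anchored_seq()] objects (or plain named
#'   character vector of DNA strings), length >= 2.
#' @param scheme a [scoring_scheme()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
pairwise_distance_matrix <- function(seqs, scheme = scoring_scheme()) {
  res <- seqs_to_strings(seqs)
  if (length(res) < 2L) stop("need at least 2 sequences")
  if (any(!nzchar(res))) stop("empty sequence")
  n <- length(res)
  D <- matrix(0, n, n, dimnames = list(names(res), names(res)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- nw_affine_cpp(res[[i]], res[[j]], scheme$match_score,
                        scheme$mismatch_score, scheme$gap_open,
                        scheme$gap_extend)
    d <- 1 - percent_identity(al$aligned_a, al$aligned_b)
    D[i, j] <- D[j, i] <- d
  }
  D
}

seqs_to_strings <- function(seqs) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    return(seqs)
  }
  out <- vapply(seqs, function(s)
    if (inherits(s, "anchored_seq")) s$residues else as.character(s),
    character(1))
  nm <- names(seqs) %||% vapply(seqs, function(s) s$species_id, character(1))
  if (is.null(names(out)) || any(!nzchar(names(out)))) names(out) <- nm
  out
}

#' UPGMA guide tree
#'
#' Average-linkage (UPGMA) clustering of a distance matrix into a rooted
#' ultrametric tree.  Ties in the minimal distance are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest member id), so the tree and its newick
#' serialization are deterministic.
#'
#' @param dist symmetric distance matrix with species ids as dimnames.
#' @return an `ape` `phylo` object (rooted, with branch lengths); its
#'   deterministic newick string is in `attr(tree, "newick")`.
#' @export
build_guide_tree <- function(dist) {
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-9)))
    stop("distance matrix must be symmetric")
  n <- nrow(dist)
  if (n < 2L) stop("need at least 2 taxa")
  ids <- rownames(dist)
  nodes <- lapply(ids, function(id)
    list(newick = id, height = 0, size = 1L, label = id))
  D <- dist
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      d <- D[i, j]
      lab <- sort(c(nodes[[i]]$label, nodes[[j]]$label))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
        best <- list(d = d, i = i, j = j, lab = lab)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    bi <- h - nodes[[i]]$height; bj <- h - nodes[[j]]$height
    # children ordered by label for deterministic serialization
    kids <- list(nodes[[i]], nodes[[j]])
    lens <- c(bi, bj)
    ord <- order(vapply(kids, `[[`, character(1), "label"))
    newick <- sprintf("(%s:%.10g,%s:%.10g)",
                      kids[[ord[1]]]$newick, lens[ord[1]],
                      kids[[ord[2]]]$newick, lens[ord[2]])
    new_node <- list(newick = newick, height = h,
                     size = nodes[[i]]$size + nodes[[j]]$size,
                     label = min(nodes[[i]]$label, nodes[[j]]$label))
    # average-linkage update
    for (k in active) {
      if (k == i || k == j) next
      dk <- (nodes[[i]]$size * D[i, k] + nodes[[j]]$size * D[j, k]) /
        (nodes[[i]]$size + nodes[[j]]$size)
      D[i, k] <- D[k, i] <- dk
    }
    nodes[[i]] <- new_node
    active <- setdiff(active, j)
  }
  nwk <- paste0(nodes[[active]]$newick, ";")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "newick") <- nwk
  tree
}

#' Progressive multiple alignment
#'
#' Profile-profile progressive alignment following the guide tree's merge
#' order, with mean-of-pairs substitution scores and affine gap penalties
#' from the scoring scheme.  The dynamic program breaks ties
#' deterministically (match > delete > insert), so the output is a pure
#' function of the inputs.
#'
#' @param seqs named list of [anchored_seq()] objects or named character
#'   vector of DNA strings.
#' @param tree optional guide tree (`phylo`); defaults to
#'   [build_guide_tree()] on [pairwise_distance_matrix()].
#' @param scheme a [scoring_scheme()].
#' @return object of class `msa`: `rows` (named character vector of
#'   equal-length gapped strings, in guide-tree leaf order) plus cached
#'   column maps; see [msa_pos_to_col()].
#' @export
progressive_align <- function(seqs, tree = NULL, scheme = scoring_scheme()) {
  strs <- seqs_to_strings(seqs)
  if (is.null(tree)) {
    if (length(strs) == 1L) return(new_msa(strs))
    tree <- build_guide_tree(pairwise_distance_matrix(strs, scheme))
  }
  if (!setequal(tree$tip.label, names(strs)))
    stop("guide tree leaves do not match sequence ids")
  if (length(strs) == 1L) return(new_msa(strs))
  # post-order traversal over internal nodes
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  profiles <- vector("list", n_tip + tr$Nnode)
  for (i in seq_len(n_tip)) profiles[[i]] <- strs[tr$tip.label[i]]
  edges <- tr$edge
  for (node in unique(edges[, 1])) {
    kids <- edges[edges[, 1] == node, 2]
    prof <- profiles[[kids[1]]]
    for (k in kids[-1]) prof <- merge_profiles(prof, profiles[[k]], scheme)
    profiles[[node]] <- prof
  }
  root <- n_tip + 1L
  new_msa(profiles[[root]])
}

merge_profiles <- function(a, b, scheme) {
  U <- profile_counts(a); V <- profile_counts(b)
  res <- profile_align_cpp(U, V, length(a), length(b),
                           scheme$match_score, scheme$mismatch_score,
                           scheme$gap_open, scheme$gap_extend)
  path <- strsplit(res$path, "", fixed = TRUE)[[1]]
  ai <- cumsum(path != "Y")   # consumed columns of a
  bi <- cumsum(path != "X")
  expand <- function(rows, take, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      out <- rep("-", length(path))
      out[take] <- ch[idx[take]]
      paste(out, collapse = "")
    }, character(1))
  }
  c(expand(a, path != "Y", ai), expand(b, path != "X", bi))
}

# residue counts per column (rows A,C,G,T,N), gaps contribute nothing
profile_counts <- function(rows) {
  L <- nchar(rows[[1]])
  M <- matrix(0, 5, L)
  for (r in rows) {
    v <- encode_dna_int(r)
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    keep <- ch != "-"
    idx <- which(keep)
    M[cbind(v[idx], idx)] <- M[cbind(v[idx], idx)] + 1
  }
  M
}

new_msa <- function(rows) {
  rows <- unlist(rows)
  stopifnot(length(unique(nchar(rows))) == 1L)
  maps <- lapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    col2pos <- ifelse(ch == "-", NA_integer_, cumsum(ch != "-"))
    pos2col <- which(ch != "-")
    list(col2pos = col2pos, pos2col = pos2col)
  })
  structure(list(rows = rows, maps = maps), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[[1]])))
  invisible(x)
}

#' Map between ungapped positions and alignment columns
#'
#' `msa_pos_to_col` maps a 1-based position in a row's ungapped sequence
#' to its alignment column; `msa_col_to_pos` is the inverse (NA at gap
#' columns).  Degapping any row reproduces its input sequence exactly.
#'
#' @param msa an `msa` object from [progressive_align()].
#' @param species row id.
#' @param pos,col integer vectors.
#' @return integer vector.
#' @export
msa_pos_to_col <- function(msa, species, pos) {
  map <- msa$maps[[species]]$pos2col
  if (any(pos < 1L | pos > length(map))) stop("position outside aligned row")
  map[pos]
}

#' @rdname msa_pos_to_col
#' @export
msa_col_to_pos <- function(msa, species, col) {
  map <- msa$maps[[species]]$col2pos
  if (any(col < 1L | col > length(map))) stop("column outside alignment")
  map[col]
}

#' Remove gaps from an MSA row
#' @param msa an `msa` object.
#' @param species row id.
#' @return the row's ungapped sequence string.
#' @export
msa_degap <- function(msa, species) gsub("-", "", msa$rows[[species]], fixed = TRUE)

#' Read/write aligned FASTA
#'
#' @param msa an `msa` object.
#' @param path file path.
#' @return `write_msa_fasta` returns `path` invisibly; `read_msa_fasta`
#'   returns an `msa` object.
#' @export
write_msa_fasta <- function(msa, path) {
  set <- Biostrings::BStringSet(msa$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(set),
                          vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1))
  new_msa(rows)
}

# sum-of-pairs score of an MSA under a scoring scheme (gap of length L in
# a pairwise projection costs gap_open + gap_ext * L; columns where both
# rows have gaps are skipped)
msa_sp_score <- function(msa, scheme) {
  rows <- msa$rows
  n <- length(rows)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(rows[[i]], "", fixed = TRUE)[[1]]
    b <- strsplit(rows[[j]], "", fixed = TRUE)[[1]]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    gap <- a == "-" | b == "-"
    mm <- sum(!gap & (a != b | a == "N" | b == "N"))
    mt <- sum(!gap) - mm
    total <- total + mt * scheme$match_score + mm * scheme$mismatch_score
    # affine gap cost on maximal gap runs
    r <- rle(gap)
    runs <- r$lengths[r$values]
    total <- total - sum(scheme$gap_open + scheme$gap_extend * runs)
  }
  total
}
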