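#' Default mammal-like 7-taxon phylogeny
#'
#' Rooted newick tree with branch lengths in expected substitutions per
#' site, with primate, carnivore/ungulate and rodent depths chosen to
#' give neutral pairwise identities from ~96% (human-chimp) down to ~53%
#' (human-mouse) under JC69.
#'
#' @return newick string with 7 leaves
#'   (human, chimp, dog, horse, cow, mouse, rat).
#' @export
default_mammal_tree <- function() {
  paste0("((human:0.02,chimp:0.02):0.16,",
         "((dog:0.18,(horse:0.15,cow:0.17):0.03):0.20,",
         "(mouse:0.22,rat:0.23):0.35):0.04);")
}

#' Specification for synthetic upstream-sequence evolution
#'
#' Describes a root sequence with embedded slow-evolving conserved
#' elements (optionally carrying planted motif instances), evolved down a
#' phylogeny under JC69 (or K80 with a transition/transversion ratio)
#' with indels outside elements.  The default configuration emulates a
#' multi-mammal upstream scan: 5 kb of neutral sequence with a 250 bp
#' promoter-like element near the anchor and a 400 bp enhancer-like
#' element ~3 kb upstream, both at 5% of the neutral substitution rate.
#'
#' @param tree newick string with branch lengths (expected substitutions
#'   per site per branch).
#' @param root_length root sequence length in bp.
#' @param model `"JC69"` or `"K80"`.
#' @param kappa transition/transversion rate ratio for K80.
#' @param elements data frame `start`, `end` (1-based root coordinates,
#'   non-overlapping), `rate_mult` in `[0, 1]`.
#' @param plantings optional data frame `pwm_id`, `element` (row index
#'   into `elements`), `offset` (1-based within the element), `species`
#'   (comma-separated carrier subset, or NA for all species).
#' @param pwms named list of [pwm()] objects referenced by `plantings`.
#' @param indel_rate indel events per site per unit branch length outside
#'   elements (0 inside elements, so truth coordinates stay exact).
#' @param indel_p geometric length parameter (mean length `1/indel_p`).
#' @param composition root/insertion base composition.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return an object of class `phylo_spec`.
#' @export
phylo_spec <- function(tree = default_mammal_tree(), root_length = 5000L,
                       model = c("JC69", "K80"), kappa = 2,
                       elements = data.frame(start = c(1601L, 4701L),
                                             end = c(2000L, 4950L),
                                             rate_mult = c(0.05, 0.05)),
                       plantings = NULL, pwms = NULL,
                       indel_rate = 0.02, indel_p = 0.5,
                       composition = stats::setNames(rep(0.25, 4), DNA_BASES),
                       seed = 1L) {
  model <- match.arg(model)
  root_length <- as.integer(root_length)
  if (nrow(elements) > 0) {
    stopifnot(all(elements$start >= 1L), all(elements$end <= root_length),
              all(elements$start <= elements$end),
              all(elements$rate_mult >= 0), all(elements$rate_mult <= 1))
    ord <- order(elements$start)
    elements <- elements[ord, , drop = FALSE]
    if (nrow(elements) > 1 &&
        any(elements$start[-1] <= elements$end[-nrow(elements)]))
      stop("overlapping elements")
  }
  if (!is.null(plantings) && nrow(plantings) > 0) {
    if (is.null(pwms)) stop("plantings given but no pwms")
    for (i in seq_len(nrow(plantings))) {
      e <- plantings$element[i]
      w <- pwms[[plantings$pwm_id[i]]]$width
      if (e < 1 || e > nrow(elements)) stop("planting outside element range")
      if (plantings$offset[i] < 1 ||
          elements$start[e] + plantings$offset[i] - 1 + w - 1 > elements$end[e])
        stop("planting outside element")
    }
  }
  structure(list(tree = tree, root_length = root_length, model = model,
                 kappa = kappa, elements = elements,
                 plantings = plantings, pwms = pwms,
                 indel_rate = indel_rate, indel_p = indel_p,
                 composition = composition, seed = as.integer(seed)),
            class = "phylo_spec")
}

# substitution: returns mutated integer-coded sequence
# JC69: P(change) = 3/4 (1 - exp(-4 d r / 3)), new base uniform among other 3.
# K80:  transition and transversion probabilities from the standard
#       closed form with rate normalised to d substitutions/site.
mutate_branch <- function(codes, rates, d, model, kappa) {
  n <- length(codes)
  if (d <= 0 || n == 0L) return(codes)
  dr <- d * rates
  if (model == "JC69") {
    p_change <- 0.75 * (1 - exp(-4 * dr / 3))
    hit <- which(runif(n) < p_change)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
    }
  } else {
    # K80 with kappa = alpha/beta; rate scaled so d = expected subs/site
    beta <- 1 / (kappa + 2)
    alpha <- kappa * beta
    e4 <- exp(-4 * beta * dr)
    e2 <- exp(-2 * (alpha + beta) * dr)
    p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
    p_tv <- 0.5 - 0.5 * e4          # total for the two transversions
    u <- runif(n)
    ts <- which(u < p_ts)
    tv <- which(u >= p_ts & u < p_ts + p_tv)
    # transitions: A<->G (1<->3), C<->T (2<->4)
    codes[ts] <- c(3L, 4L, 1L, 2L)[codes[ts]]
    if (length(tv)) {
      pick <- sample.int(2L, length(tv), replace = TRUE)
      tvmap <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
      codes[tv] <- tvmap[cbind(codes[tv], pick)]
    }
  }
  codes
}

# apply indel events to a node state (list of parallel vectors)
apply_indels <- function(st, d, spec) {
  n <- length(st$codes)
  eligible <- st$elem == 0L
  lam <- spec$indel_rate * d * sum(eligible)
  if (lam <= 0) return(st)
  n_ev <- rpois(1, lam)
  for (ev in seq_len(n_ev)) {
    n <- length(st$codes)
    idx_ok <- which(st$elem == 0L)
    if (length(idx_ok) == 0L) break
    at <- idx_ok[sample.int(length(idx_ok), 1L)]
    len <- rgeom(1, spec$indel_p) + 1L
    if (runif(1) < 0.5) {
      # deletion starting at `at`, truncated at the next element base
      to <- at
      while (to < n && to - at + 1L < len && st$elem[to + 1L] == 0L) to <- to + 1L
      keep <- setdiff(seq_len(n), at:to)
      st$codes <- st$codes[keep]; st$rates <- st$rates[keep]
      st$elem <- st$elem[keep]; st$root <- st$root[keep]
    } else {
      ins <- sample.int(4L, len, replace = TRUE,
                        prob = spec$composition[DNA_BASES])
      st$codes <- append(st$codes, ins, after = at)
      st$rates <- append(st$rates, rep(1, len), after = at)
      st$elem <- append(st$elem, rep(0L, len), after = at)
      st$root <- append(st$root, rep(NA_integer_, len), after = at)
    }
  }
  st
}

#' Simulate multi-species upstream sequences with known truth
#'
#' Draws a root sequence from the background composition, writes planted
#' motif instances (sampled from their PWM probabilities) into the
#' conserved elements, evolves the sequence down the phylogeny with
#' per-region rate multipliers and neutral-region indels, and anchors
#' each tip sequence at its 3' end so element coordinates are negative
#' ATG-relative positions.  Plantings restricted to a species subset are
#' re-randomized from the background in non-carrier species.
#'
#' @param spec a [phylo_spec()].
#' @return list with `sequences` (named list of [anchored_seq()]),
#'   `truth` (list of data frames `elements` and `motifs` with per-species
#'   ATG-relative coordinates), and `spec`.
#' @export
simulate_evolution <- function(spec) {
  stopifnot(inherits(spec, "phylo_spec"))
  tree <- ape::read.tree(text = spec$tree)
  withr::with_seed(spec$seed, {
    L <- spec$root_length
    codes <- sample.int(4L, L, replace = TRUE,
                        prob = spec$composition[DNA_BASES])
    rates <- rep(1, L)
    elem <- integer(L)
    for (i in seq_len(nrow(spec$elements))) {
      span <- spec$elements$start[i]:spec$elements$end[i]
      rates[span] <- spec$elements$rate_mult[i]
      elem[span] <- i
    }
    planted <- list()
    if (!is.null(spec$plantings) && nrow(spec$plantings) > 0) {
      for (i in seq_len(nrow(spec$plantings))) {
        p <- spec$plantings[i, ]
        w <- spec$pwms[[p$pwm_id]]
        site <- vapply(seq_len(w$width), function(j)
          sample(DNA_BASES, 1L, prob = w$probs[, j]), character(1))
        at <- spec$elements$start[p$element] + p$offset - 1L
        codes[at:(at + w$width - 1L)] <- match(site, DNA_BASES)
        carriers <- if (is.null(p$species) || is.na(p$species)) tree$tip.label
                    else strsplit(p$species, ",")[[1]]
        planted[[i]] <- list(pwm_id = p$pwm_id, root_start = at,
                             root_end = at + w$width - 1L,
                             carriers = carriers)
      }
    }
    root_state <- list(codes = codes, rates = rates, elem = elem,
                       root = seq_len(L))
    n_tip <- length(tree$tip.label)
    states <- vector("list", n_tip + tree$Nnode)
    states[[n_tip + 1L]] <- root_state
    # preorder traversal: parents before children
    edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    for (k in seq_len(nrow(pre))) {
      parent <- pre[k, 1]; child <- pre[k, 2]
      d <- tree$edge.length[which(tree$edge[, 1] == parent &
                                  tree$edge[, 2] == child)]
      st <- states[[parent]]
      st$codes <- mutate_branch(st$codes, st$rates, d, spec$model, spec$kappa)
      st <- apply_indels(st, d, spec)
      states[[child]] <- st
    }
    # non-carrier knockouts: replace planted positions by background draws
    for (pl in planted) {
      non <- setdiff(tree$tip.label, pl$carriers)
      for (sp in non) {
        i <- match(sp, tree$tip.label)
        st <- states[[i]]
        at <- which(!is.na(st$root) & st$root >= pl$root_start &
                    st$root <= pl$root_end)
        st$codes[at] <- sample.int(4L, length(at), replace = TRUE,
                                   prob = spec$composition[DNA_BASES])
        states[[i]] <- st
      }
    }
    seqs <- list(); el_truth <- list(); mo_truth <- list()
    for (i in seq_len(n_tip)) {
      sp <- tree$tip.label[i]
      st <- states[[i]]
      res <- paste(DNA_BASES[st$codes], collapse = "")
      as <- anchored_seq(res, species_id = sp)
      seqs[[sp]] <- as
      for (e in seq_len(nrow(spec$elements))) {
        at <- which(st$elem == e)
        if (length(at) == 0L) next
        el_truth[[length(el_truth) + 1L]] <- data.frame(
          species = sp, element = e,
          low = index_to_atg(as, min(at)), high = index_to_atg(as, max(at)),
          root_start = spec$elements$start[e], root_end = spec$elements$end[e],
          stringsAsFactors = FALSE)
      }
      for (pl in planted) {
        if (!sp %in% pl$carriers) next
        at <- which(!is.na(st$root) & st$root >= pl$root_start &
                    st$root <= pl$root_end)
        if (length(at) == 0L) next
        mo_truth[[length(mo_truth) + 1L]] <- data.frame(
          species = sp, pwm_id = pl$pwm_id,
          low = index_to_atg(as, min(at)), high = index_to_atg(as, max(at)),
          strand = "+", stringsAsFactors = FALSE)
      }
    }
    truth <- list(
      elements = if (length(el_truth)) do.call(rbind, el_truth)
                 else data.frame(species = character(), element = integer(),
                                 low = integer(), high = integer(),
                                 root_start = integer(), root_end = integer()),
      motifs = if (length(mo_truth)) do.call(rbind, mo_truth)
               else data.frame(species = character(), pwm_id = character(),
                               low = integer(), high = integer(),
                               strand = character()))
    list(sequences = seqs, truth = truth, spec = spec)
  })
}

#' Nucleotide-level recovery metrics against a truth set
#'
#' Compares called intervals to true intervals on one species as
#' position sets: precision (1 by convention when nothing is called),
#' recall, and Jaccard index of the two sets.
#'
#' @param called data frame with ATG-relative `low`/`high` columns
#'   (e.g. [call_conserved_regions()] output).
#' @param truth data frame with `species`, `low`, `high` (e.g.
#'   `simulate_evolution()$truth$elements`).
#' @param species species id both tables are evaluated on.
#' @return list with `precision`, `recall`, `jaccard`.
#' @export
recovery_metrics <- function(called, truth, species) {
  truth <- truth[truth$species == species, , drop = FALSE]
  expand <- function(df) {
    if (nrow(df) == 0L) return(integer(0))
    unique(unlist(lapply(seq_len(nrow(df)), function(i)
      atg_to_axis(df$low[i]):atg_to_axis(df$high[i]))))
  }
  cset <- expand(called); tset <- expand(truth)
  inter <- length(intersect(cset, tset))
  un <- length(union(cset, tset))
  list(precision = if (length(cset) == 0L) 1 else inter / length(cset),
       recall = if (length(tset) == 0L) 1 else inter / length(tset),
       jaccard = if (un == 0L) 1 else inter / un)
}
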