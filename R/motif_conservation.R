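#' Map motif hits onto alignment columns
#'
#' Each hit's interval on its row's ungapped sequence is projected to an
#' alignment column interval; gaps inside the hit's span widen the column
#' interval.  Hits come from scanning ungapped sequence, so a hit can
#' never itself span a gap character in its own row.
#'
#' @param msa an `msa` from [progressive_align()].
#' @param hits_by_species named list (by species) of hit tables from
#'   [scan_pwm()], with `start`/`end` positions on the species' ungapped
#'   region sequence.
#' @return data frame: `species`, `matrix_id`, `col_start`, `col_end`,
#'   `strand`, `log2_ratio`, `start`, `end`.
#' @export
map_hits_to_columns <- function(msa, hits_by_species) {
  rows <- lapply(names(hits_by_species), function(sp) {
    h <- hits_by_species[[sp]]
    if (is.null(h) || nrow(h) == 0L) return(NULL)
    if (!sp %in% names(msa$rows)) stop("species not in alignment: ", sp)
    data.frame(species = sp, matrix_id = h$matrix_id,
               col_start = msa_pos_to_col(msa, sp, h$start),
               col_end = msa_pos_to_col(msa, sp, h$end),
               strand = h$strand, log2_ratio = h$log2_ratio,
               start = h$start, end = h$end, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(species = character(), matrix_id = character(),
                      col_start = integer(), col_end = integer(),
                      strand = character(), log2_ratio = numeric(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call cross-species conserved motifs
#'
#' Hits for one matrix are clustered by aligned position: clusters are
#' seeded in column order, and a species joins a cluster when one of its
#' hits overlaps the seed's column interval by at least
#' `overlap_fraction` of the shorter interval.  Each species contributes
#' at most one hit per cluster (best overlap, ties broken by higher
#' likelihood ratio, then leftmost).  Clusters carried by at least
#' `min_species` species are emitted with the union column interval.
#'
#' @param msa an `msa` from [progressive_align()].
#' @param hits_by_species named list (by species) of [scan_pwm()] tables;
#'   may contain several matrices (clustered separately).
#' @param min_species minimum number of species carrying the motif
#'   (default 4).
#' @param overlap_fraction minimum column overlap as a fraction of the
#'   shorter interval (default 0.5).
#' @return data frame of conserved motifs sorted by matrix then column:
#'   `matrix_id`, `col_start`, `col_end` (union interval), `n_species`,
#'   `species` (comma-separated); the per-species member hits of each
#'   cluster are in `attr(, "members")`.
#' @export
call_conserved_motifs <- function(msa, hits_by_species, min_species = 4L,
                                  overlap_fraction = 0.5) {
  mapped <- map_hits_to_columns(msa, hits_by_species)
  empty <- data.frame(matrix_id = character(), col_start = integer(),
                      col_end = integer(), n_species = integer(),
                      species = character(), stringsAsFactors = FALSE)
  if (nrow(mapped) == 0L) { attr(empty, "members") <- list(); return(empty) }
  out <- list(); members <- list()
  for (mid in sort(unique(mapped$matrix_id))) {
    hh <- mapped[mapped$matrix_id == mid, , drop = FALSE]
    hh <- hh[order(hh$col_start, hh$col_end, hh$species, hh$strand), , drop = FALSE]
    used <- rep(FALSE, nrow(hh))
    for (i in seq_len(nrow(hh))) {
      if (used[i]) next
      seed <- hh[i, ]
      cluster <- integer(0)
      for (sp in sort(unique(hh$species))) {
        cand <- which(!used & hh$species == sp)
        if (length(cand) == 0L) next
        ov <- overlap_len(hh$col_start[cand], hh$col_end[cand],
                          seed$col_start, seed$col_end)
        shorter <- pmin(hh$col_end[cand] - hh$col_start[cand] + 1L,
                        seed$col_end - seed$col_start + 1L)
        ok <- ov >= overlap_fraction * shorter
        if (!any(ok)) next
        cand <- cand[ok]; ov <- ov[ok]
        pick <- cand[order(-ov, -hh$log2_ratio[cand], hh$col_start[cand])][1]
        cluster <- c(cluster, pick)
      }
      used[cluster] <- TRUE
      used[i] <- TRUE    # the seed is consumed even if its cluster is small
      if (length(unique(hh$species[cluster])) >= min_species) {
        memb <- hh[cluster, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          matrix_id = mid,
          col_start = min(memb$col_start), col_end = max(memb$col_end),
          n_species = length(unique(memb$species)),
          species = paste(sort(unique(memb$species)), collapse = ","),
          stringsAsFactors = FALSE)
        members[[length(members) + 1L]] <- memb
      }
    }
  }
  if (length(out) == 0L) { attr(empty, "members") <- list(); return(empty) }
  res <- do.call(rbind, out)
  ord <- order(res$matrix_id, res$col_start)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "members") <- members[ord]
  res
}

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)

#' Write a conserved-motif table as TSV
#'
#' One row per conserved motif with per-species presence flags, mirroring
#' the layout of cross-species motif summary tables.
#'
#' @param conserved output of [call_conserved_motifs()].
#' @param species all species in the analysis (column order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conserved_motif_tsv <- function(conserved, species, path) {
  tab <- conserved
  for (sp in species)
    tab[[sp]] <- vapply(strsplit(conserved$species, ","), function(x) sp %in% x,
                        logical(1))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
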