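#' Pipeline configuration
#'
#' Bundles every parameter of the footprinting workflow.  Sequences can
#' be given directly (named list of [anchored_seq()]) or as a FASTA path
#' with optional anchors.  All downstream parameters are echoed into the
#' run report for reproducibility.
#'
#' @param reference reference species id.
#' @param sequences named list of [anchored_seq()] objects.
#' @param fasta path to an anchored FASTA (alternative to `sequences`).
#' @param anchors optional named anchor vector for [read_anchored_fasta()].
#' @param scheme a [scoring_scheme()].
#' @param criteria a [conservation_criteria()].
#' @param seed_word seed word size for [find_local_alignments()].
#' @param pwms named list of [pwm()] objects, or a JASPAR file path, or
#'   NULL to skip the motif stages.
#' @param bg a [background()].
#' @param motif_threshold [scan_pwm()] hit threshold.
#' @param n_rand randomizations for [pvalues_by_randomization()].
#' @param null_modes randomization modes.
#' @param min_motif_species cross-species motif filter threshold.
#' @param overlap_fraction motif clustering overlap rule.
#' @param mutation_table optional data frame `factor`, `wt`, `mut` for the
#'   motif-loss check.
#' @param seed master seed recorded in every output.
#' @param out_dir output directory (created); NULL for in-memory only.
#' @return an object of class `footprint_config`.
#' @export
footprint_config <- function(reference, sequences = NULL, fasta = NULL,
                             anchors = NULL, scheme = scoring_scheme(),
                             criteria = conservation_criteria(),
                             seed_word = 11L, pwms = NULL, bg = background(),
                             motif_threshold = 0.80, n_rand = 1000L,
                             null_modes = c("shuffle_sequence",
                                            "shuffle_matrix_columns"),
                             min_motif_species = 4L, overlap_fraction = 0.5,
                             mutation_table = NULL, seed = 1L,
                             out_dir = NULL) {
  if (is.null(sequences) && is.null(fasta))
    stop("either sequences or fasta must be given")
  if (!is.null(fasta) && !file.exists(fasta)) stop("no such file: ", fasta)
  if (is.character(pwms)) {
    if (!file.exists(pwms)) stop("no such PWM file: ", pwms)
  }
  structure(list(reference = reference, sequences = sequences, fasta = fasta,
                 anchors = anchors, scheme = scheme, criteria = criteria,
                 seed_word = as.integer(seed_word), pwms = pwms, bg = bg,
                 motif_threshold = motif_threshold,
                 n_rand = as.integer(n_rand), null_modes = null_modes,
                 min_motif_species = as.integer(min_motif_species),
                 overlap_fraction = overlap_fraction,
                 mutation_table = mutation_table, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "footprint_config")
}

#' Run the phylogenetic-footprinting pipeline
#'
#' Executes, in order: pairwise local alignment of the reference against
#' every other species, conserved-region calling, per-region multiple
#' alignment of the orthologous sequences, PWM scanning and motif
#' over-representation with randomization p-values, cross-species motif
#' conservation filtering, and (optionally) the wild-type/mutant
#' motif-loss check.  Every stage's outputs are written under
#' `config$out_dir` when set; re-running with the same config and seed
#' reproduces the report exactly (timings excepted, kept in a separate
#' field).
#'
#' @param config a [footprint_config()].
#' @return object of class `footprint_report`; see Details.
#' @details The report contains `params` (full parameter echo incl. seed),
#'   `counts` (per-stage record counts), `regions`, `alignments`,
#'   `region_msas`, `region_hits`, `overrepresentation`,
#'   `conserved_motifs`, `mutation_check`, `timings`.
#' @export
run_footprint <- function(config) {
  stopifnot(inherits(config, "footprint_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() t0 <<- proc.time()[["elapsed"]]
  toc <- function(stage) {
    timings[stage] <<- proc.time()[["elapsed"]] - t0
  }

  tic()
  seqs <- config$sequences %||%
    read_anchored_fasta(config$fasta, config$anchors)
  if (!config$reference %in% names(seqs))
    stop("[input] reference species '", config$reference,
         "' not among sequences")
  others <- setdiff(names(seqs), config$reference)
  ref <- seqs[[config$reference]]
  toc("input")
  message(sprintf("[input] %d sequences, reference %s (%d bp)",
                  length(seqs), config$reference, seq_length(ref)))

  tic()
  ka <- karlin_altschul_params(config$scheme)
  alignments <- lapply(stats::setNames(others, others), function(sp)
    find_local_alignments(ref, seqs[[sp]], config$scheme,
                          seed_word = config$seed_word, ka = ka))
  toc("alignments")
  message(sprintf("[alignments] %d HSPs across %d species pairs",
                  sum(vapply(alignments, nrow, integer(1))), length(others)))

  tic()
  regions <- call_conserved_regions(config$reference, alignments,
                                    config$criteria)
  toc("regions")
  message(sprintf("[regions] %d conserved regions", nrow(regions)))

  pwms <- config$pwms
  if (is.character(pwms)) pwms <- load_pwms(pwms)
  region_msas <- list(); region_hits <- list()
  overrep <- list(); conserved_motifs <- list()
  if (is.null(pwms) || length(pwms) == 0L) {
    if (!is.null(config$pwms))
      warning("empty PWM set; motif stages skipped", call. = FALSE)
    message("[motifs] skipped (no PWMs)")
  } else {
    tic()
    for (ri in seq_len(nrow(regions))) {
      sub <- region_orthologs(ref, seqs, alignments, regions[ri, ],
                              config$criteria)
      if (length(sub) < 2L) next
      msa <- progressive_align(sub, scheme = config$scheme)
      hits <- lapply(sub, function(s)
        do.call(rbind, lapply(pwms, function(p)
          scan_pwm(s, p, config$bg, config$motif_threshold))))
      rid <- sprintf("region_%d", ri)
      region_msas[[rid]] <- msa
      region_hits[[rid]] <- hits
      overrep[[rid]] <- lapply(pwms, function(p)
        pvalues_by_randomization(sub, p, config$bg, n_rand = config$n_rand,
                                 seed = config$seed,
                                 modes = config$null_modes))
      conserved_motifs[[rid]] <- call_conserved_motifs(
        msa, hits, config$min_motif_species, config$overlap_fraction)
    }
    toc("motifs")
    message(sprintf("[motifs] %d regions analysed, %d conserved motifs",
                    length(region_msas),
                    sum(vapply(conserved_motifs, nrow, integer(1)))))
  }

  mutcheck <- NULL
  if (!is.null(config$mutation_table) && !is.null(pwms) && length(pwms)) {
    tic()
    mutcheck <- check_mutation_table(config$mutation_table, pwms, config$bg,
                                     config$motif_threshold)
    toc("mutation_check")
    message(sprintf("[mutation_check] %d/%d sites lose their motif",
                    sum(mutcheck$motif_lost, na.rm = TRUE), nrow(mutcheck)))
  }

  report <- structure(list(
    params = report_params(config),
    counts = list(
      sequences = length(seqs),
      alignments = sum(vapply(alignments, nrow, integer(1))),
      regions = nrow(regions),
      regions_with_motifs = length(region_msas),
      conserved_motifs = sum(vapply(conserved_motifs, nrow, integer(1))),
      mutation_sites = if (is.null(mutcheck)) 0L else nrow(mutcheck)),
    regions = regions, alignments = alignments,
    region_msas = region_msas, region_hits = region_hits,
    overrepresentation = overrep, conserved_motifs = conserved_motifs,
    mutation_check = mutcheck, timings = timings),
    class = "footprint_report")
  if (!is.null(config$out_dir)) write_report(report, ref, config$out_dir)
  report
}

# per-species orthologous subsequences of one conserved region: the union
# span of each species' qualifying alignments that overlap the region,
# plus the reference interval itself
region_orthologs <- function(ref, seqs, alignments, region, criteria) {
  out <- list()
  out[[ref$species_id]] <- anchored_seq(
    substr(ref$residues, atg_to_index(ref, region$low),
           atg_to_index(ref, region$high)),
    species_id = ref$species_id, record_id = "region")
  for (sp in names(alignments)) {
    a <- alignments[[sp]]
    if (nrow(a) == 0L) next
    keep <- which(a$identity >= criteria$min_identity &
      atg_to_axis(a$q_low) <= atg_to_axis(region$high) &
      atg_to_axis(a$q_high) >= atg_to_axis(region$low))
    if (length(keep) == 0L) next
    spans <- lapply(keep, function(r)
      project_query_window(a[r, ], region$low, region$high))
    spans <- Filter(Negate(is.null), spans)
    if (length(spans) == 0L) next
    s <- seqs[[sp]]
    lo <- min(vapply(spans, `[[`, integer(1), 1L))
    hi <- max(vapply(spans, `[[`, integer(1), 2L))
    out[[sp]] <- anchored_seq(substr(s$residues, atg_to_index(s, lo),
                                     atg_to_index(s, hi)),
                              species_id = sp, record_id = "region")
  }
  out
}

# project a query-side ATG window through a gapped alignment row onto the
# subject, returning the subject's ATG interval (or NULL if the window
# covers no subject base)
project_query_window <- function(aln_row, q_from, q_to) {
  qa <- strsplit(aln_row$aligned_query, "", fixed = TRUE)[[1]]
  sa <- strsplit(aln_row$aligned_subject, "", fixed = TRUE)[[1]]
  qax <- atg_to_axis(aln_row$q_low) - 1L + cumsum(qa != "-")
  sax <- atg_to_axis(aln_row$s_low) - 1L + cumsum(sa != "-")
  inwin <- qa != "-" & qax >= atg_to_axis(q_from) & qax <= atg_to_axis(q_to) &
    sa != "-"
  if (!any(inwin)) return(NULL)
  c(axis_to_atg(min(sax[inwin])), axis_to_atg(max(sax[inwin])))
}

report_params <- function(config) {
  list(reference = config$reference,
       scheme = unclass(config$scheme),
       criteria = unclass(config$criteria),
       seed_word = config$seed_word,
       motif_threshold = config$motif_threshold,
       n_rand = config$n_rand, null_modes = config$null_modes,
       min_motif_species = config$min_motif_species,
       overlap_fraction = config$overlap_fraction,
       seed = config$seed)
}

write_report <- function(report, ref, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(report$regions, ref, file.path(out_dir, "conserved_regions.bed"))
  write.table(report$regions, file.path(out_dir, "conserved_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  aln <- do.call(rbind, c(unname(report$alignments),
                          list(make.row.names = FALSE)))
  if (!is.null(aln) && nrow(aln)) {
    write.table(aln[, setdiff(names(aln),
                              c("aligned_query", "aligned_subject"))],
                file.path(out_dir, "alignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (rid in names(report$region_msas))
    write_msa_fasta(report$region_msas[[rid]],
                    file.path(out_dir, paste0(rid, "_msa.fasta")))
  for (rid in names(report$conserved_motifs)) {
    cm <- report$conserved_motifs[[rid]]
    if (nrow(cm))
      write.table(cm, file.path(out_dir, paste0(rid, "_conserved_motifs.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$mutation_check))
    write.table(report$mutation_check, file.path(out_dir, "mutation_check.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  json <- report_json(report)
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}

# deterministic JSON view of a report (timings excluded)
report_json <- function(report) {
  list(params = report$params, counts = report$counts,
       regions = report$regions,
       overrepresentation = lapply(report$overrepresentation, function(rr)
         lapply(rr, function(o) list(matrix_id = o$matrix_id,
                                     raw_score = o$raw_score,
                                     p_values = as.list(o$p_values),
                                     n_rand = o$n_rand, seed = o$seed))),
       conserved_motifs = report$conserved_motifs,
       mutation_check = report$mutation_check)
}

#' @export
print.footprint_report <- function(x, ...) {
  cat("<footprint_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Compare called regions against an expected set
#'
#' For every expected (labelled) interval, reports the best-overlap
#' Jaccard index among the called regions and a hit/miss verdict at the
#' given threshold.  Used for validating a run against previously
#' characterised regulatory regions.
#'
#' @param called data frame with `low`/`high` ATG-relative columns.
#' @param expected data frame with `label`, `low`, `high`.
#' @param threshold Jaccard needed to count as a hit (default 0.5).
#' @return data frame: `label`, `low`, `high`, `best_jaccard`,
#'   `best_low`, `best_high`, `hit`.
#' @export
validate_against_expected <- function(called, expected, threshold = 0.5) {
  res <- lapply(seq_len(nrow(expected)), function(i) {
    e_lo <- atg_to_axis(expected$low[i]); e_hi <- atg_to_axis(expected$high[i])
    best <- 0; b_lo <- NA_integer_; b_hi <- NA_integer_
    for (j in seq_len(nrow(called))) {
      c_lo <- atg_to_axis(called$low[j]); c_hi <- atg_to_axis(called$high[j])
      inter <- max(0L, min(e_hi, c_hi) - max(e_lo, c_lo) + 1L)
      un <- (e_hi - e_lo + 1L) + (c_hi - c_lo + 1L) - inter
      jac <- inter / un
      if (jac > best) { best <- jac; b_lo <- called$low[j]; b_hi <- called$high[j] }
    }
    data.frame(label = expected$label[i], low = expected$low[i],
               high = expected$high[i], best_jaccard = best,
               best_low = b_lo, best_high = b_hi,
               hit = best >= threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
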