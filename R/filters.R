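# Admissibility, the three-step probe filter, uniqueness, and gene-name
# reconciliation, producing the per-probe annotation table.

#' Probe filter configuration
#'
#' Admissibility ("up to four mismatches and up to two gaps of up to 4 bp")
#' and the three-step retention filter: bitscore strictly above
#' `bitscore_min`, a unique genomic match, and no mismatch at or adjacent to
#' the assayed CpG.
#'
#' @param bitscore_min bitscore threshold (strict `>`; default 70).
#' @param require_unique require exactly one admissible hit.
#' @param exclude_near_cpg if `TRUE` (default) the mismatch step demands a
#'   fully clean CpG neighbourhood (category `clean`); if `FALSE` only
#'   mismatches in the CpG itself (or an absent CpG) fail the step.
#' @param max_mismatches,max_gap_runs,max_gap_len admissibility bounds
#'   (inclusive).
#' @param evalue_max e-value cutoff defining a countable hit.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(bitscore_min = 70, require_unique = TRUE,
                          exclude_near_cpg = TRUE, max_mismatches = 4L,
                          max_gap_runs = 2L, max_gap_len = 4L,
                          evalue_max = exp(-10)) {
  stopifnot(bitscore_min >= 0, max_mismatches >= 0, max_gap_runs >= 0,
            max_gap_len >= 0, evalue_max > 0)
  structure(list(bitscore_min = bitscore_min,
                 require_unique = isTRUE(require_unique),
                 exclude_near_cpg = isTRUE(exclude_near_cpg),
                 max_mismatches = as.integer(max_mismatches),
                 max_gap_runs = as.integer(max_gap_runs),
                 max_gap_len = as.integer(max_gap_len),
                 evalue_max = evalue_max),
            class = "filter_config")
}

parse_gap_lengths <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(g) as.integer(g[nzchar(g)]))
}

#' Keep admissible alignments
#'
#' Retains alignments with at most `max_mismatches` mismatches, at most
#' `max_gap_runs` gap runs, and every gap no longer than `max_gap_len`
#' (all bounds inclusive).
#'
#' @param alignments alignment data frame from [align_probe()].
#' @param cfg a [filter_config()].
#' @return The admissible subset, original order preserved.
#' @export
admit <- function(alignments, cfg = filter_config()) {
  if (nrow(alignments) == 0) return(alignments)
  gl <- parse_gap_lengths(alignments$gap_lengths)
  max_gl <- vapply(gl, function(g) if (length(g)) max(g) else 0L, integer(1))
  keep <- alignments$n_mismatch <= cfg$max_mismatches &
    alignments$n_gaps <= cfg$max_gap_runs &
    max_gl <= cfg$max_gap_len
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the three-step probe filter
#'
#' Sets `pass_bitscore` (strict `bitscore > bitscore_min`), `pass_unique`,
#' `pass_mismatch` (category `clean` when `exclude_near_cpg`, else any
#' category except `at_cpg`/`cpg_absent`) and their conjunction `pass_all`
#' on an annotation table. Probes without an admissible hit fail every step.
#'
#' @param records annotation data frame (rows from [annotate_probe_set()]).
#' @param cfg a [filter_config()].
#' @return `records` with the four flag columns set.
#' @export
three_step_filter <- function(records, cfg = filter_config()) {
  mapped <- records$n_hits > 0
  if (any(mapped & is.na(records$mismatch_category)))
    stop("mapped record lacks a mismatch annotation")
  records$pass_bitscore <- mapped & !is.na(records$bitscore) &
    records$bitscore > cfg$bitscore_min
  records$pass_unique <- mapped &
    (if (cfg$require_unique) records$unique else TRUE)
  ok_cat <- if (cfg$exclude_near_cpg) "clean" else c("clean", "near_cpg")
  records$pass_mismatch <- mapped & records$mismatch_category %in% ok_cat
  records$pass_all <- records$pass_bitscore & records$pass_unique &
    records$pass_mismatch
  records
}

split_gene_tokens <- function(x) {
  toks <- strsplit(toupper(x), "[^A-Za-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Classify the gene-name agreement of a probe
#'
#' Compares the probe's human gene annotation with the target-species gene
#' nearest its mapped CpG. Precedence: exact (case-insensitive equality) >
#' ortholog (the ortholog map sends a probe gene to the target gene) >
#' partial (any alphanumeric token shared between names) > none;
#' `unannotated` when the probe carries no gene names.
#'
#' @param probe_genes character vector of human gene names (may be empty).
#' @param target_gene target-species gene name, or `NA`/`NULL`.
#' @param ortholog_map named character vector (human -> target), optional.
#' @return One of "exact", "ortholog", "partial", "none", "unannotated".
#' @export
match_gene <- function(probe_genes, target_gene, ortholog_map = NULL) {
  probe_genes <- probe_genes[!is.na(probe_genes) & nzchar(probe_genes)]
  if (length(probe_genes) == 0) return("unannotated")
  if (is.null(target_gene) || is.na(target_gene) || !nzchar(target_gene))
    return("none")
  pg <- toupper(probe_genes); tg <- toupper(target_gene)
  if (any(pg == tg)) return("exact")
  if (!is.null(ortholog_map) && length(ortholog_map) > 0) {
    om <- setNames(toupper(unname(ortholog_map)), toupper(names(ortholog_map)))
    mapped <- unname(om[pg])
    if (any(!is.na(mapped) & mapped == tg)) return("ortholog")
  }
  t_tok <- split_gene_tokens(tg)
  for (g in pg) {
    if (any(split_gene_tokens(g) %in% t_tok)) return("partial")
  }
  "none"
}

# Nearest gene to each CpG coordinate (0 distance inside the interval, ties
# to the alphabetically first name). Vectorized over positions; `genes` is a
# BED-style data frame.
nearest_gene <- function(contig, pos0, genes) {
  out <- rep(NA_character_, length(pos0))
  if (is.null(genes) || nrow(genes) == 0) return(out)
  ok <- !is.na(pos0) & !is.na(contig)
  if (!any(ok)) return(out)
  qgr <- GenomicRanges::GRanges(contig[ok],
                                IRanges::IRanges(pos0[ok] + 1L, width = 1L))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L, genes$end))
  h <- GenomicRanges::distanceToNearest(qgr, ggr, select = "all")
  d <- as.data.frame(h)
  d$name <- genes$name[d$subjectHits]
  d <- d[order(d$queryHits, d$name), , drop = FALSE]
  d <- d[!duplicated(d$queryHits), , drop = FALSE]
  res <- rep(NA_character_, sum(ok))
  res[d$queryHits] <- d$name
  out[ok] <- res
  out
}

#' Annotate a probe set against a target genome
#'
#' The full per-probe pipeline: align (seed-and-extend), keep admissible
#' hits, count hits and uniqueness, take the best hit, project and classify
#' the assayed CpG, look up the nearest target gene, classify gene-name
#' agreement, and apply the three-step filter. Probes with no admissible hit
#' yield a record with `n_hits` 0 and all pass flags `FALSE`.
#'
#' @param probes manifest data frame.
#' @param genome target [genome_seq()].
#' @param params a [scoring_params()].
#' @param cfg a [filter_config()].
#' @param ortholog_map optional named character vector (human -> target).
#' @param genes optional gene BED data frame (chrom, start, end, name).
#' @param progress_every log every this many probes (0 = silent).
#' @return A data frame of class `cm_annotation`, one row per probe.
#' @export
annotate_probe_set <- function(probes, genome, params = scoring_params(),
                               cfg = filter_config(), ortholog_map = NULL,
                               genes = NULL, progress_every = 0L) {
  n <- nrow(probes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- probes[i, ]
    alns <- admit(align_probe(p, genome, params), cfg)
    alns <- alns[alns$evalue < cfg$evalue_max, , drop = FALSE]
    n_hits <- nrow(alns)
    if (n_hits == 0) {
      rows[[i]] <- data.frame(
        probe_id = p$probe_id, contig = NA_character_, start = NA_integer_,
        end = NA_integer_, strand = NA_character_, raw_score = NA_integer_,
        bitscore = NA_real_, evalue = NA_real_,
        percent_identity = NA_real_, n_mismatch = NA_integer_,
        n_gaps = NA_integer_, cpg_present = FALSE, cpg_mismatch = FALSE,
        near_cpg_mismatch = FALSE, n_hits = 0L, unique = FALSE,
        gene_match_class = "unannotated", mismatch_category = NA_character_,
        probe_type = p$probe_type, target_gene = NA_character_,
        cpg_coord = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    best <- alns[1, ]
    anchor <- locate_cpg(p)
    cls <- classify_mismatches(best, anchor, genome, probe_seq = p$probe_seq)
    rows[[i]] <- data.frame(
      probe_id = p$probe_id, contig = best$contig, start = best$start,
      end = best$end, strand = best$strand, raw_score = best$raw_score,
      bitscore = best$bitscore, evalue = best$evalue,
      percent_identity = best$percent_identity,
      n_mismatch = best$n_mismatch, n_gaps = best$n_gaps,
      cpg_present = cls$cpg_present, cpg_mismatch = cls$cpg_mismatch,
      near_cpg_mismatch = cls$near_cpg_mismatch, n_hits = n_hits,
      unique = n_hits == 1L, gene_match_class = NA_character_,
      mismatch_category = cls$category, probe_type = p$probe_type,
      target_gene = NA_character_, cpg_coord = cls$cpg_coord,
      stringsAsFactors = FALSE)
    if (progress_every > 0 && i %% progress_every == 0)
      message("annotated ", i, "/", n, " probes")
  }
  out <- do.call(rbind, rows)
  out$cpg_contig <- ifelse(out$n_hits > 0 & !is.na(out$cpg_coord),
                           out$contig, NA_character_)
  out$target_gene <- nearest_gene(out$cpg_contig, out$cpg_coord, genes)
  gene_lists <- strsplit(probes$gene_names, ";", fixed = TRUE)
  out$gene_match_class <- vapply(seq_len(n), function(i) {
    if (out$n_hits[i] == 0) return("unannotated")
    match_gene(gene_lists[[i]], out$target_gene[i], ortholog_map)
  }, character(1))
  out <- three_step_filter(out, cfg)
  rownames(out) <- NULL
  class(out) <- c("cm_annotation", "data.frame")
  out
}

#' Bookkeeping fractions of the probe-filtering pipeline
#'
#' Pure arithmetic on probe counts: the CM-probe count (mapped probes whose
#' assayed CpG is present and unmismatched), the CpG-mismatch fraction of
#' mapped probes, the gene-concordance fraction of annotated CM probes, and
#' the final array coverage after the three-step filter.
#'
#' @param n_total probes on the array.
#' @param n_mapped probes with an admissible genomic match.
#' @param n_cpg_mismatch mapped probes with a mismatch in the CpG itself,
#'   including those whose CpG is absent.
#' @param n_gene_annotated CM probes carrying a human gene annotation.
#' @param n_gene_matched of those, probes whose target gene agrees (exact,
#'   partial or ortholog).
#' @param n_pass_filter probes surviving the three-step filter.
#' @return List with `cm_count`, `pct_mapped`, `pct_cpg_mismatch`,
#'   `pct_cm`, `pct_gene_matched`, `pct_coverage`.
#' @export
filter_bookkeeping <- function(n_total, n_mapped, n_cpg_mismatch,
                               n_gene_annotated = NA, n_gene_matched = NA,
                               n_pass_filter = NA) {
  list(cm_count = n_mapped - n_cpg_mismatch,
       pct_mapped = 100 * n_mapped / n_total,
       pct_cpg_mismatch = 100 * n_cpg_mismatch / n_mapped,
       pct_cm = 100 * (n_mapped - n_cpg_mismatch) / n_total,
       pct_gene_matched = 100 * n_gene_matched / n_gene_annotated,
       pct_coverage = 100 * n_pass_filter / n_total)
}

#' Summarize a probe annotation table
#'
#' @param object a `cm_annotation` data frame.
#' @param ... unused.
#' @return A list of class `cm_annotation_summary`: totals, mapped and
#'   CpG-mismatch counts, CM-probe count, uniqueness and gene-concordance
#'   fractions among CM probes, and the sequential three-step filter counts.
#' @export
summary.cm_annotation <- function(object, ...) {
  n_total <- nrow(object)
  mapped <- object$n_hits > 0
  n_mapped <- sum(mapped)
  n_cpg_mm <- sum(mapped & object$cpg_mismatch)
  cm <- mapped & object$cpg_present & !object$cpg_mismatch
  n_cm <- sum(cm)
  n_unique_cm <- sum(cm & object$unique)
  annotated_cm <- cm & object$gene_match_class != "unannotated"
  matched_cm <- annotated_cm &
    object$gene_match_class %in% c("exact", "partial", "ortholog")
  seq_counts <- c(bitscore = sum(object$pass_bitscore),
                  uniqueness = sum(object$pass_bitscore & object$pass_unique),
                  mismatch = sum(object$pass_all))
  bk <- filter_bookkeeping(n_total, n_mapped, n_cpg_mm,
                           sum(annotated_cm), sum(matched_cm),
                           seq_counts[["mismatch"]])
  structure(c(list(n_total = n_total, n_mapped = n_mapped,
                   n_cpg_mismatch = n_cpg_mm, n_cm = n_cm,
                   n_unique_cm = n_unique_cm,
                   pct_unique_cm = 100 * n_unique_cm / n_cm,
                   n_gene_annotated_cm = sum(annotated_cm),
                   n_gene_matched_cm = sum(matched_cm),
                   sequential_counts = list(seq_counts)),
              bk),
            class = "cm_annotation_summary")
}

#' @export
print.cm_annotation_summary <- function(x, ...) {
  cat(sprintf("Probes: %d; mapped: %d (%.1f%%)\n",
              x$n_total, x$n_mapped, x$pct_mapped))
  cat(sprintf("CpG mismatch/absent among mapped: %d (%.1f%%)\n",
              x$n_cpg_mismatch, x$pct_cpg_mismatch))
  cat(sprintf("CM probes (mapped, CpG intact): %d (%.1f%% of array)\n",
              x$n_cm, x$pct_cm))
  cat(sprintf("Unique matches among CM probes: %d (%.1f%%)\n",
              x$n_unique_cm, x$pct_unique_cm))
  if (x$n_gene_annotated_cm > 0)
    cat(sprintf("Gene-name concordance among annotated CM probes: %d/%d (%.1f%%)\n",
                x$n_gene_matched_cm, x$n_gene_annotated_cm, x$pct_gene_matched))
  sc <- x$sequential_counts[[1]]
  cat(sprintf("Sequential filter: bitscore %d -> +uniqueness %d -> +mismatch %d (coverage %.1f%%)\n",
              sc[["bitscore"]], sc[["uniqueness"]], sc[["mismatch"]],
              x$pct_coverage))
  invisible(x)
}

#' @export
print.cm_annotation <- function(x, ...) {
  cat("Probe annotation:", nrow(x), "probes,",
      sum(x$n_hits > 0), "mapped,", sum(x$pass_all), "pass the three-step filter\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("probe_id", "contig", "start",
                                                    "bitscore", "n_hits",
                                                    "mismatch_category", "pass_all")]), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
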