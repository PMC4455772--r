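# Probe-to-genome local alignment. The production path is a word-seeded,
# band-limited Smith-Waterman (src/align.cpp); the exhaustive Smith-Waterman
# scan over every position is kept as an independent oracle for testing.
# Both strands are searched by also aligning the reverse-complemented probe
# against the + strand; hit coordinates are always reported on the + strand
# of the contig, with a strand flag.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

ALN_COLS <- c("probe_id", "contig", "start", "end", "strand", "qstart",
              "qend", "raw_score", "bitscore", "evalue", "percent_identity",
              "n_mismatch", "n_gaps", "gap_lengths", "probe_aln",
              "subject_aln")

empty_alignments <- function() {
  data.frame(probe_id = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             qstart = integer(), qend = integer(), raw_score = integer(),
             bitscore = numeric(), evalue = numeric(),
             percent_identity = numeric(), n_mismatch = integer(),
             n_gaps = integer(), gap_lengths = character(),
             probe_aln = character(), subject_aln = character(),
             stringsAsFactors = FALSE)
}

# Shared hit assembly for both engines. `engine` maps
# (query, subject, min_score) -> raw hit data frame from the C++ layer.
align_query <- function(probe_id, probe_seq, genome, params, engine) {
  probe_seq <- toupper(probe_seq)
  m <- nchar(probe_seq)
  min_score <- min_raw_score(params, m, genome)
  rows <- list()
  for (contig in names(genome$contigs)) {
    subject <- genome$contigs[[contig]]
    for (str in c("+", "-")) {
      q <- if (str == "+") probe_seq else revcomp(probe_seq)
      h <- engine(q, subject, min_score)
      if (nrow(h) == 0) next
      stats <- lapply(seq_len(nrow(h)),
                      function(i) alignment_stats(h$qaln[i], h$saln[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = probe_id, contig = contig,
        start = h$sstart, end = h$send, strand = str,
        qstart = h$qstart, qend = h$qend,
        raw_score = h$score,
        bitscore = bitscore(h$score, params),
        evalue = evalue(bitscore(h$score, params), m, genome),
        percent_identity = vapply(stats, `[[`, numeric(1), "percent_identity"),
        n_mismatch = vapply(stats, `[[`, integer(1), "n_mismatch"),
        n_gaps = vapply(stats, `[[`, integer(1), "n_gaps"),
        gap_lengths = vapply(stats, function(s)
          paste(s$gap_lengths, collapse = ","), character(1)),
        probe_aln = h$qaln, subject_aln = h$saln,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_alignments())
  out <- do.call(rbind, rows)
  out <- out[out$evalue < params$evalue_max, , drop = FALSE]
  out <- out[order(-out$bitscore, out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align one probe to a genome (seed-and-extend)
#'
#' Word-seeded local alignment of the 50-mer probe against both strands of
#' the genome, with blastn-style scoring and Karlin-Altschul statistics. Each
#' exact `word_size`-mer shared by probe and genome defines a candidate
#' diagonal; a banded (+/- 5 diagonals) affine-gap Smith-Waterman is run
#' around it. Overlapping hits in the same diagonal band collapse to the
#' highest-scoring one. Only hits with `evalue < params$evalue_max` are
#' returned, sorted by descending bitscore with ties broken by
#' (contig, start).
#'
#' A hit is guaranteed to be found whenever its optimal alignment contains an
#' exact match of length >= `word_size` and stays within the band; see
#' [brute_force_align()] for the seed-insensitive oracle.
#'
#' @param probe one manifest row (list or data frame with `probe_id`,
#'   `probe_seq`).
#' @param genome a [genome_seq()] object.
#' @param params a [scoring_params()] object.
#' @param band half-width of the diagonal band for gapped extension.
#' @return Data frame of alignments (possibly 0 rows): + strand coordinates
#'   `start`/`end` (0-based half-open), `strand`, query span, raw score,
#'   bitscore, e-value, percent identity, mismatch and gap-run counts, gap
#'   lengths, and the two gapped alignment strings (for `-` strand hits,
#'   `probe_aln` is the reverse complement of the probe as aligned to the +
#'   strand).
#' @export
align_probe <- function(probe, genome, params = scoring_params(), band = 5L) {
  engine <- function(q, subject, min_score)
    .cpp_seed_hits(q, subject, params$word_size, params$reward,
                   params$penalty, params$gap_open, params$gap_extend,
                   min_score, as.integer(band))
  align_query(probe$probe_id, probe$probe_seq, genome, params, engine)
}

#' Align one probe by exhaustive Smith-Waterman (test oracle)
#'
#' Full affine-gap Smith-Waterman of the probe against every position of both
#' strands, independent of any seeding heuristic. Same output contract as
#' [align_probe()]. Quadratic: refuses genomes over 1 Mb.
#'
#' @param probe_seq DNA string (optionally named; the name becomes the
#'   probe_id).
#' @param genome a [genome_seq()] object with `total_length <= 1e6`.
#' @param params a [scoring_params()] object.
#' @param band diagonal band half-width used only to merge overlapping hits.
#' @return Data frame of alignments, as [align_probe()].
#' @export
brute_force_align <- function(probe_seq, genome, params = scoring_params(),
                              band = 5L) {
  if (genome$total_length > 1e6)
    stop("brute_force_align is quadratic; genome exceeds 1e6 bp guard")
  id <- if (!is.null(names(probe_seq))) names(probe_seq)[1] else "query"
  engine <- function(q, subject, min_score)
    .cpp_sw_hits(q, subject, params$reward, params$penalty,
                 params$gap_open, params$gap_extend, min_score,
                 as.integer(band))
  align_query(id, unname(probe_seq)[1], genome, params, engine)
}

#' Align every probe of a manifest
#'
#' @param manifest probe manifest data frame.
#' @param genome a [genome_seq()] object.
#' @param params a [scoring_params()] object.
#' @param progress_every log a message every this many probes (0 = silent).
#' @return Data frame of alignments for all probes.
#' @export
align_probe_set <- function(manifest, genome, params = scoring_params(),
                            progress_every = 0L) {
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    out[[i]] <- align_probe(manifest[i, ], genome, params)
    if (progress_every > 0 && i %% progress_every == 0)
      message("aligned ", i, "/", nrow(manifest), " probes")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_alignments()
  rownames(res) <- NULL
  res
}

#' Write alignments as a BLAST outfmt-6-like TSV
#'
#' Standard twelve columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore; coordinates 1-based
#' inclusive on the + strand) plus extension columns `strand`, `raw_score`,
#' `gap_lengths`, `qaln`, `saln`.
#'
#' @param alignments data frame from [align_probe_set()].
#' @param path output TSV path.
#' @export
write_alignment_tsv <- function(alignments, path) {
  a <- alignments
  stats <- lapply(seq_len(nrow(a)),
                  function(i) alignment_stats(a$probe_aln[i], a$subject_aln[i]))
  out <- data.frame(
    qseqid = a$probe_id, sseqid = a$contig,
    pident = sprintf("%.4f", a$percent_identity),
    length = vapply(stats, `[[`, integer(1), "length"),
    mismatch = a$n_mismatch, gapopen = a$n_gaps,
    qstart = a$qstart + 1L, qend = a$qend,
    sstart = a$start + 1L, send = a$end,
    evalue = sprintf("%.4e", a$evalue),
    bitscore = sprintf("%.4f", a$bitscore),
    strand = a$strand, raw_score = a$raw_score,
    gap_lengths = a$gap_lengths,
    qaln = a$probe_aln, saln = a$subject_aln,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an alignment TSV written by [write_alignment_tsv()]
#' @param path TSV path.
#' @return Alignment data frame (internal 0-based coordinates restored).
#' @export
read_alignment_tsv <- function(path) {
  if (!file.exists(path)) stop("alignment TSV not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(gap_lengths = "character"))
  data.frame(probe_id = df$qseqid, contig = df$sseqid,
             start = df$sstart - 1L, end = df$send, strand = df$strand,
             qstart = df$qstart - 1L, qend = df$qend,
             raw_score = df$raw_score, bitscore = df$bitscore,
             evalue = df$evalue, percent_identity = df$pident,
             n_mismatch = df$mismatch, n_gaps = df$gapopen,
             gap_lengths = ifelse(is.na(df$gap_lengths), "", df$gap_lengths),
             probe_aln = df$qaln, subject_aln = df$saln,
             stringsAsFactors = FALSE)
}
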