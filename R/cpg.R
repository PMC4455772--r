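# Locating the assayed CpG relative to each probe alignment and classifying
# mismatches by signed distance from the CpG cytosine.
#
# Conventions (probe design-strand coordinates 0..49, 5' -> 3'):
#   * type I probes cover the CpG C with their 3'-terminal base (offset 49);
#     the G lies immediately 3' of the 50-mer.
#   * type II probes end immediately 5' of the CpG: the CG dinucleotide is
#     the virtual offsets 50/51.
#   * signed mismatch offset = probe position - CpG C position (negative =
#     5' of the CpG). Offsets 0/+1 are the CpG itself; the flanks are -1 and
#     +2 ("mismatch at +/- 1 bp from the CpG site").

#' Locate the assayed CpG in probe coordinates
#'
#' @param probe one manifest row (needs `probe_type`).
#' @return A list of class `cpg_anchor` with `probe_offset` (49 for type I;
#'   `NA` for type II, meaning immediately 3' of the 50-mer) and
#'   `derivation`.
#' @export
locate_cpg <- function(probe) {
  type <- probe$probe_type
  if (identical(type, "I")) {
    a <- list(probe_offset = 49L, derivation = "type_I_terminal")
  } else if (identical(type, "II")) {
    a <- list(probe_offset = NA_integer_, derivation = "type_II_adjacent")
  } else {
    stop("unknown probe_type: ", type)
  }
  structure(a, class = "cpg_anchor")
}

# effective CpG C offset in probe coordinates (50 = immediately 3')
anchor_offset <- function(anchor) {
  if (is.na(anchor$probe_offset)) 50L else anchor$probe_offset
}

# Map an aligned-query position to a + strand subject position.
# Returns list(spos, covered, in_gap). Positions outside the aligned query
# span are extrapolated ungapped past the alignment ends.
map_query_position <- function(aln, q) {
  if (q >= aln$qstart && q < aln$qend) {
    qc <- strsplit(aln$probe_aln, "")[[1]]
    sc <- strsplit(aln$subject_aln, "")[[1]]
    qi <- aln$qstart; si <- aln$start
    for (k in seq_along(qc)) {
      q_res <- qc[k] != "-"; s_res <- sc[k] != "-"
      if (q_res && qi == q)
        return(list(spos = if (s_res) si else NA_integer_,
                    covered = TRUE, in_gap = !s_res))
      if (q_res) qi <- qi + 1L
      if (s_res) si <- si + 1L
    }
    stop("internal: query position not found in alignment columns")
  }
  spos <- if (q < aln$qstart) aln$start - (aln$qstart - q)
          else aln$end + (q - aln$qend)
  list(spos = spos, covered = FALSE, in_gap = FALSE)
}

#' Project the assayed CpG through an alignment onto the target genome
#'
#' Maps the CpG cytosine (and its G) through the gapped alignment to +
#' strand target coordinates, handling hit strand. Anchors lying outside the
#' aligned probe span (always the case for type II probes) are extrapolated
#' ungapped past the alignment end.
#'
#' @param aln one alignment row from [align_probe()].
#' @param anchor a [locate_cpg()] anchor from the same probe.
#' @param genome the target [genome_seq()].
#' @param probe_len probe length (Infinium probes are 50-mers).
#' @return `NULL` when the projection runs off the contig or through a
#'   deletion in the target; otherwise a list with `contig`, `start`/`end`
#'   (0-based half-open + strand interval of the target dinucleotide, C
#'   first) and `dinucleotide` (as read from the + strand).
#' @export
project_cpg <- function(aln, anchor, genome, probe_len = 50L) {
  o <- anchor_offset(anchor)
  q <- if (aln$strand == "+") o else probe_len - 1L - o
  m <- map_query_position(aln, q)
  if (m$covered && m$in_gap) return(NULL)
  if (is.na(m$spos)) return(NULL)
  c_pos <- if (aln$strand == "+") m$spos else m$spos - 1L
  contig_len <- nchar(genome$contigs[[aln$contig]])
  if (c_pos < 0 || c_pos + 2 > contig_len) return(NULL)
  list(contig = aln$contig, start = c_pos, end = c_pos + 2L,
       dinucleotide = substr(genome$contigs[[aln$contig]], c_pos + 1L, c_pos + 2L))
}

#' Classify alignment mismatches relative to the assayed CpG
#'
#' Walks the gapped alignment columns recording, for every mismatch, its
#' signed offset from the CpG C in probe coordinates; gap columns count as
#' mismatches at the probe offsets they touch. Probe positions not covered by
#' the local alignment (trimmed ends) are checked directly against the genome
#' by ungapped extrapolation when `probe_seq` is supplied, so a planted
#' mismatch at a probe terminus is not silently lost to local-alignment
#' trimming; extrapolated positions falling off the contig count as
#' mismatches.
#'
#' `cpg_present` is read from the genome at the projected CpG interval.
#' `cpg_mismatch` is true when the probe mismatches the CpG itself (offsets
#' 0/+1) or the CpG is absent/unprojectable, mirroring the bookkeeping that
#' groups "mismatch in the CpG site itself, including those that do not have
#' the CpG site". Category precedence: cpg_absent > at_cpg > near_cpg >
#' clean.
#'
#' @param aln one alignment row.
#' @param anchor a [locate_cpg()] anchor.
#' @param genome the target [genome_seq()].
#' @param probe_seq the probe 50-mer (design strand); enables the
#'   uncovered-position check.
#' @param near_offsets signed offsets counting as "near the CpG"
#'   (default -1 and +2, the two bases flanking the CG).
#' @param probe_len probe length.
#' @return A list: `cpg_present`, `cpg_mismatch`, `near_cpg_mismatch`,
#'   `mismatch_offsets` (sorted unique signed integers),
#'   `n_gaps_overlapping_cpg`, `category` (clean / near_cpg / at_cpg /
#'   cpg_absent), `cpg_contig`, `cpg_coord` (0-based C position on +
#'   strand, NA if unprojectable).
#' @export
classify_mismatches <- function(aln, anchor, genome, probe_seq = NULL,
                                near_offsets = c(-1L, 2L), probe_len = 50L) {
  o <- anchor_offset(anchor)
  plus <- aln$strand == "+"
  to_probe <- function(q) if (plus) q else probe_len - 1L - q

  proj <- project_cpg(aln, anchor, genome, probe_len)
  cpg_present <- !is.null(proj) && identical(proj$dinucleotide, "CG")

  qc <- strsplit(aln$probe_aln, "")[[1]]
  sc <- strsplit(aln$subject_aln, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  offsets <- integer(0)
  gap_run_offsets <- list()   # offsets touched by each gap run
  qi <- aln$qstart
  run_open <- FALSE
  for (k in seq_along(qc)) {
    q_res <- qc[k] != "-"; s_res <- sc[k] != "-"
    if (q_res && s_res) {
      off <- to_probe(qi) - o
      if (qc[k] != sc[k] || !(qc[k] %in% acgt) || !(sc[k] %in% acgt))
        offsets <- c(offsets, off)
      qi <- qi + 1L
      run_open <- FALSE
    } else {
      # gap column: attribute to the probe position it touches
      off <- to_probe(qi) - o
      offsets <- c(offsets, off)
      if (!run_open) {
        gap_run_offsets[[length(gap_run_offsets) + 1L]] <- integer(0)
        run_open <- TRUE
      }
      gap_run_offsets[[length(gap_run_offsets)]] <-
        c(gap_run_offsets[[length(gap_run_offsets)]], off)
      if (q_res) qi <- qi + 1L
    }
  }

  # probe positions trimmed off by the local alignment
  if (!is.null(probe_seq)) {
    probe_seq <- toupper(probe_seq)
    contig <- genome$contigs[[aln$contig]]
    contig_len <- nchar(contig)
    uncovered <- setdiff(seq_len(probe_len) - 1L,
                         seq(aln$qstart, length.out = aln$qend - aln$qstart))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (q in uncovered) {
      p <- to_probe(q)
      off <- p - o
      m <- map_query_position(aln, q)
      s <- m$spos
      if (s < 0 || s >= contig_len) {
        offsets <- c(offsets, off)
        next
      }
      qbase <- substr(probe_seq, p + 1L, p + 1L)
      if (!plus) qbase <- unname(comp[qbase])
      sbase <- substr(contig, s + 1L, s + 1L)
      if (is.na(qbase) || !identical(qbase, sbase) || !(sbase %in% acgt))
        offsets <- c(offsets, off)
    }
  }

  offsets <- sort(unique(offsets))
  at <- any(offsets %in% c(0L, 1L))
  near <- any(offsets %in% near_offsets)
  cpg_window <- c(near_offsets, 0L, 1L)
  n_gap_cpg <- sum(vapply(gap_run_offsets,
                          function(g) any(g %in% cpg_window), logical(1)))
  category <- if (!cpg_present) "cpg_absent"
              else if (at) "at_cpg"
              else if (near) "near_cpg"
              else "clean"
  list(cpg_present = cpg_present,
       cpg_mismatch = at || !cpg_present,
       near_cpg_mismatch = near,
       mismatch_offsets = offsets,
       n_gaps_overlapping_cpg = n_gap_cpg,
       category = category,
       cpg_contig = if (is.null(proj)) NA_character_ else proj$contig,
       cpg_coord = if (is.null(proj)) NA_integer_ else proj$start)
}
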