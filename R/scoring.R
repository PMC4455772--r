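#' Alignment scoring parameters
#'
#' Bundles the match/mismatch scores, affine gap costs, Karlin-Altschul
#' parameters and the e-value cutoff used by [align_probe()]. Defaults mirror
#' the blastn task defaults (+2/-3, gap open 5, gap extend 2) with the gapped
#' Karlin-Altschul parameters lambda = 0.625 nats and K = 0.41 appropriate for
#' that scoring system. A length-L gap costs `gap_open + L * gap_extend`.
#'
#' The default e-value cutoff is `exp(-10)`, reading the threshold
#' "e^-10" literally as e to the minus ten; pass `evalue_max = 1e-10` for the
#' power-of-ten reading.
#'
#' @param reward integer, match score (> 0).
#' @param penalty integer, mismatch score (< 0).
#' @param gap_open,gap_extend non-negative integers, affine gap costs.
#' @param lambda,K Karlin-Altschul parameters (lambda in nats).
#' @param word_size integer >= 4, seed word length for the production aligner.
#' @param evalue_max positive e-value cutoff; alignments at or above it are
#'   discarded.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(reward = 2L, penalty = -3L,
                           gap_open = 5L, gap_extend = 2L,
                           lambda = 0.625, K = 0.41,
                           word_size = 11L, evalue_max = exp(-10)) {
  reward <- as.integer(reward); penalty <- as.integer(penalty)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  word_size <- as.integer(word_size)
  stopifnot(reward > 0, penalty < 0, gap_open >= 0, gap_extend >= 0,
            lambda > 0, K > 0, word_size >= 4, evalue_max > 0)
  structure(list(reward = reward, penalty = penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K,
                 word_size = word_size, evalue_max = evalue_max),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Scoring parameters: match", x$reward, "/ mismatch", x$penalty,
      "/ gap", paste0(x$gap_open, "+", x$gap_extend, "L"), "\n")
  cat("Karlin-Altschul: lambda =", x$lambda, ", K =", x$K,
      "; word size", x$word_size, "; E <", format(x$evalue_max), "\n")
  invisible(x)
}

#' Bitscore of a raw alignment score
#'
#' `(lambda * S - ln K) / ln 2`; strictly increasing in the raw score.
#'
#' @param raw_score numeric raw score(s).
#' @param params a [scoring_params()] object.
#' @return Numeric bitscore(s).
#' @export
bitscore <- function(raw_score, params = scoring_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Expected number of chance alignments at a given bitscore
#'
#' `m * n_eff * 2^(-bitscore)` with `m` the query length and
#' `n_eff = 2 * total genome length` (both strands searched, no edge-length
#' correction).
#'
#' @param bits numeric bitscore(s).
#' @param query_len positive integer, query length.
#' @param genome a `genome_seq` object (see [read_genome()]).
#' @return Positive numeric e-value(s).
#' @export
evalue <- function(bits, query_len, genome) {
  stopifnot(query_len > 0)
  n_eff <- 2 * genome$total_length
  query_len * n_eff * 2^(-bits)
}

# Smallest integer raw score whose e-value clears the cutoff.
min_raw_score <- function(params, query_len, genome) {
  s <- 1L
  bits_needed <- log2(query_len * 2 * genome$total_length / params$evalue_max)
  raw <- (bits_needed * log(2) + log(params$K)) / params$lambda
  s <- max(1L, as.integer(floor(raw)) - 1L)
  while (evalue(bitscore(s, params), query_len, genome) >= params$evalue_max)
    s <- s + 1L
  s
}

#' Recompute the raw score of a gapped alignment
#'
#' Scores two equal-length gapped strings under a scoring scheme. Columns with
#' two residues score `reward`/`penalty` (any non-ACGT base mismatches
#' everything); each gap run of length L costs `gap_open + L * gap_extend`.
#'
#' @param qaln,saln gapped alignment strings of equal length.
#' @param params a [scoring_params()] object.
#' @return Integer raw score.
#' @export
score_alignment <- function(qaln, saln, params = scoring_params()) {
  qc <- strsplit(toupper(qaln), "")[[1]]
  sc <- strsplit(toupper(saln), "")[[1]]
  stopifnot(length(qc) == length(sc))
  qgap <- qc == "-"; sgap <- sc == "-"
  resid <- !qgap & !sgap
  acgt <- c("A", "C", "G", "T")
  match <- resid & qc == sc & qc %in% acgt
  score <- sum(match) * params$reward + sum(resid & !match) * params$penalty
  runs <- function(g) {
    r <- rle(g)
    r$lengths[r$values]
  }
  gl <- c(runs(qgap), runs(sgap))
  score - (params$gap_open * length(gl) + params$gap_extend * sum(gl))
}

# Per-alignment statistics from the gapped strings.
alignment_stats <- function(qaln, saln) {
  qc <- strsplit(toupper(qaln), "")[[1]]
  sc <- strsplit(toupper(saln), "")[[1]]
  qgap <- qc == "-"; sgap <- sc == "-"
  resid <- !qgap & !sgap
  acgt <- c("A", "C", "G", "T")
  match <- resid & qc == sc & qc %in% acgt
  runs <- function(g) {
    r <- rle(g)
    r$lengths[r$values]
  }
  gl <- c(runs(qgap), runs(sgap))
  list(n_mismatch = sum(resid & !match),
       n_gaps = length(gl),
       gap_lengths = as.integer(gl),
       length = length(qc),
       percent_identity = 100 * sum(match) / length(qc))
}
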