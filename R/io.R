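# Readers and writers for the external table formats. Internal coordinates
# are 0-based half-open on the + strand; every file dialect here (manifest,
# methylation table, annotation CSV) is 1-based inclusive, except gene BED,
# which keeps the canonical 0-based half-open BED convention. Conversion
# happens only at this boundary.

#' Construct a genome object from named sequences
#'
#' @param contigs named character vector of DNA sequences (upper-cased on
#'   construction; IUPAC ambiguity codes allowed, treated as mismatching
#'   everything by the aligner).
#' @return An object of class `genome_seq` with elements `contigs` and
#'   `total_length`.
#' @export
genome_seq <- function(contigs) {
  if (length(contigs) == 0) stop("genome has no contigs")
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig name: ",
         names(contigs)[duplicated(names(contigs))][1])
  contigs <- toupper(contigs)
  structure(list(contigs = contigs,
                 total_length = sum(nchar(contigs))),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("Genome:", length(x$contigs), "contig(s),",
      x$total_length, "bp total\n")
  invisible(x)
}

#' Read a genome FASTA
#'
#' @param path FASTA file, possibly multi-contig. Sequence names are taken up
#'   to the first whitespace.
#' @return A [genome_seq()] object.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  genome_seq(setNames(as.character(seqs), nm))
}

#' Write a genome FASTA
#'
#' @param genome a [genome_seq()] object.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(genome$contigs), path, width = 70L)
  invisible(path)
}

#' Read a probe manifest
#'
#' Expects a CSV with header columns `probe_id`, `probe_seq`, `chrom`,
#' `cpg_pos` (1-based coordinate of the C of the assayed CpG on the + strand),
#' `strand`, `probe_type` (I/II), `gene_names` (';'-separated, possibly
#' empty), and optionally `polymorphic_flag`. Gene names are de-duplicated
#' preserving order.
#'
#' @param path CSV path.
#' @return A data frame with one row per probe; `gene_names` holds the
#'   ';'-joined de-duplicated names.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("probe_id", "probe_seq", "chrom", "cpg_pos", "strand",
           "probe_type", "gene_names")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("manifest missing column(s): ",
                             paste(miss, collapse = ", "))
  df$cpg_pos <- as.integer(df$cpg_pos)
  if ("polymorphic_flag" %in% names(df)) {
    df$polymorphic_flag <- as.logical(df$polymorphic_flag)
  } else {
    df$polymorphic_flag <- FALSE
  }
  validate_manifest(df)
  df$gene_names <- vapply(strsplit(df$gene_names, ";", fixed = TRUE),
                          function(g) paste(unique(g[nzchar(g)]), collapse = ";"),
                          character(1))
  df
}

validate_manifest <- function(df) {
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) stop("duplicate probe_id in manifest: ", dup[1])
  seqs <- toupper(df$probe_seq)
  bad_len <- which(nchar(seqs) != 50L)
  if (length(bad_len) > 0)
    stop("probe_seq is not 50 bp at manifest row ", bad_len[1])
  bad_alpha <- which(grepl("[^ACGT]", seqs))
  if (length(bad_alpha) > 0)
    stop("probe_seq contains non-ACGT base at manifest row ", bad_alpha[1])
  if (!all(df$strand %in% c("+", "-")))
    stop("manifest strand must be '+' or '-'")
  if (!all(df$probe_type %in% c("I", "II")))
    stop("manifest probe_type must be 'I' or 'II'")
  if (any(is.na(df$cpg_pos)) || any(df$cpg_pos < 1L))
    stop("manifest cpg_pos must be an integer >= 1")
  invisible(df)
}

#' Write a probe manifest
#'
#' @param manifest data frame as returned by [read_manifest()].
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("probe_id", "probe_seq", "chrom", "cpg_pos", "strand",
            "probe_type", "gene_names", "polymorphic_flag")
  write.csv(manifest[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-CpG bisulfite methylation count table
#'
#' Tab-separated with header columns `chrom`, `pos` (1-based C of the CpG on
#' the + strand), `meth_count`, `total_count`. Rows below the coverage cutoff
#' are dropped (the boundary is inclusive: "at least 10x" keeps depth 10), the
#' methylation ratio is computed for the rest, and rows are returned sorted by
#' (chrom, pos).
#'
#' @param path TSV path.
#' @param min_coverage minimum read depth retained (inclusive).
#' @return Data frame with columns chrom, pos, meth_count, total_count, ratio.
#' @export
read_meth_table <- function(path, min_coverage = 10L) {
  if (!file.exists(path)) stop("methylation table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "meth_count", "total_count")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("methylation table missing column(s): ",
                             paste(miss, collapse = ", "))
  bad <- which(df$meth_count > df$total_count)
  if (length(bad) > 0)
    stop("meth_count exceeds total_count at row ", bad[1])
  df <- df[df$total_count >= min_coverage, , drop = FALSE]
  df$ratio <- ifelse(df$total_count > 0, df$meth_count / df$total_count, NA_real_)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a methylation count table
#'
#' @param calls data frame with chrom, pos, meth_count, total_count.
#' @param path output TSV path.
#' @export
write_meth_table <- function(calls, path) {
  write.table(calls[, c("chrom", "pos", "meth_count", "total_count")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an array beta-value matrix
#'
#' CSV with a `probe_id` first column and one column per sample; values in
#' `[0, 1]`, empty cells for missing. An optional parallel CSV of the same
#' shape carries per-probe detection p-values.
#'
#' @param path beta CSV path.
#' @param detection_path optional detection p-value CSV path.
#' @return A list of class `beta_matrix` with `beta` (numeric matrix, probes
#'   x samples) and `detection_p` (matrix or NULL).
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  if (!file.exists(path)) stop("beta matrix not found: ", path)
  read_mat <- function(p) {
    df <- read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "probe_id") stop("first column must be probe_id: ", p)
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- df$probe_id
    m
  }
  beta <- read_mat(path)
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values outside [0, 1]")
  dp <- NULL
  if (!is.null(detection_path)) {
    dp <- read_mat(detection_path)
    if (!identical(dim(dp), dim(beta)))
      stop("detection p-value matrix dimensions differ from beta matrix")
  }
  structure(list(beta = beta, detection_p = dp), class = "beta_matrix")
}

#' Write an array beta-value matrix
#'
#' @param bm a `beta_matrix` (or a bare numeric matrix with dimnames).
#' @param path beta CSV path.
#' @param detection_path optional detection p-value CSV path.
#' @export
write_beta_matrix <- function(bm, path, detection_path = NULL) {
  if (is.matrix(bm)) bm <- structure(list(beta = bm, detection_p = NULL),
                                     class = "beta_matrix")
  write_mat <- function(m, p) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, p, row.names = FALSE, quote = FALSE, na = "")
  }
  write_mat(bm$beta, path)
  if (!is.null(detection_path) && !is.null(bm$detection_p))
    write_mat(bm$detection_p, detection_path)
  invisible(path)
}

#' Read an ortholog gene-name map
#'
#' Two-column TSV with header `human_gene`, `target_gene`.
#'
#' @param path TSV path.
#' @return Named character vector: target names keyed by human names.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("ortholog map not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("human_gene", "target_gene") %in% names(df)))
    stop("ortholog map needs columns human_gene, target_gene")
  setNames(df$target_gene, df$human_gene)
}

#' Write an ortholog gene-name map
#' @param map named character vector (human -> target).
#' @param path output TSV path.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(data.frame(human_gene = names(map), target_gene = unname(map)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene annotation BED
#'
#' Four columns (chrom, start, end, name), no header, canonical BED 0-based
#' half-open coordinates.
#'
#' @param path BED path.
#' @return Data frame with columns chrom, start, end, name.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("gene BED not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene BED needs 4 columns (chrom, start, end, name)")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "name")
  df
}

#' Write a gene annotation BED
#' @param genes data frame with chrom, start, end, name (0-based half-open).
#' @param path output path.
#' @export
write_gene_bed <- function(genes, path) {
  write.table(genes[, c("chrom", "start", "end", "name")], path,
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed column order of the annotation deliverable
ANNOT_COLS <- c("probe_id", "contig", "start", "end", "strand", "raw_score",
                "bitscore", "evalue", "percent_identity", "n_mismatch",
                "n_gaps", "cpg_present", "cpg_mismatch", "near_cpg_mismatch",
                "n_hits", "unique", "gene_match_class", "pass_bitscore",
                "pass_unique", "pass_mismatch", "pass_all",
                # extension columns
                "mismatch_category", "probe_type", "target_gene", "cpg_coord")

#' Write the probe annotation file
#'
#' One row per probe with the best-hit alignment, CpG conservation/mismatch
#' classification, hit multiplicity and the three sequential filter flags, in
#' a fixed column order. Coordinates are written 1-based inclusive; the four
#' trailing columns (mismatch category, probe type, nearest target gene,
#' projected CpG coordinate) extend the core record. Floats carry 4 decimals
#' (e-values: 4 significant digits).
#'
#' @param records annotation data frame from [annotate_probe_set()].
#' @param path output CSV path.
#' @export
write_annotation <- function(records, path) {
  if (is.null(records) || nrow(records) == 0)
    stop("no annotation records to write")
  out <- records[, ANNOT_COLS]
  out$start <- out$start + 1L          # 1-based inclusive
  out$cpg_coord <- out$cpg_coord + 1L
  for (col in c("bitscore", "percent_identity"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.4f", out[[col]]))
  out$evalue <- ifelse(is.na(out$evalue), "", sprintf("%.4e", out$evalue))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a probe annotation file written by [write_annotation()]
#'
#' @param path CSV path.
#' @return Annotation data frame (internal 0-based coordinates restored).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$start <- df$start - 1L
  df$cpg_coord <- df$cpg_coord - 1L
  for (col in c("cpg_present", "cpg_mismatch", "near_cpg_mismatch", "unique",
                "pass_bitscore", "pass_unique", "pass_mismatch", "pass_all"))
    df[[col]] <- as.logical(df[[col]])
  df$cpg_contig <- ifelse(!is.na(df$cpg_coord), df$contig, NA_character_)
  class(df) <- c("cm_annotation", "data.frame")
  df
}
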