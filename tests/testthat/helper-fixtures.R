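# Shared fixtures and small independent oracles. Cohorts are memoized so
# several test files can reuse the same annotated synthetic study.

.fixture_cache <- new.env(parent = emptyenv())

# 100-probe default-proportion study with its annotation, reused widely
cohort_fixture <- function() {
  if (!exists("default", .fixture_cache)) {
    co <- synthetic_cohort(seed = 101, n_probes = 100,
                           genome_length = 40000, n_samples = 4)
    co$annot <- annotate_probe_set(co$manifest, co$genome,
                                   ortholog_map = co$orthologs,
                                   genes = co$genes)
    assign("default", co, .fixture_cache)
  }
  get("default", .fixture_cache)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build an alignment row from explicit gapped strings
make_aln <- function(qaln, saln, start, qstart = 0L, strand = "+",
                     contig = "c1", probe_id = "p1",
                     params = scoring_params()) {
  st <- crossmeth:::alignment_stats(qaln, saln)
  q_res <- sum(strsplit(qaln, "")[[1]] != "-")
  s_res <- sum(strsplit(saln, "")[[1]] != "-")
  data.frame(probe_id = probe_id, contig = contig,
             start = as.integer(start), end = as.integer(start + s_res),
             strand = strand, qstart = as.integer(qstart),
             qend = as.integer(qstart + q_res),
             raw_score = score_alignment(qaln, saln, params),
             bitscore = NA_real_, evalue = NA_real_,
             percent_identity = st$percent_identity,
             n_mismatch = st$n_mismatch, n_gaps = st$n_gaps,
             gap_lengths = paste(st$gap_lengths, collapse = ","),
             probe_aln = qaln, subject_aln = saln,
             stringsAsFactors = FALSE)
}

# textbook two-pass Pearson correlation (independent of stats::cor)
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# genome of 'A's with one CG planted so that a type I probe window ending at
# cpg_c carries the C at its 3' terminus
flat_genome <- function(len = 400, cpg_c = 149) {
  chars <- rep("A", len)
  chars[cpg_c + 1] <- "C"; chars[cpg_c + 2] <- "G"
  genome_seq(setNames(paste(chars, collapse = ""), "c1"))
}
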