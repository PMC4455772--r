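fake_aln_row <- function(n_mismatch, n_gaps, gap_lengths = "") {
  data.frame(probe_id = "p", contig = "c1", start = 0L, end = 50L,
             strand = "+", qstart = 0L, qend = 50L, raw_score = 80L,
             bitscore = 75, evalue = 1e-10, percent_identity = 92,
             n_mismatch = n_mismatch, n_gaps = n_gaps,
             gap_lengths = gap_lengths, probe_aln = "", subject_aln = "",
             stringsAsFactors = FALSE)
}

test_that("admissibility bounds are inclusive", {
  cfg <- filter_config()
  expect_equal(nrow(admit(fake_aln_row(5L, 0L), cfg)), 0)
  expect_equal(nrow(admit(fake_aln_row(4L, 2L, "4,4"), cfg)), 1)
  expect_equal(nrow(admit(fake_aln_row(0L, 1L, "5"), cfg)), 0)
  expect_equal(nrow(admit(fake_aln_row(0L, 3L, "1,1,1"), cfg)), 0)
})

test_that("admitted count equals a naive recount on random alignments", {
  set.seed(21)
  rows <- do.call(rbind, lapply(1:200, function(i) {
    ng <- sample(0:3, 1)
    gl <- if (ng > 0) sample(1:6, ng, replace = TRUE) else integer(0)
    fake_aln_row(sample(0:6, 1), ng, paste(gl, collapse = ","))
  }))
  cfg <- filter_config()
  gl <- crossmeth:::parse_gap_lengths(rows$gap_lengths)
  naive <- sum(rows$n_mismatch <= 4 & rows$n_gaps <= 2 &
                 vapply(gl, function(g) length(g) == 0 || max(g) <= 4,
                        logical(1)))
  expect_equal(nrow(admit(rows, cfg)), naive)
})

test_that("the bitscore step is strictly greater-than 70", {
  rec <- data.frame(probe_id = "p", bitscore = 70, unique = TRUE,
                    mismatch_category = "clean", n_hits = 1L,
                    stringsAsFactors = FALSE)
  out <- three_step_filter(rec, filter_config())
  expect_false(out$pass_bitscore)
  expect_false(out$pass_all)
  rec$bitscore <- 70 + 1e-9
  expect_true(three_step_filter(rec, filter_config())$pass_bitscore)
})

test_that("a near-CpG mismatch fails the mismatch step despite a good hit", {
  rec <- data.frame(probe_id = "p", bitscore = 71, unique = TRUE,
                    mismatch_category = "near_cpg", n_hits = 1L,
                    stringsAsFactors = FALSE)
  out <- three_step_filter(rec, filter_config())
  expect_true(out$pass_bitscore)
  expect_true(out$pass_unique)
  expect_false(out$pass_mismatch)
  expect_false(out$pass_all)
  # the relaxed reading only rejects the CpG itself
  out2 <- three_step_filter(rec, filter_config(exclude_near_cpg = FALSE))
  expect_true(out2$pass_all)
  # unmapped probes fail everything; missing annotation on a mapped probe errors
  rec$mismatch_category <- NA_character_
  expect_error(three_step_filter(rec, filter_config()), "mismatch annotation")
  rec$n_hits <- 0L
  expect_false(any(unlist(three_step_filter(rec, filter_config())[
    c("pass_bitscore", "pass_unique", "pass_mismatch", "pass_all")])))
})

test_that("gene matching follows the exact > ortholog > partial precedence", {
  expect_equal(match_gene("TP53", "TP53"), "exact")
  expect_equal(match_gene("tp53", "TP53"), "exact")
  expect_equal(match_gene("TP53", "LOC-TP53-like"), "partial")
  expect_equal(match_gene("HBA1", "MACF-HBA", c(HBA1 = "MACF-HBA")), "ortholog")
  expect_equal(match_gene("HBA1", "ZZZ9"), "none")
  expect_equal(match_gene(character(0), "TP53"), "unannotated")
  expect_equal(match_gene("TP53", NA_character_), "none")
})

test_that("a planted five-class cohort passes at exactly the clean fraction", {
  co <- synthetic_cohort(seed = 301, n_probes = 50, genome_length = 25000,
                         n_samples = 2,
                         proportions = c(clean = 0.2, mm_far = 0,
                                         mm_near = 0.2, mm_cpg = 0.2,
                                         cpg_lost = 0, duplicated = 0.2,
                                         absent = 0.2))
  annot <- annotate_probe_set(co$manifest, co$genome)
  expect_equal(sum(annot$pass_all), sum(co$truth$class == "clean"))
  expect_identical(annot$pass_all, co$truth$class == "clean")
})

test_that("tightening any filter never increases the pass count", {
  co <- cohort_fixture()
  annot <- co$annot
  base <- sum(three_step_filter(annot, filter_config())$pass_all)
  for (cfg in list(filter_config(bitscore_min = 75),
                   filter_config(bitscore_min = 80),
                   filter_config(exclude_near_cpg = TRUE))) {
    expect_lte(sum(three_step_filter(annot, cfg)$pass_all), base)
  }
  relaxed <- sum(three_step_filter(annot, filter_config(require_unique = FALSE))$pass_all)
  expect_gte(relaxed, base)
})

test_that("sequential filter counts are non-increasing and order-independent", {
  co <- cohort_fixture()
  a <- co$annot
  n1 <- sum(a$pass_bitscore)
  n2 <- sum(a$pass_bitscore & a$pass_unique)
  n3 <- sum(a$pass_bitscore & a$pass_unique & a$pass_mismatch)
  expect_true(n1 >= n2 && n2 >= n3)
  expect_equal(n3, sum(a$pass_mismatch & a$pass_unique & a$pass_bitscore))
  expect_equal(n3, sum(a$pass_all))
  s <- summary(a)
  expect_equal(unname(s$sequential_counts[[1]]), c(n1, n2, n3))
})

test_that("CM-probe identity: CM = mapped - (CpG mismatch or absent)", {
  co <- cohort_fixture()
  a <- co$annot
  s <- summary(a)
  expect_equal(s$n_cm, s$n_mapped - s$n_cpg_mismatch)
  # against the generator truth: conserved CpG without a probe-side CpG hit
  expected_cm <- sum(co$truth$cpg_conserved & co$truth$class != "mm_cpg")
  expect_equal(s$n_cm, expected_cm)
})

test_that("summary fractions equal an independent table scan", {
  co <- cohort_fixture()
  a <- co$annot
  s <- summary(a)
  expect_equal(s$pct_mapped, 100 * mean(a$n_hits > 0))
  expect_equal(s$pct_cpg_mismatch,
               100 * sum(a$n_hits > 0 & a$cpg_mismatch) / sum(a$n_hits > 0))
  expect_equal(s$pct_coverage, 100 * mean(a$pass_all))
  cm <- a$n_hits > 0 & a$cpg_present & !a$cpg_mismatch
  expect_equal(s$pct_unique_cm, 100 * sum(cm & a$unique) / sum(cm))
})

test_that("probes absent from the genome yield empty records", {
  set.seed(33)
  g <- generate_genome(33, 5000)
  man <- data.frame(probe_id = "cg_none", probe_seq = rand_seq(50),
                    chrom = "syn1", cpg_pos = 10L, strand = "+",
                    probe_type = "I", gene_names = "",
                    polymorphic_flag = FALSE, stringsAsFactors = FALSE)
  a <- annotate_probe_set(man, g)
  expect_equal(a$n_hits, 0L)
  expect_false(a$pass_all)
  expect_true(is.na(a$bitscore))
})
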