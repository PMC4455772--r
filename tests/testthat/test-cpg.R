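test_that("CpG anchors follow the probe chemistry conventions", {
  a1 <- locate_cpg(list(probe_type = "I"))
  expect_equal(a1$probe_offset, 49L)
  expect_equal(a1$derivation, "type_I_terminal")
  a2 <- locate_cpg(list(probe_type = "II"))
  expect_true(is.na(a2$probe_offset))
  expect_equal(a2$derivation, "type_II_adjacent")
  expect_error(locate_cpg(list(probe_type = "III")), "probe_type")
})

test_that("ungapped projection is plain offset arithmetic on both strands", {
  g <- flat_genome(400, cpg_c = 149)
  probe <- substr(g$contigs[[1]], 101, 150)      # ends on the C at 0-based 149
  aln <- make_aln(probe, probe, start = 100)
  proj <- project_cpg(aln, locate_cpg(list(probe_type = "I")), g)
  expect_equal(proj$start, 149L)
  expect_equal(proj$end, 151L)
  expect_equal(proj$dinucleotide, "CG")

  # same chemistry on a - strand hit: the design-strand C maps onto the +
  # strand G, so the CpG C sits one base 5' of it. For - strand hits the
  # stored probe_aln is the reverse complement of the probe, i.e. the +
  # strand window itself.
  g2chars <- rep("A", 400); g2chars[100] <- "C"; g2chars[101] <- "G"  # 0-based 99/100
  g2 <- genome_seq(c(c1 = paste(g2chars, collapse = "")))
  win <- substr(g2$contigs[[1]], 101, 150)       # starts at 0-based 100 = the G
  aln2 <- make_aln(win, win, start = 100, strand = "-")
  proj2 <- project_cpg(aln2, locate_cpg(list(probe_type = "I")), g2)
  expect_equal(proj2$start, 99L)
  expect_equal(proj2$dinucleotide, "CG")
})

test_that("type II anchors project immediately 3' of the alignment", {
  g <- flat_genome(400, cpg_c = 150)             # CG at 0-based 150/151
  probe <- substr(g$contigs[[1]], 101, 150)      # window [100, 150)
  aln <- make_aln(probe, probe, start = 100)
  proj <- project_cpg(aln, locate_cpg(list(probe_type = "II")), g)
  expect_equal(proj$start, 150L)
  expect_equal(proj$dinucleotide, "CG")
})

test_that("a target deletion 5' of the CpG shifts the projection by its length", {
  # hand-traced: 10 query bases, then a 2-bp deletion in the target
  # (columns where the subject shows '-'), then the rest; the C that would
  # land at start+49 lands at start+47
  g <- flat_genome(400, cpg_c = 147)
  chars <- strsplit(g$contigs[[1]], "")[[1]]
  subject_res <- paste(chars[101:148], collapse = "")   # 48 bases, [100,148)
  qaln <- paste0(substr(subject_res, 1, 10), "TT", substr(subject_res, 11, 48))
  saln <- paste0(substr(subject_res, 1, 10), "--", substr(subject_res, 11, 48))
  aln <- make_aln(qaln, saln, start = 100)
  expect_equal(aln$qend, 50L)
  expect_equal(aln$end, 148L)
  proj <- project_cpg(aln, locate_cpg(list(probe_type = "I")), g)
  expect_equal(proj$start, 147L)
  expect_equal(proj$dinucleotide, "CG")
})

test_that("projection through a deletion or off the contig returns NONE", {
  g <- flat_genome(400, cpg_c = 149)
  probe <- substr(g$contigs[[1]], 101, 150)
  # CpG C itself aligned against a subject gap
  qaln <- probe
  saln <- paste0(substr(probe, 1, 49), "-")
  aln <- make_aln(qaln, saln, start = 100)
  expect_null(project_cpg(aln, locate_cpg(list(probe_type = "I")), g))
  # projection past the contig end
  g_short <- genome_seq(c(c1 = substr(g$contigs[[1]], 1, 150)))
  aln2 <- make_aln(probe, probe, start = 100)
  expect_null(project_cpg(aln2, locate_cpg(list(probe_type = "II")), g_short))
})

test_that("mismatch offsets drive the category exactly as planted", {
  g <- flat_genome(400, cpg_c = 149)
  window <- substr(g$contigs[[1]], 101, 150)
  anchor <- locate_cpg(list(probe_type = "I"))
  mutate_at <- function(s, j, b) { substr(s, j + 1, j + 1) <- b; s }

  clean <- classify_mismatches(make_aln(window, window, 100), anchor, g,
                               probe_seq = window)
  expect_true(clean$cpg_present)
  expect_false(clean$cpg_mismatch)
  expect_equal(clean$category, "clean")
  expect_length(clean$mismatch_offsets, 0)

  cases <- list(list(j = 44L, off = -5L, cat = "clean"),
                list(j = 48L, off = -1L, cat = "near_cpg"),
                list(j = 49L, off = 0L, cat = "at_cpg"))
  for (cs in cases) {
    probe <- mutate_at(window, cs$j, "T")
    cls <- classify_mismatches(make_aln(probe, window, 100), anchor, g,
                               probe_seq = probe)
    expect_equal(cls$mismatch_offsets, cs$off)
    expect_equal(cls$category, cs$cat)
    expect_equal(cls$near_cpg_mismatch, cs$cat == "near_cpg")
    expect_equal(cls$cpg_mismatch, cs$cat == "at_cpg")
    expect_true(cls$cpg_present)
  }

  # absent CpG: genome dinucleotide mutated away
  g_lost <- genome_seq(c(c1 = sub("CG", "TA", g$contigs[[1]])))
  win_l <- substr(g_lost$contigs[[1]], 101, 150)
  cls <- classify_mismatches(make_aln(window, win_l, 100), anchor, g_lost,
                             probe_seq = window)
  expect_false(cls$cpg_present)
  expect_true(cls$cpg_mismatch)
  expect_equal(cls$category, "cpg_absent")
})

test_that("a gap over the CpG flank counts as a mismatch at that offset", {
  g <- flat_genome(400, cpg_c = 149)
  window <- substr(g$contigs[[1]], 101, 150)
  # subject insertion between probe positions 47 and 48: gap column at
  # offset -1
  qaln <- paste0(substr(window, 1, 48), "-", substr(window, 49, 50))
  saln <- paste0(substr(window, 1, 48), "G", substr(window, 49, 50))
  aln <- make_aln(qaln, saln, 100)
  cls <- classify_mismatches(aln, locate_cpg(list(probe_type = "I")), g,
                             probe_seq = window)
  expect_true(-1L %in% cls$mismatch_offsets)
  expect_true(cls$near_cpg_mismatch)
  expect_equal(cls$n_gaps_overlapping_cpg, 1L)
})

test_that("offsets agree with an independent column walk on real alignments", {
  co <- cohort_fixture()
  checked <- 0L
  for (i in seq(2, 100, by = 2)) {
    p <- co$manifest[i, ]
    alns <- align_probe(p, co$genome)
    if (nrow(alns) == 0) next
    aln <- alns[1, ]
    anchor <- locate_cpg(p)
    o <- crossmeth:::anchor_offset(anchor)
    cls <- classify_mismatches(aln, anchor, co$genome)   # covered columns only
    qc <- strsplit(aln$probe_aln, "")[[1]]
    sc <- strsplit(aln$subject_aln, "")[[1]]
    offs <- integer(0); qi <- aln$qstart
    for (k in seq_along(qc)) {
      pth <- if (aln$strand == "+") qi else 49L - qi
      if (qc[k] != "-" && sc[k] != "-") {
        if (qc[k] != sc[k]) offs <- c(offs, pth - o)
        qi <- qi + 1L
      } else {
        offs <- c(offs, pth - o)
        if (qc[k] != "-") qi <- qi + 1L
      }
    }
    expect_equal(cls$mismatch_offsets, sort(unique(offs)), info = p$probe_id)
    checked <- checked + 1L
  }
  expect_gt(checked, 30)
})

test_that("classification is invariant under genome reverse complement", {
  co <- cohort_fixture()
  g <- co$genome
  g_rc <- genome_seq(setNames(crossmeth:::revcomp(g$contigs[[1]]),
                              names(g$contigs)))
  for (i in seq(1, 60, by = 4)) {
    p <- co$manifest[i, ]
    anchor <- locate_cpg(p)
    a1 <- align_probe(p, g); a2 <- align_probe(p, g_rc)
    expect_equal(nrow(a1), nrow(a2), info = p$probe_id)
    if (nrow(a1) == 0) next
    c1 <- classify_mismatches(a1[1, ], anchor, g, probe_seq = p$probe_seq)
    c2 <- classify_mismatches(a2[1, ], anchor, g_rc, probe_seq = p$probe_seq)
    expect_equal(c1$category, c2$category, info = p$probe_id)
    expect_equal(c1$mismatch_offsets, c2$mismatch_offsets, info = p$probe_id)
  }
})

test_that("every mapped probe gets exactly one category and counts add up", {
  co <- cohort_fixture()
  mapped <- co$annot[co$annot$n_hits > 0, ]
  expect_true(all(mapped$mismatch_category %in%
                    c("clean", "near_cpg", "at_cpg", "cpg_absent")))
  tab <- table(mapped$mismatch_category)
  expect_equal(sum(tab), nrow(mapped))
})
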