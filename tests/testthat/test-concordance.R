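toy_annot <- function() {
  structure(data.frame(
    probe_id = c("cg1", "cg2"), contig = "c1", start = c(100L, 300L),
    end = c(150L, 350L), strand = "+", raw_score = 100L, bitscore = 91.5,
    evalue = 1e-20, percent_identity = 100, n_mismatch = 0L, n_gaps = 0L,
    cpg_present = TRUE, cpg_mismatch = FALSE, near_cpg_mismatch = FALSE,
    n_hits = 1L, unique = TRUE, gene_match_class = "exact",
    mismatch_category = "clean", probe_type = c("I", "II"),
    target_gene = "G", cpg_coord = c(149L, 350L), cpg_contig = "c1",
    pass_bitscore = TRUE, pass_unique = TRUE, pass_mismatch = TRUE,
    pass_all = TRUE, stringsAsFactors = FALSE),
    class = c("cm_annotation", "data.frame"))
}

toy_calls <- function(pos, ratio, depth = 20L) {
  data.frame(chrom = "c1", pos = pos, meth_count = round(ratio * depth),
             total_count = depth, ratio = ratio, stringsAsFactors = FALSE)
}

test_that("probes pair at the C and fold calls made on the G", {
  annot <- toy_annot()
  beta <- matrix(c(0.2, 0.8), 2, 1, dimnames = list(c("cg1", "cg2"), "S01"))
  # cg1: call exactly on the C (1-based 150); cg2: call on the G (1-based 352)
  meth <- list(S01 = toy_calls(c(150L, 352L), c(0.4, 0.9)))
  pairs <- join_shared(annot, beta, meth)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$seq_ratio, c(0.4, 0.9))
  expect_equal(pairs$diff, c(0.2, 0.1))
  expect_equal(pairs$mean_meth, c(0.3, 0.85))
  expect_equal(pairs$meth_tier, c("mid", "high"))
  # missing beta drops the pair
  beta[1, 1] <- NA
  expect_equal(nrow(join_shared(annot, beta, meth)), 1)
})

test_that("pair count on synthetic data equals the generator expectation", {
  co <- cohort_fixture()
  pairs <- join_shared(co$annot, co$betas, co$meth)
  # expected: conserved primary CpG, call retained at >= 10x, beta present
  truth <- co$truth
  expected <- 0L
  for (s in names(co$meth)) {
    call_keys <- c(paste(co$meth[[s]]$chrom, co$meth[[s]]$pos - 1L),
                   paste(co$meth[[s]]$chrom, co$meth[[s]]$pos - 2L))
    ok <- !is.na(truth$cpg_coord0) &
      paste(truth$contig, truth$cpg_coord0) %in% call_keys &
      !is.na(co$betas$beta[truth$probe_id, s])
    expected <- expected + sum(ok)
  }
  expect_equal(nrow(pairs), expected)
})

test_that("identical measurements give r = 1 and all bins at 100", {
  pairs <- data.frame(probe_id = paste0("p", 1:3), sample_id = "S01",
                      beta = c(0.1, 0.5, 0.9), seq_ratio = c(0.1, 0.5, 0.9),
                      stringsAsFactors = FALSE)
  s <- summarize_concordance(pairs)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$pct_within_20, 100)
  expect_equal(s$pct_within_5, 100)
})

test_that("the worked four-point example reproduces exactly", {
  pairs <- data.frame(probe_id = paste0("p", 1:4), sample_id = "S01",
                      beta = c(0, 0.2, 0.4, 0.6),
                      seq_ratio = c(0.1, 0.1, 0.5, 0.9),
                      stringsAsFactors = FALSE)
  for (m in c("pooled", "per_sample")) {
    s <- summarize_concordance(pairs, method = m)
    expect_equal(s$pearson_r, 0.943879807448539, tolerance = 1e-9)
    expect_equal(s$pct_within_20, 75)
    expect_equal(s$pct_within_10, 75)
    expect_equal(s$pct_within_5, 0)
  }
})

test_that("zero-variance strata report NA correlation, not NaN", {
  pairs <- data.frame(probe_id = paste0("p", 1:3), sample_id = "S01",
                      beta = c(0.5, 0.5, 0.5), seq_ratio = c(0.1, 0.5, 0.9),
                      stringsAsFactors = FALSE)
  s <- summarize_concordance(pairs)
  expect_true(is.na(s$pearson_r))
  expect_false(is.nan(s$pearson_r))
})

test_that("Pearson agrees with a textbook two-pass computation", {
  set.seed(77)
  for (i in 1:20) {
    x <- runif(50); y <- x + rnorm(50, 0, 0.2)
    pairs <- data.frame(probe_id = paste0("p", 1:50), sample_id = "S01",
                        beta = x, seq_ratio = y, stringsAsFactors = FALSE)
    s <- summarize_concordance(pairs, method = "pooled")
    expect_equal(s$pearson_r, pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("error bins are nested in every stratum of a synthetic run", {
  co <- cohort_fixture()
  pairs <- join_shared(co$annot, co$betas, co$meth)
  for (stratum in c("bitscore_bin", "unique", "mismatch_category",
                    "probe_type", "meth_tier")) {
    s <- summarize_concordance(pairs, stratum)
    expect_true(all(s$pct_within_5 <= s$pct_within_10 + 1e-12))
    expect_true(all(s$pct_within_10 <= s$pct_within_20 + 1e-12))
  }
})

test_that("Bland-Altman differences are sequencing minus array", {
  pairs <- data.frame(probe_id = "p1", sample_id = "S01",
                      beta = 0.2, seq_ratio = 0.4,
                      mean_meth = 0.3, diff = 0.2, stringsAsFactors = FALSE)
  ba <- bland_altman(pairs)
  expect_equal(ba$table$mean_meth, 0.3)
  expect_equal(ba$table$diff, 0.2)

  co <- cohort_fixture()
  all_pairs <- join_shared(co$annot, co$betas, co$meth)
  ba2 <- bland_altman(all_pairs)
  expect_equal(ba2$mean_diff,
               mean(all_pairs$seq_ratio) - mean(all_pairs$beta),
               tolerance = 1e-12)
  ident <- all_pairs; ident$diff <- 0
  ba3 <- bland_altman(ident)
  expect_equal(ba3$mean_diff, 0)
  expect_equal(ba3$lower, 0); expect_equal(ba3$upper, 0)
})

test_that("binomial sequencing noise makes mid-methylation pairs noisier", {
  co <- cohort_fixture()
  pairs <- join_shared(co$annot, co$betas, co$meth)
  clean <- pairs[pairs$mismatch_category == "clean", ]
  expect_gt(sd(clean$diff[clean$meth_tier == "mid"]),
            sd(clean$diff[clean$meth_tier != "mid"]))
})

test_that("lower measurement noise gives higher r and tighter bins", {
  set.seed(88)
  t <- runif(300)
  mk <- function(sd) data.frame(probe_id = paste0("p", 1:300),
                                sample_id = "S01", beta = pmin(1, pmax(0, t + rnorm(300, 0, sd))),
                                seq_ratio = t, stringsAsFactors = FALSE)
  lo <- summarize_concordance(mk(0.02)); hi <- summarize_concordance(mk(0.2))
  expect_gt(lo$pearson_r, hi$pearson_r)
  expect_gt(lo$pct_within_10, hi$pct_within_10)
})

test_that("inter-individual deltas follow the definition and nest", {
  pairs <- data.frame(probe_id = "p1", sample_id = c("S01", "S02"),
                      beta = c(0.2, 0.6), seq_ratio = c(0.3, 0.5),
                      stringsAsFactors = FALSE)
  dc <- delta_concordance(pairs)
  expect_equal(dc$n_observations, 1L)
  expect_equal(dc$pct_within_20, 100)   # |(-0.4) - (-0.2)| = 0.2, inclusive
  expect_equal(dc$pct_within_10, 0)

  shifted <- data.frame(probe_id = "p1", sample_id = c("S01", "S02"),
                        beta = c(0.2, 0.6), seq_ratio = c(0.3, 0.7),
                        stringsAsFactors = FALSE)
  expect_equal(delta_concordance(shifted)$pct_within_5, 100)

  set.seed(99)
  rnd <- data.frame(probe_id = rep(paste0("p", 1:40), each = 4),
                    sample_id = rep(paste0("S", 1:4), 40),
                    beta = runif(160), seq_ratio = runif(160),
                    stringsAsFactors = FALSE)
  dc2 <- delta_concordance(rnd)
  expect_lte(dc2$pct_within_5, dc2$pct_within_10)
  expect_lte(dc2$pct_within_10, dc2$pct_within_20)
})

test_that("detection correlations handle degenerate inputs", {
  co <- cohort_fixture()
  betas <- co$betas
  # constant detection p: undefined
  betas$detection_p[] <- 0.01
  d <- detection_alignment_correlation(co$annot, betas)
  expect_true(all(is.na(d$rho_bitscore)))
  # perfectly anti-ranked detection p vs bitscore on ten distinct probes
  annot10 <- toy_annot()[rep(1, 10), ]
  annot10$probe_id <- paste0("cg", 1:10)
  annot10$bitscore <- 71:80
  annot10$evalue <- 2^-(71:80)
  betas2 <- structure(list(
    beta = matrix(runif(10), 10, 1, dimnames = list(annot10$probe_id, "S01")),
    detection_p = matrix((10:1) / 20, 10, 1,
                         dimnames = list(annot10$probe_id, "S01"))),
    class = "beta_matrix")
  d2 <- detection_alignment_correlation(annot10, betas2)
  expect_equal(d2$rho_bitscore, -1, tolerance = 1e-9)
  expect_equal(d2$rho_evalue, 1, tolerance = 1e-9)
})
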