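# Agreement between array beta values and bisulfite-sequencing methylation
# ratios at shared CpGs: error bins, Pearson correlation per stratum,
# Bland-Altman differences, inter-individual deltas, and the detection-p /
# alignment-quality rank correlations.

#' Pair array probes with sequencing calls at shared CpGs
#'
#' A probe pairs with a methylation call when the call coordinate equals the
#' probe's projected CpG C on the + strand, or the G right after it (calls
#' made on the reverse strand fold onto the C). One row per (probe, sample)
#' with a non-missing beta. If several probes project to the same CpG they
#' all pair, and a message reports the multiplicity.
#'
#' @param annot `cm_annotation` data frame (probes with an intact projected
#'   CpG participate).
#' @param betas a `beta_matrix` (or bare matrix, probes x samples).
#' @param meth named list of methylation-call data frames (one per sample,
#'   names matching the beta columns), already coverage-filtered.
#' @return Data frame of paired observations with stratification keys:
#'   `beta`, `seq_ratio`, `coverage`, `mean_meth`, `diff`
#'   (= seq_ratio - beta), `bitscore_bin` (<70 / 70-80 / >80), `unique`,
#'   `mismatch_category`, `probe_type`, `meth_tier` (low < 0.3,
#'   mid in [0.3, 0.7], high > 0.7).
#' @export
join_shared <- function(annot, betas, meth) {
  if (is.matrix(betas)) betas <- list(beta = betas, detection_p = NULL)
  beta <- betas$beta
  if (is.null(names(meth)) || !all(names(meth) %in% colnames(beta)))
    stop("meth must be a named list keyed by sample id present in the beta matrix")
  cand <- annot[annot$n_hits > 0 & annot$cpg_present & !is.na(annot$cpg_coord), ,
                drop = FALSE]
  dup_coords <- duplicated(paste(cand$cpg_contig, cand$cpg_coord))
  if (any(dup_coords))
    message(sum(dup_coords), " probe(s) share a projected CpG with another probe")
  rows <- list()
  for (s in names(meth)) {
    calls <- meth[[s]]
    key_c <- paste(calls$chrom, calls$pos - 1L)        # call on the C
    key_g <- paste(calls$chrom, calls$pos - 2L)        # call on the G folds back
    probe_key <- paste(cand$cpg_contig, cand$cpg_coord)
    idx <- match(probe_key, key_c)
    from_g <- is.na(idx)
    idx[from_g] <- match(probe_key[from_g], key_g)
    have <- !is.na(idx) & cand$probe_id %in% rownames(beta)
    if (!any(have)) next
    b <- beta[cand$probe_id[have], s]
    ok <- !is.na(b)
    sub <- cand[have, , drop = FALSE][ok, , drop = FALSE]
    calls_sub <- calls[idx[have][ok], , drop = FALSE]
    if (nrow(sub) == 0) next
    rows[[s]] <- data.frame(
      probe_id = sub$probe_id, sample_id = s,
      beta = b[ok], seq_ratio = calls_sub$ratio,
      coverage = calls_sub$total_count,
      bitscore = sub$bitscore, unique = sub$unique,
      mismatch_category = sub$mismatch_category,
      probe_type = sub$probe_type,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(probe_id = character(), sample_id = character(),
                      beta = numeric(), seq_ratio = numeric(),
                      coverage = integer(), bitscore = numeric(),
                      unique = logical(), mismatch_category = character(),
                      probe_type = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  out$mean_meth <- (out$beta + out$seq_ratio) / 2
  out$diff <- out$seq_ratio - out$beta
  out$bitscore_bin <- cut(out$bitscore, breaks = c(-Inf, 70, 80, Inf),
                          labels = c("<70", "70-80", ">80"), right = TRUE)
  out$bitscore_bin <- as.character(out$bitscore_bin)
  out$meth_tier <- ifelse(out$mean_meth < 0.3, "low",
                          ifelse(out$mean_meth > 0.7, "high", "mid"))
  rownames(out) <- NULL
  out
}

concordance_metrics <- function(beta, seq_ratio) {
  n <- length(beta)
  r <- if (n >= 2 && sd(beta) > 0 && sd(seq_ratio) > 0)
    stats::cor(beta, seq_ratio) else NA_real_
  d <- abs(seq_ratio - beta)
  c(n_pairs = n, pearson_r = r,
    pct_within_20 = 100 * mean(d <= 0.20),
    pct_within_10 = 100 * mean(d <= 0.10),
    pct_within_5 = 100 * mean(d <= 0.05))
}

#' Summarize array/sequencing concordance per stratum
#'
#' Per stratum: Pearson r between beta and sequencing ratio, and the percent
#' of pairs whose absolute methylation difference is within 0.20 / 0.10 /
#' 0.05 (inclusive thresholds on the 0-1 scale). With
#' `method = "per_sample"` (default) metrics are computed per sample and
#' averaged unweighted; `method = "pooled"` pools all pairs. Strata with
#' fewer than two pairs, or zero variance, report `NA` correlation.
#'
#' @param pairs data frame from [join_shared()].
#' @param strata character vector of stratification columns (subset of
#'   `bitscore_bin`, `unique`, `mismatch_category`, `probe_type`,
#'   `meth_tier`); empty for a single overall stratum.
#' @param method "per_sample" or "pooled".
#' @return Data frame: stratum key columns, `n_pairs`, `pearson_r`,
#'   `pct_within_20`, `pct_within_10`, `pct_within_5`.
#' @export
summarize_concordance <- function(pairs, strata = character(),
                                  method = c("per_sample", "pooled")) {
  method <- match.arg(method)
  key <- if (length(strata) == 0) rep("all", nrow(pairs))
         else do.call(paste, c(pairs[strata], sep = "|"))
  groups <- split(seq_len(nrow(pairs)), key)
  res <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    sub <- pairs[idx, , drop = FALSE]
    if (method == "pooled") {
      m <- concordance_metrics(sub$beta, sub$seq_ratio)
      m["n_pairs"] <- nrow(sub)
    } else {
      per <- lapply(split(sub, sub$sample_id),
                    function(ss) concordance_metrics(ss$beta, ss$seq_ratio))
      mm <- do.call(rbind, per)
      m <- c(n_pairs = nrow(sub),
             pearson_r = mean(mm[, "pearson_r"], na.rm = TRUE),
             pct_within_20 = mean(mm[, "pct_within_20"]),
             pct_within_10 = mean(mm[, "pct_within_10"]),
             pct_within_5 = mean(mm[, "pct_within_5"]))
      if (is.nan(m[["pearson_r"]])) m[["pearson_r"]] <- NA_real_
    }
    metrics <- as.data.frame(as.list(m))
    if (length(strata) == 0) return(metrics)
    keyvals <- pairs[idx[1], strata, drop = FALSE]
    rownames(keyvals) <- NULL
    cbind(keyvals, metrics)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bland-Altman table of paired methylation measurements
#'
#' Emits one (mean, difference) point per pair, with the difference defined
#' as sequencing ratio minus array beta, plus the overall mean difference
#' and 1.96-sd limits of agreement.
#'
#' @param pairs data frame from [join_shared()].
#' @return List with `table` (probe_id, sample_id, mean_meth, diff),
#'   `mean_diff`, `lower`, `upper`.
#' @export
bland_altman <- function(pairs) {
  tab <- pairs[, c("probe_id", "sample_id", "mean_meth", "diff")]
  md <- mean(tab$diff)
  s <- if (nrow(tab) >= 2) sd(tab$diff) else 0
  list(table = tab, mean_diff = md,
       lower = md - 1.96 * s, upper = md + 1.96 * s)
}

#' Concordance of inter-individual methylation differences
#'
#' For every probe shared by at least two samples and every unordered sample
#' pair, compares the between-individual difference measured on the array
#' (beta_i - beta_j) with the one measured by sequencing (ratio_i -
#' ratio_j), and reports the percent of observations whose absolute
#' discrepancy is within 0.20 / 0.10 / 0.05 (inclusive).
#'
#' @param pairs data frame from [join_shared()].
#' @return List with `n_observations`, `pct_within_20`, `pct_within_10`,
#'   `pct_within_5`.
#' @export
delta_concordance <- function(pairs) {
  disc <- numeric(0)
  for (sub in split(pairs, pairs$probe_id)) {
    if (nrow(sub) < 2) next
    cmb <- utils::combn(nrow(sub), 2)
    d_array <- sub$beta[cmb[1, ]] - sub$beta[cmb[2, ]]
    d_seq <- sub$seq_ratio[cmb[1, ]] - sub$seq_ratio[cmb[2, ]]
    disc <- c(disc, abs(d_array - d_seq))
  }
  list(n_observations = length(disc),
       pct_within_20 = 100 * mean(disc <= 0.20),
       pct_within_10 = 100 * mean(disc <= 0.10),
       pct_within_5 = 100 * mean(disc <= 0.05))
}

#' Rank correlation of detection p-values with alignment quality
#'
#' Per sample, Spearman rho (average ranks on ties) between the per-probe
#' detection p-value and each of the best hit's e-value, percent identity
#' and bitscore, over mapped probes. Optionally excludes probes with a
#' mismatch adjacent to the CpG before correlating (the second-pass
#' analysis). Zero-variance inputs report `NA`.
#'
#' @param annot `cm_annotation` data frame.
#' @param betas a `beta_matrix` carrying `detection_p`.
#' @param exclude_near_cpg drop probes with category `near_cpg` first.
#' @return Data frame: sample_id, n_probes, rho_evalue,
#'   rho_percent_identity, rho_bitscore.
#' @export
detection_alignment_correlation <- function(annot, betas,
                                            exclude_near_cpg = FALSE) {
  if (is.null(betas$detection_p))
    stop("beta matrix carries no detection p-values")
  dp <- betas$detection_p
  sub <- annot[annot$n_hits > 0, , drop = FALSE]
  if (exclude_near_cpg)
    sub <- sub[sub$mismatch_category != "near_cpg", , drop = FALSE]
  sub <- sub[sub$probe_id %in% rownames(dp), , drop = FALSE]
  rho <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok], method = "spearman")
  }
  res <- lapply(colnames(dp), function(s) {
    p <- dp[sub$probe_id, s]
    data.frame(sample_id = s, n_probes = sum(!is.na(p)),
               rho_evalue = rho(p, sub$evalue),
               rho_percent_identity = rho(p, sub$percent_identity),
               rho_bitscore = rho(p, sub$bitscore),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
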