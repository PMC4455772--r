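# Synthetic inputs with planted ground truth: genome, probe manifest, gene
# annotation, ortholog map, beta matrix with detection p-values, and
# per-CpG bisulfite count tables. Every probe belongs to a divergence class
# whose expected behaviour in the pipeline is known exactly.

with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Divergence class proportions for the probe generator
#'
#' Classes: `clean` (probe equals its genomic target), `mm_far` (1-4
#' substitutions, all more than 1 bp from the CpG), `mm_near` (a
#' substitution on a CpG flank, plus 2-3 far substitutions), `mm_cpg`
#' (mismatch in the CG dinucleotide itself), `cpg_lost` (target CG mutated
#' away), `duplicated` (target planted twice), `absent` (no target in the
#' genome).
#'
#' @param clean,mm_far,mm_near,mm_cpg,cpg_lost,duplicated,absent class
#'   proportions, summing to 1.
#' @param seed RNG seed used by [plant_probes()].
#' @return An object of class `divergence_spec`.
#' @export
divergence_spec <- function(clean = 0.4, mm_far = 0.2, mm_near = 0.1,
                            mm_cpg = 0.1, cpg_lost = 0.05, duplicated = 0.1,
                            absent = 0.05, seed = 1L) {
  p <- c(clean = clean, mm_far = mm_far, mm_near = mm_near, mm_cpg = mm_cpg,
         cpg_lost = cpg_lost, duplicated = duplicated, absent = absent)
  if (abs(sum(p) - 1) > 1e-8) stop("class proportions must sum to 1")
  structure(list(proportions = p, seed = as.integer(seed)),
            class = "divergence_spec")
}

largest_remainder <- function(props, n) {
  base <- floor(props * n)
  rem <- props * n - base
  left <- n - sum(base)
  if (left > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a random genome
#'
#' I.i.d. bases at the requested GC content, deterministic under the seed.
#'
#' @param seed RNG seed.
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in `[0, 1]`.
#' @param contig_name name of the single contig.
#' @return A [genome_seq()] object.
#' @export
generate_genome <- function(seed, length, gc = 0.41, contig_name = "syn1") {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    genome_seq(setNames(paste(bases, collapse = ""), contig_name))
  })
}

# longest mismatch-free run left in a 50-mer carrying mismatches at `pos`
longest_clean_run <- function(pos, probe_len = 50L) {
  b <- c(-1L, sort(unique(pos)), probe_len)
  max(diff(b)) - 1L
}

#' Plant probes of known divergence classes into a genome
#'
#' Carves non-overlapping windows out of the (first) contig, forces a CG
#' dinucleotide at the position the probe chemistry expects (type I: the C
#' under the probe 3' terminus; type II: immediately 3' of the 50-mer),
#' takes the probe as the exact window sequence, then mutates the genome
#' copy according to the probe's divergence class. Probe types alternate
#' I/II and design strands alternate +/- deterministically. Substitution
#' positions are re-drawn until the probe keeps a mismatch-free stretch of
#' at least 12 bp, so every planted target stays seedable by design.
#'
#' `mm_cpg` on type I probes mutates the probe base over the CpG C (the
#' genomic CpG stays intact and assayable: an at-CpG mismatch); on type II
#' probes, whose 50-mer does not cover the CG, it mutates one base of the
#' genomic CG (the CpG is absent from the target).
#'
#' Gene annotation is attached to roughly 77% of probes, with agreement
#' classes (exact 45%, ortholog 25%, partial 15%, none 15%) realised through
#' the emitted gene intervals and ortholog map.
#'
#' @param genome a [genome_seq()]; mutated copy is returned.
#' @param n_probes number of probes.
#' @param spec a [divergence_spec()] (carries the seed).
#' @return List: `genome` (mutated), `manifest`, `truth` (one row per probe:
#'   class, planted coordinates, expected CpG conservation, divergence
#'   count, duplicate locus, gene class), `genes` (BED data frame),
#'   `orthologs` (named character vector).
#' @export
plant_probes <- function(genome, n_probes, spec = divergence_spec()) {
  contig <- names(genome$contigs)[1]
  chars <- strsplit(genome$contigs[[contig]], "")[[1]]
  len <- length(chars)
  W <- 80L; margin <- 10L
  counts <- largest_remainder(spec$proportions, n_probes)
  names(counts) <- names(spec$proportions)
  n_dup <- counts[["duplicated"]]
  n_slots <- length(seq(1L, len - W + 1L, by = W))
  if (n_slots < n_probes + n_dup)
    stop("insufficient genome space: need ", n_probes + n_dup,
         " slots of ", W, " bp, have ", n_slots)
  acgt <- c("A", "C", "G", "T")
  mutate_at <- function(g0) {   # 0-based position
    cur <- chars[g0 + 1L]
    chars[g0 + 1L] <<- sample(setdiff(acgt, cur), 1L)
  }

  with_seed(spec$seed, {
    classes <- sample(rep(names(counts), counts))
    slot_ids <- sample(n_slots, n_probes + n_dup)
    probe_slots <- slot_ids[seq_len(n_probes)]
    dup_slots <- slot_ids[n_probes + seq_len(n_dup)]
    dup_i <- 0L

    man <- vector("list", n_probes)
    truth <- vector("list", n_probes)
    gene_rows <- list()
    orthologs <- character(0)

    for (i in seq_len(n_probes)) {
      cls <- classes[i]
      type <- if (i %% 2L == 1L) "I" else "II"
      strand <- if (((i - 1L) %/% 2L) %% 2L == 0L) "+" else "-"
      p <- (probe_slots[i] - 1L) * W + margin      # 0-based window start
      probe_id <- sprintf("cg%05d", i)

      # probe offset j <-> 0-based genome position
      gpos <- function(j) if (strand == "+") p + j else p + 49L - j

      if (cls != "absent") {
        # plant the CG the chemistry expects
        if (strand == "+") {
          cpg0 <- if (type == "I") p + 49L else p + 50L
        } else {
          cpg0 <- if (type == "I") p - 1L else p - 2L
        }
        chars[cpg0 + 1L] <- "C"; chars[cpg0 + 2L] <- "G"
        window <- paste(chars[(p + 1L):(p + 50L)], collapse = "")
        probe_seq <- if (strand == "+") window else revcomp(window)
      } else {
        cpg0 <- NA_integer_
        probe_seq <- paste(sample(acgt, 50L, replace = TRUE), collapse = "")
        if (type == "I") substr(probe_seq, 50L, 50L) <- "C"
      }

      far_range <- if (type == "I") 0:47 else 0:48
      near_j <- if (type == "I") 48L else 49L
      n_mut <- 0L
      mut_j <- integer(0)

      if (cls == "mm_far") {
        k <- sample(1:4, 1L)
        repeat {
          mut_j <- sample(far_range, k)
          if (longest_clean_run(mut_j) >= 12L) break
        }
        for (j in mut_j) mutate_at(gpos(j))
        n_mut <- k
      } else if (cls == "mm_near") {
        k <- sample(2:3, 1L)
        repeat {
          mut_j <- c(near_j, sample(setdiff(far_range, near_j), k))
          if (longest_clean_run(mut_j) >= 12L) break
        }
        for (j in mut_j) mutate_at(gpos(j))
        n_mut <- k + 1L
      } else if (cls == "mm_cpg") {
        if (type == "I") {
          substr(probe_seq, 50L, 50L) <- sample(setdiff(acgt, "C"), 1L)
          mut_j <- 49L
        } else {
          mutate_at(cpg0 + 1L)        # the G of the CG
        }
        n_mut <- 1L
      } else if (cls == "cpg_lost") {
        chars[cpg0 + 1L] <- sample(setdiff(acgt, "C"), 1L)
        chars[cpg0 + 2L] <- sample(setdiff(acgt, "G"), 1L)
        n_mut <- 2L
      }

      dup_cpg0 <- NA_integer_; dup_start0 <- NA_integer_
      if (cls == "duplicated") {
        dup_i <- dup_i + 1L
        q <- (dup_slots[dup_i] - 1L) * W + margin
        ext <- if (strand == "+") {
          if (type == "I") c(0L, 51L) else c(0L, 52L)
        } else {
          if (type == "I") c(-1L, 50L) else c(-2L, 50L)
        }
        src <- (p + ext[1] + 1L):(p + ext[2])
        chars[(q + ext[1] + 1L):(q + ext[2])] <- chars[src]
        dup_start0 <- q
        dup_cpg0 <- cpg0 - p + q
      }

      # gene annotation
      gene_class <- "unannotated"; human_gene <- ""; target_gene <- NA_character_
      if (runif(1) < 0.77) {
        gene_class <- sample(c("exact", "ortholog", "partial", "none"), 1L,
                             prob = c(0.45, 0.25, 0.15, 0.15))
        human_gene <- sprintf("GEN%04dA", i)
        target_gene <- switch(gene_class,
          exact = human_gene,
          ortholog = sprintf("ORTH%04d", i),
          partial = paste0("LOC-", human_gene),
          none = sprintf("ZZX%04d", i))
        if (gene_class == "ortholog")
          orthologs[human_gene] <- target_gene
        if (cls != "absent") {
          gene_rows[[length(gene_rows) + 1L]] <-
            data.frame(chrom = contig, start = p - 8L, end = p + 58L,
                       name = target_gene, stringsAsFactors = FALSE)
          if (cls == "duplicated")
            gene_rows[[length(gene_rows) + 1L]] <-
              data.frame(chrom = contig, start = dup_start0 - 8L,
                         end = dup_start0 + 58L, name = target_gene,
                         stringsAsFactors = FALSE)
        }
      }

      man[[i]] <- data.frame(
        probe_id = probe_id, probe_seq = probe_seq, chrom = contig,
        cpg_pos = if (is.na(cpg0)) p + 50L else cpg0 + 1L,
        strand = strand, probe_type = type, gene_names = human_gene,
        polymorphic_flag = FALSE, stringsAsFactors = FALSE)

      conserved <- cls %in% c("clean", "mm_far", "mm_near", "duplicated") ||
        (cls == "mm_cpg" && type == "I")
      truth[[i]] <- data.frame(
        probe_id = probe_id, class = cls, probe_type = type, strand = strand,
        contig = contig, start0 = if (cls == "absent") NA_integer_ else p,
        cpg_coord0 = if (conserved) cpg0 else NA_integer_,
        cpg_conserved = conserved,
        corrupted = cls %in% c("mm_cpg", "cpg_lost", "mm_near", "absent"),
        n_mut = n_mut,
        dup_start0 = dup_start0, dup_cpg_coord0 = dup_cpg0,
        gene_class = gene_class, stringsAsFactors = FALSE)
    }

    # decoy ortholog entries that match nothing
    orthologs[sprintf("DEC%02dH", 1:5)] <- sprintf("DEC%02dM", 1:5)

    genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), stringsAsFactors = FALSE)
    out_genome <- genome
    out_genome$contigs[[contig]] <- paste(chars, collapse = "")
    list(genome = out_genome,
         manifest = do.call(rbind, man),
         truth = do.call(rbind, truth),
         genes = genes,
         orthologs = orthologs)
  })
}

#' Simulate array and sequencing methylomes over planted probes
#'
#' The true methylation level of every CpG is drawn from the bimodal mixture
#' `0.4 Beta(0.5, 8) + 0.4 Beta(8, 0.5) + 0.2 Uniform(0, 1)`. Per sample,
#' sequencing counts are `meth ~ Binomial(depth, level)` with
#' `depth ~ Poisson(depth_mean)`, emitted alternately on the C or the G of
#' the CpG; the array reads `clip(level + Normal(0, sd))` with
#' `sd = array_noise_sd * (1 + noise_per_mismatch * n_mut)` for uncorrupted
#' probes (divergence degrades hybridization), the average of its two loci
#' for duplicated probes (cross-hybridization), and `Uniform(0, 1)` for
#' corrupted probes (near-CpG and CpG mismatches decouple the signal).
#' Detection p-values rise noisily with probe divergence; probes with no
#' genomic target draw them uniformly.
#'
#' @param truth truth table from [plant_probes()].
#' @param n_samples number of individuals (the study design assayed 11
#'   muscle biopsies).
#' @param depth_mean mean sequencing depth per CpG.
#' @param array_noise_sd baseline array noise sd on the beta scale.
#' @param noise_per_mismatch per-substitution multiplier on the array noise.
#' @param missing_rate fraction of betas set missing at random.
#' @param seed RNG seed.
#' @return List: `betas` (a `beta_matrix` with detection p-values), `meth`
#'   (named list of unfiltered call data frames, one per sample),
#'   `truth_meth` (per-probe true levels).
#' @export
simulate_methylomes <- function(truth, n_samples = 11L, depth_mean = 30,
                                array_noise_sd = 0.03,
                                noise_per_mismatch = 0.8,
                                missing_rate = 0, seed = 1L) {
  n <- nrow(truth)
  samples <- sprintf("S%02d", seq_len(n_samples))
  clip01 <- function(x) pmin(1, pmax(0, x))
  with_seed(seed, {
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    t1 <- ifelse(comp == 1, stats::rbeta(n, 0.5, 8),
                 ifelse(comp == 2, stats::rbeta(n, 8, 0.5), runif(n)))
    comp2 <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    t2 <- ifelse(comp2 == 1, stats::rbeta(n, 0.5, 8),
                 ifelse(comp2 == 2, stats::rbeta(n, 8, 0.5), runif(n)))

    beta <- matrix(NA_real_, n, n_samples,
                   dimnames = list(truth$probe_id, samples))
    detp <- matrix(NA_real_, n, n_samples,
                   dimnames = list(truth$probe_id, samples))
    sd_i <- array_noise_sd * (1 + noise_per_mismatch * truth$n_mut)
    for (s in seq_len(n_samples)) {
      b <- clip01(t1 + rnorm(n, 0, sd_i))
      dup <- truth$class == "duplicated"
      b[dup] <- clip01((t1[dup] + t2[dup]) / 2 + rnorm(sum(dup), 0, array_noise_sd))
      b[truth$corrupted] <- runif(sum(truth$corrupted))
      if (missing_rate > 0) b[runif(n) < missing_rate] <- NA_real_
      beta[, s] <- b
      d <- plogis(rnorm(n, mean = -4 + 0.9 * truth$n_mut, sd = 0.8))
      d[truth$class == "absent"] <- runif(sum(truth$class == "absent"))
      detp[, s] <- d
    }

    loci <- rbind(
      data.frame(contig = truth$contig, coord0 = truth$cpg_coord0,
                 level = t1, stringsAsFactors = FALSE),
      data.frame(contig = truth$contig, coord0 = truth$dup_cpg_coord0,
                 level = t2, stringsAsFactors = FALSE))
    loci <- loci[!is.na(loci$coord0), , drop = FALSE]
    loci <- loci[order(loci$contig, loci$coord0), , drop = FALSE]
    on_g <- seq_len(nrow(loci)) %% 2L == 0L   # alternate C / G emission

    meth <- setNames(vector("list", n_samples), samples)
    for (s in seq_len(n_samples)) {
      depth <- rpois(nrow(loci), depth_mean)
      mc <- rbinom(nrow(loci), depth, loci$level)
      keep <- depth > 0
      meth[[s]] <- data.frame(
        chrom = loci$contig[keep],
        pos = loci$coord0[keep] + 1L + ifelse(on_g[keep], 1L, 0L),
        meth_count = mc[keep], total_count = depth[keep],
        ratio = mc[keep] / depth[keep], stringsAsFactors = FALSE)
    }
    list(betas = structure(list(beta = beta, detection_p = detp),
                           class = "beta_matrix"),
         meth = meth,
         truth_meth = data.frame(probe_id = truth$probe_id, true_meth = t1,
                                 dup_meth = t2, stringsAsFactors = FALSE))
  })
}

#' Apply the read-coverage filter to methylation calls
#'
#' @param calls call data frame (or named list of them).
#' @param min_coverage minimum depth retained (inclusive).
#' @return Filtered calls in the same shape.
#' @export
filter_coverage <- function(calls, min_coverage = 10L) {
  f <- function(df) {
    out <- df[df$total_count >= min_coverage, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  if (is.data.frame(calls)) f(calls) else lapply(calls, f)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: genome, planted probes, and simulated methylomes
#' under one master seed. The defaults are the reference study conditions
#' used throughout the package's validation: 400 probes over a 120 kb
#' genome, default class proportions, 11 individuals, mean depth 30,
#' coverage filter at 10x.
#'
#' @param seed master seed (sub-seeds are derived from it).
#' @param n_probes,genome_length,gc,n_samples,depth_mean,array_noise_sd,noise_per_mismatch,missing_rate,min_coverage
#'   forwarded to the generators.
#' @param proportions optional named vector overriding the class
#'   proportions of [divergence_spec()].
#' @return List with `genome`, `manifest`, `truth`, `genes`, `orthologs`,
#'   `betas`, `meth` (coverage-filtered), `meth_raw`, `truth_meth`.
#' @export
synthetic_cohort <- function(seed = 1L, n_probes = 400L,
                             genome_length = 120000L, gc = 0.41,
                             n_samples = 11L, depth_mean = 30,
                             array_noise_sd = 0.03, noise_per_mismatch = 0.8,
                             missing_rate = 0, min_coverage = 10L,
                             proportions = NULL) {
  spec <- if (is.null(proportions)) divergence_spec(seed = seed + 1L)
          else do.call(divergence_spec, c(as.list(proportions),
                                          list(seed = seed + 1L)))
  genome <- generate_genome(seed, genome_length, gc)
  planted <- plant_probes(genome, n_probes, spec)
  sim <- simulate_methylomes(planted$truth, n_samples = n_samples,
                             depth_mean = depth_mean,
                             array_noise_sd = array_noise_sd,
                             noise_per_mismatch = noise_per_mismatch,
                             missing_rate = missing_rate, seed = seed + 2L)
  c(planted, list(betas = sim$betas,
                  meth = filter_coverage(sim$meth, min_coverage),
                  meth_raw = sim$meth,
                  truth_meth = sim$truth_meth))
}
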