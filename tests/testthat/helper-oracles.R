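# Independent oracles, kept free of any package internals they check.

# Brute-force rank-sum p: enumerate every assignment of m of the N
# combined ranks to x (midranks from the pooled data), and count
# assignments at least as extreme as the observed rank sum.
oracle_ranksum_p <- function(x, y, alternative) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(N, m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  if (alternative == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}

# Exhaustive hypergeometric one-sided p for the 2x2 expansion table:
# enumerate all possible post counts at fixed margins via choose().
oracle_fisher_p <- function(count_pre, total_pre, count_post, total_post) {
  k <- count_pre + count_post          # successes overall
  n1 <- total_post; n2 <- total_pre    # draws in each arm
  xs <- max(0, k - n2):min(k, n1)      # feasible post counts
  probs <- choose(n1, xs) * choose(n2, k - xs) / choose(n1 + n2, k)
  sum(probs[xs >= count_post])
}

# Step-up BH from its definition: q_(i) = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(n), function(i) {
    min(ps[i:n] * n / (i:n), 1)
  }, numeric(1))
  q[order(o)]
}

# Straight-line evaluation of the five scoring equations, sharing no code
# with the package (used for the scoring-equation oracle criterion).
oracle_peptide_score <- function(affinity, cleavage, tap, tpm, lower_q,
                                 upper_q, vaf, neoorf, anchor,
                                 both_identified, dl_rank) {
  mhc <- tanh((500 - affinity) / 200)
  cle <- tanh(cleavage * 3)
  tp <- tanh(tap * 2.5) / 2 + 0.5
  comb <- 0.8 * mhc + 0.15 * cle + 0.05 * tp
  expr <- if (tpm == 0) 0 else if (tpm > upper_q) 1 else
    if (tpm < lower_q) 0.33 else 0.66
  cls <- if (neoorf) {
    if (affinity < 150) 1 else 4
  } else if (anchor) {
    if (affinity < 150) 2 else 5
  } else {
    if (affinity < 150) 3 else 6
  }
  tw <- c(1, 0.6, 0.5, 0.25, 0.15, 0.125)[cls]
  dw <- if (both_identified && tpm > 15 && affinity < 100) 1 else
    if (both_identified && (tpm > 15 || affinity < 100)) 0.5 else
    if (both_identified && tpm < 15 && affinity > 100 &&
          !is.na(dl_rank) && dl_rank < 30) 0.25 else 0.125
  comb * expr * vaf * tw * dw
}

# Closed-form count of k-mers of a length-L context covering 0-based
# mutant index m.
window_count_formula <- function(L, k, m) {
  max(0, min(m, L - k) - max(0, m - k + 1) + 1)
}

# Small deterministic variant factory for filter tests; all read-level
# metrics passing unless overridden.
make_snv <- function(id = "v1", chrom = "chr1", pos = 1000,
                     depth_tumor = 100, vaf_tumor = 0.3, vaf_normal = 0,
                     mq_mut = rep(60, 12), mq_ref = rep(55, 12),
                     bq_mut = rep(35, 12), bq_ref = rep(32, 12),
                     dend_mut = seq(30, 52, 2), dend_ref = seq(20, 42, 2),
                     ...) {
  variant_record(chrom, pos, "A", "T", vtype = "SNV",
                 depth_tumor = depth_tumor, depth_normal = 80,
                 vaf_tumor = vaf_tumor, vaf_normal = vaf_normal,
                 gene = "G1", consequence = "missense",
                 protein_change = "p.A50V", variant_id = id,
                 mq_mut = mq_mut, mq_ref = mq_ref, bq_mut = bq_mut,
                 bq_ref = bq_ref, dend_mut = dend_mut, dend_ref = dend_ref,
                 ...)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "truneo", mustWork = TRUE)
}
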