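# Benchmarking metrics: recall@k over a ranked cohort, the random
# baseline, the Elispot true-positive rate, and the TPM-threshold
# sensitivity sweep.

#' Recall at k over a ranked cohort
#'
#' Counts labeled-immunogenic candidates ranked in the top k within each
#' patient, sums over patients, and divides by the cohort denominator
#' (the total number of confirmed immunogenic epitopes). Unlabeled
#' candidates occupy ranked slots but never count as hits.
#'
#' @param cohort data.frame with `patient_id`, `rank`, `immunogenic`
#'   (1/0/NA); one prediction method at a time.
#' @param k top-k cutoff (>= 1).
#' @param total_immunogenic cohort denominator (e.g. 19).
#' @param per_patient_mean if `TRUE`, return instead the mean over
#'   patients of the per-patient recall (not the headline metric).
#' @return percentage (full precision; round with [round_half_up()]).
#' @export
recall_at_k <- function(cohort, k, total_immunogenic,
                        per_patient_mean = FALSE) {
  assert_that(k >= 1, "k must be >= 1")
  assert_that(total_immunogenic > 0, "total_immunogenic must be positive")
  hit <- !is.na(cohort$immunogenic) & cohort$immunogenic == 1 &
    cohort$rank <= k
  if (per_patient_mean) {
    pp <- tapply(hit, cohort$patient_id, sum)
    np <- tapply(!is.na(cohort$immunogenic) & cohort$immunogenic == 1,
                 cohort$patient_id, sum)
    return(mean(ifelse(np > 0, pp / np, NA), na.rm = TRUE) * 100)
  }
  sum(hit) / total_immunogenic * 100
}

#' Expected recall of a random pick
#' @param total_immunogenic,total_assayed cohort totals (e.g. 19 / 1599).
#' @return percentage.
#' @export
random_baseline <- function(total_immunogenic, total_assayed) {
  assert_that(total_assayed > 0, "total_assayed must be positive")
  total_immunogenic / total_assayed * 100
}

#' True-positive rate of validated top-k peptides
#' @param outcomes logical vector of per-peptide validation outcomes.
#' @return percentage of `TRUE`.
#' @export
positive_rate <- function(outcomes) {
  assert_that(length(outcomes) > 0, "outcomes must be non-empty")
  sum(outcomes) / length(outcomes) * 100
}

#' Recall@10 as a function of a minimal TPM threshold
#'
#' For each threshold, candidates with TPM below it are dropped, the
#' remaining candidates are re-ranked preserving their original order,
#' and recall@10 is recomputed.
#'
#' @param cohort rank-list data.frame with a `tpm` column.
#' @param thresholds numeric vector of minimal TPM values.
#' @param total_immunogenic cohort denominator.
#' @param k top-k cutoff (default 10).
#' @return data.frame (threshold, recall).
#' @export
tpm_threshold_sweep <- function(cohort, thresholds, total_immunogenic,
                                k = 10) {
  assert_that("tpm" %in% names(cohort), "cohort needs a tpm column")
  rows <- lapply(thresholds, function(t) {
    drop <- !is.na(cohort$tpm) & cohort$tpm < t
    kept <- cohort[!drop, , drop = FALSE]
    # each kept candidate moves up by the number of dropped candidates
    # ranked above it in the same patient, preserving the original order
    kept$rank <- vapply(seq_len(nrow(kept)), function(i) {
      kept$rank[i] - sum(drop & cohort$patient_id == kept$patient_id[i] &
                           cohort$rank < kept$rank[i])
    }, numeric(1))
    data.frame(threshold = t,
               recall = recall_at_k(kept, k, total_immunogenic))
  })
  do.call(rbind, rows)
}

#' One-sided Fisher's exact test for clonotype expansion
#'
#' Tests enrichment of a clone after stimulation on the 2x2 table
#' `[[count_post, total_post - count_post], [count_pre, total_pre -
#' count_pre]]` via the hypergeometric tail. The odds ratio is the
#' unconditional sample OR `(count_post * (total_pre - count_pre)) /
#' (count_pre * (total_post - count_post))`; 0/0 is reported as 1 with
#' `or_defined = FALSE`, x/0 as `Inf`.
#'
#' @param count_pre,total_pre clone count / library size before
#'   stimulation.
#' @param count_post,total_post after stimulation.
#' @return list with `p`, `odds_ratio`, `or_defined`.
#' @export
fisher_exact_one_sided <- function(count_pre, total_pre, count_post,
                                   total_post) {
  assert_that(all(c(count_pre, total_pre, count_post, total_post) >= 0) &&
                count_pre <= total_pre && count_post <= total_post,
              "counts must satisfy 0 <= count <= total")
  a <- count_post; b <- total_post - count_post
  c_ <- count_pre; d <- total_pre - count_pre
  # P(X >= a), X ~ Hypergeom drawing total_post from (a + c_) successes
  p <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  num <- a * d; den <- c_ * b
  if (num == 0 && den == 0) {
    list(p = p, odds_ratio = 1, or_defined = FALSE)
  } else if (den == 0) {
    list(p = p, odds_ratio = Inf, or_defined = TRUE)
  } else {
    list(p = p, odds_ratio = num / den, or_defined = TRUE)
  }
}
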