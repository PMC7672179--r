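# Composite neoantigen scoring.
#
# PeptideScore = CombineScore * ExpressionScore * VAF * PeptideWeight,
# where CombineScore = 0.8*MHCBindingScore + 0.15*ProteasomalCleavageScore
# + 0.05*TAPTransportScore, PeptideWeight = NeoantigenTypeWeight *
# DeepLearningWeight. Binding, cleavage and TAP raw predictions are mapped
# through tanh squashes so each component lives on a comparable scale.

#' MHC binding component score
#'
#' `tanh((500 - affinity_nM) / 200)`: +1 asymptote for strong binders,
#' 0 at the 500 nM candidate cutoff, negative above it.
#'
#' @param affinity_nM predicted IC50 in nM (positive).
#' @return numeric score.
#' @export
mhc_binding_score <- function(affinity_nM) {
  assert_that(all(affinity_nM > 0), "affinity must be positive")
  tanh((500 - affinity_nM) / 200)
}

#' TAP transport component score
#' @param tap raw TAP transport prediction (typical range -3..3).
#' @return `tanh(2.5 * tap) / 2 + 0.5`, in (0, 1).
#' @export
tap_transport_score <- function(tap) {
  tanh(tap * 2.5) / 2 + 0.5
}

#' Proteasomal cleavage component score
#' @param cleavage raw C-terminal cleavage propensity (typical range 0..1).
#' @return `tanh(3 * cleavage)`.
#' @export
cleavage_score <- function(cleavage) {
  tanh(cleavage * 3)
}

#' Combined antigen-processing score
#' @param mhc_s,cleav_s,tap_s component scores.
#' @param weights length-3 weights summing to 1 (default 0.8/0.15/0.05).
#' @return weighted sum.
#' @export
combine_score <- function(mhc_s, cleav_s, tap_s,
                          weights = c(0.8, 0.15, 0.05)) {
  weights[1] * mhc_s + weights[2] * cleav_s + weights[3] * tap_s
}

#' Expression quartiles of the tumor sample
#' @param expression named TPM vector over genes.
#' @param population `"positive"` (genes with TPM > 0, default) or
#'   `"all"`.
#' @return `c(lower, upper)` quartiles.
#' @export
expression_quartiles <- function(expression,
                                 population = c("positive", "all")) {
  population <- match.arg(population)
  pop <- if (population == "positive") expression[expression > 0]
         else expression
  if (length(pop) == 0) return(c(lower = 0, upper = 0))
  q <- quantile(pop, c(0.25, 0.75), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Rank-normalised expression score
#'
#' 0 for unexpressed genes, 0.33 below the lower TPM quartile, 0.66
#' between the quartiles (boundaries inclusive), 1 above the upper
#' quartile.
#'
#' @param tpm gene TPM (non-negative).
#' @param lower_q,upper_q TPM quartiles from [expression_quartiles()].
#' @return values in `{0, 0.33, 0.66, 1}`.
#' @export
expression_score <- function(tpm, lower_q, upper_q) {
  assert_that(all(tpm >= 0), "TPM must be non-negative")
  assert_that(lower_q <= upper_q, "quartiles must be ordered")
  ifelse(tpm == 0, 0,
         ifelse(tpm > upper_q, 1,
                ifelse(tpm < lower_q, 0.33, 0.66)))
}

#' Assign the six-class epitope taxonomy
#'
#' Classes 1-3 are high-affinity (IC50 < 150 nM): neoORF, anchor-changing
#' substitution, non-anchor substitution; classes 4-6 are the same split
#' at 150-500 nM. Exactly 150 nM falls in the low-affinity classes.
#'
#' @param is_neoorf logical: neoORF-derived candidate.
#' @param anchor_changed logical: substitution at P2 or the C-terminus.
#' @param affinity_nM predicted IC50, must be <= 500 (filtered candidate).
#' @param high_affinity_nM class split (150 nM).
#' @return integer class 1-6 (vectorized).
#' @export
assign_class <- function(is_neoorf, anchor_changed, affinity_nM,
                         high_affinity_nM = 150) {
  assert_that(all(affinity_nM <= 500),
              "class taxonomy applies to filtered candidates (<= 500 nM)",
              class = "truneo_contract_error")
  high <- affinity_nM < high_affinity_nM
  base <- ifelse(is_neoorf, 1L, ifelse(anchor_changed, 2L, 3L))
  ifelse(high, base, base + 3L)
}

#' Neoantigen type weight for a class
#' @param class integer 1-6.
#' @param weights the six class weights.
#' @return numeric weight.
#' @export
type_weight <- function(class, weights = c(1, 0.6, 0.5, 0.25, 0.15, 0.125)) {
  assert_that(all(class %in% 1:6), "class must be 1..6")
  weights[class]
}

#' Deep-learning weight
#'
#' Branches on whether the peptide is identified both by the affinity
#' predictor and the learned presentation model, together with expression
#' and affinity: 1 when both identified, TPM > 15 and IC50 < 100 nM; 0.5
#' when both identified and (TPM > 15 or IC50 < 100); 0.25 when both
#' identified, TPM < 15, IC50 > 100 and the within-patient presentation
#' rank < 30; 0.125 otherwise. Equality gaps (TPM exactly 15, IC50
#' exactly 100) fall through to 0.125.
#'
#' @param both_identified logical.
#' @param tpm gene TPM.
#' @param affinity_nM IC50 in nM.
#' @param dl_rank within-patient presentation rank (may be `NA`).
#' @param cfg a [truneo_config()].
#' @return weight in `{1, 0.5, 0.25, 0.125}` (vectorized).
#' @export
dl_weight <- function(both_identified, tpm, affinity_nM, dl_rank = NA,
                      cfg = truneo_config()) {
  n <- max(lengths(list(both_identified, tpm, affinity_nM, dl_rank)))
  both_identified <- rep_len(both_identified, n)
  tpm <- rep_len(tpm, n); affinity_nM <- rep_len(affinity_nM, n)
  dl_rank <- rep_len(dl_rank, n)
  hi_tpm <- tpm > cfg$dl_tpm
  hi_aff <- affinity_nM < cfg$dl_affinity_nM
  rank_ok <- !is.na(dl_rank) & dl_rank < cfg$dl_rank_max
  w <- rep(0.125, n)
  w[both_identified & !hi_tpm & affinity_nM > cfg$dl_affinity_nM &
      tpm < cfg$dl_tpm & rank_ok] <- 0.25
  w[both_identified & (hi_tpm | hi_aff)] <- 0.5
  w[both_identified & hi_tpm & hi_aff] <- 1
  w
}

#' Final peptide score
#' @param combine,expression,vaf,type_w,dl_w component values.
#' @return `combine * expression * vaf * type_w * dl_w`.
#' @export
peptide_score <- function(combine, expression, vaf, type_w, dl_w) {
  combine * expression * vaf * type_w * dl_w
}

#' High-confidence neoantigen flag
#'
#' VAF strictly above 0.1, IC50 strictly below 100 nM, TPM strictly above
#' 15, and the presenting HLA allele not lost to LOH.
#'
#' @param vaf,affinity_nM,tpm candidate values.
#' @param allele_lost logical: the candidate's allele is LOH-lost.
#' @param cfg a [truneo_config()].
#' @return logical (vectorized).
#' @export
high_confidence_filter <- function(vaf, affinity_nM, tpm, allele_lost,
                                   cfg = truneo_config()) {
  vaf > cfg$hc_min_vaf & affinity_nM < cfg$hc_max_affinity_nM &
    tpm > cfg$hc_min_tpm & !allele_lost
}

#' Rank scored candidates
#'
#' Descending peptide score; ties broken by ascending affinity, then
#' lexicographic peptide. Ranks are 1-based and dense.
#'
#' @param scored data.frame with `peptide_score`, `affinity_nM` and
#'   `sequence` columns.
#' @return the table sorted by rank with a `rank` column added.
#' @export
rank_candidates <- function(scored) {
  if (nrow(scored) == 0) {
    scored$rank <- integer(0)
    return(scored)
  }
  o <- order(-scored$peptide_score, scored$affinity_nM, scored$sequence)
  scored <- scored[o, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored
}

#' Score a candidate table
#'
#' Joins candidates with predictor scores, expression, per-variant VAF and
#' LOH results, computes every component of the composite score, ranks,
#' and flags high-confidence neoantigens.
#'
#' @param candidates [enumerate_candidates()] output (post
#'   [candidate_filters()], i.e. affinity <= 500 nM).
#' @param scores predictor score table (one row per peptide/allele; must
#'   carry `affinity_nM`, `cleavage`, `tap`, `dl_identified`, `dl_rank`).
#' @param expression named TPM vector.
#' @param gene_of named character: gene per variant_id.
#' @param vaf_of named numeric: tumor VAF per variant_id.
#' @param lost_alleles character vector of LOH-lost allele strings.
#' @param cfg a [truneo_config()].
#' @return ranked data.frame of scored neoantigens.
#' @export
score_candidates <- function(candidates, scores, expression, gene_of,
                             vaf_of, lost_alleles = character(0),
                             cfg = truneo_config()) {
  if (nrow(candidates) == 0) {
    out <- candidates
    for (col in c("affinity_nM", "combine_score", "expression_score",
                  "vaf", "tpm", "peptide_score"))
      out[[col]] <- numeric(0)
    out$rank <- integer(0); out$high_confidence <- logical(0)
    return(out)
  }
  key <- paste(candidates$sequence, candidates$allele, sep = "/")
  idx <- match(key, paste(scores$peptide, scores$allele, sep = "/"))
  assert_that(!anyNA(idx), "missing predictor scores for %d candidates",
              sum(is.na(idx)))
  sc <- scores[idx, , drop = FALSE]
  out <- candidates
  out$affinity_nM <- sc$affinity_nM
  out$mhc_binding_score <- mhc_binding_score(sc$affinity_nM)
  out$cleavage_score <- cleavage_score(sc$cleavage)
  out$tap_score <- tap_transport_score(sc$tap)
  out$combine_score <- combine_score(out$mhc_binding_score,
                                     out$cleavage_score, out$tap_score,
                                     cfg$combine_weights)
  q <- expression_quartiles(expression, cfg$expression_population)
  genes <- unname(gene_of[out$variant_id])
  out$tpm <- unname(expression[genes])
  out$tpm[is.na(out$tpm)] <- 0
  out$expression_score <- expression_score(out$tpm, q["lower"], q["upper"])
  out$vaf <- unname(vaf_of[out$variant_id])
  len <- nchar(out$sequence)
  anchor <- !out$neoorf &
    mapply(function(off, l) any(off == 2L | off == l),
           out$mutant_offsets, len, USE.NAMES = FALSE)
  out$anchor_changed <- anchor
  out$neo_class <- assign_class(out$neoorf, anchor, out$affinity_nM,
                                cfg$class_affinity_nM)
  out$type_weight <- type_weight(out$neo_class, cfg$class_weights)
  both <- (sc$affinity_nM <= cfg$affinity_filter_nM) & sc$dl_identified
  dl_rank <- sc$dl_rank %||% rep(NA_integer_, nrow(sc))
  out$dl_weight <- dl_weight(both, out$tpm, out$affinity_nM, dl_rank, cfg)
  out$peptide_weight <- out$type_weight * out$dl_weight
  out$peptide_score <- peptide_score(out$combine_score,
                                     out$expression_score, out$vaf,
                                     out$type_weight, out$dl_weight)
  out$loh_lost_allele <- out$allele %in% lost_alleles
  out$high_confidence <- high_confidence_filter(out$vaf, out$affinity_nM,
                                                out$tpm,
                                                out$loh_lost_allele, cfg)
  rank_candidates(out)
}

#' Collapse a ranked candidate table to one row per variant
#'
#' Keeps each variant's best-ranked candidate and re-ranks.
#'
#' @param scored output of [score_candidates()].
#' @return one row per variant, ranked.
#' @export
collapse_by_variant <- function(scored) {
  if (nrow(scored) == 0) return(scored)
  best <- !duplicated(scored$variant_id)  # already rank-sorted
  out <- scored[best, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
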