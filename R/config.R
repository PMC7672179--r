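#' Pipeline run configuration
#'
#' Collects every numeric threshold of the pipeline in one object. The
#' defaults are the published operating point of the method; an empty call
#' reproduces it exactly.
#'
#' @param snv_min_depth minimum tumor depth at an SNV (default 10x).
#' @param snv_min_vaf_tumor minimum tumor VAF for SNVs (default 0.05).
#' @param snv_max_vaf_normal maximum normal VAF (default 0.02, strict `<`).
#' @param snv_min_distance adjacent-SNV spacing in bp; SNVs closer than or
#'   equal to this on the same chromosome fail (default 10, pass is `> 10`).
#' @param snv_min_mq minimum median mapping quality of mutant reads (30).
#' @param snv_mq_p rank-sum p cutoff for mapping quality (0.2; a variant
#'   fails when the one-sided "mutant reads worse" test has `p <` cutoff).
#' @param snv_min_bq minimum median base quality of mutant reads (20).
#' @param snv_bq_p rank-sum p cutoff for base quality (0.05).
#' @param snv_dend_p rank-sum p cutoff for read-end distance (0.1).
#' @param indel_min_depth minimum tumor depth at an InDel (10x).
#' @param indel_min_vaf_tumor tumor VAF for InDels (0.10, strict `>`).
#' @param indel_max_vaf_normal normal VAF for InDels (0.02, strict `<`).
#' @param loh_alpha p-value cutoff of the paired allelic-imbalance t-test
#'   (0.0002).
#' @param loh_pseudocount if `TRUE`, add 0.5 to zero read counts instead of
#'   dropping the site (default `FALSE`: drop).
#' @param affinity_filter_nM candidate IC50 cutoff in nM (500; peptides with
#'   affinity `> 500` are dropped, exactly 500 is kept).
#' @param min_rna_mut_reads RNA mutant reads needed to call a mutation
#'   expressed (1).
#' @param combine_weights length-3 weights of binding, cleavage and TAP in
#'   the combined processing score; must sum to 1 (0.8, 0.15, 0.05).
#' @param class_weights length-6 epitope-class weights
#'   (1, 0.6, 0.5, 0.25, 0.15, 0.125).
#' @param class_affinity_nM affinity split between high- and low-affinity
#'   classes (150 nM, high is strict `<`).
#' @param dl_tpm,dl_affinity_nM,dl_rank_max thresholds of the deep-learning
#'   weight branches (TPM 15, 100 nM, rank 30).
#' @param dl_cutoff presentation-score cutoff above which the learned model
#'   calls a peptide presented (0.5).
#' @param hc_min_vaf,hc_max_affinity_nM,hc_min_tpm high-confidence filter
#'   thresholds (VAF `> 0.1`, affinity `< 100` nM, TPM `> 15`).
#' @param expression_population `"positive"` (genes with TPM > 0, default)
#'   or `"all"`: population over which expression quartiles are taken.
#' @param ranksum_exact_n largest combined sample size for the exact
#'   rank-sum distribution (25; larger uses the normal approximation).
#' @param seed integer random seed for stochastic components.
#' @return an object of class `truneo_config` (a validated named list).
#' @examples
#' cfg <- truneo_config()
#' cfg$affinity_filter_nM
#' @export
truneo_config <- function(snv_min_depth = 10,
                          snv_min_vaf_tumor = 0.05,
                          snv_max_vaf_normal = 0.02,
                          snv_min_distance = 10,
                          snv_min_mq = 30,
                          snv_mq_p = 0.2,
                          snv_min_bq = 20,
                          snv_bq_p = 0.05,
                          snv_dend_p = 0.1,
                          indel_min_depth = 10,
                          indel_min_vaf_tumor = 0.10,
                          indel_max_vaf_normal = 0.02,
                          loh_alpha = 0.0002,
                          loh_pseudocount = FALSE,
                          affinity_filter_nM = 500,
                          min_rna_mut_reads = 1,
                          combine_weights = c(mhc = 0.8, cleavage = 0.15,
                                              tap = 0.05),
                          class_weights = c(1, 0.6, 0.5, 0.25, 0.15, 0.125),
                          class_affinity_nM = 150,
                          dl_tpm = 15,
                          dl_affinity_nM = 100,
                          dl_rank_max = 30,
                          dl_cutoff = 0.5,
                          hc_min_vaf = 0.1,
                          hc_max_affinity_nM = 100,
                          hc_min_tpm = 15,
                          expression_population = c("positive", "all"),
                          ranksum_exact_n = 25,
                          seed = 1L) {
  cfg <- list(
    snv_min_depth = snv_min_depth,
    snv_min_vaf_tumor = snv_min_vaf_tumor,
    snv_max_vaf_normal = snv_max_vaf_normal,
    snv_min_distance = snv_min_distance,
    snv_min_mq = snv_min_mq,
    snv_mq_p = snv_mq_p,
    snv_min_bq = snv_min_bq,
    snv_bq_p = snv_bq_p,
    snv_dend_p = snv_dend_p,
    indel_min_depth = indel_min_depth,
    indel_min_vaf_tumor = indel_min_vaf_tumor,
    indel_max_vaf_normal = indel_max_vaf_normal,
    loh_alpha = loh_alpha,
    loh_pseudocount = isTRUE(loh_pseudocount),
    affinity_filter_nM = affinity_filter_nM,
    min_rna_mut_reads = min_rna_mut_reads,
    combine_weights = combine_weights,
    class_weights = class_weights,
    class_affinity_nM = class_affinity_nM,
    dl_tpm = dl_tpm,
    dl_affinity_nM = dl_affinity_nM,
    dl_rank_max = dl_rank_max,
    dl_cutoff = dl_cutoff,
    hc_min_vaf = hc_min_vaf,
    hc_max_affinity_nM = hc_max_affinity_nM,
    hc_min_tpm = hc_min_tpm,
    expression_population = match.arg(expression_population),
    ranksum_exact_n = ranksum_exact_n,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "truneo_config")
}

validate_config <- function(cfg) {
  assert_that(length(cfg$combine_weights) == 3 &&
                abs(sum(cfg$combine_weights) - 1) < 1e-9,
              "combine_weights must be 3 values summing to 1")
  assert_that(length(cfg$class_weights) == 6 && all(cfg$class_weights > 0),
              "class_weights must be 6 positive values")
  pos <- c("snv_min_depth", "snv_min_vaf_tumor", "snv_max_vaf_normal",
           "snv_min_distance", "snv_min_mq", "snv_mq_p", "snv_min_bq",
           "snv_bq_p", "snv_dend_p", "indel_min_depth",
           "indel_min_vaf_tumor", "indel_max_vaf_normal", "loh_alpha",
           "affinity_filter_nM", "min_rna_mut_reads", "class_affinity_nM",
           "dl_tpm", "dl_affinity_nM", "dl_rank_max", "dl_cutoff",
           "hc_min_vaf", "hc_max_affinity_nM", "hc_min_tpm",
           "ranksum_exact_n")
  for (nm in pos) {
    assert_that(is.numeric(cfg[[nm]]) && length(cfg[[nm]]) == 1 &&
                  cfg[[nm]] > 0, "config field '%s' must be positive", nm)
  }
  invisible(cfg)
}

#' Read a configuration document
#'
#' The config file is a JSON object whose keys are [truneo_config()]
#' arguments; keys that are absent keep their published default, so an
#' empty document `{}` reproduces the default operating point.
#'
#' @param path path to a JSON file, or `NULL` for all defaults.
#' @return a `truneo_config`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(truneo_config())
  assert_that(file.exists(path), "config file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(truneo_config))
  bad <- setdiff(names(doc), known)
  assert_that(length(bad) == 0, "unknown config keys: %s",
              paste(bad, collapse = ", "))
  do.call(truneo_config, doc)
}

#' @export
print.truneo_config <- function(x, ...) {
  cat("truneo run configuration\n")
  for (nm in setdiff(names(x), c("combine_weights", "class_weights"))) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  cat(sprintf("  %-22s %s\n", "combine_weights",
              paste(x$combine_weights, collapse = "/")))
  cat(sprintf("  %-22s %s\n", "class_weights",
              paste(x$class_weights, collapse = "/")))
  invisible(x)
}
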