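# High-confidence somatic variant filters.
#
# SNVs pass five criteria: (1) depth/VAF, (2) adjacent-SNV spacing > 10 bp,
# (3) mutant-read mapping quality (median >= 30 and not significantly worse
# than reference reads, rank-sum p cutoff 0.2), (4) mutant-read base quality
# (median >= 20, p cutoff 0.05), (5) mutant reads not enriched near read
# ends (p cutoff 0.1). The rank-sum comparisons are one-sided
# "mutant worse" (lower quality / closer to the read end); a variant fails
# when the test is significant at the printed cutoff.

SNV_RULES <- c("depth_vaf", "adjacent", "mapping_quality", "base_quality",
               "read_end")

filter_report <- function(variant_id, verdicts) {
  applicable <- verdicts != "not_applicable"
  structure(list(variant_id = variant_id, verdicts = verdicts,
                 overall = all(verdicts[applicable] == "pass")),
            class = "truneo_filter_report")
}

#' @export
print.truneo_filter_report <- function(x, ...) {
  cat(sprintf("variant %s: %s\n", x$variant_id,
              if (x$overall) "PASS" else "FAIL"))
  for (nm in names(x$verdicts)) {
    cat(sprintf("  %-16s %s\n", nm, x$verdicts[nm]))
  }
  invisible(x)
}

#' Filter a somatic SNV
#'
#' @param v one-row `truneo_variants` record with `vtype == "SNV"`.
#' @param all_variants full candidate table (pre-filter), used for the
#'   adjacent-SNV spacing rule; ordering is irrelevant.
#' @param cfg a [truneo_config()].
#' @return a filter report with per-rule verdicts and the overall verdict.
#' @export
filter_snv <- function(v, all_variants, cfg = truneo_config()) {
  v <- as.data.frame(v)
  assert_that(nrow(v) == 1 && v$vtype == "SNV",
              "filter_snv requires a single SNV record",
              class = "truneo_contract_error")
  verdicts <- c(
    depth_vaf = rule_depth_vaf(v, cfg),
    adjacent = rule_adjacent(v, all_variants, cfg),
    mapping_quality = rule_quality(v$mq_mut[[1]], v$mq_ref[[1]],
                                   cfg$snv_min_mq, cfg$snv_mq_p, cfg),
    base_quality = rule_quality(v$bq_mut[[1]], v$bq_ref[[1]],
                                cfg$snv_min_bq, cfg$snv_bq_p, cfg),
    read_end = rule_read_end(v$dend_mut[[1]], v$dend_ref[[1]],
                             cfg$snv_dend_p, cfg)
  )
  for (nm in names(verdicts)) truneo_log(v$variant_id, nm, verdicts[nm])
  filter_report(v$variant_id, verdicts)
}

rule_depth_vaf <- function(v, cfg) {
  ok <- v$depth_tumor >= cfg$snv_min_depth &&
    v$vaf_tumor >= cfg$snv_min_vaf_tumor &&
    v$vaf_normal < cfg$snv_max_vaf_normal
  if (isTRUE(ok)) "pass" else "fail"
}

rule_adjacent <- function(v, all_variants, cfg) {
  sel <- all_variants$vtype == "SNV" & all_variants$chrom == v$chrom &
    all_variants$variant_id != v$variant_id
  pos <- all_variants$pos[sel]
  if (length(pos) == 0) return("pass")
  if (min(abs(pos - v$pos)) > cfg$snv_min_distance) "pass" else "fail"
}

rule_quality <- function(mut, ref, min_median, p_cut, cfg) {
  if (length(mut) == 0 || length(ref) == 0) return("not_applicable")
  if (median(mut) < min_median) return("fail")
  p <- rank_sum_test(mut, ref, "less", exact_n = cfg$ranksum_exact_n)
  if (p >= p_cut) "pass" else "fail"
}

rule_read_end <- function(mut, ref, p_cut, cfg) {
  if (length(mut) == 0 || length(ref) == 0) return("not_applicable")
  # smaller distance-to-end of mutant reads = enrichment near read ends
  p <- rank_sum_test(mut, ref, "less", exact_n = cfg$ranksum_exact_n)
  if (p >= p_cut) "pass" else "fail"
}

#' Filter a somatic InDel
#'
#' Depth >= 10x, tumor VAF strictly > 10%, normal VAF strictly < 2%.
#'
#' @inheritParams filter_snv
#' @return a filter report.
#' @export
filter_indel <- function(v, cfg = truneo_config()) {
  v <- as.data.frame(v)
  assert_that(nrow(v) == 1 && v$vtype %in% c("insertion", "deletion"),
              "filter_indel requires an insertion or deletion record",
              class = "truneo_contract_error")
  ok <- v$depth_tumor >= cfg$indel_min_depth &&
    v$vaf_tumor > cfg$indel_min_vaf_tumor &&
    v$vaf_normal < cfg$indel_max_vaf_normal
  verdict <- if (isTRUE(ok)) "pass" else "fail"
  truneo_log(v$variant_id, "indel_depth_vaf", verdict)
  filter_report(v$variant_id, c(indel_depth_vaf = verdict))
}

#' Filter a whole variant table
#'
#' Applies [filter_snv()] to SNVs and [filter_indel()] to indels; fusions
#' (called from RNA) have no DNA-level filter and pass with a
#' `not_applicable` verdict.
#'
#' @param variants a `truneo_variants` table.
#' @param cfg a [truneo_config()].
#' @return list with `report` (long data.frame: variant_id, rule, verdict)
#'   and `pass` (character vector of passing variant ids).
#' @export
filter_variants <- function(variants, cfg = truneo_config()) {
  av <- as.data.frame(variants)
  reports <- lapply(seq_len(nrow(av)), function(i) {
    v <- av[i, , drop = FALSE]
    switch(v$vtype,
           SNV = filter_snv(v, av, cfg),
           insertion = ,
           deletion = filter_indel(v, cfg),
           fusion = filter_report(v$variant_id,
                                  c(fusion = "not_applicable")))
  })
  report <- do.call(rbind, lapply(reports, function(r) {
    data.frame(variant_id = r$variant_id, rule = names(r$verdicts),
               verdict = unname(r$verdicts), overall = r$overall,
               stringsAsFactors = FALSE)
  }))
  pass <- vapply(reports, function(r) r$overall, logical(1))
  list(report = report, pass = av$variant_id[pass])
}
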