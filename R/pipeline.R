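# End-to-end pipeline: variant filters -> HLA consensus + LOH -> peptide
# enumeration -> candidate filters -> predictor scores -> composite
# scoring, ranking and the high-confidence subset.

#' Run the full prioritization pipeline on a patient bundle
#'
#' @param bundle a `patient_bundle` (see [generate_synthetic_bundle()]),
#'   or an equivalently shaped list assembled from files.
#' @param cfg a [truneo_config()].
#' @return list with:
#'   `filter` (variant filter report + passing ids),
#'   `genotype` (consensus HLA genotype),
#'   `loh` (per-gene LOH results), `lost_alleles`,
#'   `candidates` (enumerated, pre-filter),
#'   `candidate_filter` (per-candidate filter verdicts),
#'   `scored` (ranked peptide-level table),
#'   `by_variant` (ranked, one row per variant),
#'   `high_confidence` (variant ids with a high-confidence candidate).
#' @export
run_pipeline <- function(bundle, cfg = truneo_config()) {
  fl <- filter_variants(bundle$variants, cfg)
  genotype <- consensus_genotype(bundle$hla_calls)
  loh <- if (length(bundle$loh_inputs)) loh_test_all(bundle$loh_inputs, cfg)
         else NULL
  lost <- if (!is.null(loh)) loh$lost_allele[loh$loh] else character(0)
  lost <- lost[!is.na(lost)]

  av <- as.data.frame(bundle$variants)
  passing <- av[av$variant_id %in% fl$pass &
                  av$consequence %in% c("missense", "frameshift",
                                        "inframe_indel", "fusion"), ,
                drop = FALSE]
  alleles <- unique(genotype$alleles)
  cand_list <- lapply(seq_len(nrow(passing)), function(i) {
    v <- passing[i, , drop = FALSE]
    prot <- if (v$consequence == "fusion") NULL
            else unname(bundle$proteome[v$gene])
    ctx <- build_context(v, prot)
    enumerate_candidates(ctx, alleles)
  })
  candidates <- if (length(cand_list)) {
    data.table::setDF(data.table::rbindlist(cand_list))
  } else candidate_frame_empty()

  if (nrow(candidates) == 0) {
    return(list(filter = fl, genotype = genotype, loh = loh,
                lost_alleles = lost, candidates = candidates,
                candidate_filter = NULL,
                scored = score_candidates(candidates, NULL,
                                          bundle$expression,
                                          character(0), numeric(0),
                                          lost, cfg),
                by_variant = candidates,
                high_confidence = character(0)))
  }

  scores <- mock_predict(candidates$sequence, candidates$allele,
                         seed = bundle$seed %||% cfg$seed,
                         fixture = bundle$predictor_scores, cfg = cfg)
  mut_reads <- bundle$rna_mut_reads[candidates$variant_id]
  mut_reads[is.na(mut_reads)] <- 0L
  cf <- data.frame(
    variant_id = candidates$variant_id,
    sequence = candidates$sequence, allele = candidates$allele,
    expressed = unname(mut_reads) >= cfg$min_rna_mut_reads,
    not_self = !is_self_peptide(candidates$sequence, bundle$proteome),
    affinity = scores$affinity_nM <= cfg$affinity_filter_nM,
    stringsAsFactors = FALSE
  )
  cf$overall <- cf$expressed & cf$not_self & cf$affinity
  kept <- candidates[cf$overall, , drop = FALSE]
  kept_scores <- scores[cf$overall, , drop = FALSE]
  kept_scores$dl_rank <- if (nrow(kept_scores))
    dl_rank_within_patient(kept_scores) else integer(0)

  gene_of <- setNames(av$gene, av$variant_id)
  vaf_of <- setNames(av$vaf_tumor, av$variant_id)
  scored <- score_candidates(kept, kept_scores, bundle$expression,
                             gene_of, vaf_of, lost, cfg)
  by_variant <- collapse_by_variant(scored)
  list(filter = fl, genotype = genotype, loh = loh, lost_alleles = lost,
       candidates = candidates, candidate_filter = cf, scored = scored,
       by_variant = by_variant,
       high_confidence = unique(scored$variant_id[scored$high_confidence]))
}
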