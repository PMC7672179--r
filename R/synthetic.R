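# Synthetic patient-bundle generator.
#
# Stands in for the out-of-scope raw-data processing (alignment, somatic
# calling, HLA typing, expression quantification): it emits the annotated
# inputs the pipeline consumes, with a planted ground truth. Planted
# "immunogenic" variants are constructed to pass every stage (variant
# filters, candidate filters, high-confidence thresholds, no LOH) with
# fully separated predictor scores; every non-planted variant violates at
# least one stage by construction, spread over failure modes (DNA filter
# failures, silent consequence, unexpressed in RNA, sub-threshold VAF and
# TPM, a low-VAF indel, a low-expression fusion).

DEFAULT_ALLELES <- c("HLA-A*11:01", "HLA-A*02:10", "HLA-B*40:01",
                     "HLA-B*40:01", "HLA-C*08:01", "HLA-C*07:02")

rand_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic patient bundle with planted truth
#'
#' Deterministic given `seed`; the same call twice yields identical
#' bundles. The planted variants are drawn so they satisfy the
#' high-confidence filter (IC50 < 100 nM, TPM > 15, VAF > 0.1, no LOH)
#' and pass the somatic filters, while each non-planted variant fails at
#' least one stage.
#'
#' @param n_variants total somatic variants.
#' @param n_immunogenic number of planted true neoantigen variants
#'   (`0 <= n_immunogenic <= n_variants`).
#' @param seed integer RNG seed.
#' @param alleles the patient's 6 HLA alleles.
#' @param n_background_genes extra expressed genes without variants (50).
#' @return list with `bundle` (a `patient_bundle`) and `truth` (character
#'   vector of planted variant ids). The bundle carries a `meta`
#'   data.frame with each variant's generator category and the expected
#'   variant-filter verdict.
#' @export
generate_synthetic_bundle <- function(n_variants, n_immunogenic, seed = 1L,
                                      alleles = DEFAULT_ALLELES,
                                      n_background_genes = 50L) {
  assert_that(n_immunogenic >= 0 && n_immunogenic <= n_variants,
              "need 0 <= n_immunogenic <= n_variants")
  with_seed(seed, build_bundle(n_variants, n_immunogenic, seed, alleles,
                               n_background_genes))
}

build_bundle <- function(n_variants, n_immunogenic, seed, alleles,
                         n_background_genes) {
  patient_id <- sprintf("SYN%04d", seed %% 10000L)
  if (n_variants == 0) {
    return(list(bundle = empty_bundle(patient_id, alleles, seed),
                truth = character(0)))
  }
  n_decoy <- n_variants - n_immunogenic
  decoy_modes <- c("subthreshold", "silent", "fail_depth", "fail_bq",
                   "unexpressed", "indel_fail", "fusion_lowexpr")
  category <- c(rep("planted", n_immunogenic),
                if (n_decoy > 0) decoy_modes[(seq_len(n_decoy) - 1L) %%
                                               length(decoy_modes) + 1L])
  genes <- sprintf("G%04d", seq_len(n_variants))
  prot_len <- 81L
  proteome <- setNames(vapply(seq_len(n_variants),
                              function(i) rand_aa(prot_len), character(1)),
                       genes)

  rows <- vector("list", n_variants)
  tpm <- numeric(n_variants)
  rna_reads <- integer(n_variants)
  fixture_rows <- list()
  truth <- character(0)

  # read-metric generators: passing variants draw mutant reads slightly
  # better than reference reads so the one-sided "mutant worse" tests are
  # never significant; quality failures push the median below threshold.
  metrics_pass <- function() list(
    mq_mut = pmin(60, round(rnorm(15, 59, 2))),
    mq_ref = pmin(60, round(rnorm(15, 55, 2))),
    bq_mut = round(rnorm(15, 36, 2)), bq_ref = round(rnorm(15, 32, 2)),
    dend_mut = round(runif(15, 30, 70)), dend_ref = round(runif(15, 20, 60))
  )

  for (i in seq_len(n_variants)) {
    cat_i <- category[i]
    gene <- genes[i]
    pos <- 10000L * i
    chrom <- sprintf("chr%d", (i %% 20L) + 1L)
    mm <- metrics_pass()
    base <- list(chrom = chrom, pos = pos, gene = gene,
                 variant_id = sprintf("%s:v%04d", patient_id, i))
    if (cat_i == "planted") {
      is_fs <- (i %% 5L) == 0L
      aa_pos <- sample(20:60, 1)
      if (is_fs) {
        v <- variant_record(chrom, pos, "A", "AT", vtype = "insertion",
                            depth_tumor = sample(150:300, 1),
                            depth_normal = sample(80:150, 1),
                            vaf_tumor = runif(1, 0.15, 0.6),
                            vaf_normal = 0,
                            gene = gene, consequence = "frameshift",
                            variant_id = base$variant_id,
                            aa_pos = aa_pos, novel_tail = rand_aa(10),
                            mq_mut = mm$mq_mut, mq_ref = mm$mq_ref,
                            bq_mut = mm$bq_mut, bq_ref = mm$bq_ref,
                            dend_mut = mm$dend_mut, dend_ref = mm$dend_ref)
      } else {
        ref_aa <- substr(proteome[[gene]], aa_pos, aa_pos)
        alt_aa <- sample(setdiff(AA_ALPHABET, ref_aa), 1)
        v <- variant_record(chrom, pos, "A", "T", vtype = "SNV",
                            depth_tumor = sample(150:300, 1),
                            depth_normal = sample(80:150, 1),
                            vaf_tumor = runif(1, 0.15, 0.6),
                            vaf_normal = 0,
                            gene = gene, consequence = "missense",
                            protein_change = sprintf("p.%s%d%s", ref_aa,
                                                     aa_pos, alt_aa),
                            variant_id = base$variant_id,
                            mq_mut = mm$mq_mut, mq_ref = mm$mq_ref,
                            bq_mut = mm$bq_mut, bq_ref = mm$bq_ref,
                            dend_mut = mm$dend_mut, dend_ref = mm$dend_ref)
      }
      tpm[i] <- runif(1, 40, 200)
      rna_reads[i] <- sample(3:40, 1)
      # designed candidate: one 9-mer per allele gets strong scores
      ctx <- build_context(v, proteome[[gene]])
      cand9 <- enumerate_candidates(ctx, alleles[1], lengths = 9)
      designed <- cand9$sequence[ceiling(nrow(cand9) / 2)]
      fixture_rows[[length(fixture_rows) + 1]] <- data.frame(
        peptide = designed, allele = alleles[1],
        affinity_nM = runif(1, 20, 80), cleavage = runif(1, 0.6, 0.95),
        tap = runif(1, 0.5, 2), dl_score = runif(1, 0.8, 0.99),
        stringsAsFactors = FALSE)
      truth <- c(truth, v$variant_id)
    } else if (cat_i == "subthreshold") {
      v <- decoy_missense(base, proteome, mm, vaf = runif(1, 0.05, 0.09))
      tpm[i] <- runif(1, 0.5, 12); rna_reads[i] <- sample(1:10, 1)
    } else if (cat_i == "silent") {
      v <- variant_record(chrom, pos, "G", "A", vtype = "SNV",
                          depth_tumor = sample(50:200, 1),
                          depth_normal = sample(50:150, 1),
                          vaf_tumor = runif(1, 0.1, 0.4), vaf_normal = 0,
                          gene = gene, consequence = "silent",
                          variant_id = base$variant_id,
                          mq_mut = mm$mq_mut, mq_ref = mm$mq_ref,
                          bq_mut = mm$bq_mut, bq_ref = mm$bq_ref,
                          dend_mut = mm$dend_mut, dend_ref = mm$dend_ref)
      tpm[i] <- runif(1, 0, 30); rna_reads[i] <- sample(0:10, 1)
    } else if (cat_i == "fail_depth") {
      v <- decoy_missense(base, proteome, mm, vaf = runif(1, 0.1, 0.3),
                          depth = sample(3:9, 1))
      tpm[i] <- runif(1, 0, 30); rna_reads[i] <- sample(1:10, 1)
    } else if (cat_i == "fail_bq") {
      mm$bq_mut <- round(rnorm(15, 12, 2))
      v <- decoy_missense(base, proteome, mm, vaf = runif(1, 0.1, 0.3))
      tpm[i] <- runif(1, 0, 30); rna_reads[i] <- sample(1:10, 1)
    } else if (cat_i == "unexpressed") {
      v <- decoy_missense(base, proteome, mm, vaf = runif(1, 0.05, 0.09))
      tpm[i] <- runif(1, 0, 10); rna_reads[i] <- 0L
    } else if (cat_i == "indel_fail") {
      v <- variant_record(chrom, pos, "ATT", "A", vtype = "deletion",
                          depth_tumor = sample(50:200, 1),
                          depth_normal = sample(50:150, 1),
                          vaf_tumor = runif(1, 0.03, 0.09), vaf_normal = 0,
                          gene = gene, consequence = "inframe_indel",
                          variant_id = base$variant_id,
                          aa_pos = sample(20:60, 1), del_len = 1L)
      tpm[i] <- runif(1, 0, 30); rna_reads[i] <- sample(1:10, 1)
    } else {  # fusion_lowexpr
      b <- 12L
      v <- variant_record(chrom, pos, "N", "N", vtype = "fusion",
                          depth_tumor = NA, depth_normal = NA,
                          vaf_tumor = runif(1, 0.05, 0.08), vaf_normal = 0,
                          gene = gene, consequence = "fusion",
                          variant_id = base$variant_id,
                          junction_seq = rand_aa(24), junction_pos = b)
      tpm[i] <- runif(1, 0.5, 12); rna_reads[i] <- sample(1:10, 1)
    }
    rows[[i]] <- v
  }
  variants <- bind_variants(rows)
  names(tpm) <- genes
  bg <- setNames(runif(n_background_genes, 0, 50),
                 sprintf("BG%04d", seq_len(n_background_genes)))
  expression <- c(tpm, bg)
  names(rna_reads) <- variants$variant_id

  hla_calls <- hla_call_set(alleles, alleles, alleles, alleles)
  loh_inputs <- lapply(c("A", "B", "C"), function(g) {
    pair <- sort(unique(alleles[hla_gene(alleles) == g]))
    if (length(pair) == 1) pair <- rep(pair, 2)
    normal1 <- sample(80:160, 12, replace = TRUE)
    normal2 <- sample(80:160, 12, replace = TRUE)
    loh_input(g, pair[1], pair[2],
              tumor1 = round(normal1 * runif(12, 0.92, 1.08)),
              normal1 = normal1,
              tumor2 = round(normal2 * runif(12, 0.92, 1.08)),
              normal2 = normal2)
  })
  fixture <- if (length(fixture_rows)) do.call(rbind, fixture_rows)
             else NULL
  # fusions carry no DNA-level filter and pass with not_applicable
  expected_pass <- !category %in% c("fail_depth", "fail_bq", "indel_fail")
  meta <- data.frame(variant_id = variants$variant_id, category = category,
                     expected_filter_pass = expected_pass,
                     stringsAsFactors = FALSE)
  bundle <- structure(list(
    patient_id = patient_id, variants = variants, expression = expression,
    rna_mut_reads = rna_reads, hla_calls = hla_calls,
    loh_inputs = loh_inputs, proteome = proteome,
    predictor_scores = fixture, seed = as.integer(seed), meta = meta
  ), class = "patient_bundle")
  list(bundle = bundle, truth = truth)
}

decoy_missense <- function(base, proteome, mm, vaf, depth = NULL) {
  aa_pos <- sample(20:60, 1)
  ref_aa <- substr(proteome[[base$gene]], aa_pos, aa_pos)
  alt_aa <- sample(setdiff(AA_ALPHABET, ref_aa), 1)
  variant_record(base$chrom, base$pos, "C", "G", vtype = "SNV",
                 depth_tumor = depth %||% sample(50:200, 1),
                 depth_normal = sample(50:150, 1),
                 vaf_tumor = vaf, vaf_normal = 0,
                 gene = base$gene, consequence = "missense",
                 protein_change = sprintf("p.%s%d%s", ref_aa, aa_pos,
                                          alt_aa),
                 variant_id = base$variant_id,
                 mq_mut = mm$mq_mut, mq_ref = mm$mq_ref,
                 bq_mut = mm$bq_mut, bq_ref = mm$bq_ref,
                 dend_mut = mm$dend_mut, dend_ref = mm$dend_ref)
}

empty_bundle <- function(patient_id, alleles, seed) {
  structure(list(
    patient_id = patient_id,
    variants = candidate_frame_empty_variants(),
    expression = setNames(numeric(0), character(0)),
    rna_mut_reads = setNames(integer(0), character(0)),
    hla_calls = hla_call_set(alleles, alleles, alleles, alleles),
    loh_inputs = list(), proteome = setNames(character(0), character(0)),
    predictor_scores = NULL, seed = as.integer(seed),
    meta = data.frame(variant_id = character(0), category = character(0),
                      expected_filter_pass = logical(0))
  ), class = "patient_bundle")
}

candidate_frame_empty_variants <- function() {
  v <- variant_record("chr1", 1, "A", "T")
  v[0, , drop = FALSE]
}

#' @export
print.patient_bundle <- function(x, ...) {
  cat(sprintf("patient bundle %s: %d variants, %d genes, %d HLA alleles\n",
              x$patient_id, nrow(x$variants), length(x$expression),
              length(unique(x$hla_calls$poly_normal))))
  invisible(x)
}
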