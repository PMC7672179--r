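mk_missense <- function(protein, pos, alt = NULL) {
  ref <- substr(protein, pos, pos)
  if (is.null(alt)) alt <- setdiff(c("A", "V"), ref)[1]
  variant_record("chr1", 1000, "A", "T", vtype = "SNV",
                 gene = "G1", consequence = "missense",
                 protein_change = sprintf("p.%s%d%s", ref, pos, alt),
                 variant_id = "v1")
}

test_that("missense context is a 21-mer centred on the substitution", {
  set.seed(1)
  prot <- paste(sample(c("A", "C", "D", "E"), 200, replace = TRUE),
                collapse = "")
  ctx <- build_context(mk_missense(prot, 50, "W"), prot)
  expect_equal(nchar(ctx$mut_context), 21)
  expect_equal(ctx$mutant_positions, 11L)   # centre, 1-based
  expect_equal(substr(ctx$mut_context, 11, 11), "W")
  expect_equal(substr(ctx$wt_context, 11, 11), substr(prot, 50, 50))
  # flanks are the untouched protein
  expect_equal(ctx$wt_context, substr(prot, 40, 60))
})

test_that("contexts truncate at protein boundaries", {
  prot <- strrep("A", 200)
  ctx <- build_context(mk_missense(prot, 3, "V"), prot)
  expect_equal(nchar(ctx$mut_context), 13)  # 2 left + 1 + 10 right
  expect_equal(ctx$mutant_positions, 3L)
  ctx <- build_context(mk_missense(prot, 199, "V"), prot)
  expect_equal(nchar(ctx$mut_context), 12)  # 10 left + 1 + 1 right
})

test_that("frameshift context is upstream flank plus the novel tail", {
  prot <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  v <- variant_record("chr1", 1, "A", "AT", vtype = "insertion",
                      gene = "G1", consequence = "frameshift",
                      variant_id = "fs1", aa_pos = 51,
                      novel_tail = "MLR*IGNORED")
  ctx <- build_context(v, prot)
  expect_equal(ctx$mut_context, paste0(substr(prot, 41, 50), "MLR"))
  expect_equal(ctx$mutant_positions, 11:13)
  expect_true(ctx$neoorf)
  # stop at the first novel codon: no context, no candidates
  v$novel_tail <- "*"
  ctx <- build_context(v, prot)
  expect_equal(nchar(ctx$mut_context), 0)
  expect_equal(nrow(enumerate_candidates(ctx, "HLA-A*11:01")), 0)
  silent <- variant_record("chr1", 5, "G", "A", vtype = "SNV",
                           consequence = "silent", variant_id = "s1")
  expect_error(build_context(silent, prot),
               class = "truneo_contract_error")
})

test_that("a full 21-mer context yields 38 windows per allele", {
  prot <- paste(sample(c("G", "H", "I", "K"), 100, replace = TRUE),
                collapse = "")
  ctx <- build_context(mk_missense(prot, 50, "W"), prot)
  one <- enumerate_candidates(ctx, "HLA-A*11:01")
  expect_equal(nrow(one), 38)
  expect_equal(sum(nchar(one$sequence) == 8), 8)
  expect_equal(sum(nchar(one$sequence) == 11), 11)
  # crossing with alleles: homozygous duplicates collapse
  six <- enumerate_candidates(ctx, c("HLA-A*11:01", "HLA-A*02:10",
                                     "HLA-B*40:01", "HLA-B*40:01",
                                     "HLA-C*08:01", "HLA-C*07:02"))
  expect_equal(nrow(six), 38 * 5)
  expect_equal(length(unique(six$allele)), 5)
  # minimal context: one window
  short <- protein_context("v", strrep("A", 8), paste0("W", strrep("A", 7)),
                           1L)
  expect_equal(nrow(enumerate_candidates(short, "HLA-A*11:01")), 1)
})

test_that("window counts match the closed-form formula for all L, k, m", {
  for (L in 8:30) {
    for (m0 in seq(0, L - 1, by = 3)) {
      wt <- strrep("A", L)
      mut <- wt
      substr(mut, m0 + 1, m0 + 1) <- "W"
      ctx <- protein_context("v", wt, mut, m0 + 1L)
      cand <- enumerate_candidates(ctx, "HLA-A*11:01")
      for (k in 8:11) {
        expect_equal(sum(nchar(cand$sequence) == k),
                     window_count_formula(L, k, m0),
                     info = sprintf("L=%d k=%d m=%d", L, k, m0))
      }
    }
  }
})

test_that("every candidate covers a mutant residue inside its context", {
  set.seed(30)
  for (i in 1:15) {
    L <- sample(8:30, 1)
    wt <- paste(sample(c("A", "C", "D", "E", "F"), L, replace = TRUE),
                collapse = "")
    pos <- sample(L, 1)
    mut <- wt; substr(mut, pos, pos) <- "W"
    ctx <- protein_context("v", wt, mut, pos)
    cand <- enumerate_candidates(ctx, "HLA-A*11:01")
    if (nrow(cand) == 0) next
    expect_true(all(grepl("W", cand$sequence, fixed = TRUE)))
    expect_true(all(vapply(cand$sequence, grepl, logical(1), x = mut,
                           fixed = TRUE)))
    # offsets point at the mutated residue
    hit <- mapply(function(s, off) substr(s, off[1], off[1]) == "W",
                  cand$sequence, cand$mutant_offsets)
    expect_true(all(hit))
  }
})

test_that("fusion candidates span the junction", {
  v <- variant_record("chr1", 1, "N", "N", vtype = "fusion",
                      gene = "G1", consequence = "fusion",
                      variant_id = "fus1",
                      junction_seq = paste0(strrep("A", 12), strrep("C", 12)),
                      junction_pos = 12L)
  ctx <- build_context(v)
  cand <- enumerate_candidates(ctx, "HLA-A*11:01")
  expect_gt(nrow(cand), 0)
  # every window contains both an A-side and a C-side residue
  expect_true(all(grepl("AC", cand$sequence, fixed = TRUE)))
  expect_true(all(cand$neoorf))
})

test_that("candidate filters implement the three conditions", {
  proteome <- c(P1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  cand <- list(sequence = "AYWAKQRQI")
  cfg <- truneo_config()
  v <- candidate_filters(cand, rna_mut_reads = 0, proteome, 100, cfg)
  expect_false(v[["expressed"]]); expect_false(v[["overall"]])
  v <- candidate_filters(cand, 1, proteome, 100, cfg)
  expect_true(v[["overall"]])
  # boundary: exactly 500 nM retained, above dropped
  expect_true(candidate_filters(cand, 1, proteome, 500)[["affinity"]])
  expect_false(candidate_filters(cand, 1, proteome, 500.01)[["affinity"]])
  # verbatim self peptide fails homology
  self <- list(sequence = "TAYIAKQRQ")
  v <- candidate_filters(self, 1, proteome, 100)
  expect_false(v[["not_self"]]); expect_false(v[["overall"]])
  expect_error(candidate_filters(cand, 1, proteome, NA_real_),
               class = "truneo_contract_error")
  # verdicts are conjunctive, hence order-independent by construction
  v <- candidate_filters(self, 0, proteome, 600)
  expect_equal(unname(v), c(FALSE, FALSE, FALSE, FALSE))
})

test_that("anchor detection fires at P2 and the C-terminus only", {
  mk <- function(off) list(sequence = "ABCDEFGHK", wt_sequence = "ABCDEFGHI",
                           mutant_offsets = off)
  expect_true(detect_anchor_change(mk(2L)))
  expect_true(detect_anchor_change(mk(9L)))
  expect_false(detect_anchor_change(mk(5L)))
  expect_false(detect_anchor_change(mk(1L)))
  neo <- list(sequence = "ABCDEFGHK", wt_sequence = NA_character_,
              mutant_offsets = 2L)
  expect_error(detect_anchor_change(neo), class = "truneo_contract_error")
})
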