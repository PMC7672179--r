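test_that("tanh component scores reproduce the worked values", {
  expect_equal(mhc_binding_score(500), 0)
  expect_equal(mhc_binding_score(100), 0.9640, tolerance = 1e-4)
  expect_equal(mhc_binding_score(300), 0.7616, tolerance = 1e-4)
  expect_error(mhc_binding_score(0), "positive")
  expect_equal(tap_transport_score(0), 0.5)
  expect_equal(tap_transport_score(1), 0.9933, tolerance = 1e-4)
  expect_lt(abs(tap_transport_score(-1) - 0.0067), 1e-4)
  expect_equal(cleavage_score(0), 0)
  expect_equal(cleavage_score(1), 0.9951, tolerance = 1e-4)
  expect_equal(cleavage_score(0.5), 0.9051, tolerance = 1e-4)
})

test_that("combine_score applies the 0.8/0.15/0.05 weights", {
  expect_equal(combine_score(1, 1, 1), 1)
  expect_equal(combine_score(0, 0, 0.5), 0.025)
  expect_equal(combine_score(0.9640, 0.9951, 0.9933), 0.9702,
               tolerance = 1e-3)
})

test_that("expression score is the four-level rank normalisation", {
  expect_equal(expression_score(0, 5, 50), 0)
  expect_equal(expression_score(100, 5, 50), 1)
  expect_equal(expression_score(20, 5, 50), 0.66)
  expect_equal(expression_score(2, 5, 50), 0.33)
  # boundaries land in the middle band
  expect_equal(expression_score(5, 5, 50), 0.66)
  expect_equal(expression_score(50, 5, 50), 0.66)
  expect_error(expression_score(-1, 5, 50), "non-negative")
  # only the four printed values ever occur
  set.seed(2)
  tpm <- c(0, runif(500, 0, 100))
  sc <- expression_score(tpm, 10, 60)
  expect_true(all(sc %in% c(0, 0.33, 0.66, 1)))
  # quartiles are order-invariant, so permuting the table changes nothing
  expr <- setNames(runif(80, 0, 50), paste0("G", 1:80))
  q1 <- expression_quartiles(expr)
  q2 <- expression_quartiles(sample(expr))
  expect_equal(q1, q2)
  expect_equal(expression_score(expr, q1["lower"], q1["upper"]),
               expression_score(expr, q2["lower"], q2["upper"]))
})

test_that("six-class taxonomy and type weights follow the definitions", {
  expect_equal(assign_class(TRUE, FALSE, 100), 1L)
  expect_equal(assign_class(FALSE, TRUE, 100), 2L)
  expect_equal(assign_class(FALSE, FALSE, 100), 3L)
  expect_equal(assign_class(TRUE, FALSE, 300), 4L)
  expect_equal(assign_class(FALSE, TRUE, 300), 5L)
  expect_equal(assign_class(FALSE, FALSE, 300), 6L)
  # boundary: exactly 150 nM is low-affinity
  expect_equal(assign_class(TRUE, FALSE, 150), 4L)
  expect_error(assign_class(TRUE, FALSE, 501),
               class = "truneo_contract_error")
  expect_equal(type_weight(1:6), c(1, 0.6, 0.5, 0.25, 0.15, 0.125))
})

test_that("deep-learning weight branches match the definition", {
  cfg <- truneo_config()
  expect_equal(dl_weight(TRUE, 20, 80, 5, cfg), 1)
  expect_equal(dl_weight(TRUE, 20, 200, 50, cfg), 0.5)
  expect_equal(dl_weight(TRUE, 5, 80, 50, cfg), 0.5)
  expect_equal(dl_weight(TRUE, 5, 200, 5, cfg), 0.25)
  expect_equal(dl_weight(TRUE, 5, 200, 40, cfg), 0.125)
  expect_equal(dl_weight(FALSE, 100, 50, NA, cfg), 0.125)
  # equality gaps fall through to 0.125
  expect_equal(dl_weight(TRUE, 15, 100, 5, cfg), 0.125)
})

test_that("peptide score multiplies its five factors", {
  expect_equal(peptide_score(1, 1, 0.5, 1, 1), 0.5)
  expect_equal(peptide_score(0.7, 0, 0.5, 0.6, 1), 0)
  expect_lt(abs(peptide_score(0.9702, 0.66, 0.3, 0.6, 0.5) - 0.05764),
            1e-4)
})

test_that("ranking is a dense permutation with documented tie-breaks", {
  df <- data.frame(sequence = c("AA", "BB", "CC", "DD"),
                   peptide_score = c(0.5, 0.9, 0.5, 0.5),
                   affinity_nM = c(120, 10, 80, 80))
  r <- rank_candidates(df)
  expect_equal(r$rank, 1:4)
  expect_equal(r$sequence, c("BB", "CC", "DD", "AA"))
  expect_equal(rank_candidates(r)$sequence, r$sequence)  # idempotent
  empty <- rank_candidates(df[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("high-confidence filter uses strict thresholds and LOH", {
  expect_true(high_confidence_filter(0.2, 80, 20, FALSE))
  expect_false(high_confidence_filter(0.1, 80, 20, FALSE))
  expect_false(high_confidence_filter(0.2, 100, 20, FALSE))
  expect_false(high_confidence_filter(0.2, 80, 15, FALSE))
  expect_false(high_confidence_filter(0.2, 80, 20, TRUE))
})

test_that("peptide score is monotone non-increasing in affinity and
           bounded in [0,1] for filtered candidates", {
  cfg <- truneo_config()
  set.seed(8)
  for (i in 1:60) {
    cleav <- runif(1); tap <- runif(1, -3, 3)
    tpm <- runif(1, 0, 100); vaf <- runif(1)
    neoorf <- sample(c(TRUE, FALSE), 1)
    anchor <- if (neoorf) FALSE else sample(c(TRUE, FALSE), 1)
    both <- sample(c(TRUE, FALSE), 1); dlr <- sample(c(5L, 50L), 1)
    grid <- sort(runif(25, 1, 500))
    sc <- vapply(grid, function(aff) {
      comb <- combine_score(mhc_binding_score(aff), cleavage_score(cleav),
                            tap_transport_score(tap))
      es <- expression_score(tpm, 10, 60)
      tw <- type_weight(assign_class(neoorf, anchor, aff))
      dw <- dl_weight(both, tpm, aff, dlr, cfg)
      peptide_score(comb, es, vaf, tw, dw)
    }, numeric(1))
    expect_true(all(diff(sc) <= 1e-12), info = sprintf("case %d", i))
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("pipeline scoring agrees with the straight-line oracle to 1e-9", {
  set.seed(14)
  n <- 1000
  expr <- setNames(runif(n, 0, 120), sprintf("G%04d", 1:n))
  q <- quantile(expr[expr > 0], c(0.25, 0.75), names = FALSE)
  aff <- runif(n, 1, 500)
  cleav <- runif(n); tap <- runif(n, -3, 3)
  vaf <- runif(n)
  neoorf <- sample(c(TRUE, FALSE), n, replace = TRUE)
  # anchor status is driven by the mutant offset within a 9-mer
  off <- sample(c(2L, 5L, 9L), n, replace = TRUE)
  both <- sample(c(TRUE, FALSE), n, replace = TRUE)
  dlr <- sample(c(3L, 40L), n, replace = TRUE)
  ids <- sprintf("v%04d", 1:n)
  cands <- data.frame(
    variant_id = ids,
    sequence = vapply(1:n, function(i) {
      s <- sample(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]], 9,
                  replace = TRUE)
      s[off[i]] <- "W"; paste(s, collapse = "")
    }, character(1)),
    allele = "HLA-A*02:01",
    wt_sequence = NA_character_, neoorf = neoorf,
    stringsAsFactors = FALSE)
  cands$wt_sequence[!neoorf] <- strrep("A", 9)
  cands$mutant_offsets <- as.list(off)
  scores <- data.frame(peptide = cands$sequence, allele = cands$allele,
                       affinity_nM = aff, cleavage = cleav, tap = tap,
                       dl_identified = both, dl_rank = dlr)
  scored <- score_candidates(cands, scores, expr,
                             gene_of = setNames(names(expr), ids),
                             vaf_of = setNames(vaf, ids),
                             cfg = truneo_config())
  key <- match(ids, scored$variant_id)
  oracle <- vapply(1:n, function(i) {
    oracle_peptide_score(aff[i], cleav[i], tap[i], unname(expr[i]),
                         q[1], q[2], vaf[i], neoorf[i],
                         !neoorf[i] && off[i] %in% c(2L, 9L),
                         both[i], dlr[i])
  }, numeric(1))
  expect_equal(scored$peptide_score[key], oracle, tolerance = 1e-9)
  expect_true(all(scored$rank == seq_len(n)))
})
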