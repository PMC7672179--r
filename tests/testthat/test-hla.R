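geno <- function(a1, a2, b1 = "HLA-B*40:01", b2 = "HLA-B*44:02",
                 c1 = "HLA-C*08:01", c2 = "HLA-C*07:02") {
  c(a1, a2, b1, b2, c1, c2)
}

test_that("consensus decision tree follows the four branches", {
  g <- geno("HLA-A*11:01", "HLA-A*02:10")
  # (i) caller 1 agrees across samples
  cs <- consensus_genotype(hla_call_set(g, g, g, g))
  expect_equal(cs$confidence, "high")
  expect_true(all(cs$per_gene$source == "caller1"))
  expect_setequal(cs$alleles, g)
  # (ii) caller 1 discordant, caller 2 concordant -> caller 2
  g2 <- geno("HLA-A*01:01", "HLA-A*02:10")
  cs <- consensus_genotype(hla_call_set(g, g2, g2, g2))
  expect_equal(cs$per_gene$source[cs$per_gene$gene == "A"], "caller2")
  expect_true("HLA-A*01:01" %in% cs$alleles)
  expect_equal(cs$confidence, "high")
  # (iii) both discordant across samples but agreeing on normal
  g3 <- geno("HLA-A*03:01", "HLA-A*02:10")
  cs <- consensus_genotype(hla_call_set(g, g2, g3, g2))
  expect_equal(cs$per_gene$source[cs$per_gene$gene == "A"],
               "normal_agreement")
  # (iv) all four distinct -> caller 1 normal, low confidence
  g4 <- geno("HLA-A*24:02", "HLA-A*02:10")
  cs <- consensus_genotype(hla_call_set(g, g2, g3, g4))
  expect_equal(cs$per_gene$source[cs$per_gene$gene == "A"],
               "caller1_normal_fallback")
  expect_equal(cs$confidence, "low")
  expect_true("HLA-A*01:01" %in% cs$alleles)  # poly_normal's allele
})

test_that("every equality pattern maps to exactly one branch", {
  # randomized call sets over a tiny allele pool exercise all patterns;
  # an inline re-statement of the decision tree is the oracle
  pool <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01")
  set.seed(5)
  for (i in 1:60) {
    picks <- replicate(4, sort(sample(pool, 2, replace = TRUE)),
                       simplify = FALSE)
    cs <- consensus_genotype(hla_call_set(
      geno(picks[[1]][1], picks[[1]][2]), geno(picks[[2]][1], picks[[2]][2]),
      geno(picks[[3]][1], picks[[3]][2]), geno(picks[[4]][1], picks[[4]][2])))
    row <- cs$per_gene[cs$per_gene$gene == "A", ]
    expected <- if (identical(picks[[1]], picks[[2]])) {
      list(picks[[2]], "caller1", "high")
    } else if (identical(picks[[3]], picks[[4]])) {
      list(picks[[4]], "caller2", "high")
    } else if (identical(picks[[2]], picks[[4]])) {
      list(picks[[2]], "normal_agreement", "high")
    } else list(picks[[2]], "caller1_normal_fallback", "low")
    expect_equal(sort(c(row$allele1, row$allele2)), expected[[1]])
    expect_equal(row$source, expected[[2]])
    expect_equal(row$confidence, expected[[3]])
  }
})

test_that("hla_call_set validates allele strings and gene structure", {
  g <- geno("HLA-A*11:01", "HLA-A*02:10")
  bad <- g; bad[1] <- "A*11:01"
  expect_error(hla_call_set(bad, g, g, g),
               class = "truneo_validation_error")
  bad <- geno("HLA-A*11:01", "HLA-A*02:10", b1 = "HLA-A*01:01")
  expect_error(hla_call_set(bad, bad, bad, bad),
               class = "truneo_validation_error")
})

test_that("LOH detected for a half-coverage allele; jitter yields none", {
  set.seed(9)
  n1 <- sample(150:250, 30, replace = TRUE)
  n2 <- sample(150:250, 30, replace = TRUE)
  jit <- function(x, lo = 0.97, hi = 1.03) round(x * runif(length(x), lo, hi))
  inp <- loh_input("A", "HLA-A*11:01", "HLA-A*02:10",
                   tumor1 = jit(n1 / 2), normal1 = n1,
                   tumor2 = jit(n2), normal2 = n2)
  res <- loh_test(inp)
  expect_lt(res$p_value, 2e-4)
  expect_true(res$loh)
  expect_equal(res$lost_allele, "HLA-A*11:01")
  # balanced alleles with symmetric jitter: no call
  inp2 <- loh_input("A", "HLA-A*11:01", "HLA-A*02:10",
                    tumor1 = jit(n1, 0.92, 1.08), normal1 = n1,
                    tumor2 = jit(n2, 0.92, 1.08), normal2 = n2)
  res2 <- loh_test(inp2)
  expect_false(res2$loh)
  expect_true(is.na(res2$lost_allele))
})

test_that("degenerate LOH inputs follow the documented conventions", {
  # identical ratios at every site: zero differences, p = 1
  inp <- loh_input("B", "HLA-B*40:01", "HLA-B*44:02",
                   tumor1 = c(100, 120, 80), normal1 = c(100, 120, 80),
                   tumor2 = c(50, 60, 40), normal2 = c(50, 60, 40))
  res <- loh_test(inp)
  expect_equal(res$p_value, 1)
  expect_false(res$loh)
  # two sites with differences +0.5 / -0.5: t = 0 by symmetry
  inp <- loh_input("B", "HLA-B*40:01", "HLA-B*44:02",
                   tumor1 = c(100 * sqrt(2), 100), normal1 = c(100, 100),
                   tumor2 = c(100, 100 * sqrt(2)), normal2 = c(100, 100))
  res <- loh_test(inp)
  expect_gt(res$p_value, 2e-4)
  expect_false(res$loh)
  # constant non-zero difference: p = 0 with a warning
  inp <- loh_input("B", "HLA-B*40:01", "HLA-B*44:02",
                   tumor1 = c(50, 60), normal1 = c(100, 120),
                   tumor2 = c(100, 120), normal2 = c(100, 120))
  expect_warning(res <- loh_test(inp), "zero-variance")
  expect_equal(res$p_value, 0)
  expect_true(res$loh)
})

test_that("loh_test is label-symmetric and matches the t oracle", {
  set.seed(21)
  for (i in 1:20) {
    ns <- sample(4:12, 1)
    t1 <- sample(20:200, ns, replace = TRUE)
    n1 <- sample(20:200, ns, replace = TRUE)
    t2 <- sample(20:200, ns, replace = TRUE)
    n2 <- sample(20:200, ns, replace = TRUE)
    a <- loh_test(loh_input("C", "HLA-C*08:01", "HLA-C*07:02",
                            t1, n1, t2, n2))
    b <- loh_test(loh_input("C", "HLA-C*07:02", "HLA-C*08:01",
                            t2, n2, t1, n1))
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$mean_diff, -b$mean_diff)
    d <- log2(t1 / n1) - log2(t2 / n2)
    expect_equal(a$p_value, t.test(d)$p.value, tolerance = 1e-12)
  }
})

test_that("zero-count sites are dropped (or pseudocounted) and guarded", {
  inp <- loh_input("A", "HLA-A*11:01", "HLA-A*02:10",
                   tumor1 = c(0, 100, 120), normal1 = c(50, 100, 100),
                   tumor2 = c(60, 90, 100), normal2 = c(60, 100, 110))
  expect_equal(loh_test(inp)$n_sites, 2)
  cfg <- truneo_config(loh_pseudocount = TRUE)
  expect_equal(loh_test(inp, cfg)$n_sites, 3)
  too_few <- loh_input("A", "HLA-A*11:01", "HLA-A*02:10",
                       tumor1 = c(0, 100), normal1 = c(50, 100),
                       tumor2 = c(60, 90), normal2 = c(60, 100))
  expect_error(loh_test(too_few), class = "truneo_insufficient_data")
  hom <- loh_input("B", "HLA-B*40:01", "HLA-B*40:01",
                   tumor1 = c(1, 2), normal1 = c(1, 2),
                   tumor2 = c(1, 2), normal2 = c(1, 2))
  expect_equal(loh_test(hom)$status, "not_applicable")
})
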