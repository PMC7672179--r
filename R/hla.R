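# HLA class-I consensus genotyping and loss-of-heterozygosity.

HLA_ALLELE_RE <- "^HLA-[ABC]\\*\\d{2}:\\d{2}$"

hla_gene <- function(allele) sub("^HLA-([ABC]).*$", "\\1", allele)

validate_genotype <- function(g, what) {
  assert_that(length(g) == 6, "%s must contain 6 alleles", what,
              class = "truneo_validation_error")
  assert_that(all(grepl(HLA_ALLELE_RE, g)),
              "malformed allele string in %s: %s", what,
              paste(g[!grepl(HLA_ALLELE_RE, g)], collapse = ", "),
              class = "truneo_validation_error")
  tab <- table(hla_gene(g))
  assert_that(all(c("A", "B", "C") %in% names(tab)) && all(tab == 2),
              "%s must have exactly 2 alleles per gene", what,
              class = "truneo_validation_error")
  invisible(g)
}

#' Bundle the four HLA genotype calls (2 callers x 2 samples)
#'
#' @param poly_tumor,poly_normal,bwa_tumor,bwa_normal character vectors of
#'   6 alleles each (2 per gene A/B/C) in 4-digit nomenclature,
#'   e.g. `"HLA-A*11:01"`.
#' @return an `hla_call_set`.
#' @export
hla_call_set <- function(poly_tumor, poly_normal, bwa_tumor, bwa_normal) {
  calls <- list(poly_tumor = poly_tumor, poly_normal = poly_normal,
                bwa_tumor = bwa_tumor, bwa_normal = bwa_normal)
  for (nm in names(calls)) validate_genotype(calls[[nm]], nm)
  structure(calls, class = "hla_call_set")
}

gene_pair <- function(g, gene) sort(g[hla_gene(g) == gene])

#' Resolve a consensus HLA genotype from two callers and two samples
#'
#' Per gene (A, B, C independently): if caller 1 (Polysolver-style) agrees
#' between tumor and normal, its genotype is used; else if caller 2
#' (BWA-HLA-style) agrees between tumor and normal, caller 2's genotype is
#' used; else if the two callers agree on the normal sample, that normal
#' genotype is used; otherwise caller 1's normal-sample genotype is used
#' and marked low confidence.
#'
#' @param calls an [hla_call_set()].
#' @return list with `alleles` (6 allele strings), `confidence`
#'   (`"high"`/`"low"`, low iff any gene hit the fallback branch) and
#'   `per_gene` (data.frame gene / allele1 / allele2 / source / confidence).
#' @export
consensus_genotype <- function(calls) {
  assert_that(inherits(calls, "hla_call_set"),
              "calls must be an hla_call_set")
  per_gene <- do.call(rbind, lapply(c("A", "B", "C"), function(gene) {
    pt <- gene_pair(calls$poly_tumor, gene)
    pn <- gene_pair(calls$poly_normal, gene)
    bt <- gene_pair(calls$bwa_tumor, gene)
    bn <- gene_pair(calls$bwa_normal, gene)
    if (identical(pt, pn)) {
      res <- list(pn, "caller1", "high")
    } else if (identical(bt, bn)) {
      res <- list(bn, "caller2", "high")
    } else if (identical(pn, bn)) {
      res <- list(pn, "normal_agreement", "high")
    } else {
      res <- list(pn, "caller1_normal_fallback", "low")
    }
    data.frame(gene = gene, allele1 = res[[1]][1], allele2 = res[[1]][2],
               source = res[[2]], confidence = res[[3]],
               stringsAsFactors = FALSE)
  }))
  list(alleles = as.vector(rbind(per_gene$allele1, per_gene$allele2)),
       confidence = if (any(per_gene$confidence == "low")) "low" else "high",
       per_gene = per_gene)
}

#' Paired tumor/normal allele coverage for the LOH test
#'
#' @param gene HLA gene (`"A"`, `"B"` or `"C"`).
#' @param allele1,allele2 allele strings.
#' @param tumor1,normal1 per-site unique read counts of allele 1.
#' @param tumor2,normal2 per-site unique read counts of allele 2.
#' @param site_id optional site labels.
#' @return a `loh_input`.
#' @export
loh_input <- function(gene, allele1, allele2, tumor1, normal1, tumor2,
                      normal2, site_id = NULL) {
  n <- length(tumor1)
  assert_that(all(lengths(list(normal1, tumor2, normal2)) == n),
              "allele count vectors must share one site list")
  assert_that(all(c(tumor1, normal1, tumor2, normal2) >= 0),
              "read counts must be non-negative")
  structure(list(gene = gene, allele1 = allele1, allele2 = allele2,
                 tumor1 = tumor1, normal1 = normal1,
                 tumor2 = tumor2, normal2 = normal2,
                 site_id = site_id %||% paste0("s", seq_len(n))),
            class = "loh_input")
}

#' Test an HLA gene for loss of heterozygosity
#'
#' Per shared polymorphic site s and allele a the coverage log-ratio
#' `r(a, s) = log2(tumor_unique(a, s) / normal_unique(a, s))` is formed;
#' allelic imbalance is assessed by a two-sided paired t-test of
#' `r(allele1, .)` against `r(allele2, .)`. LOH is reported when
#' `p < alpha` (default 0.0002); the lost allele is the one with the
#' smaller mean log-ratio. Sites with a zero count are dropped (or, with
#' `cfg$loh_pseudocount`, continuity-corrected by +0.5); at least 2 usable
#' sites are required. A homozygous gene yields a `not_applicable` result.
#'
#' @param input a [loh_input()].
#' @param cfg a [truneo_config()] (uses `loh_alpha`, `loh_pseudocount`).
#' @return list with `gene`, `p_value`, `loh`, `lost_allele`,
#'   `mean_diff` (mean r1 - r2), `n_sites`, `status`
#'   (`"ok"`/`"not_applicable"`) and `degenerate` flag (zero-variance
#'   differences).
#' @export
loh_test <- function(input, cfg = truneo_config()) {
  assert_that(inherits(input, "loh_input"), "input must be a loh_input")
  if (input$allele1 == input$allele2) {
    return(list(gene = input$gene, p_value = NA_real_, loh = FALSE,
                lost_allele = NA_character_, mean_diff = NA_real_,
                n_sites = 0L, status = "not_applicable",
                degenerate = FALSE))
  }
  t1 <- input$tumor1; n1 <- input$normal1
  t2 <- input$tumor2; n2 <- input$normal2
  if (cfg$loh_pseudocount) {
    t1 <- t1 + 0.5; n1 <- n1 + 0.5; t2 <- t2 + 0.5; n2 <- n2 + 0.5
    keep <- rep(TRUE, length(t1))
  } else {
    keep <- t1 > 0 & n1 > 0 & t2 > 0 & n2 > 0
  }
  assert_that(sum(keep) >= 2, "fewer than 2 usable LOH sites for gene %s",
              input$gene, class = "truneo_insufficient_data")
  r1 <- log2(t1[keep] / n1[keep])
  r2 <- log2(t2[keep] / n2[keep])
  d <- r1 - r2
  n <- length(d)
  degenerate <- FALSE
  if (all(abs(d - d[1]) < 1e-12)) {
    # zero-variance differences: identical ratios -> no evidence (p = 1);
    # constant non-zero shift -> infinitely strong evidence (p = 0)
    degenerate <- TRUE
    p <- if (abs(d[1]) < 1e-12) 1 else 0
    if (p == 0) warning("zero-variance non-zero LOH differences for gene ",
                        input$gene)
  } else {
    tstat <- mean(d) * sqrt(n) / stats::sd(d)
    p <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  }
  loh <- p < cfg$loh_alpha
  lost <- if (loh) {
    if (mean(r1) < mean(r2)) input$allele1 else input$allele2
  } else NA_character_
  list(gene = input$gene, p_value = p, loh = loh, lost_allele = lost,
       mean_diff = mean(d), n_sites = n, status = "ok",
       degenerate = degenerate)
}

#' Run the LOH test over all genes of a patient
#' @param inputs list of [loh_input()] objects.
#' @param cfg a [truneo_config()].
#' @return data.frame (gene, p_value, loh, lost_allele, n_sites, status).
#' @export
loh_test_all <- function(inputs, cfg = truneo_config()) {
  rows <- lapply(inputs, function(inp) {
    r <- loh_test(inp, cfg)
    data.frame(gene = r$gene, p_value = r$p_value, loh = r$loh,
               lost_allele = r$lost_allele, n_sites = r$n_sites,
               status = r$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
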