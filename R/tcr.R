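# TCR clonotype-expansion analysis.
#
# A clone is called expanded in a peptide-stimulated culture when (1) it
# is significantly enriched vs the unstimulated control (one-sided
# Fisher's exact test, Benjamini-Hochberg FDR q < 0.05, family = clones of
# that culture), (2) it is not significant in any other peptide culture,
# and (3) its odds ratio exceeds 1.

#' Call antigen-specific expanded TCR clones
#'
#' @param cultures named list of per-culture data.frames (`cdr3`, `count`,
#'   `total`), one per stimulating peptide.
#' @param control unstimulated-culture data.frame (`cdr3`, `count`,
#'   `total`); clones absent from the control are treated as count 0.
#' @param alpha FDR cutoff (default 0.05).
#' @return named list of data.frames, one per culture, with columns
#'   `cdr3`, `count_pre`, `count_post`, `p`, `q`, `odds_ratio`,
#'   `expanded`.
#' @export
call_expanded_clones <- function(cultures, control, alpha = 0.05) {
  assert_that(length(cultures) > 0, "no cultures supplied")
  total_pre <- control$total[1] %||% sum(control$count)
  per_culture <- lapply(cultures, function(cu) {
    total_post <- cu$total[1]
    pre <- control$count[match(cu$cdr3, control$cdr3)]
    pre[is.na(pre)] <- 0L
    stats_ <- lapply(seq_len(nrow(cu)), function(i) {
      fisher_exact_one_sided(pre[i], total_pre, cu$count[i], total_post)
    })
    out <- data.frame(
      cdr3 = cu$cdr3, count_pre = pre, count_post = cu$count,
      p = vapply(stats_, `[[`, numeric(1), "p"),
      odds_ratio = vapply(stats_, `[[`, numeric(1), "odds_ratio"),
      stringsAsFactors = FALSE
    )
    out$q <- benjamini_hochberg(out$p)
    out
  })
  # criterion (2): significance in any other culture disqualifies
  sig_sets <- lapply(per_culture, function(df) df$cdr3[df$q < alpha])
  out <- lapply(names(per_culture), function(nm) {
    df <- per_culture[[nm]]
    other_sig <- unique(unlist(sig_sets[setdiff(names(per_culture), nm)]))
    df$expanded <- df$q < alpha & df$odds_ratio > 1 &
      !(df$cdr3 %in% other_sig)
    df
  })
  names(out) <- names(per_culture)
  out
}
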