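# Predictor adapter contract.
#
# The pipeline consumes one PredictorScores row per (peptide, allele):
# binding affinity (IC50, nM), C-terminal cleavage propensity, TAP
# transport propensity, and a learned-presentation score with its
# identified flag. External binaries (NetMHCpan/netChop/netCTLpan-style)
# plug in behind this contract; the shipped backends are a deterministic
# mock and a fixture table, which is all the tests use.

PREDICTOR_COLS <- c("peptide", "allele", "affinity_nM", "cleavage", "tap",
                    "dl_score", "dl_identified")

#' Deterministic mock epitope predictor
#'
#' Hash-seeded scores: a pure function of (peptide, allele, seed). An
#' optional fixture table overrides individual (peptide, allele) pairs,
#' which is how generated bundles inject designed scores.
#'
#' @param peptides,alleles character vectors (recycled to common length).
#' @param seed integer; part of the hash, so different seeds give
#'   independent score sets.
#' @param fixture optional data.frame with columns `peptide`, `allele`,
#'   `affinity_nM`, `cleavage`, `tap`, `dl_score` (and optionally
#'   `dl_identified`).
#' @param cfg a [truneo_config()] (uses `dl_cutoff`).
#' @return data.frame with columns `peptide`, `allele`, `affinity_nM`
#'   (log-uniform 10-10000 nM), `cleavage` in (0,1), `tap` in (-3,3),
#'   `dl_score` in (0,1), `dl_identified`.
#' @export
mock_predict <- function(peptides, alleles, seed = 1L, fixture = NULL,
                         cfg = truneo_config()) {
  n <- max(length(peptides), length(alleles))
  peptides <- rep_len(peptides, n); alleles <- rep_len(alleles, n)
  key <- paste(peptides, alleles, sep = "/")
  # hash peptides and alleles once each (few unique alleles), then mix
  up <- unique(peptides); ua <- unique(alleles)
  hp <- hash_from_codes(hash_codes(up), 11L)[match(peptides, up)]
  ha <- hash_from_codes(hash_codes(ua), 29L)[match(alleles, ua)]
  mod <- 2147483629
  h <- (hp * 69069 + ha) %% mod
  mix <- function(salt) {
    x <- (h + salt * 7919 + (seed %% 1024L) * 104729) %% mod
    x <- (x * 48271 + salt) %% 2147483647
    x <- (x * 69621) %% 2147483647
    (x + 0.5) / 2147483647
  }
  u1 <- mix(11L); u2 <- mix(23L); u3 <- mix(37L); u4 <- mix(53L)
  out <- data.frame(
    peptide = peptides, allele = alleles,
    affinity_nM = 10^(1 + 3 * u1),
    cleavage = u2,
    tap = 6 * u3 - 3,
    dl_score = u4,
    stringsAsFactors = FALSE
  )
  if (!is.null(fixture) && nrow(fixture) > 0) {
    idx <- match(key, paste(fixture$peptide, fixture$allele, sep = "/"))
    hit <- !is.na(idx)
    for (col in c("affinity_nM", "cleavage", "tap", "dl_score")) {
      if (col %in% names(fixture)) out[[col]][hit] <- fixture[[col]][idx[hit]]
    }
  }
  out$dl_identified <- out$dl_score > cfg$dl_cutoff
  if (!is.null(fixture) && "dl_identified" %in% names(fixture)) {
    idx <- match(key, paste(fixture$peptide, fixture$allele, sep = "/"))
    hit <- !is.na(idx)
    out$dl_identified[hit] <- as.logical(fixture$dl_identified[idx[hit]])
  }
  out
}

#' Read a predictor fixture table
#' @param path TSV with columns `peptide`, `allele`, `affinity_nM`,
#'   `cleavage`, `tap`, `dl_score` (optionally `dl_identified`, `dl_rank`).
#' @return data.frame.
#' @export
read_predictor_fixture <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Within-patient presentation rank
#'
#' Ranks candidates by descending learned-presentation score (1-based;
#' ties broken by lexicographic peptide) over the patient's candidate set.
#'
#' @param scores a predictor score table with `peptide` and `dl_score`.
#' @return integer vector of ranks aligned with `scores` rows.
#' @export
dl_rank_within_patient <- function(scores) {
  o <- order(-scores$dl_score, scores$peptide)
  rank <- integer(nrow(scores))
  rank[o] <- seq_len(nrow(scores))
  rank
}
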