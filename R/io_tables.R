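# Readers/writers for the flat-table inputs: expression, RNA mutant reads,
# proteome FASTA, HLA genotype calls, LOH site counts, rank lists, Elispot
# outcomes and clonotype counts.

#' Read a gene expression table
#'
#' @param path two-column TSV with header (`gene_id`, `tpm`).
#' @return named numeric vector of TPM values, names = gene ids.
#' @export
read_expression <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "expression table needs 2 columns",
              class = "truneo_parse_error")
  gene <- as.character(df[[1]])
  tpm <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(tpm))
  if (length(bad)) {
    stop_truneo("malformed TPM at line %d of %s", bad[1] + 1L, path,
                class = "truneo_parse_error")
  }
  assert_that(!anyDuplicated(gene), "duplicate gene_id in %s", path,
              class = "truneo_validation_error")
  assert_that(all(tpm >= 0), "negative TPM in %s", path,
              class = "truneo_validation_error")
  setNames(tpm, gene)
}

#' Read per-variant RNA mutant-read counts
#' @param path two-column TSV (`variant_id`, `mut_reads`) with header.
#' @return named integer vector.
#' @export
read_rna_mut_reads <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  counts <- suppressWarnings(as.integer(df[[2]]))
  assert_that(!anyNA(counts) || nrow(df) == 0,
              "malformed mut_reads in %s", path, class = "truneo_parse_error")
  assert_that(all(counts >= 0), "negative read count in %s", path,
              class = "truneo_validation_error")
  setNames(counts, as.character(df[[1]]))
}

#' Read a protein FASTA into a named character vector
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector (20-letter alphabet plus `*`).
#' @export
read_proteome <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  out <- setNames(as.character(aa), names(aa))
  assert_that(all(is_aa_string(out, allow_stop = TRUE)),
              "non amino-acid characters in %s", path,
              class = "truneo_validation_error")
  out
}

#' Write peptide candidates as FASTA
#'
#' Headers are `variant_id|allele|offsets` with mutant offsets
#' comma-separated and 1-based.
#'
#' @param candidates candidate table from [enumerate_candidates()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(candidates, path) {
  hdr <- paste(candidates$variant_id, candidates$allele,
               vapply(candidates$mutant_offsets, paste, character(1),
                      collapse = ","), sep = "|")
  seqs <- Biostrings::AAStringSet(setNames(candidates$sequence, hdr))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read HLA genotype calls of two callers in two samples
#'
#' @param path 4-column TSV (`caller`, `sample`, `gene`, `allele`) with
#'   header; callers `poly`/`bwa`, samples `tumor`/`normal`, 2 alleles per
#'   gene per (caller, sample).
#' @return an `hla_call_set` (see [hla_call_set()]).
#' @export
read_hla_calls <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  get <- function(caller, sample) {
    sub <- df[df$caller == caller & df$sample == sample, ]
    sub <- sub[order(sub$gene, sub$allele), ]
    sub$allele
  }
  hla_call_set(poly_tumor = get("poly", "tumor"),
               poly_normal = get("poly", "normal"),
               bwa_tumor = get("bwa", "tumor"),
               bwa_normal = get("bwa", "normal"))
}

#' Read LOH input site counts
#'
#' @param path TSV (`gene`, `allele`, `site_id`, `tumor_unique`,
#'   `normal_unique`) with header.
#' @return list of per-gene LOH inputs (see [loh_input()]).
#' @export
read_loh_inputs <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$gene), function(g) {
    alleles <- unique(g$allele)
    assert_that(length(alleles) %in% c(1, 2),
                "gene %s has %d alleles in LOH table", g$gene[1],
                length(alleles))
    if (length(alleles) == 1) alleles <- rep(alleles, 2)
    a1 <- g[g$allele == alleles[1], ]
    a2 <- g[g$allele == alleles[2], ]
    sites <- intersect(a1$site_id, a2$site_id)
    loh_input(gene = g$gene[1], allele1 = alleles[1], allele2 = alleles[2],
              tumor1 = a1$tumor_unique[match(sites, a1$site_id)],
              normal1 = a1$normal_unique[match(sites, a1$site_id)],
              tumor2 = a2$tumor_unique[match(sites, a2$site_id)],
              normal2 = a2$normal_unique[match(sites, a2$site_id)],
              site_id = sites)
  })
}

#' Read a per-epitope rank list for cohort evaluation
#'
#' Layout mirrors a published per-epitope rank table: one row per
#' (patient, method, candidate), with the method-assigned rank and an
#' immunogenicity label (1/0/NA).
#'
#' @param path TSV with columns `patient_id`, `method`, `rank`,
#'   `candidate_id`, `immunogenic` and optional `tpm`.
#' @return data.frame.
#' @export
read_rank_list <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "method", "rank", "candidate_id", "immunogenic")
  assert_that(all(need %in% names(df)), "missing columns: %s",
              paste(setdiff(need, names(df)), collapse = ", "),
              class = "truneo_parse_error")
  df$rank <- as.integer(df$rank)
  df$immunogenic <- as.integer(df$immunogenic)
  df
}

#' Read Elispot validation outcomes
#' @param path TSV with columns `method`, `rank`, `peptide`, `elispot`
#'   (`true`/`false`).
#' @return data.frame with logical `elispot`.
#' @export
read_elispot <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$elispot <- tolower(as.character(df$elispot)) %in% c("true", "1", "yes")
  df
}

#' Read TCR clonotype count tables
#' @param path TSV with columns `culture`, `cdr3`, `count`, `total`.
#' @return named list of data.frames, one per culture.
#' @export
read_clonotypes <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$count <- as.integer(df$count); df$total <- as.integer(df$total)
  assert_that(all(df$count >= 0) && all(df$count <= df$total),
              "clonotype counts must satisfy 0 <= count <= total",
              class = "truneo_validation_error")
  split(df[c("cdr3", "count", "total")], df$culture)
}
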