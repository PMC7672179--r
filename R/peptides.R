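# Mutant peptide enumeration.
#
# A protein context is the mutant sequence window surrounding the altered
# residues (21-mer centred on a missense substitution when flanks suffice),
# plus the indices of the mutant residues. Candidates are all 8-11-mer
# windows of the context containing at least one mutant residue, crossed
# with the patient's distinct HLA alleles.

protein_context <- function(variant_id, wt_context, mut_context,
                            mutant_positions, neoorf = FALSE,
                            junction = NA_integer_) {
  structure(list(variant_id = variant_id, wt_context = wt_context,
                 mut_context = mut_context,
                 mutant_positions = as.integer(mutant_positions),
                 neoorf = neoorf, junction = as.integer(junction)),
            class = "protein_context")
}

empty_context <- function(variant_id) {
  protein_context(variant_id, "", "", integer(0))
}

parse_protein_change <- function(pc) {
  m <- regmatches(pc, regexec("^p\\.([A-Y\\*])(\\d+)([A-Y\\*])$", pc))[[1]]
  assert_that(length(m) == 4, "cannot parse protein change '%s'", pc,
              class = "truneo_parse_error")
  list(ref = m[2], pos = as.integer(m[3]), alt = m[4])
}

#' Build the mutant protein context of a variant
#'
#' Missense: a window of up to 10 residues each side of the substituted
#' residue (a 21-mer when flanks suffice, truncated at the protein ends).
#' Frameshift: the 10 wild-type residues upstream of the first altered
#' position followed by the full novel tail translated to the first stop
#' (candidates from the tail are neoORF-derived, no wild-type counterpart).
#' In-frame indel: 10 residues each side of the altered segment. Fusion:
#' 10 residues each side of the junction; only junction-spanning windows
#' count as mutant.
#'
#' @param v one-row `truneo_variants` record with consequence in
#'   missense/frameshift/inframe_indel/fusion. Missense uses
#'   `protein_change` (HGVS p. single substitution) or `aa_pos`;
#'   frameshift uses `aa_pos` + `novel_tail`; in-frame indels use
#'   `aa_pos` + `ins_seq`/`del_len`; fusions use `junction_seq` +
#'   `junction_pos`.
#' @param transcript_protein wild-type protein sequence of the transcript
#'   (not needed for fusions).
#' @param flank residues kept each side of the altered position (10).
#' @return a `protein_context`; empty when a frameshift stops immediately.
#' @export
build_context <- function(v, transcript_protein = NULL, flank = 10) {
  v <- as.data.frame(v)
  assert_that(nrow(v) == 1, "build_context takes one variant")
  cons <- v$consequence
  assert_that(cons %in% c("missense", "frameshift", "inframe_indel",
                          "fusion"),
              "no peptide context for consequence '%s'", cons,
              class = "truneo_contract_error")
  id <- v$variant_id
  if (cons == "fusion") {
    assert_that(!is.na(v$junction_seq) && !is.na(v$junction_pos),
                "fusion variant %s needs junction_seq and junction_pos", id)
    js <- v$junction_seq; b <- v$junction_pos
    lo <- max(1, b - flank + 1); hi <- min(nchar(js), b + flank)
    mut <- substr(js, lo, hi)
    bb <- b - lo + 1  # junction index inside the window
    return(protein_context(id, NA_character_, mut,
                           mutant_positions = c(bb, bb + 1),
                           neoorf = TRUE, junction = bb))
  }
  prot <- transcript_protein
  assert_that(is.character(prot) && nchar(prot) > 0,
              "transcript protein required for %s", id)
  if (cons == "missense") {
    assert_that(!is.na(v$protein_change),
                "missense variant %s needs protein_change", id)
    ch <- parse_protein_change(v$protein_change)
    pos <- ch$pos; alt_aa <- ch$alt
    assert_that(pos <= nchar(prot), "aa position %d beyond protein", pos)
    ref_aa <- substr(prot, pos, pos)
    assert_that(ref_aa == ch$ref,
                "protein_change %s does not match protein (found %s)",
                v$protein_change, ref_aa)
    lo <- max(1, pos - flank); hi <- min(nchar(prot), pos + flank)
    wt <- substr(prot, lo, hi)
    mut <- wt
    substr(mut, pos - lo + 1, pos - lo + 1) <- alt_aa
    return(protein_context(id, wt, mut, mutant_positions = pos - lo + 1))
  }
  if (cons == "frameshift") {
    pos <- v$aa_pos
    assert_that(!is.na(pos) && !is.na(v$novel_tail),
                "frameshift variant %s needs aa_pos and novel_tail", id)
    tail_aa <- sub("\\*.*$", "", v$novel_tail)
    if (nchar(tail_aa) == 0) return(empty_context(id))
    lo <- max(1, pos - flank)
    up <- substr(prot, lo, pos - 1)
    mut <- paste0(up, tail_aa)
    return(protein_context(id, NA_character_, mut,
                           mutant_positions =
                             nchar(up) + seq_len(nchar(tail_aa)),
                           neoorf = TRUE))
  }
  # in-frame indel: replace del_len residues at aa_pos by ins_seq
  pos <- v$aa_pos
  del_len <- if (is.na(v$del_len)) 0L else v$del_len
  ins <- if (is.na(v$ins_seq)) "" else v$ins_seq
  assert_that(!is.na(pos), "inframe_indel %s needs aa_pos", id)
  lo <- max(1, pos - flank)
  hi <- min(nchar(prot), pos + del_len - 1 + flank)
  left <- substr(prot, lo, pos - 1)
  right <- substr(prot, pos + del_len, hi)
  mut <- paste0(left, ins, right)
  if (nchar(ins) > 0) {
    mpos <- nchar(left) + seq_len(nchar(ins))
  } else {
    # pure deletion: mark the junction residue
    mpos <- min(nchar(left) + 1L, nchar(mut))
  }
  if (nchar(mut) == 0) return(empty_context(id))
  protein_context(id, NA_character_, mut, mutant_positions = mpos,
                  neoorf = FALSE)
}

#' Enumerate 8-11-mer mutant peptide candidates
#'
#' All 8-11-mer windows of the mutant context containing at least one
#' mutant residue (and spanning the junction, for fusion contexts), crossed
#' with each distinct HLA allele; duplicate (sequence, allele) pairs from
#' one variant are collapsed. Substitution-derived candidates carry the
#' same-coordinate wild-type window; neoORF-derived candidates have no
#' wild-type counterpart.
#'
#' @param ctx a `protein_context` from [build_context()].
#' @param alleles character vector of HLA alleles (duplicates dropped).
#' @param lengths peptide lengths to scan (default 8:11).
#' @return data.frame with columns `variant_id`, `sequence`, `allele`,
#'   `wt_sequence`, `neoorf`, and list-column `mutant_offsets` (1-based
#'   positions of mutant residues within the peptide).
#' @export
enumerate_candidates <- function(ctx, alleles, lengths = 8:11) {
  assert_that(inherits(ctx, "protein_context"), "ctx must be a context")
  alleles <- unique(alleles)
  L <- nchar(ctx$mut_context)
  if (L == 0 || length(ctx$mutant_positions) == 0) {
    return(candidate_frame_empty())
  }
  rows <- list()
  has_wt <- !is.na(ctx$wt_context) && !ctx$neoorf &&
    nchar(ctx$wt_context) == L
  for (k in lengths) {
    if (k > L) next
    starts <- seq_len(L - k + 1)
    for (s in starts) {
      off <- ctx$mutant_positions - s + 1L
      off <- off[off >= 1 & off <= k]
      if (length(off) == 0) next
      if (!is.na(ctx$junction)) {
        # fusion: the window must span the junction bond
        if (!(s <= ctx$junction && s + k - 1 >= ctx$junction + 1)) next
      }
      rows[[length(rows) + 1]] <- list(
        sequence = substr(ctx$mut_context, s, s + k - 1),
        wt_sequence = if (has_wt) substr(ctx$wt_context, s, s + k - 1)
                      else NA_character_,
        offsets = off
      )
    }
  }
  if (length(rows) == 0) return(candidate_frame_empty())
  seqs <- vapply(rows, `[[`, character(1), "sequence")
  keep <- !duplicated(seqs)
  rows <- rows[keep]; seqs <- seqs[keep]
  n <- length(rows); a <- length(alleles)
  out <- data.frame(
    variant_id = rep(ctx$variant_id, n * a),
    sequence = rep(seqs, times = a),
    allele = rep(alleles, each = n),
    wt_sequence = rep(vapply(rows, `[[`, character(1), "wt_sequence"),
                      times = a),
    neoorf = rep(ctx$neoorf || is.na(ctx$wt_context), n * a),
    stringsAsFactors = FALSE
  )
  out$mutant_offsets <- rep(lapply(rows, `[[`, "offsets"), times = a)
  out
}

candidate_frame_empty <- function() {
  out <- data.frame(variant_id = character(0), sequence = character(0),
                    allele = character(0), wt_sequence = character(0),
                    neoorf = logical(0), stringsAsFactors = FALSE)
  out$mutant_offsets <- list()
  out
}

#' Candidate-level filters
#'
#' A candidate survives when (1) its source mutation is expressed
#' (RNA mutant reads >= 1), (2) the mutant peptide is not an exact
#' substring of any reference proteome entry (self-homology), and (3) its
#' predicted IC50 is not above 500 nM (exactly 500 is kept).
#'
#' @param candidate one row of an [enumerate_candidates()] table (or any
#'   list with a `sequence` field).
#' @param rna_mut_reads RNA mutant-read count of the source variant.
#' @param proteome named character vector of reference protein sequences.
#' @param affinity_nM predicted IC50 in nM (required).
#' @param cfg a [truneo_config()].
#' @return named logical vector `c(expressed, not_self, affinity, overall)`.
#' @export
candidate_filters <- function(candidate, rna_mut_reads, proteome,
                              affinity_nM, cfg = truneo_config()) {
  assert_that(length(affinity_nM) == 1 && is.finite(affinity_nM),
              "affinity_nM is required", class = "truneo_contract_error")
  seqs <- if (is.data.frame(candidate)) candidate$sequence
          else candidate[["sequence"]]
  expressed <- rna_mut_reads >= cfg$min_rna_mut_reads
  not_self <- !is_self_peptide(seqs, proteome)
  affinity <- affinity_nM <= cfg$affinity_filter_nM
  c(expressed = expressed, not_self = not_self, affinity = affinity,
    overall = expressed && not_self && affinity)
}

# Exact substring match of peptides against the proteome; vectorized over
# peptides (proteome concatenated with a separator absent from peptides).
is_self_peptide <- function(peptides, proteome) {
  if (length(proteome) == 0) return(rep(FALSE, length(peptides)))
  haystack <- paste(proteome, collapse = "!")
  vapply(peptides, function(p) grepl(p, haystack, fixed = TRUE),
         logical(1), USE.NAMES = FALSE)
}

#' Does a substitution hit an MHC anchor position?
#'
#' Anchor positions are fixed at P2 and the C-terminal residue (the
#' canonical class-I anchors) for all alleles.
#'
#' @param candidate a candidate row with `sequence`, `mutant_offsets` and
#'   `wt_sequence` (must be substitution-derived, i.e. not neoORF).
#' @return `TRUE` when any mutant offset is position 2 or the last
#'   position of the peptide.
#' @export
detect_anchor_change <- function(candidate) {
  wt <- if (is.data.frame(candidate)) candidate$wt_sequence
        else candidate[["wt_sequence"]]
  assert_that(!is.null(wt) && !is.na(wt),
              "anchor detection applies to substitution-derived candidates",
              class = "truneo_contract_error")
  seq <- if (is.data.frame(candidate)) candidate$sequence
         else candidate[["sequence"]]
  off <- if (is.data.frame(candidate)) candidate$mutant_offsets[[1]]
         else candidate[["mutant_offsets"]]
  any(off == 2L | off == nchar(seq))
}
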