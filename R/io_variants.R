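# Variant table I/O.
#
# Variants travel as a data.frame (class "truneo_variants") with one row per
# variant and list-columns for the per-read metric vectors, so no BAM access
# is ever needed downstream. Identity key is (chrom, pos, ref, alt),
# positions 1-based VCF-style.

VECTOR_COLS <- c("mq_mut", "mq_ref", "bq_mut", "bq_ref",
                 "dend_mut", "dend_ref")

#' Construct a somatic variant record
#'
#' @param chrom chromosome name.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt reference / alternate allele strings.
#' @param vtype one of `"SNV"`, `"insertion"`, `"deletion"`, `"fusion"`;
#'   inferred from ref/alt lengths when `NULL`.
#' @param depth_tumor,depth_normal read depth at the position.
#' @param vaf_tumor,vaf_normal variant allele fraction in `[0, 1]`.
#' @param mq_mut,mq_ref per-read mapping qualities of mutant- and
#'   reference-supporting reads.
#' @param bq_mut,bq_ref per-read base qualities at the variant base.
#' @param dend_mut,dend_ref per-read distance to the nearer read end (bp).
#' @param gene gene symbol.
#' @param protein_change HGVS p. style single substitution (e.g. `"p.A50V"`)
#'   for missense variants; free text otherwise.
#' @param consequence one of `"missense"`, `"frameshift"`,
#'   `"inframe_indel"`, `"silent"`, `"fusion"`, `"other"`.
#' @param variant_id identifier; defaults to `chrom:pos:ref:alt`.
#' @param aa_pos 1-based amino-acid position of the first altered residue.
#' @param novel_tail frameshift-only: translated novel C-terminal peptide
#'   (up to and excluding the stop `*`).
#' @param ins_seq,del_len in-frame indel payload (inserted residues /
#'   number of deleted residues).
#' @param junction_seq,junction_pos fusion-only: protein-space junction
#'   sequence and the index of its last 5'-partner residue.
#' @return one-row `truneo_variants` data.frame.
#' @export
variant_record <- function(chrom, pos, ref, alt, vtype = NULL,
                           depth_tumor = NA_integer_,
                           depth_normal = NA_integer_,
                           vaf_tumor = NA_real_, vaf_normal = NA_real_,
                           mq_mut = numeric(0), mq_ref = numeric(0),
                           bq_mut = numeric(0), bq_ref = numeric(0),
                           dend_mut = numeric(0), dend_ref = numeric(0),
                           gene = NA_character_,
                           protein_change = NA_character_,
                           consequence = "other",
                           variant_id = NULL,
                           aa_pos = NA_integer_,
                           novel_tail = NA_character_,
                           ins_seq = NA_character_, del_len = NA_integer_,
                           junction_seq = NA_character_,
                           junction_pos = NA_integer_) {
  if (is.null(vtype)) {
    vtype <- if (nchar(ref) == nchar(alt)) "SNV"
             else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
  }
  assert_that(vtype %in% VTYPE_LEVELS, "unknown vtype '%s'", vtype)
  assert_that(consequence %in% CONSEQUENCE_LEVELS,
              "unknown consequence '%s'", consequence)
  for (v in list(vaf_tumor, vaf_normal)) {
    assert_that(is.na(v) || (v >= 0 && v <= 1),
                "VAF outside [0,1]: %s", format(v))
  }
  df <- data.frame(
    variant_id = variant_id %||% paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    vtype = vtype, depth_tumor = as.integer(depth_tumor),
    depth_normal = as.integer(depth_normal),
    vaf_tumor = vaf_tumor, vaf_normal = vaf_normal,
    gene = gene, protein_change = protein_change,
    consequence = consequence, aa_pos = as.integer(aa_pos),
    novel_tail = novel_tail, ins_seq = ins_seq,
    del_len = as.integer(del_len),
    junction_seq = junction_seq, junction_pos = as.integer(junction_pos),
    stringsAsFactors = FALSE
  )
  df$mq_mut <- list(as.numeric(mq_mut)); df$mq_ref <- list(as.numeric(mq_ref))
  df$bq_mut <- list(as.numeric(bq_mut)); df$bq_ref <- list(as.numeric(bq_ref))
  df$dend_mut <- list(as.numeric(dend_mut))
  df$dend_ref <- list(as.numeric(dend_ref))
  class(df) <- c("truneo_variants", "data.frame")
  df
}

#' Bind variant records into one table
#' @param ... `truneo_variants` rows or a list of them.
#' @return `truneo_variants` data.frame.
#' @export
bind_variants <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) parts <- parts[[1]]
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("truneo_variants", "data.frame")
  out
}

parse_vector_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

fmt_vector_field <- function(v) {
  vapply(v, function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                              collapse = ","), character(1))
}

normalize_consequence <- function(x) {
  map <- c(missense = "missense", missense_variant = "missense",
           frameshift = "frameshift", frameshift_variant = "frameshift",
           inframe_indel = "inframe_indel",
           inframe_insertion = "inframe_indel",
           inframe_deletion = "inframe_indel",
           silent = "silent", synonymous_variant = "silent",
           fusion = "fusion", gene_fusion = "fusion", other = "other")
  out <- unname(map[tolower(x)])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_truneo("unknown consequence string '%s' (row %d)",
                x[bad[1]], bad[1], class = "truneo_validation_error")
  }
  out[is.na(x)] <- "other"
  out
}

#' Read an annotated somatic variant table
#'
#' Two dialects are supported: a flat TSV with the documented column names,
#' and VCF 4.x with `DP_T/DP_N/VAF_T/VAF_N` and the per-read metric vectors
#' `MQ_MUT/MQ_REF/BQ_MUT/BQ_REF/DEND_MUT/DEND_REF` as comma-delimited INFO
#' fields plus `ANN=consequence|gene|protein_change`. VCF parsing uses
#' VariantAnnotation.
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @return a `truneo_variants` data.frame, one row per variant/ALT.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: %s", path)
  if (dialect == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

read_variants_tsv <- function(path) {
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_truneo("cannot parse %s: %s", path,
                                    conditionMessage(e),
                                    class = "truneo_parse_error"))
  need <- c("chrom", "pos", "ref", "alt")
  assert_that(all(need %in% names(df)),
              "missing columns: %s",
              paste(setdiff(need, names(df)), collapse = ", "),
              class = "truneo_parse_error")
  n <- nrow(df)
  get_num <- function(nm, default = NA_real_) {
    if (!nm %in% names(df)) return(rep(default, n))
    out <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(!is.na(df[[nm]]) & nzchar(df[[nm]]) & is.na(out))
    if (length(bad)) {
      stop_truneo("malformed numeric field '%s' at line %d of %s",
                  nm, bad[1] + 1L, path, class = "truneo_parse_error")
    }
    out
  }
  get_chr <- function(nm) {
    if (nm %in% names(df)) df[[nm]] else rep(NA_character_, n)
  }
  out <- data.frame(
    variant_id = if ("variant_id" %in% names(df)) df$variant_id else
      paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"),
    chrom = df$chrom, pos = as.integer(get_num("pos")),
    ref = df$ref, alt = df$alt,
    vtype = if ("vtype" %in% names(df)) df$vtype else
      ifelse(nchar(df$ref) == nchar(df$alt), "SNV",
             ifelse(nchar(df$alt) > nchar(df$ref), "insertion", "deletion")),
    depth_tumor = as.integer(get_num("depth_tumor")),
    depth_normal = as.integer(get_num("depth_normal")),
    vaf_tumor = get_num("vaf_tumor"), vaf_normal = get_num("vaf_normal"),
    gene = get_chr("gene"), protein_change = get_chr("protein_change"),
    consequence = normalize_consequence(get_chr("consequence")),
    aa_pos = as.integer(get_num("aa_pos")),
    novel_tail = get_chr("novel_tail"), ins_seq = get_chr("ins_seq"),
    del_len = as.integer(get_num("del_len")),
    junction_seq = get_chr("junction_seq"),
    junction_pos = as.integer(get_num("junction_pos")),
    stringsAsFactors = FALSE
  )
  for (vc in VECTOR_COLS) {
    out[[vc]] <- if (vc %in% names(df)) parse_vector_field(df[[vc]])
                 else rep(list(numeric(0)), n)
  }
  bad_vaf <- which(!is.na(out$vaf_tumor) &
                     (out$vaf_tumor < 0 | out$vaf_tumor > 1))
  bad_vaf <- c(bad_vaf, which(!is.na(out$vaf_normal) &
                                (out$vaf_normal < 0 | out$vaf_normal > 1)))
  if (length(bad_vaf)) {
    stop_truneo("VAF outside [0,1] at line %d of %s",
                min(bad_vaf) + 1L, path, class = "truneo_validation_error")
  }
  bad_vt <- which(!out$vtype %in% VTYPE_LEVELS)
  if (length(bad_vt)) {
    stop_truneo("unknown vtype '%s' at line %d", out$vtype[bad_vt[1]],
                bad_vt[1] + 1L, class = "truneo_validation_error")
  }
  class(out) <- c("truneo_variants", "data.frame")
  out
}

read_variants_vcf <- function(path) {
  assert_that(requireNamespace("VariantAnnotation", quietly = TRUE),
              "VariantAnnotation is required for dialect = 'vcf'")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  ref <- as.character(VariantAnnotation::ref(vcf))
  ann <- if ("ANN" %in% names(info)) {
    vapply(info$ANN, function(x)
      if (length(x)) as.character(x[[1]]) else NA_character_, character(1))
  } else rep(NA_character_, n)
  ann_parts <- strsplit(ifelse(is.na(ann), "||", ann), "|", fixed = TRUE)
  pick <- function(i) vapply(ann_parts, function(p)
    if (length(p) >= i && nzchar(p[i])) p[i] else NA_character_, character(1))
  num1 <- function(key, default = NA_real_) {
    if (!key %in% names(info)) return(rep(default, n))
    as.numeric(info[[key]])
  }
  vec_field <- function(key) {
    if (!key %in% names(info)) return(rep(list(numeric(0)), n))
    lapply(info[[key]], function(x) {
      if (length(x) == 1 && is.character(x)) {
        parse_vector_field(x)[[1]]
      } else as.numeric(unlist(x))
    })
  }
  out <- data.frame(
    variant_id = paste(as.character(GenomicRanges::seqnames(rr)),
                       GenomicRanges::start(rr), ref, alt, sep = ":"),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), ref = ref, alt = alt,
    vtype = ifelse(nchar(ref) == nchar(alt), "SNV",
                   ifelse(nchar(alt) > nchar(ref), "insertion", "deletion")),
    depth_tumor = as.integer(num1("DP_T")),
    depth_normal = as.integer(num1("DP_N")),
    vaf_tumor = num1("VAF_T"), vaf_normal = num1("VAF_N"),
    gene = pick(2), protein_change = pick(3),
    consequence = normalize_consequence(pick(1)),
    aa_pos = NA_integer_, novel_tail = NA_character_,
    ins_seq = NA_character_, del_len = NA_integer_,
    junction_seq = NA_character_, junction_pos = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$mq_mut <- vec_field("MQ_MUT"); out$mq_ref <- vec_field("MQ_REF")
  out$bq_mut <- vec_field("BQ_MUT"); out$bq_ref <- vec_field("BQ_REF")
  out$dend_mut <- vec_field("DEND_MUT"); out$dend_ref <- vec_field("DEND_REF")
  rownames(out) <- NULL
  class(out) <- c("truneo_variants", "data.frame")
  out
}

#' Write a variant table as TSV
#'
#' Inverse of `read_variants(dialect = "tsv")`: writing then reading
#' reproduces the table field-for-field.
#'
#' @param variants a `truneo_variants` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  df <- as.data.frame(variants)
  for (vc in VECTOR_COLS) df[[vc]] <- fmt_vector_field(df[[vc]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
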