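# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CONSEQUENCE_LEVELS <- c("missense", "frameshift", "inframe_indel",
                        "silent", "fusion", "other")

VTYPE_LEVELS <- c("SNV", "insertion", "deletion", "fusion")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half up to a fixed number of decimals
#'
#' Plain `round()` uses banker's rounding; reported percentages use
#' conventional half-up rounding (52.635 -> 52.64).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_aa_string <- function(x, allow_stop = FALSE) {
  alpha <- paste(AA_ALPHABET, collapse = "")
  if (allow_stop) alpha <- paste0(alpha, "*")
  grepl(sprintf("^[%s]+$", gsub("\\*", "\\\\*", alpha)), x)
}

# Deterministic polynomial rolling hash of strings, vectorized.
# hash_codes builds a padded character-code matrix once so several salted
# hashes can be derived from it cheaply. Used by the mock predictor only.
hash_codes <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), 0, 0))
  codes <- lapply(x, utf8ToInt)
  maxlen <- max(lengths(codes))
  t(vapply(codes, function(v) c(v, rep(7L, maxlen - length(v))),
           integer(maxlen)))
}

hash_from_codes <- function(mat, salt = 0L) {
  mod <- 2147483629  # prime < 2^31
  h <- rep((salt %% mod) + 1, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    h <- (h * 131 + mat[, j]) %% mod
  }
  h
}

hash_strings <- function(x, salt = 0L) hash_from_codes(hash_codes(x), salt)

# Uniform(0,1) deviates derived from string hashes; pure in (x, salt, seed).
hash_unif_from_codes <- function(mat, salt, seed) {
  h <- hash_from_codes(mat, salt = salt + 1000003L * (seed %% 1024L))
  # second mixing round to decorrelate consecutive salts
  h2 <- (h * 48271 + salt + seed) %% 2147483647
  (h2 + 0.5) / 2147483647
}

hash_unif <- function(x, salt, seed) {
  hash_unif_from_codes(hash_codes(x), salt, seed)
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_truneo <- function(fmt, ..., class = "truneo_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

assert_that <- function(ok, fmt, ..., class = "truneo_error") {
  if (!isTRUE(ok)) stop_truneo(fmt, ..., class = class)
  invisible(TRUE)
}

# One structured line per filter decision, so filter counts are auditable.
truneo_log <- function(variant_id, rule, verdict) {
  if (isTRUE(getOption("truneo.log", FALSE))) {
    message(sprintf("[truneo] variant=%s rule=%s verdict=%s",
                    variant_id, rule, verdict))
  }
  invisible(NULL)
}
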