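# Toy surrogate of the learned presentation model.
#
# Architecture: one-hot encoded 8-11-mer (padded to 11 positions x 20
# letters), two fully connected layers of 256 and 74 relu units, and a
# 74-wide embedding vector per HLA allele that gates the output through a
# dot product followed by a sigmoid. Trained with binary cross-entropy and
# plain minibatch gradient descent (Adam), 10% validation split, stopping
# when validation loss stops decreasing. This demonstrates the
# architecture at desk scale on synthetic data; it makes no claim of
# predictive accuracy for real pMHC presentation.

PEP_MAXLEN <- 11L

encode_peptides <- function(peptides) {
  assert_that(all(is_aa_string(peptides)),
              "peptides must use the 20-letter amino-acid alphabet")
  assert_that(all(nchar(peptides) >= 8 & nchar(peptides) <= PEP_MAXLEN),
              "peptides must be 8-11 residues")
  n <- length(peptides)
  X <- matrix(0, n, PEP_MAXLEN * 20L)
  for (i in seq_len(n)) {
    aa <- strsplit(peptides[i], "")[[1]]
    j <- match(aa, AA_ALPHABET)
    X[i, (seq_along(j) - 1L) * 20L + j] <- 1
  }
  X
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

init_surrogate <- function(alleles, h1 = 256L, h2 = 74L, seed = 1L) {
  with_seed(seed, {
    d <- PEP_MAXLEN * 20L
    list(
      W1 = matrix(rnorm(d * h1, sd = sqrt(2 / d)), d, h1),
      b1 = rep(0, h1),
      W2 = matrix(rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
      b2 = rep(0, h2),
      E = matrix(rnorm(length(alleles) * h2, sd = 0.1), length(alleles), h2,
                 dimnames = list(alleles, NULL)),
      b_out = 0
    )
  })
}

surrogate_forward <- function(model, X, allele_idx) {
  H1 <- relu(sweep(X %*% model$W1, 2, model$b1, `+`))
  H2 <- relu(sweep(H1 %*% model$W2, 2, model$b2, `+`))
  z <- rowSums(H2 * model$E[allele_idx, , drop = FALSE]) + model$b_out
  list(H1 = H1, H2 = H2, z = z, p = sigmoid(z))
}

#' Train the toy presentation surrogate
#'
#' @param positives,negatives data.frames (or lists) with `peptide` and
#'   `allele` columns; both non-empty, peptides 8-11-mers.
#' @param epochs maximum training epochs (default 60).
#' @param seed RNG seed (weights, shuffling, validation split).
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param patience early-stopping patience on validation loss (3).
#' @return a `surrogate_model` with weights, allele vocabulary and the
#'   per-epoch training history.
#' @export
train_surrogate <- function(positives, negatives, epochs = 60, seed = 1L,
                            lr = 5e-3, batch = 32L, patience = 3L) {
  positives <- as.data.frame(positives); negatives <- as.data.frame(negatives)
  assert_that(nrow(positives) > 0 && nrow(negatives) > 0,
              "both positive and negative examples are required")
  pep <- c(positives$peptide, negatives$peptide)
  all_ <- c(positives$allele, negatives$allele)
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))
  X <- encode_peptides(pep)
  alleles <- sort(unique(all_))
  ai <- match(all_, alleles)
  model <- init_surrogate(alleles, seed = seed)
  n <- length(y)
  with_seed(seed + 1L, {
    perm <- sample(n)
  })
  n_val <- max(1L, floor(0.1 * n))
  val <- perm[seq_len(n_val)]; tr <- perm[-seq_len(n_val)]
  adam <- list(); t_step <- 0
  best <- Inf; best_model <- model; bad <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  bce <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 100L + ep, sample(tr))
    for (s in seq(1, length(ord), by = batch)) {
      idx <- ord[s:min(s + batch - 1, length(ord))]
      fw <- surrogate_forward(model, X[idx, , drop = FALSE], ai[idx])
      m <- length(idx)
      dz <- (fw$p - y[idx]) / m                       # dL/dz
      Ei <- model$E[ai[idx], , drop = FALSE]
      dH2 <- (dz * Ei) * (fw$H2 > 0)
      dE_rows <- dz * fw$H2                           # per-example dL/dE
      dW2 <- t(fw$H1) %*% dH2
      db2 <- colSums(dH2)
      dH1 <- (dH2 %*% t(model$W2)) * (fw$H1 > 0)
      dW1 <- t(X[idx, , drop = FALSE]) %*% dH1
      db1 <- colSums(dH1)
      dE <- matrix(0, nrow(model$E), ncol(model$E))
      for (r in seq_len(m)) dE[ai[idx][r], ] <- dE[ai[idx][r], ] + dE_rows[r, ]
      grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, E = dE,
                    b_out = sum(dz))
      t_step <- t_step + 1
      for (nm in names(grads)) {
        g <- grads[[nm]]
        if (is.null(adam[[nm]])) adam[[nm]] <- list(m = g * 0, v = g * 0)
        adam[[nm]]$m <- 0.9 * adam[[nm]]$m + 0.1 * g
        adam[[nm]]$v <- 0.999 * adam[[nm]]$v + 0.001 * g^2
        mhat <- adam[[nm]]$m / (1 - 0.9^t_step)
        vhat <- adam[[nm]]$v / (1 - 0.999^t_step)
        model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    tl <- bce(surrogate_forward(model, X[tr, , drop = FALSE], ai[tr])$p, y[tr])
    vl <- bce(surrogate_forward(model, X[val, , drop = FALSE], ai[val])$p,
              y[val])
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl,
                                         val_loss = vl))
    if (vl < best - 1e-6) {
      best <- vl; best_model <- model; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  structure(list(weights = best_model, alleles = alleles,
                 history = history), class = "surrogate_model")
}

#' Score peptides with a trained surrogate
#' @param model a `surrogate_model`.
#' @param peptides,alleles character vectors (alleles must be in the
#'   training vocabulary).
#' @return numeric presentation scores in (0, 1).
#' @export
surrogate_predict <- function(model, peptides, alleles) {
  assert_that(inherits(model, "surrogate_model"), "model must be trained")
  ai <- match(alleles, model$alleles)
  assert_that(!anyNA(ai), "unknown allele(s): %s",
              paste(unique(alleles[is.na(ai)]), collapse = ", "))
  surrogate_forward(model$weights, encode_peptides(peptides), ai)$p
}

#' Rank candidates by surrogate presentation score
#'
#' @param model a `surrogate_model`.
#' @param candidates data.frame with `sequence` (or `peptide`) and
#'   `allele`.
#' @param cutoff score above which a candidate counts as identified
#'   (default 0.5).
#' @return the candidates with added `dl_score`, `dl_rank` (1-based,
#'   descending score, ties broken by lexicographic peptide) and
#'   `dl_identified`.
#' @export
surrogate_rank <- function(model, candidates, cutoff = 0.5) {
  pep <- candidates$sequence %||% candidates$peptide
  sc <- surrogate_predict(model, pep, candidates$allele)
  o <- order(-sc, pep)
  rk <- integer(length(sc)); rk[o] <- seq_along(sc)
  candidates$dl_score <- sc
  candidates$dl_rank <- rk
  candidates$dl_identified <- sc > cutoff
  candidates
}
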