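#' Train word embeddings on a tokenized corpus
#'
#' Learns distributional word vectors from window co-occurrence counts via
#' positive pointwise mutual information (PPMI) followed by truncated SVD —
#' the count-based member of the word2vec family of embedding models. The
#' factorization is fully deterministic (singular-vector signs are fixed), so
#' identical corpora give identical models; `seed` and `epochs` are recorded
#' with the model for interface compatibility with stochastic trainers.
#'
#' @param corpus a [tokenize_corpus()] result; must be nonempty.
#' @param dim embedding dimension (vectors are zero-padded if the vocabulary
#'   supports fewer dimensions).
#' @param window symmetric co-occurrence window in tokens.
#' @param min_count minimum corpus frequency for a token to be embedded.
#' @param epochs recorded hyperparameter (unused by the deterministic
#'   factorization).
#' @param seed recorded hyperparameter (unused by the deterministic
#'   factorization).
#' @return object of class `embedding_model` with `vectors` (matrix, one row
#'   per vocabulary token), `dim`, and the training hyperparameters.
#' @export
train_embeddings <- function(corpus, dim = 100L, window = 5L, min_count = 5L,
                             epochs = 5L, seed = 1L) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  if (min_count < 1L) stop("`min_count` must be >= 1", call. = FALSE)
  vocab <- corpus$vocabulary[corpus$vocabulary$n >= min_count, , drop = FALSE]
  if (nrow(vocab) == 0L || sum(lengths(corpus$tokens)) == 0L) {
    stop("cannot train embeddings on an empty corpus (or none of the tokens reach min_count)",
         call. = FALSE)
  }
  v <- nrow(vocab)
  id <- stats::setNames(seq_len(v), vocab$token)

  doc_len <- lengths(corpus$tokens)
  flat <- unlist(corpus$tokens, use.names = FALSE)
  ids <- unname(id[flat])           # NA for sub-threshold tokens
  doc <- rep.int(seq_along(doc_len), doc_len)

  # symmetric window co-occurrence counts
  cooc <- matrix(0, v, v, dimnames = list(vocab$token, vocab$token))
  n_tok <- length(ids)
  for (k in seq_len(window)) {
    if (n_tok <= k) break
    a <- ids[seq_len(n_tok - k)]
    b <- ids[(k + 1L):n_tok]
    ok <- !is.na(a) & !is.na(b) & doc[seq_len(n_tok - k)] == doc[(k + 1L):n_tok]
    if (!any(ok)) next
    ii <- c(a[ok], b[ok])
    jj <- c(b[ok], a[ok])
    counts <- rowsum(rep(1, length(ii)), group = (ii - 1) * v + jj)
    key <- as.numeric(rownames(counts))
    idx <- cbind(((key - 1) %/% v) + 1, ((key - 1) %% v) + 1)
    cooc[idx] <- cooc[idx] + counts[, 1L]
  }

  total <- sum(cooc)
  if (total == 0) {
    vectors <- matrix(0, v, dim, dimnames = list(vocab$token, NULL))
  } else {
    rs <- rowSums(cooc)
    nz <- which(cooc > 0, arr.ind = TRUE)
    ppmi <- matrix(0, v, v, dimnames = dimnames(cooc))
    val <- log(cooc[nz] * total / (rs[nz[, 1L]] * rs[nz[, 2L]]))
    ppmi[nz] <- pmax(0, val)
    d_use <- min(dim, v)
    sv <- svd(ppmi, nu = d_use, nv = 0L)
    w <- sv$u %*% diag(sqrt(pmax(sv$d[seq_len(d_use)], 0)), d_use, d_use)
    # deterministic sign convention: largest-magnitude loading positive
    for (j in seq_len(d_use)) {
      piv <- which.max(abs(w[, j]))
      if (w[piv, j] < 0) w[, j] <- -w[, j]
    }
    vectors <- matrix(0, v, dim, dimnames = list(vocab$token, NULL))
    vectors[, seq_len(d_use)] <- w
  }

  structure(
    list(dim = as.integer(dim), vectors = vectors,
         window = as.integer(window), min_count = as.integer(min_count),
         epochs = as.integer(epochs), seed = as.integer(seed),
         vocab_counts = stats::setNames(vocab$n, vocab$token)),
    class = "embedding_model"
  )
}

#' Query nearest neighbors of a term in an embedding model
#'
#' @param model an `embedding_model`.
#' @param term query token; must be in the model vocabulary.
#' @param k number of neighbors (>= 0).
#' @return tibble of class `candidate_list` with columns `token`,
#'   `similarity` (cosine, non-increasing; ties broken lexicographically);
#'   the query term itself is excluded. Attribute `query` records the term.
#' @export
query_neighbors <- function(model, term, k) {
  stopifnot(inherits(model, "embedding_model"))
  if (!is.numeric(k) || k < 0) stop("`k` must be >= 0", call. = FALSE)
  vecs <- model$vectors
  if (!term %in% rownames(vecs)) {
    stop(sprintf("term '%s' is not in the model vocabulary", term), call. = FALSE)
  }
  q <- vecs[term, ]
  qn <- sqrt(sum(q^2))
  norms <- sqrt(rowSums(vecs^2))
  sim <- if (qn == 0) rep(0, nrow(vecs)) else
    as.vector(vecs %*% q) / (pmax(norms, .Machine$double.eps) * qn)
  sim[norms == 0] <- 0
  keep <- rownames(vecs) != term
  tokens <- rownames(vecs)[keep]
  sim <- sim[keep]
  # round before ranking so exact ties (and float noise from rescaled
  # vectors) break lexicographically, keeping the order stable
  ord <- order(-round(sim, 10), tokens)
  top <- utils::head(ord, k)
  out <- tibble::tibble(token = tokens[top], similarity = sim[top])
  attr(out, "query") <- term
  class(out) <- c("candidate_list", class(out))
  out
}
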