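# Latent Dirichlet allocation over rule-engine phrase corpora, by collapsed
# Gibbs sampling (compiled in src/).  Each phrase is one vocabulary token.

#' Fit an LDA topic model to a phrase corpus
#'
#' Bag-of-words LDA with symmetric Dirichlet priors (defaults
#' `alpha = eta = 1/k`), estimated by collapsed Gibbs sampling; the returned
#' document-topic proportions are Rao-Blackwellised averages over the
#' post-burn-in sweeps, so each is a strictly positive vector on the
#' k-simplex.  Topic labels are arbitrary (identifiable only up to
#' permutation); a fixed seed reproduces the fit exactly.
#'
#' @param corpus list of `text_document`s from [build_corpus()].
#' @param k number of topics (default 5, chosen as the point past which
#'   validation accuracy stops improving when varying k over 2..10).
#' @param alpha,eta symmetric Dirichlet concentrations; default `1/k`.
#' @param n_iter,burnin Gibbs sweeps and burn-in (defaults 300 / 100).
#' @param seed RNG seed.
#' @return object of class `lda_model`: `vocab`, `beta` (k x V topic-word
#'   matrix), `theta` (M x k document-topic matrix, rows named by patient),
#'   counts for fold-in inference, and the call configuration.
#' @export
fit_lda <- function(corpus, k = 5L, alpha = 1 / k, eta = 1 / k,
                    n_iter = 300L, burnin = 100L, seed = 1L) {
  if (length(corpus) == 0L) stop("empty corpus")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  tokens <- lapply(corpus, function(d) d$words)
  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  if (length(vocab) == 0L) stop("empty vocabulary")
  doc_id <- rep(seq_along(tokens), lengths(tokens)) - 1L
  word_id <- match(unlist(tokens, use.names = FALSE), vocab) - 1L
  set.seed(seed)
  fit <- lda_gibbs_fit(doc_id, word_id, length(tokens), length(vocab),
                       k, alpha, eta, as.integer(n_iter), as.integer(burnin))
  theta <- fit$theta / rowSums(fit$theta)   # exact simplex normalization
  rownames(theta) <- vapply(corpus, function(d) d$patient_id, character(1))
  colnames(theta) <- paste0("topic", seq_len(k))
  beta <- fit$beta / rowSums(fit$beta)
  colnames(beta) <- vocab
  structure(list(vocab = vocab, beta = beta, theta = theta,
                 nkw = fit$nkw, nk = fit$nk, k = k, alpha = alpha, eta = eta,
                 n_iter = n_iter, burnin = burnin, seed = seed),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> k=%d topics, %d documents, vocabulary %d phrases\n",
              x$k, nrow(x$theta), length(x$vocab)))
  invisible(x)
}

#' Infer the topic proportions of a (possibly unseen) document
#'
#' Fold-in Gibbs sampling with the fitted topic-word counts held fixed.
#' Phrases outside the training vocabulary are ignored.
#'
#' @param model an `lda_model`.
#' @param document a `text_document` (or character vector of phrases).
#' @param n_iter,burnin fold-in sweeps (defaults 100 / 50).
#' @param seed RNG seed.
#' @return numeric topic vector of length `k`, non-negative, summing to 1.
#' @export
infer_topics <- function(model, document, n_iter = 100L, burnin = 50L,
                         seed = 1L) {
  stopifnot(inherits(model, "lda_model"))
  words <- if (inherits(document, "text_document")) document$words
  else as.character(document)
  wid <- match(words, model$vocab)
  wid <- wid[!is.na(wid)] - 1L
  if (length(wid) == 0L)
    return(rep(1 / model$k, model$k))   # uninformative: prior mean
  set.seed(seed)
  th <- lda_gibbs_infer(wid, model$nkw, model$nk, length(model$vocab),
                        model$k, model$alpha, model$eta,
                        as.integer(n_iter), as.integer(burnin))
  as.numeric(th / sum(th))
}

#' Topic feature matrix for a corpus
#'
#' Convenience wrapper: fits LDA on the corpus and returns the document-topic
#' matrix as a data.frame keyed by patient id.
#'
#' @inheritParams fit_lda
#' @return data.frame (rownames = patient ids, columns `topic1..topick`) with
#'   the fitted `lda_model` as attribute `model`.
#' @export
topic_feature_matrix <- function(corpus, k = 5L, seed = 1L, ...) {
  model <- fit_lda(corpus, k = k, seed = seed, ...)
  df <- as.data.frame(model$theta)
  attr(df, "model") <- model
  df
}
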