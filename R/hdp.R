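#' HDP hyperparameters
#'
#' Parameters of the truncated stick-breaking variational approximation to
#' the hierarchical Dirichlet process. `T` and `K` are inference-side
#' truncation levels (global and per-document), not model assumptions: the
#' HDP itself places no prior bound on the number of topics, and the
#' truncations are set high relative to a two-document corpus so they are
#' never binding in practice. `gamma` and `alpha` are the corpus- and
#' document-level concentrations, `eta` the symmetric Dirichlet smoothing on
#' topic-term weights. Defaults (`gamma = alpha = 1`, `eta = 0.01`,
#' `T = 150`, `K = 15`) follow common HDP practice; a small `eta` lets
#' topics specialize sharply on the few pseudo-terms of a sentence pair.
#'
#' @param gamma Top-level concentration, > 0.
#' @param alpha Document-level concentration, > 0.
#' @param eta Topic-term smoothing, > 0.
#' @param T Global topic truncation, integer >= 1.
#' @param K Per-document truncation, integer in `[1, T]`.
#' @param iterations Outer variational EM passes, >= 1.
#' @param seed Integer seed for the topic-term initialization.
#' @return An `hdp_params`.
#' @export
hdp_params <- function(gamma = 1, alpha = 1, eta = 0.01,
                       T = 150L, K = 15L, iterations = 100L, seed = 1L) {
  if (gamma <= 0 || alpha <= 0 || eta <= 0)
    err_config("gamma, alpha and eta must all be > 0")
  if (T < 1 || K < 1 || K > T)
    err_config("truncations must satisfy 1 <= K <= T")
  if (iterations < 1) err_config("iterations must be >= 1")
  structure(list(gamma = gamma, alpha = alpha, eta = eta,
                 T = as.integer(T), K = as.integer(K),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "hdp_params")
}

#' Fit an HDP topic model on a pseudo-bag-of-words corpus
#'
#' Batch mean-field variational inference for the stick-breaking
#' representation of the HDP. Each outer pass recomputes the expected
#' log topic-term weights and global stick proportions, runs a per-document
#' E-step (document sticks, document-to-global topic assignment, per-term
#' responsibilities), and updates the topic-term Dirichlet parameters and
#' global sticks from the accumulated sufficient statistics. All randomness
#' is confined to the seeded initialization, so refitting with identical
#' inputs reproduces the model bit for bit.
#'
#' @param dictionary A [term_dictionary()] covering every term id in `corpus`.
#' @param corpus List of [pseudo_bow()] documents in dictionary-id space.
#' @param params An [hdp_params()].
#' @return An `hdp_model` with fields `lambda` (T x V topic-term weights),
#'   `Elogbeta`, `Elogsticks` and the inputs, usable with
#'   [topic_distribution()].
#' @export
fit_hdp <- function(dictionary, corpus, params = hdp_params()) {
  if (!inherits(dictionary, "term_dictionary"))
    err_invalid_input("`dictionary` must be a term_dictionary")
  if (!is.list(corpus) || length(corpus) == 0L)
    err_invalid_input("`corpus` must be a non-empty list of pseudo_bow documents")
  V <- dictionary$n_terms
  for (d in corpus) {
    if (!inherits(d, "pseudo_bow")) err_invalid_input("corpus entries must be pseudo_bow")
    if (length(d$term_id) == 0L)
      err_degenerate("corpus contains an empty document")
    if (any(d$term_id >= V))
      err_dictionary("document term id outside the dictionary")
  }
  Tt <- params$T

  total_w <- sum(vapply(corpus, function(d) sum(d$weight), 0))
  # term-anchored initialization: every dictionary term starts with a
  # preferred topic (cycling when V > T), plus mild symmetry-breaking noise.
  # Anchoring matters for pair corpora: it gives a term the *same* candidate
  # topic in both documents, so shared terms pull the two topic
  # distributions together instead of each document claiming private topics
  # for them.
  lambda <- with_seed(params$seed, {
    lam <- params$eta + matrix(stats::rgamma(Tt * V, shape = 1, rate = 1), Tt, V) *
      (0.1 * total_w / (Tt * V))
    anchor_topic <- ((seq_len(V) - 1L) %% Tt) + 1L
    lam[cbind(anchor_topic, seq_len(V))] <-
      lam[cbind(anchor_topic, seq_len(V))] + total_w / V
    lam
  })
  stick_a <- rep(1, max(Tt - 1L, 0L))
  stick_b <- rep(params$gamma, max(Tt - 1L, 0L))
  zeta_state <- vector("list", length(corpus))

  for (it in seq_len(params$iterations)) {
    Elogbeta <- digamma(lambda) - digamma(rowSums(lambda))
    Elogsticks <- expect_log_sticks(stick_a, stick_b, Tt)
    ss_lambda <- matrix(0, Tt, V)
    m_t <- numeric(Tt)
    for (j in seq_along(corpus)) {
      d <- corpus[[j]]
      es <- hdp_doc_estep(d, Elogbeta, Elogsticks, params,
                          zeta_init = zeta_state[[j]])
      zeta_state[[j]] <- es$zeta                # warm start next pass
      wgt <- t(es$zeta * d$weight)              # K x N
      ss_lambda[, d$term_id + 1L] <- ss_lambda[, d$term_id + 1L] +
        t(es$phi) %*% wgt                       # T x N scatter into word cols
      m_t <- m_t + colSums(es$phi)
    }
    lambda_new <- params$eta + ss_lambda
    converged <- mean(abs(lambda_new - lambda)) / (mean(lambda) + 1e-12) < 1e-6
    lambda <- lambda_new
    if (Tt > 1L) {
      tail_m <- rev(cumsum(rev(m_t)))           # sum_{s >= t} m_s
      stick_a <- 1 + m_t[seq_len(Tt - 1L)]
      stick_b <- params$gamma + tail_m[2:Tt]
    }
    # `iterations` caps the EM passes; stop early once the topic-term
    # parameters are stationary (two-document corpora converge fast)
    if (converged && it > 1L) break
  }

  structure(list(lambda = lambda,
                 Elogbeta = digamma(lambda) - digamma(rowSums(lambda)),
                 Elogsticks = expect_log_sticks(stick_a, stick_b, Tt),
                 stick_a = stick_a, stick_b = stick_b,
                 dictionary = dictionary, corpus = corpus, params = params),
            class = "hdp_model")
}

#' @export
print.hdp_model <- function(x, ...) {
  cat("<hdp_model> T = ", x$params$T, ", V = ", x$dictionary$n_terms,
      ", docs = ", length(x$corpus), "\n", sep = "")
  invisible(x)
}

#' Topic distribution of a document under a fitted model
#'
#' Runs the document E-step against the fitted topic-term weights and global
#' sticks and returns the expected topic proportions: non-negative, summing
#' to one, length `T`. Deterministic given the model.
#'
#' @param model An [fit_hdp()] result.
#' @param doc A [pseudo_bow()] in the model's dictionary-id space.
#' @return A `topic_distribution` (numeric vector with class attribute).
#' @export
topic_distribution <- function(model, doc) {
  if (!inherits(model, "hdp_model")) err_invalid_input("`model` must be an hdp_model")
  if (!inherits(doc, "pseudo_bow")) err_invalid_input("`doc` must be a pseudo_bow")
  if (length(doc$term_id) == 0L) err_degenerate("cannot infer topics for an empty document")
  if (any(doc$term_id >= model$dictionary$n_terms))
    err_dictionary("document term id outside the model dictionary")
  es <- hdp_doc_estep(doc, model$Elogbeta, model$Elogsticks, model$params)
  mass <- colSums(es$zeta * doc$weight)         # per doc-level topic
  theta <- as.numeric(mass %*% es$phi)          # project onto global topics
  theta <- pmax(theta, 0)
  theta <- theta / sum(theta)
  structure(theta, class = "topic_distribution")
}

#' @export
print.topic_distribution <- function(x, ...) {
  top <- order(unclass(x), decreasing = TRUE)[seq_len(min(3L, length(x)))]
  cat("<topic_distribution> length ", length(x), "; top topics: ",
      paste(sprintf("#%d (%.3f)", top, x[top]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# E[log stick lengths] of a truncated stick-breaking process with Beta
# variational parameters (a, b); the final stick takes the leftover mass.
expect_log_sticks <- function(a, b, T) {
  if (T == 1L) return(0)
  ElogW <- digamma(a) - digamma(a + b)
  Elog1mW <- digamma(b) - digamma(a + b)
  c(ElogW, 0) + c(0, cumsum(Elog1mW))
}

# Per-document coordinate ascent: zeta (N x K) term-to-document-topic
# responsibilities, phi (K x T) document-topic-to-global-topic mapping,
# document sticks re-estimated from weighted responsibilities each sweep.
# zeta starts from seeded random responsibilities rather than uniform ones:
# a uniform start is a symmetric fixed point of the updates (every table
# receives identical statistics, so all terms collapse onto one topic); the
# seed is derived from the document content, so identical documents are
# initialized — and therefore inferred — identically.
hdp_doc_estep <- function(doc, Elogbeta, Elogsticks, params,
                          max_iter = 25L, tol = 1e-10, zeta_init = NULL) {
  K <- params$K
  N <- length(doc$term_id)
  Eb <- Elogbeta[, doc$term_id + 1L, drop = FALSE]   # T x N
  zeta <- if (!is.null(zeta_init)) zeta_init else {
    doc_seed <- (params$seed %% 65011 + 1L) * 32717L + str_hash(
      paste(doc$term_id, signif(doc$weight, 12), collapse = ","))
    with_seed(doc_seed %% 2147483646L, {
      z <- matrix(stats::rgamma(N * K, shape = 1, rate = 1) + 1e-12, N, K)
      z / rowSums(z)
    })
  }
  phi <- NULL
  for (i in seq_len(max_iter)) {
    log_phi <- t(zeta * doc$weight) %*% t(Eb)                              # K x T
    log_phi <- log_phi + rep(Elogsticks, each = K)
    phi <- softmax_rows(log_phi)
    mass <- colSums(zeta * doc$weight)
    Elogsticks_doc <- if (K == 1L) 0 else {
      tail_mass <- rev(cumsum(rev(mass)))
      expect_log_sticks(1 + mass[seq_len(K - 1L)],
                        params$alpha + tail_mass[2:K], K)
    }
    log_zeta <- t(Eb) %*% t(phi)                                           # N x K
    log_zeta <- log_zeta + rep(Elogsticks_doc, each = N)
    zeta_new <- softmax_rows(log_zeta)
    delta <- mean(abs(zeta_new - zeta))
    zeta <- zeta_new
    if (delta < tol) break
  }
  list(zeta = zeta, phi = phi)
}

softmax_rows <- function(logM) {
  # ties.method = "first": the default consumes RNG and would break
  # determinism of the inference path
  mx <- logM[cbind(seq_len(nrow(logM)), max.col(logM, ties.method = "first"))]
  P <- exp(logM - mx)     # column-major recycling subtracts mx per row
  P / rowSums(P)
}
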