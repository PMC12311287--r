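#' Initialize CP factor matrices
#'
#' Entries are drawn i.i.d. from a zero-mean normal with standard deviation
#' `scale`; the draw is reproducible given `seed` and leaves the caller's RNG
#' state untouched.
#'
#' @param nV number of entities.
#' @param nR number of (augmented) relations.
#' @param D embedding dimension (the default mirrors the published
#'   configuration, D = 32).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param scale non-negative standard deviation of the entries.
#' @return a [CPFactors-class].
#' @export
initFactors <- function(nV, nR, D = 32L, seed = NULL, scale = 0.1) {
  if (nV < 1L || nR < 1L || D < 1L)
    stop("nV, nR and D must all be at least 1")
  if (scale < 0) stop("scale must be non-negative")
  .withSeed(seed, {
    new("CPFactors",
        Eh = matrix(stats::rnorm(nV * D, sd = 1) * scale, nV, D),
        Er = matrix(stats::rnorm(nR * D, sd = 1) * scale, nR, D),
        Et = matrix(stats::rnorm(nV * D, sd = 1) * scale, nV, D))
  })
}

#' Trilinear CP compatibility score of one triple
#'
#' The semantic compatibility of (h, r, t) is the trilinear product
#' `sum_d e_h(d) * e_r(d) * e_t(d)`, where the relation embedding is passed
#' explicitly so a refined (context-updated) relation vector can stand in for
#' the stored row of `Er`.
#'
#' @param factors a [CPFactors-class].
#' @param h head entity index.
#' @param rEmbedding length-D relation embedding.
#' @param t tail entity index.
#' @return a single numeric score.
#' @export
cpScore <- function(factors, h, rEmbedding, t) {
  D <- embedDim(factors)
  if (length(rEmbedding) != D)
    stop("relation embedding must have length ", D)
  if (h < 1L || h > nrow(factors@Eh) || t < 1L || t > nrow(factors@Et))
    stop("entity index out of range")
  sum(factors@Eh[h, ] * rEmbedding * factors@Et[t, ])
}

#' CP scores of a query against every entity
#'
#' Component `t` equals `cpScore(factors, qe, rEmbedding, t)`: the head row
#' of `Eh` is combined with the relation embedding and matched against every
#' row of `Et`.
#'
#' @inheritParams cpScore
#' @param qe query (head) entity index.
#' @return numeric vector over all entities.
#' @export
cpScoreAll <- function(factors, qe, rEmbedding) {
  D <- embedDim(factors)
  if (length(rEmbedding) != D)
    stop("relation embedding must have length ", D)
  as.numeric(factors@Et %*% (factors@Eh[qe, ] * rEmbedding))
}

#' N3 regularization penalty
#'
#' Sum of cubed absolute values (nuclear 3-norm surrogate) of the three
#' embeddings entering a training triple: query entity, refined query
#' relation, and answer entity. Non-negative, zero iff all inputs are zero,
#' and homogeneous of degree 3.
#'
#' @param eQe,eQr,eQa numeric vectors of equal length.
#' @return non-negative numeric scalar.
#' @export
n3Penalty <- function(eQe, eQr, eQa) {
  if (length(eQr) != length(eQe) || length(eQa) != length(eQe))
    stop("embeddings must have equal lengths")
  sum(abs(eQe)^3) + sum(abs(eQr)^3) + sum(abs(eQa)^3)
}

# L1/L2 alternatives, applied to the same three vectors.
.regPenalty <- function(kind, eQe, eQr, eQa) {
  switch(kind,
         n3 = n3Penalty(eQe, eQr, eQa),
         l1 = sum(abs(eQe)) + sum(abs(eQr)) + sum(abs(eQa)),
         l2 = sum(eQe^2) + sum(eQr^2) + sum(eQa^2),
         stop("unknown regularizer kind: ", kind))
}
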