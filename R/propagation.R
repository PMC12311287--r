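#' Expand the neighborhood of the current frontier
#'
#' Candidate edges are all augmented facts whose head lies in the frontier;
#' candidate nodes are the tails of those edges. Because every entity has an
#' identity self-loop, the frontier is always contained in the candidates.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param frontier non-empty integer vector of entity indices.
#' @return list with `nodes` (sorted integer vector) and `edges` (integer
#'   triple matrix sorted by head, relation, tail).
#' @export
expandCandidates <- function(kg, frontier) {
  if (!length(frontier)) stop("frontier must be non-empty")
  edges <- outgoingEdges(kg, frontier)
  list(nodes = sort(unique(edges[, 3L])), edges = edges)
}

#' Query-attentive edge weight
#'
#' `alpha = sigmoid(walpha' ReLU(Walpha (h_head + e_rel + e_qrel)))`: a
#' per-edge logistic gate mixing the head representation, the refined edge
#' relation, and the refined query relation. Always in (0, 1).
#'
#' @param layerParams list with `Walpha` (D x D) and `walpha` (length D).
#' @param hHead head-node representation at the previous layer.
#' @param eRel refined edge relation embedding.
#' @param eQRel refined query relation embedding.
#' @return numeric scalar in (0, 1).
#' @export
attentionWeight <- function(layerParams, hHead, eRel, eQRel) {
  z <- as.numeric(layerParams$Walpha %*% (hHead + eRel + eQRel))
  .sigmoid(sum(as.numeric(layerParams$walpha) * .relu(z)))
}

# Vectorized attention over edge rows of Z = Hh + Erel (+ query rel added).
.attentionMat <- function(Walpha, walpha, Zfull) {
  A <- .relu(Zfull %*% t(Walpha))
  as.numeric(.sigmoid(A %*% matrix(as.numeric(walpha), ncol = 1L)))
}

#' One layer of query-attentive message passing
#'
#' Each candidate node t aggregates over its incoming candidate edges
#' (h, r, t): `h_t = tanh(W %*% sum_e alpha_e (h_h + e_r))`, where `e_r` is
#' the once-refined edge relation (via [refineEdgeRelations()]) and `alpha`
#' the query-attentive gate. Candidate nodes without incoming edges are
#' absent from the result.
#'
#' @param reps numeric matrix of frontier representations, rows named by
#'   entity index.
#' @param candidateEdges integer triple matrix; every head must be in the
#'   frontier.
#' @param layerParams list with `W` (D x D), `Walpha`, `walpha`.
#' @param refiner a [RelationRefiner-class].
#' @param factors a [CPFactors-class].
#' @param queryRel refined query relation embedding for this layer.
#' @param prevEdgeRels matrix of previous-layer relation embeddings, one row
#'   per edge (NULL selects the static `Er` rows).
#' @return numeric matrix of candidate representations, rows named by entity
#'   index (sorted).
#' @export
propagateLayer <- function(reps, candidateEdges, layerParams, refiner, factors,
                           queryRel, prevEdgeRels = NULL) {
  heads <- as.character(candidateEdges[, 1L])
  if (!all(heads %in% rownames(reps)))
    stop("candidate edge with head outside the frontier")
  eRel <- refineEdgeRelations(refiner, candidateEdges, prevEdgeRels, factors)
  .propagateCore(reps, candidateEdges, layerParams, eRel, queryRel)
}

.propagateCore <- function(reps, candidateEdges, layerParams, eRel, queryRel) {
  Hh <- reps[as.character(candidateEdges[, 1L]), , drop = FALSE]
  Zsum <- Hh + eRel
  Zfull <- sweep(Zsum, 2L, queryRel, "+")
  alpha <- .attentionMat(layerParams$Walpha, layerParams$walpha, Zfull)
  M <- Zsum * alpha
  agg <- rowsum(M, group = candidateEdges[, 3L])
  H <- tanh(agg %*% t(layerParams$W))
  rownames(H) <- rownames(agg)
  H
}

#' Importance scores of candidate nodes
#'
#' Linear relevance score `s_t = Wsamp . h_t` per candidate representation.
#'
#' @param Wsamp length-D scoring vector (or D x 1 matrix).
#' @param reps numeric matrix of candidate representations, rows named by
#'   entity index.
#' @return named numeric vector of scores.
#' @export
importanceScores <- function(Wsamp, reps) {
  if (!nrow(reps)) return(stats::setNames(numeric(0), character(0)))
  s <- as.numeric(reps %*% matrix(as.numeric(Wsamp), ncol = 1L))
  stats::setNames(s, rownames(reps))
}

#' Top-K relevance selection
#'
#' Infer mode takes the exact top K by score with ties broken by ascending
#' entity index. Train mode perturbs each score with `temperature *
#' Gumbel(0,1)` noise and takes K iterative hard argmax selections without
#' replacement (equivalently, the top K of the perturbed scores); the
#' straight-through gradient of this selection lives in the training engine.
#'
#' @param scores named numeric vector (names are entity indices).
#' @param K number of nodes to keep (at least 1).
#' @param mode `"infer"` or `"train"`.
#' @param temperature positive Gumbel noise scale (train mode).
#' @param seed integer seed for the noise draw, or NULL.
#' @return sorted integer vector of `min(K, length(scores))` entity indices.
#' @export
selectTopK <- function(scores, K, mode = c("infer", "train"),
                       temperature = 1.0, seed = NULL) {
  mode <- match.arg(mode)
  if (K < 1L) stop("K must be at least 1")
  n <- length(scores)
  if (!n) return(integer(0))
  ids <- as.integer(names(scores))
  eff <- as.numeric(scores)
  if (mode == "train")
    eff <- eff + temperature * .withSeed(seed, .gumbel(n))
  ord <- order(-eff, ids)
  sort(ids[ord[seq_len(min(K, n))]])
}

# Refined embedding of each (head, relation) pair after `target` iterations
# of the gated cell from the static Er row (hidden state: static Eh row of
# the head); the iterate count is the layer index, shared by every query.
# Vectorized over pairs.
.edgeRelIterates <- function(pairs, target, refiner, factors) {
  X <- factors@Er[pairs[, 2L], , drop = FALSE]
  if (refiner@identity || !nrow(pairs)) return(X)
  H <- factors@Eh[pairs[, 1L], , drop = FALSE]
  for (it in seq_len(target)) X <- .lstmStepMat(refiner@weights, X, H)
  X
}

#' Build the query-guided subgraph
#'
#' Iterates expansion, relation refinement, attentive propagation, relevance
#' scoring and top-K filtering for `nLayers` layers starting from the query
#' entity. The query node is always retained in the frontier regardless of
#' its score (a message is emitted when this rule fires and
#' `options(kgfusion.verbose = TRUE)` is set). Deterministic in infer mode.
#'
#' @param model a [KGModel-class].
#' @param kg a [KnowledgeGraph-class].
#' @param query list with `qe` (entity index) and `qr` (augmented relation
#'   index).
#' @param nLayers,K override the model configuration if given.
#' @param mode `"infer"` (deterministic) or `"train"` (Gumbel-perturbed
#'   selection).
#' @param seed seed for train-mode selection noise.
#' @param maskEdge optional integer triple (h, r, t); that edge and its
#'   inverse are excluded from expansion (used during training so a query
#'   cannot read off its own answer edge).
#' @return a [Subgraph-class].
#' @export
buildSubgraph <- function(model, kg, query, nLayers = NULL, K = NULL,
                          mode = c("infer", "train"), seed = NULL,
                          maskEdge = NULL) {
  mode <- match.arg(mode)
  cfg <- model@config
  nLayers <- as.integer(nLayers %||% cfg$nLayers)
  K <- as.integer(K %||% cfg$K)
  qe <- as.integer(query$qe); qr <- as.integer(query$qr)
  if (qe < 1L || qe > numEntities(kg)) stop("unknown query entity index")
  if (qr < 1L || qr > numRelations(kg, augmented = TRUE))
    stop("unknown query relation index")
  params <- model@params
  factors <- cpFactors(model)
  refiner <- .refinerFromParams(params, identity = .hasFlag(cfg, "no_crr"))
  D <- cfg$D

  eQe <- .queryEntityEmbedding(model, qe)
  eQr <- .queryRelationEmbedding(model, qr)
  reps <- matrix(eQe, 1L, D, dimnames = list(as.character(qe), NULL))
  frontier <- qe
  layerLog <- vector("list", nLayers)
  edgeBag <- list()

  maskKeys <- NULL
  if (!is.null(maskEdge)) {
    n <- kg@nBaseRelations
    inv <- if (maskEdge[2L] <= n) maskEdge[2L] + n
           else if (maskEdge[2L] <= 2L * n) maskEdge[2L] - n else maskEdge[2L]
    mk <- rbind(maskEdge, c(maskEdge[3L], inv, maskEdge[1L]))
    maskKeys <- .tripleKey(mk, numEntities(kg), numRelations(kg, TRUE))
  }

  l <- 0L
  while (l < nLayers) {
    l <- l + 1L
    edges <- outgoingEdges(kg, frontier)
    if (!is.null(maskKeys)) {
      keys <- .tripleKey(edges, numEntities(kg), numRelations(kg, TRUE))
      edges <- edges[!(keys %in% maskKeys), , drop = FALSE]
    }
    if (!nrow(edges)) {
      warning("propagation reached an empty frontier at layer ", l,
              "; keeping the last non-empty layer")
      l <- l - 1L
      break
    }
    upairs <- unique(edges[, c(1L, 2L), drop = FALSE])
    prev <- .edgeRelIterates(upairs, l - 1L, refiner, factors)
    pairKey <- paste0(edges[, 1L], ".", edges[, 2L])
    upKey <- paste0(upairs[, 1L], ".", upairs[, 2L])
    prevEdge <- prev[match(pairKey, upKey), , drop = FALSE]
    eQr <- refineQueryRelation(refiner, eQr, eQe)
    lp <- .layerParams(params, l)
    H <- propagateLayer(reps, edges, lp, refiner, factors, eQr,
                        prevEdgeRels = prevEdge)
    scores <- importanceScores(params$Wsamp, H)
    sel <- selectTopK(scores, K, mode = mode, temperature = cfg$temperature,
                      seed = if (is.null(seed)) NULL else .deriveSeed(seed, l))
    if (!(qe %in% sel) && qe %in% as.integer(names(scores))) {
      drop <- sel[which.min(scores[as.character(sel)])]
      sel <- sort(c(setdiff(sel, drop), qe))
      if (isTRUE(getOption("kgfusion.verbose", FALSE)))
        message("query node retained in the frontier at layer ", l)
    }
    frontier <- sel
    reps <- H[as.character(sel), , drop = FALSE]
    edgeBag[[l]] <- edges
    layerLog[[l]] <- list(frontier = frontier, nCandidates = nrow(H))
  }

  allEdges <- if (length(edgeBag)) unique(do.call(rbind, edgeBag))
              else .emptyTriples()
  pick <- if (cfg$subgraphEdges == "final" && length(edgeBag))
    edgeBag[[length(edgeBag)]] else allEdges
  keep <- pick[, 1L] %in% frontier & pick[, 3L] %in% frontier
  new("Subgraph", nodes = as.integer(frontier),
      edges = .asTripleMatrix(pick[keep, , drop = FALSE]),
      finalReps = reps, queryRel = as.numeric(eQr),
      layers = layerLog[seq_len(l)])
}
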