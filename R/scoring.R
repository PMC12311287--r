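#' Structural readout score
#'
#' Dot product of the global readout vector with the candidate's final
#' subgraph representation. Candidates outside the final subgraph receive 0
#' (not -Inf), so the full-softmax loss stays finite and the semantic branch
#' can still rank them.
#'
#' @param w length-D readout vector (or D x 1 matrix).
#' @param rep candidate representation, or NULL if the candidate was not
#'   reached.
#' @return numeric scalar.
#' @export
structuralScore <- function(w, rep = NULL) {
  if (is.null(rep)) return(0)
  sum(as.numeric(w) * as.numeric(rep))
}

#' Hybrid fusion of structural and semantic scores
#'
#' `lambda * f + (1 - lambda) * phi`. Under the `no_phi` ablation the score
#' is exactly `f`; under `no_gsp` it is the raw `phi` (not scaled by
#' `1 - lambda`: scale is irrelevant to ranking but kept raw so the CP-only
#' model is the standard factorization model).
#'
#' @param config a configuration from [kgConfig()].
#' @param f structural score.
#' @param phi CP semantic score.
#' @return numeric scalar (vectorized over `f`/`phi`).
#' @export
hybridScore <- function(config, f, phi) {
  if (.hasFlag(config, "no_phi")) return(f)
  if (.hasFlag(config, "no_gsp")) return(phi)
  config$lambda * f + (1 - config$lambda) * phi
}

# Full per-query forward pass through the modular operations; returns the
# score vector plus the embeddings the regularizer needs.
.scoreQuery <- function(model, kg, query, mode = "infer", seed = NULL,
                        maskEdge = NULL) {
  cfg <- model@config
  nV <- numEntities(kg)
  factors <- cpFactors(model)
  eQe <- .queryEntityEmbedding(model, query$qe)

  if (.hasFlag(cfg, "no_gsp")) {
    eQr <- .queryRelationEmbedding(model, query$qr)
    phi <- as.numeric(factors@Et %*% (eQe * eQr))
    return(list(scores = phi, f = numeric(nV), phi = phi,
                eQe = eQe, eQr = eQr, sg = NULL))
  }

  sg <- buildSubgraph(model, kg, query, mode = mode, seed = seed,
                      maskEdge = maskEdge)
  f <- numeric(nV)
  if (nrow(sg@finalReps))
    f[as.integer(rownames(sg@finalReps))] <-
      as.numeric(sg@finalReps %*% matrix(as.numeric(model@params$w), ncol = 1L))
  eQr <- if (.hasFlag(cfg, "no_crr")) .queryRelationEmbedding(model, query$qr)
         else sg@queryRel
  phi <- as.numeric(factors@Et %*% (eQe * eQr))
  scores <- hybridScore(cfg, f, phi)
  list(scores = scores, f = f, phi = phi, eQe = eQe, eQr = eQr, sg = sg)
}

#' Hybrid scores of a query against all entities
#'
#' Runs the query-guided subgraph construction (unless the `no_gsp` ablation
#' is set), reads out the structural score of every reached entity, computes
#' the CP semantic score with the final refined query relation, and fuses the
#' two branches. Deterministic in infer mode.
#'
#' @param model a [KGModel-class].
#' @param kg a [KnowledgeGraph-class].
#' @param query list with `qe` and `qr`.
#' @param mode `"infer"` or `"train"`.
#' @param seed selection-noise seed (train mode).
#' @return numeric vector of scores over all entities.
#' @export
scoreAllEntities <- function(model, kg, query, mode = "infer", seed = NULL) {
  .scoreQuery(model, kg, query, mode = mode, seed = seed)$scores
}

#' Ranked predictions for one query
#'
#' @param model a [KGModel-class].
#' @param kg a [KnowledgeGraph-class].
#' @param head entity name.
#' @param relation relation name (base, `_inv`-suffixed inverse, or
#'   `_self_`).
#' @param top number of candidates to return.
#' @return data.frame with entity, hybrid score, structural and semantic
#'   components, and rank.
#' @export
predictQuery <- function(model, kg, head, relation, top = 10L) {
  qe <- match(head, entityNames(kg))
  if (is.na(qe)) stop("unknown entity name: ", head)
  qr <- match(relation, relationNames(kg, augmented = TRUE))
  if (is.na(qr)) stop("unknown relation name: ", relation)
  sq <- .scoreQuery(model, kg, list(qe = qe, qr = qr))
  ord <- order(-sq$scores, seq_along(sq$scores))[seq_len(min(top, length(sq$scores)))]
  data.frame(entity = entityNames(kg)[ord], score = sq$scores[ord],
             f = sq$f[ord], phi = sq$phi[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Export a query subgraph as an edge list
#'
#' Writes the traversed edges of a query's subgraph (entity and relation
#' names) as a tab-separated table for pathway-style inspection.
#'
#' @param sg a [Subgraph-class].
#' @param kg the [KnowledgeGraph-class] it was built on.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
exportSubgraph <- function(sg, kg, path) {
  rels <- relationNames(kg, augmented = TRUE)
  ents <- entityNames(kg)
  df <- data.frame(head = ents[sg@edges[, 1L]],
                   relation = rels[sg@edges[, 2L]],
                   tail = ents[sg@edges[, 3L]], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
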