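#' Knowledge graph accessors
#'
#' @param x a [KnowledgeGraph-class].
#' @param augmented logical; count/name relations after reverse + identity
#'   augmentation (`2n + 1` relations) instead of the `n` base relations.
#' @param split one of `"train"`, `"valid"`, `"test"`.
#'
#' @return `numEntities`/`numRelations` return integers; `entityNames` and
#'   `relationNames` character vectors; `tripleSplit` an integer triple
#'   matrix with columns head, relation, tail.
#' @name knowledgegraph-accessors
NULL

#' @rdname knowledgegraph-accessors
setMethod("numEntities", "KnowledgeGraph",
          function(x) length(x@vocab@entities))

#' @rdname knowledgegraph-accessors
setMethod("numRelations", "KnowledgeGraph", function(x, augmented = FALSE) {
  if (augmented) 2L * x@nBaseRelations + 1L else x@nBaseRelations
})

#' @rdname knowledgegraph-accessors
setMethod("entityNames", "KnowledgeGraph", function(x) x@vocab@entities)

#' @rdname knowledgegraph-accessors
setMethod("relationNames", "KnowledgeGraph", function(x, augmented = FALSE) {
  base <- x@vocab@relations
  if (!augmented) return(base)
  c(base, paste0(base, "_inv"), "_self_")
})

#' @rdname knowledgegraph-accessors
setMethod("tripleSplit", "KnowledgeGraph", function(x, split) {
  split <- match.arg(split, c("train", "valid", "test"))
  s <- x@splits[[split]]
  if (is.null(s)) matrix(integer(0), 0L, 3L,
                         dimnames = list(NULL, c("head", "relation", "tail")))
  else s
})

#' Model and factor accessors
#'
#' @param x a [CPFactors-class] or [KGModel-class].
#' @return `embedDim` returns the embedding dimension D; `cpFactors` the
#'   [CPFactors-class] view of a model's current factor matrices;
#'   `trainingLog` the per-epoch log; `modelConfig` the configuration list.
#' @name model-accessors
NULL

#' @rdname model-accessors
setMethod("embedDim", "CPFactors", function(x) ncol(x@Eh))

#' @rdname model-accessors
setMethod("embedDim", "KGModel", function(x) x@dims$D)

#' @rdname model-accessors
setMethod("cpFactors", "KGModel", function(x) {
  new("CPFactors", Eh = x@params$Eh, Er = x@params$Er, Et = x@params$Et)
})

#' @rdname model-accessors
setMethod("trainingLog", "KGModel", function(x) x@log)

#' @rdname model-accessors
setMethod("modelConfig", "KGModel", function(x) x@config)

#' Ranking result accessors
#'
#' @param x a [RankingResult-class].
#' @return `queryRanks` returns the integer vector of per-query filtered
#'   ranks.
#' @name rankingresult-accessors
NULL

#' @rdname rankingresult-accessors
setMethod("queryRanks", "RankingResult", function(x) x@ranks)

setMethod("show", "KnowledgeGraph", function(object) {
  cat(sprintf("KnowledgeGraph: %d entities, %d base relations (%d augmented)\n",
              numEntities(object), numRelations(object),
              numRelations(object, augmented = TRUE)))
  cat(sprintf("  augmented facts: %d\n", nrow(object@facts)))
  for (s in names(object@splits))
    cat(sprintf("  %s queries: %d\n", s, nrow(object@splits[[s]])))
})

setMethod("show", "CPFactors", function(object) {
  cat(sprintf("CPFactors: |V| = %d, |R| = %d, D = %d\n",
              nrow(object@Eh), nrow(object@Er), embedDim(object)))
})

setMethod("show", "RankingResult", function(object) {
  cat(sprintf("RankingResult over %d queries\n", length(object@ranks)))
  cat(sprintf("  MRR = %.4f  Hit@1 = %.4f  Hit@10 = %.4f\n",
              object@mrr, object@hit1, object@hit10))
})

setMethod("show", "KGModel", function(object) {
  cfg <- object@config
  cat(sprintf("KGModel: |V| = %d, |R_aug| = %d, D = %d, layers = %d, K = %d\n",
              object@dims$nV, object@dims$nR, object@dims$D,
              cfg$nLayers, cfg$K))
  if (length(cfg$ablation))
    cat("  ablation:", paste(cfg$ablation, collapse = ", "), "\n")
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs (best valid MRR %.4f)\n",
                max(object@log$epoch), max(object@log$validMRR, na.rm = TRUE)))
})

setMethod("show", "Subgraph", function(object) {
  cat(sprintf("Subgraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
})
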