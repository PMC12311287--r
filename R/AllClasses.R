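#' @import methods
NULL

#' Entity and relation vocabulary
#'
#' Ordered, unique entity and base-relation names. Indices are 1-based and
#' contiguous; name/index lookups are mutually inverse bijections by
#' construction (`match` against the stored vectors).
#'
#' @slot entities character vector of unique entity names, sorted (radix order).
#' @slot relations character vector of unique base relation names, sorted.
#' @export
setClass("Vocabulary",
         representation(entities = "character", relations = "character"),
         validity = function(object) {
           msg <- character(0)
           if (anyDuplicated(object@entities)) msg <- c(msg, "duplicate entity names")
           if (anyDuplicated(object@relations)) msg <- c(msg, "duplicate relation names")
           if (anyNA(object@entities) || anyNA(object@relations))
             msg <- c(msg, "NA names are not allowed")
           if (length(msg)) msg else TRUE
         })

#' Augmented multi-relational triple store
#'
#' Holds the augmented fact set of a knowledge graph G = (V, R, F, Q): for
#' every base fact (h, r, t) the inverse fact (t, r_inv, h) is present, and
#' every entity carries one identity self-loop. Relation indices are laid out
#' as base `1..n`, inverse `n+1..2n`, identity `2n+1` where `n` is the number
#' of base relations. Query splits (train/valid/test) are stored as integer
#' triple matrices over base relations.
#'
#' @slot vocab a [Vocabulary-class].
#' @slot nBaseRelations integer, number of relations before augmentation.
#' @slot facts integer matrix (rows are augmented facts; columns
#'   `head`, `relation`, `tail`), sorted by (head, relation, tail).
#' @slot headIndex list with integer vectors `start` and `end` giving, per
#'   entity, the row range of its outgoing edges in `facts` (0-length range
#'   encoded as start > end).
#' @slot splits named list of integer triple matrices (`train`, `valid`,
#'   `test`), possibly empty.
#' @export
setClass("KnowledgeGraph",
         representation(vocab = "Vocabulary", nBaseRelations = "integer",
                        facts = "matrix", headIndex = "list", splits = "list"),
         validity = function(object) {
           nV <- length(object@vocab@entities)
           n <- object@nBaseRelations
           f <- object@facts
           if (ncol(f) != 3L) return("facts must have 3 columns")
           if (nrow(f)) {
             if (min(f[, 1L]) < 1L || max(f[, 1L]) > nV ||
                 min(f[, 3L]) < 1L || max(f[, 3L]) > nV)
               return("entity index out of range")
             if (min(f[, 2L]) < 1L || max(f[, 2L]) > 2L * n + 1L)
               return("relation index out of range")
           }
           TRUE
         })

#' CP factor matrices
#'
#' The three factor matrices of a canonical polyadic decomposition of the
#' graph adjacency tensor: head-entity, relation, and tail-entity embeddings
#' sharing one embedding dimension D.
#'
#' @slot Eh numeric matrix |V| x D of head-entity embeddings.
#' @slot Er numeric matrix |R_aug| x D of relation embeddings.
#' @slot Et numeric matrix |V| x D of tail-entity embeddings.
#' @export
setClass("CPFactors",
         representation(Eh = "matrix", Er = "matrix", Et = "matrix"),
         validity = function(object) {
           D <- ncol(object@Eh)
           if (ncol(object@Er) != D || ncol(object@Et) != D)
             return("factor matrices must share the embedding dimension")
           if (!all(is.finite(object@Eh)) || !all(is.finite(object@Er)) ||
               !all(is.finite(object@Et)))
             return("factor entries must be finite")
           TRUE
         })

#' Contextual relation refiner (gated recurrent cell)
#'
#' A single-step LSTM cell that re-embeds a relation conditioned on an entity
#' embedding used as the hidden state. Weight blocks: input gate (Wi, Ui, bi),
#' forget gate (Wf, Uf, bf), output gate (Wo, Uo, bo) and candidate cell
#' (Wc, Uc, bc); all square D x D matrices plus length-D biases.
#'
#' @slot weights named list of the twelve parameter blocks.
#' @slot dim integer embedding dimension D.
#' @slot identity logical; if TRUE the refine operations are exact
#'   pass-throughs (used by the no-CRR ablation).
#' @export
setClass("RelationRefiner",
         representation(weights = "list", dim = "integer", identity = "logical"),
         validity = function(object) {
           need <- c("Wi", "Ui", "bi", "Wf", "Uf", "bf",
                     "Wo", "Uo", "bo", "Wc", "Uc", "bc")
           if (!all(need %in% names(object@weights)))
             return("missing gate weight blocks")
           D <- object@dim
           for (nm in c("Wi", "Ui", "Wf", "Uf", "Wo", "Uo", "Wc", "Uc")) {
             w <- object@weights[[nm]]
             if (!is.matrix(w) || any(dim(w) != D))
               return(sprintf("%s must be a %d x %d matrix", nm, D, D))
           }
           for (nm in c("bi", "bf", "bo", "bc"))
             if (length(object@weights[[nm]]) != D)
               return(sprintf("%s must have length %d", nm, D))
           TRUE
         })

#' Query-specific subgraph
#'
#' Result of layered query-guided subgraph construction: the finally selected
#' entity set, the traversed edges among those entities, the final node
#' representations and the refined query-relation embedding.
#'
#' @slot nodes integer vector of selected entity indices (the final frontier).
#' @slot edges integer matrix of traversed edges among selected nodes.
#' @slot finalReps numeric matrix of final-layer node representations, rows
#'   named by entity index.
#' @slot queryRel numeric vector, refined query-relation embedding at the
#'   final layer.
#' @slot layers list of per-layer records (frontier, edges) for inspection.
#' @export
setClass("Subgraph",
         representation(nodes = "integer", edges = "matrix",
                        finalReps = "matrix", queryRel = "numeric",
                        layers = "list"))

#' Filtered ranking evaluation result
#'
#' @slot ranks integer vector of per-query filtered ranks.
#' @slot mrr mean reciprocal rank.
#' @slot hit1 fraction of ranks equal to 1.
#' @slot hit10 fraction of ranks at most 10.
#' @export
setClass("RankingResult",
         representation(ranks = "integer", mrr = "numeric",
                        hit1 = "numeric", hit10 = "numeric"),
         validity = function(object) {
           if (length(object@ranks) && min(object@ranks) < 1L)
             return("ranks must be positive")
           if (object@hit1 > object@hit10 + 1e-12)
             return("hit1 cannot exceed hit10")
           TRUE
         })

#' Hybrid semantic/structural link-prediction model
#'
#' Container for all trainable parameters (CP factors, refiner gate weights,
#' per-layer propagation and attention weights, importance-scoring and
#' readout vectors), the training configuration, and the per-epoch training
#' log.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config configuration list (see [kgConfig()]).
#' @slot dims list with nV, nR (augmented) and D.
#' @slot log data.frame of per-epoch loss and validation MRR.
#' @export
setClass("KGModel",
         representation(params = "list", config = "list",
                        dims = "list", log = "data.frame"))
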