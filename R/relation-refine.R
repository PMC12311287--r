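#' Create a contextual relation refiner
#'
#' Gate weight matrices are drawn i.i.d. normal with standard deviation
#' `scale`; biases start at zero. With `identity = TRUE` the refine
#' operations become exact pass-throughs (the no-CRR ablation).
#'
#' @param D embedding dimension.
#' @param seed integer seed or NULL.
#' @param scale standard deviation of the initial gate weights.
#' @param identity logical pass-through flag.
#' @return a [RelationRefiner-class].
#' @export
newRelationRefiner <- function(D, seed = NULL, scale = 0.1, identity = FALSE) {
  D <- as.integer(D)
  if (D < 1L) stop("D must be at least 1")
  w <- .withSeed(seed, {
    mk <- function() matrix(stats::rnorm(D * D) * scale, D, D)
    list(Wi = mk(), Ui = mk(), bi = numeric(D),
         Wf = mk(), Uf = mk(), bf = numeric(D),
         Wo = mk(), Uo = mk(), bo = numeric(D),
         Wc = mk(), Uc = mk(), bc = numeric(D))
  })
  new("RelationRefiner", weights = w, dim = D, identity = identity)
}

# Refiner built as a view on a model's flat parameter list.
.refinerFromParams <- function(params, identity = FALSE) {
  new("RelationRefiner",
      weights = params[c("Wi", "Ui", "bi", "Wf", "Uf", "bf",
                         "Wo", "Uo", "bo", "Wc", "Uc", "bc")],
      dim = ncol(params$Wi), identity = identity)
}

#' One gated-cell update step
#'
#' Standard LSTM cell arithmetic with the relation embedding as input `x`,
#' an entity embedding as hidden state `h`, and an explicit cell state:
#' `i = sigmoid(Wi x + Ui h + bi)`, `f = sigmoid(Wf x + Uf h + bf)`,
#' `o = sigmoid(Wo x + Uo h + bo)`, `ctil = tanh(Wc x + Uc h + bc)`,
#' `cell' = f * cell + i * ctil`, `output = o * tanh(cell')`.
#'
#' @param refiner a [RelationRefiner-class].
#' @param input length-D relation embedding (x).
#' @param hidden length-D entity embedding (h).
#' @param cell length-D cell state; the refine operations always call with a
#'   zero cell (state is not carried across layers).
#' @return list with `output` and `cell`, both length-D.
#' @export
lstmStep <- function(refiner, input, hidden, cell = numeric(refiner@dim)) {
  D <- refiner@dim
  if (length(input) != D || length(hidden) != D || length(cell) != D)
    stop("input, hidden and cell must all have length ", D)
  w <- refiner@weights
  i <- .sigmoid(as.numeric(w$Wi %*% input + w$Ui %*% hidden) + w$bi)
  f <- .sigmoid(as.numeric(w$Wf %*% input + w$Uf %*% hidden) + w$bf)
  o <- .sigmoid(as.numeric(w$Wo %*% input + w$Uo %*% hidden) + w$bo)
  ctil <- tanh(as.numeric(w$Wc %*% input + w$Uc %*% hidden) + w$bc)
  newCell <- f * cell + i * ctil
  list(output = o * tanh(newCell), cell = newCell)
}

# Vectorized cell update over rows (zero initial cell), X and H both n x D.
.lstmStepMat <- function(w, X, H) {
  n <- nrow(X)
  bias <- function(b) matrix(b, n, length(b), byrow = TRUE)
  i <- .sigmoid(X %*% t(w$Wi) + H %*% t(w$Ui) + bias(w$bi))
  o <- .sigmoid(X %*% t(w$Wo) + H %*% t(w$Uo) + bias(w$bo))
  ctil <- tanh(X %*% t(w$Wc) + H %*% t(w$Uc) + bias(w$bc))
  cell <- i * ctil
  o * tanh(cell)
}

#' Refine edge relation embeddings for one layer
#'
#' Each edge's relation embedding is passed once through the gated cell with
#' the static head-entity embedding (`Eh` row) as hidden state and a zero
#' cell. Edges sharing (head, relation) necessarily receive identical
#' refined embeddings. With an identity refiner, the previous embeddings are
#' returned unchanged.
#'
#' @param refiner a [RelationRefiner-class].
#' @param edges integer triple matrix (head, relation, tail).
#' @param prevRel numeric matrix, one row per edge: the previous-layer
#'   relation embeddings (layer 0 uses the rows of `Er`). NULL selects the
#'   `Er` rows of `factors`.
#' @param factors a [CPFactors-class] supplying `Eh` (and default `Er`).
#' @return numeric matrix, one refined embedding row per edge.
#' @export
refineEdgeRelations <- function(refiner, edges, prevRel, factors) {
  if (is.null(prevRel)) prevRel <- factors@Er[edges[, 2L], , drop = FALSE]
  if (nrow(prevRel) != nrow(edges))
    stop("prevRel must supply one embedding per edge")
  if (refiner@identity) return(prevRel)
  if (!nrow(edges)) return(prevRel)
  H <- factors@Eh[edges[, 1L], , drop = FALSE]
  .lstmStepMat(refiner@weights, prevRel, H)
}

#' Refine the query relation embedding for one layer
#'
#' One gated-cell step with the query-entity embedding as hidden state and a
#' zero cell; iterated once per propagation layer.
#'
#' @param refiner a [RelationRefiner-class].
#' @param eQrPrev previous-layer query relation embedding.
#' @param eQe query entity embedding.
#' @return length-D numeric vector.
#' @export
refineQueryRelation <- function(refiner, eQrPrev, eQe) {
  if (refiner@identity) return(eQrPrev)
  lstmStep(refiner, eQrPrev, eQe)$output
}
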