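#' Training and model configuration
#'
#' Collects every tunable of the hybrid model. Defaults mirror the published
#' configuration where one exists (D = 32, lambda = 0.7, six propagation
#' layers, batch size 16) and this package's own choices elsewhere.
#'
#' @param D embedding dimension.
#' @param nLayers number of propagation layers (ell).
#' @param K top-K frontier size kept after relevance filtering, constant
#'   across layers.
#' @param lambda fusion weight in `[0, 1]` between the structural readout and
#'   the CP semantic score.
#' @param gamma non-negative regularization strength.
#' @param regKind one of `"n3"`, `"l1"`, `"l2"`.
#' @param lr Adam learning rate.
#' @param clipNorm global gradient-norm clipping threshold (Inf disables);
#'   standard stabilizer for recurrent-cell models on sharp loss surfaces.
#' @param epochs maximum training epochs.
#' @param batchSize queries per gradient step.
#' @param seed integer seed governing initialization, shuffling and Gumbel
#'   noise.
#' @param patience early-stopping patience in epochs of no validation-MRR
#'   improvement.
#' @param temperature Gumbel perturbation scale for train-mode top-K
#'   selection.
#' @param temperatureFinal if non-NULL, the temperature is annealed
#'   geometrically from `temperature` to this value across the training
#'   epochs (exploration early, score-driven selection late).
#' @param kStart if non-NULL, the training-time frontier size starts here
#'   and decays linearly to `K` across the epochs (a selection curriculum:
#'   early epochs see near-full recall so the readout learns, later epochs
#'   train the relevance filter at the model's working size). Inference
#'   always uses `K`.
#' @param ablation character vector, any of `"no_gsp"`, `"random_query"`,
#'   `"no_crr"`, `"no_phi"`.
#' @param inverseQueries also train on the inverse query of every training
#'   fact.
#' @param initScale standard deviation of parameter initialization.
#' @param attnGain multiplier on the initial attention weights; values above
#'   1 start the edge gates sharp (near 0/1) instead of uniform 0.5, which
#'   counteracts over-smoothing on dense graphs by breaking the symmetric
#'   mixing at initialization.
#' @param evalEvery validate every this many epochs.
#' @param subgraphEdges which traversed edges enter the reported subgraph:
#'   `"all"` layers or only the `"final"` one.
#' @param warmupEpochs optional CP-only warm-start epochs before joint
#'   training.
#' @return a named configuration list.
#' @export
kgConfig <- function(D = 32L, nLayers = 6L, K = 100L, lambda = 0.7,
                     gamma = 0.01, regKind = c("n3", "l1", "l2"),
                     lr = 1e-3, clipNorm = 1.0, epochs = 100L,
                     batchSize = 16L, seed = 1L,
                     patience = 10L, temperature = 1.0,
                     temperatureFinal = NULL, kStart = NULL,
                     ablation = character(0), inverseQueries = TRUE,
                     initScale = 0.1, attnGain = 1.0, evalEvery = 5L,
                     subgraphEdges = c("all", "final"), warmupEpochs = 0L) {
  regKind <- match.arg(regKind)
  subgraphEdges <- match.arg(subgraphEdges)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (gamma < 0) stop("gamma must be non-negative")
  if (batchSize < 1L) stop("batchSize must be at least 1")
  if (temperature <= 0) stop("temperature must be positive")
  bad <- setdiff(ablation, c("no_gsp", "random_query", "no_crr", "no_phi"))
  if (length(bad)) stop("unknown ablation flag(s): ", paste(bad, collapse = ", "))
  list(D = as.integer(D), nLayers = as.integer(nLayers),
                 K = as.integer(K), lambda = lambda, gamma = gamma,
                 regKind = regKind, lr = lr, clipNorm = clipNorm,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 patience = as.integer(patience), temperature = temperature,
                 temperatureFinal = temperatureFinal,
                 kStart = if (is.null(kStart)) NULL else as.integer(kStart),
                 ablation = ablation, inverseQueries = inverseQueries,
                 initScale = initScale, attnGain = attnGain,
                 evalEvery = as.integer(evalEvery),
                 subgraphEdges = subgraphEdges,
                 warmupEpochs = as.integer(warmupEpochs))
}

#' Derive an ablated configuration
#'
#' The four variants switch off one component each: `no_gsp` drops subgraph
#' propagation entirely (CP-only scoring), `random_query` replaces the
#' CP-derived query embeddings with frozen random vectors, `no_crr` makes the
#' relation refiner an identity pass-through, and `no_phi` removes the CP
#' branch from the score (lambda forced to 1; the loss keeps its
#' regularizer).
#'
#' @param config a configuration from [kgConfig()].
#' @param variant one of `"no_gsp"`, `"random_query"`, `"no_crr"`, `"no_phi"`.
#' @return the modified configuration.
#' @export
applyAblation <- function(config, variant) {
  variant <- match.arg(variant, c("no_gsp", "random_query", "no_crr", "no_phi"))
  config$ablation <- union(config$ablation, variant)
  if (variant == "no_phi") config$lambda <- 1.0
  config
}

.hasFlag <- function(config, flag) flag %in% config$ablation

# Flat trainable-parameter list for a graph of nV entities and nR augmented
# relations. Vectors are stored as D x 1 matrices so the optimizer and the
# tape engine can treat every parameter uniformly.
.initParams <- function(nV, nR, config) {
  D <- config$D
  s <- config$initScale
  .withSeed(config$seed, {
    mk <- function(nr, nc) matrix(stats::rnorm(nr * nc) * s, nr, nc)
    # input/output gate biases start at +1 (open gates), the standard
    # recurrent-cell initialization that keeps the refinement map close to
    # norm-preserving so signal and gradient survive repeated application
    p <- list(Eh = mk(nV, D), Er = mk(nR, D), Et = mk(nV, D),
              Wi = mk(D, D), Ui = mk(D, D), bi = rep(1, D),
              Wf = mk(D, D), Uf = mk(D, D), bf = numeric(D),
              Wo = mk(D, D), Uo = mk(D, D), bo = rep(1, D),
              Wc = mk(D, D), Uc = mk(D, D), bc = numeric(D))
    g <- config$attnGain %||% 1
    for (l in seq_len(config$nLayers)) {
      p[[sprintf("W.%d", l)]] <- mk(D, D)
      p[[sprintf("Wa.%d", l)]] <- mk(D, D) * g
      p[[sprintf("wa.%d", l)]] <- mk(D, 1L) * g
    }
    p$w <- mk(D, 1L)
    # relevance scoring starts aligned with the readout so that the learned
    # top-K filter keeps the nodes the readout considers answer-like; the
    # two vectors decouple freely during optimization
    p$Wsamp <- p$w
    if (.hasFlag(config, "random_query")) {
      # frozen random query embeddings (never optimized)
      p$Qe <- mk(nV, D)
      p$Qr <- mk(nR, D)
    }
    p
  })
}

.frozenParamNames <- c("Qe", "Qr")

#' Create an untrained model for a knowledge graph
#'
#' @param kg a [KnowledgeGraph-class].
#' @param config a configuration from [kgConfig()].
#' @return a [KGModel-class] with freshly initialized parameters.
#' @export
newKGModel <- function(kg, config = kgConfig()) {
  nV <- numEntities(kg)
  nR <- numRelations(kg, augmented = TRUE)
  new("KGModel", params = .initParams(nV, nR, config), config = config,
      dims = list(nV = nV, nR = nR, D = config$D),
      log = data.frame(epoch = integer(0), loss = numeric(0),
                       validMRR = numeric(0)))
}

# Query-side embeddings: CP rows, or the frozen random rows under the
# random_query ablation.
.queryEntityEmbedding <- function(model, qe) {
  if (.hasFlag(model@config, "random_query")) model@params$Qe[qe, ]
  else model@params$Eh[qe, ]
}

.queryRelationEmbedding <- function(model, qr) {
  if (.hasFlag(model@config, "random_query")) model@params$Qr[qr, ]
  else model@params$Er[qr, ]
}

.layerParams <- function(params, l) {
  list(W = params[[sprintf("W.%d", l)]],
       Walpha = params[[sprintf("Wa.%d", l)]],
       walpha = as.numeric(params[[sprintf("wa.%d", l)]]))
}
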