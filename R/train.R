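#' Multi-class log-loss of a score vector
#'
#' `-score[answer] + log(sum_t exp(score[t]))` over all entities, computed
#' with a numerically stable log-sum-exp. The softmax denominator spans every
#' entity, including other true answers; filtering applies only at
#' evaluation.
#'
#' @param scores numeric score vector over all entities.
#' @param answer index of the true answer.
#' @return numeric scalar loss.
#' @export
logLoss <- function(scores, answer) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (answer < 1L || answer > length(scores)) stop("answer index out of range")
  m <- max(scores)
  -scores[answer] + m + log(sum(exp(scores - m)))
}

#' Composite training loss of a query batch
#'
#' Mean log-loss over the batch plus `gamma` times the mean regularization
#' penalty (N3 by default, applied per query to the query-entity embedding,
#' the refined final-layer query relation, and the answer-entity embedding;
#' L1/L2 selectable). Computed by composing the modular per-query operations;
#' the training loop uses an equivalent batched reverse-mode implementation
#' whose value and gradients are tested against this path.
#'
#' @param queries integer matrix with columns qe, qr, qa.
#' @param model a [KGModel-class].
#' @param kg a [KnowledgeGraph-class].
#' @param mode `"infer"` or `"train"` (Gumbel-perturbed selection).
#' @param seed selection-noise seed.
#' @param maskQueryEdges exclude each query's own answer edge (and its
#'   inverse) from expansion, as done during training.
#' @return numeric scalar loss.
#' @export
totalLoss <- function(queries, model, kg, mode = "infer", seed = NULL,
                      maskQueryEdges = FALSE) {
  if (!nrow(queries)) stop("query batch must be non-empty")
  cfg <- model@config
  p <- 0
  ll <- 0
  for (i in seq_len(nrow(queries))) {
    q <- list(qe = queries[i, 1L], qr = queries[i, 2L])
    sq <- .scoreQuery(model, kg, q, mode = mode,
                      seed = if (is.null(seed)) NULL else .deriveSeed(seed, i),
                      maskEdge = if (maskQueryEdges) queries[i, ] else NULL)
    ll <- ll + logLoss(sq$scores, queries[i, 3L])
    p <- p + .regPenalty(cfg$regKind, sq$eQe, sq$eQr,
                         model@params$Et[queries[i, 3L], ])
  }
  ll / nrow(queries) + cfg$gamma * p / nrow(queries)
}

# ---------------------------------------------------------------------------
# Batched tape forward pass (training engine).

.lstmTapeStep <- function(tape, x, h, pid) {
  .tpLstm(tape, x, h, pid$Wi, pid$Ui, pid$bi, pid$Wo, pid$Uo, pid$bo,
          pid$Wc, pid$Uc, pid$bc)
}

.regPower <- function(kind) switch(kind, n3 = 3, l1 = 1, l2 = 2)

# Forward pass over a batch of queries, recording the tape. Returns ids of
# the loss and of every parameter leaf.
.tapeForward <- function(kg, queries, params, config, mode = "train",
                         noiseSeed = NULL, maskQueryEdges = FALSE) {
  noGsp <- .hasFlag(config, "no_gsp")
  noCrr <- .hasFlag(config, "no_crr")
  noPhi <- .hasFlag(config, "no_phi")
  randomQ <- .hasFlag(config, "random_query")
  B <- nrow(queries)
  nV <- numEntities(kg)
  nRa <- numRelations(kg, augmented = TRUE)
  L <- if (noGsp) 0L else config$nLayers
  K <- config$K
  tau <- config$tauNow %||% config$temperature
  train <- mode == "train"

  tape <- .tpNew()
  pid <- lapply(params, function(v) .tpInput(tape, v))

  eqeId <- .tpGather(tape, pid[[if (randomQ) "Qe" else "Eh"]], queries[, 1L])
  qrId <- .tpGather(tape, pid[[if (randomQ) "Qr" else "Er"]], queries[, 2L])

  maskKeys <- NULL
  if (maskQueryEdges) {
    n <- kg@nBaseRelations
    r <- queries[, 2L]
    inv <- ifelse(r <= n, r + n, ifelse(r <= 2L * n, r - n, r))
    maskKeys <- cbind(.tripleKey(queries, nV, nRa),
                      .tripleKey(cbind(queries[, 3L], inv, queries[, 1L]), nV, nRa))
  }

  activeQ <- seq_len(B)
  activeNode <- queries[, 1L]
  repsId <- eqeId
  facts <- kg@facts
  hi <- kg@headIndex
  # incremental (head, relation)-pair refinement cache: key -> (node, row)
  relCache <- new.env(parent = emptyenv())

  for (l in seq_len(L)) {
    st <- hi$start[activeNode]
    en <- hi$end[activeNode]
    cnt <- en - st + 1L
    rows <- sequence(cnt, from = st)
    srcRow <- rep.int(seq_along(activeNode), cnt)
    eh <- facts[rows, 1L]; er <- facts[rows, 2L]; et <- facts[rows, 3L]
    edgeQ <- activeQ[srcRow]
    if (!is.null(maskKeys)) {
      keys <- .tripleKey(cbind(eh, er, et), nV, nRa)
      drop <- keys == maskKeys[edgeQ, 1L] | keys == maskKeys[edgeQ, 2L]
      if (any(drop)) {
        keep <- !drop
        eh <- eh[keep]; er <- er[keep]; et <- et[keep]
        srcRow <- srcRow[keep]; edgeQ <- edgeQ[keep]
      }
    }

    # refined edge relations, shared across queries per (head, relation);
    # the iterate count equals the layer index, so pairs refined at the
    # previous layer advance one step and newly seen pairs catch up
    pkey <- (as.double(eh) - 1) * nRa + as.double(er)
    up <- !duplicated(pkey)
    upH <- eh[up]; upR <- er[up]; upKey <- as.character(pkey[up])
    if (noCrr) {
      pairOut <- .tpGather(tape, pid$Er, upR)
      pidx <- match(pkey, pkey[up])
    } else {
      src <- lapply(upKey, function(k) relCache[[k]])
      iter <- vapply(src, function(s) if (is.null(s)) 0L else s$iter, 0L)
      # order pairs by how many applications they still need
      ordPairs <- order(iter, vapply(src, function(s)
        if (is.null(s)) 0L else s$row, 0L))
      upH <- upH[ordPairs]; upR <- upR[ordPairs]; upKey <- upKey[ordPairs]
      src <- src[ordPairs]; iter <- iter[ordPairs]
      parts <- list()
      for (c0 in unique(iter)) {
        sel <- which(iter == c0)
        # pairs sharing an iterate count were last refined in the same
        # layer, hence live in one tape node
        blockPrev <- if (c0 == 0L) .tpGather(tape, pid$Er, upR[sel])
                     else .tpGather(tape, src[[sel[1L]]]$node,
                                    vapply(src[sel], `[[`, 0L, "row"))
        blockH <- .tpGather(tape, pid$Eh, upH[sel])
        for (it in seq_len(l - c0))
          blockPrev <- .lstmTapeStep(tape, blockPrev, blockH, pid)
        parts[[length(parts) + 1L]] <- blockPrev
      }
      pairOut <- if (length(parts) == 1L) parts[[1L]]
                 else .tpRbind(tape, parts)
      for (j in seq_along(upKey))
        relCache[[upKey[j]]] <- list(iter = l, node = pairOut, row = j)
      pidx <- match(as.character(pkey), upKey)
      qrId <- .lstmTapeStep(tape, qrId, eqeId, pid)
    }

    HhE <- .tpGather(tape, repsId, srcRow)
    ErE <- .tpGather(tape, pairOut, pidx)
    EqrE <- .tpGather(tape, qrId, edgeQ)
    S1 <- .tpAdd(tape, HhE, ErE)
    Zf <- .tpAdd(tape, S1, EqrE)
    A <- .tpRelu(tape, .tpMatmulT(tape, Zf, pid[[sprintf("Wa.%d", l)]]))
    alpha <- .tpSigmoid(tape, .tpMatmul(tape, A, pid[[sprintf("wa.%d", l)]]))
    M <- .tpColScale(tape, S1, alpha)

    ck <- (as.double(edgeQ) - 1) * nV + as.double(et)
    uc <- sort(unique(ck))
    cidx <- match(ck, uc)
    candQ <- as.integer((uc - 1) %/% nV) + 1L
    candNode <- as.integer((uc - 1) %% nV) + 1L

    agg <- .tpRowsumBy(tape, M, cidx, length(uc))
    H <- .tpTanh(tape, .tpMatmulT(tape, agg, pid[[sprintf("W.%d", l)]]))
    sId <- .tpMatmul(tape, H, pid$Wsamp)

    sval <- as.numeric(.tpVal(tape, sId))
    pert <- sval
    if (train) {
      noise <- .withSeed(if (is.null(noiseSeed)) NULL
                         else .deriveSeed(noiseSeed, l),
                         .gumbel(length(sval)))
      pert <- sval + tau * noise
    }

    selRows <- integer(0)
    steps <- list()
    for (qb in seq_len(B)) {
      qrows <- which(candQ == qb)
      if (!length(qrows)) next
      ord <- qrows[order(-pert[qrows], candNode[qrows])]
      sel <- ord[seq_len(min(K, length(ord)))]
      qe <- queries[qb, 1L]
      if (!any(candNode[sel] == qe)) {
        svals <- sval[sel]
        dr <- sel[order(svals, candNode[sel])[1L]]
        sel <- c(setdiff(sel, dr), qrows[candNode[qrows] == qe][1L])
      }
      if (train) {
        remaining <- qrows
        selOrd <- sel[order(-pert[sel], candNode[sel])]
        for (srow in selOrd) {
          ex <- exp(pert[remaining] - max(pert[remaining]))
          steps[[length(steps) + 1L]] <-
            list(rows = remaining, p = ex / sum(ex),
                 selPos = match(srow, remaining), gateRow = srow)
          remaining <- remaining[remaining != srow]
        }
      }
      selRows <- c(selRows, sel)
    }

    ord2 <- order(candQ[selRows], candNode[selRows])
    selRows <- selRows[ord2]
    newReps <- .tpGather(tape, H, selRows)
    if (train && length(steps)) {
      gatePos <- match(vapply(steps, `[[`, 0L, "gateRow"), selRows)
      for (i in seq_along(steps)) steps[[i]]$gateRow <- gatePos[i]
      steps <- steps[!is.na(gatePos)]
      gate <- .tpStGate(tape, sId, steps, length(selRows), length(uc))
      newReps <- .tpColScale(tape, newReps, gate)
    }
    repsId <- newReps
    activeQ <- candQ[selRows]
    activeNode <- candNode[selRows]
  }

  SId <- NULL
  if (!noPhi) {
    phi <- .tpMatmulT(tape, .tpMul(tape, eqeId, qrId), pid$Et)
    SId <- if (noGsp) phi else .tpScale(tape, phi, 1 - config$lambda)
  }
  if (!noGsp) {
    fv <- .tpMatmul(tape, repsId, pid$w)
    Sf <- .tpScatter(tape, fv, activeQ, activeNode, B, nV)
    if (noPhi) SId <- Sf
    else SId <- .tpAdd(tape, .tpScale(tape, Sf, config$lambda), SId)
  }

  lossVec <- .tpLogLoss(tape, SId, queries[, 3L])
  lossMean <- .tpMean(tape, lossVec)
  pw <- .regPower(config$regKind)
  eqaId <- .tpGather(tape, pid$Et, queries[, 3L])
  reg <- .tpAdd(tape, .tpAdd(tape, .tpAbsPowRowsum(tape, eqeId, pw),
                             .tpAbsPowRowsum(tape, qrId, pw)),
                .tpAbsPowRowsum(tape, eqaId, pw))
  total <- .tpAdd(tape, lossMean, .tpScale(tape, .tpMean(tape, reg), config$gamma))
  list(tape = tape, lossId = total, dataLossId = lossMean, paramIds = pid)
}

# Loss value and analytic gradients w.r.t. every trainable parameter.
.lossAndGrad <- function(kg, queries, params, config, mode = "train",
                         noiseSeed = NULL, maskQueryEdges = FALSE) {
  fw <- .tapeForward(kg, queries, params, config, mode = mode,
                     noiseSeed = noiseSeed, maskQueryEdges = maskQueryEdges)
  grads <- .tpBackward(fw$tape, fw$lossId)
  nms <- setdiff(names(params), .frozenParamNames)
  g <- stats::setNames(vector("list", length(nms)), nms)
  for (nm in nms) {
    gi <- grads[[fw$paramIds[[nm]]]]
    if (is.null(gi)) {
      gi <- params[[nm]]
      gi[] <- 0
    } else if (!is.matrix(params[[nm]])) {
      gi <- as.numeric(gi)
    }
    g[[nm]] <- gi
  }
  list(loss = as.numeric(.tpVal(fw$tape, fw$lossId)),
       dataLoss = as.numeric(.tpVal(fw$tape, fw$dataLossId)),
       grads = g)
}

# ---------------------------------------------------------------------------
# Adam optimizer (hand-rolled; standard bias-corrected first-order updates).

.adamNew <- function(params, names) {
  list(t = 0L,
       m = lapply(params[names], function(p) { p[] <- 0; p }),
       v = lapply(params[names], function(p) { p[] <- 0; p }))
}

# Scale the gradient set so its global L2 norm is at most `clip`.
.clipGrads <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (nrm > clip) grads <- lapply(grads, function(g) g * (clip / nrm))
  grads
}

.adamStep <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(state = state, params = params)
}

.withParams <- function(model, params) {
  model@params <- params
  model
}

#' Train the hybrid model
#'
#' Joint gradient-based optimization (Adam) of all parameters under the
#' composite loss: per-batch mean log-loss plus the weighted regularizer.
#' Each training query masks its own answer edge (and its inverse) from
#' expansion so the propagation branch must reason over paths rather than
#' copy the direct edge; optionally the inverse query of every training fact
#' is trained as well. Validation MRR is computed every `evalEvery` epochs
#' in deterministic infer mode; the best-validation parameters are restored
#' at the end, with early stopping after `patience` epochs without
#' improvement. Fully reproducible given `config$seed`.
#'
#' @param kg a [KnowledgeGraph-class] with a non-empty train split.
#' @param config a configuration from [kgConfig()].
#' @param quiet suppress per-evaluation progress messages.
#' @return a trained [KGModel-class]; `trainingLog(model)` holds the
#'   per-epoch loss and validation MRR.
#' @export
trainKGModel <- function(kg, config = kgConfig(), quiet = TRUE) {
  ts <- tripleSplit(kg, "train")
  if (!nrow(ts)) stop("train split is empty")
  model <- newKGModel(kg, config)
  params <- model@params
  queries <- ts
  if (config$inverseQueries) {
    n <- kg@nBaseRelations
    queries <- rbind(ts, cbind(ts[, 3L], ts[, 2L] + n, ts[, 1L]))
  }
  vs <- tripleSplit(kg, "valid")
  nQ <- nrow(queries)
  nms <- setdiff(names(params), .frozenParamNames)
  adam <- .adamNew(params, nms)

  # optional CP-only warm start
  if (config$warmupEpochs > 0L && !.hasFlag(config, "no_phi")) {
    cfgW <- config
    cfgW$ablation <- union(cfgW$ablation, "no_gsp")
    for (epoch in seq_len(config$warmupEpochs)) {
      perm <- .withSeed(.deriveSeed(config$seed, 500000L + epoch), sample(nQ))
      for (b in seq_len(ceiling(nQ / config$batchSize))) {
        idx <- perm[((b - 1L) * config$batchSize + 1L):min(b * config$batchSize, nQ)]
        lg <- .lossAndGrad(kg, queries[idx, , drop = FALSE], params, cfgW,
                           mode = "train",
                           noiseSeed = .deriveSeed(config$seed, epoch * 100000L + b),
                           maskQueryEdges = TRUE)
        upd <- .adamStep(adam, params, .clipGrads(lg$grads, config$clipNorm),
                         config$lr)
        adam <- upd$state; params <- upd$params
      }
    }
  }

  log <- data.frame(epoch = integer(0), loss = numeric(0), validMRR = numeric(0))
  best <- list(params = params, mrr = -Inf, epoch = 0L)
  lastImproved <- 0L

  for (epoch in seq_len(config$epochs)) {
    cfgE <- config
    frac <- if (config$epochs > 1L) (epoch - 1) / (config$epochs - 1) else 1
    if (!is.null(config$temperatureFinal))
      cfgE$tauNow <- config$temperature *
        (config$temperatureFinal / config$temperature)^frac
    if (!is.null(config$kStart))
      cfgE$K <- as.integer(round(config$kStart +
                                 (config$K - config$kStart) * frac))
    perm <- .withSeed(.deriveSeed(config$seed, 1000L + epoch), sample(nQ))
    epochLoss <- 0
    nb <- ceiling(nQ / config$batchSize)
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * config$batchSize + 1L):min(b * config$batchSize, nQ)]
      lg <- .lossAndGrad(kg, queries[idx, , drop = FALSE], params, cfgE,
                         mode = "train",
                         noiseSeed = .deriveSeed(config$seed, epoch * 100000L + b),
                         maskQueryEdges = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged at epoch %d, batch %d (non-finite loss)",
                     epoch, b))
      epochLoss <- epochLoss + lg$loss * length(idx)
      upd <- .adamStep(adam, params, .clipGrads(lg$grads, config$clipNorm),
                       config$lr)
      adam <- upd$state; params <- upd$params
    }
    epochLoss <- epochLoss / nQ

    vmrr <- NA_real_
    if (nrow(vs) && (epoch %% config$evalEvery == 0L || epoch == config$epochs)) {
      vres <- evaluateModel(.withParams(model, params), kg, queries = vs)
      vmrr <- vres@mrr
      if (!quiet)
        message(sprintf("epoch %3d  loss %.4f  valid MRR %.4f",
                        epoch, epochLoss, vmrr))
      if (vmrr > best$mrr + 1e-12) {
        best <- list(params = params, mrr = vmrr, epoch = epoch)
        lastImproved <- epoch
      } else if (epoch - lastImproved >= config$patience) {
        log <- rbind(log, data.frame(epoch = epoch, loss = epochLoss,
                                     validMRR = vmrr))
        break
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = epochLoss,
                                 validMRR = vmrr))
  }

  final <- if (is.finite(best$mrr)) best$params else params
  out <- .withParams(model, final)
  out@log <- log
  out
}

# ---------------------------------------------------------------------------
# Evaluation.

.rankingResult <- function(ranks) {
  ranks <- as.integer(ranks)
  new("RankingResult", ranks = ranks,
      mrr = if (length(ranks)) mean(1 / ranks) else NA_real_,
      hit1 = if (length(ranks)) mean(ranks <= 1L) else NA_real_,
      hit10 = if (length(ranks)) mean(ranks <= 10L) else NA_real_)
}

#' Filtered rank of the true answer
#'
#' Scores of all other known answers for the same (qe, qr) are set to -Inf,
#' then the answer is ranked pessimistically: competitors with equal scores
#' are counted ahead of it, so with all-equal scores and no other known
#' answers the rank equals the number of candidates.
#'
#' @param scores numeric score vector over all entities.
#' @param answer index of the true answer.
#' @param known integer vector of all known true answers for this query
#'   (must contain `answer`).
#' @return positive integer rank.
#' @export
filteredRank <- function(scores, answer, known) {
  if (!(answer %in% known)) stop("answer must be among the known answers")
  s <- scores
  s[setdiff(known, answer)] <- -Inf
  as.integer(sum(s >= s[answer]))
}

#' Filtered ranking evaluation over a query split
#'
#' Scores every query in deterministic infer mode, computes the filtered
#' rank of each answer, and aggregates MRR, Hit@1 and Hit@10.
#'
#' @param model a trained [KGModel-class].
#' @param kg a [KnowledgeGraph-class].
#' @param split `"train"`, `"valid"` or `"test"`.
#' @param queries optional integer query matrix overriding `split`.
#' @return a [RankingResult-class].
#' @export
evaluateModel <- function(model, kg, split = "test", queries = NULL) {
  q <- queries %||% tripleSplit(kg, split)
  if (!nrow(q)) stop("no queries to evaluate")
  ranks <- integer(nrow(q))
  for (i in seq_len(nrow(q))) {
    sc <- scoreAllEntities(model, kg, list(qe = q[i, 1L], qr = q[i, 2L]),
                           mode = "infer")
    ranks[i] <- filteredRank(sc, q[i, 3L], knownAnswers(kg, q[i, 1L], q[i, 2L]))
  }
  .rankingResult(ranks)
}
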