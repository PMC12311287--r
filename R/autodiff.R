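# Minimal eager reverse-mode tape over dense matrices, sized for the small
# graphs this package trains on. Each node stores its value, its parents and
# a backward closure returning the parents' gradient contributions. Values
# are numeric matrices (vectors allowed for bias leaves).

.tpNew <- function() {
  tape <- new.env(parent = emptyenv())
  tape$n <- 0L
  tape$vals <- vector("list", 256L)
  tape$parents <- vector("list", 256L)
  tape$backs <- vector("list", 256L)
  tape
}

.tpPush <- function(tape, val, parents = integer(0), back = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$vals)) {
    grow <- function(x) c(x, vector("list", length(x)))
    tape$vals <- grow(tape$vals)
    tape$parents <- grow(tape$parents)
    tape$backs <- grow(tape$backs)
  }
  tape$vals[[n]] <- val
  tape$parents[[n]] <- parents
  tape$backs[[n]] <- back
  tape$n <- n
  n
}

.tpVal <- function(tape, id) tape$vals[[id]]

# Leaf (parameter or constant) node.
.tpInput <- function(tape, val) .tpPush(tape, val)

.tpGather <- function(tape, a, idx) {
  force(a)
  A <- tape$vals[[a]]
  idx <- as.integer(idx)
  dimsA <- dim(A)
  .tpPush(tape, A[idx, , drop = FALSE], a, function(g) {
    G <- matrix(0, dimsA[1L], dimsA[2L])
    rs <- rowsum(g, group = idx)
    G[as.integer(rownames(rs)), ] <- rs
    list(G)
  })
}

.tpAdd <- function(tape, a, b) {
  force(a); force(b)
  .tpPush(tape, tape$vals[[a]] + tape$vals[[b]], c(a, b),
          function(g) list(g, g))
}

# Matrix plus a broadcast row vector (bias).
.tpAddVec <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]
  bv <- as.numeric(tape$vals[[b]])
  .tpPush(tape, sweep(A, 2L, bv, "+"), c(a, b),
          function(g) list(g, colSums(g)))
}

.tpMul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  .tpPush(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

.tpMatmul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  .tpPush(tape, A %*% B, c(a, b),
          function(g) list(g %*% t(B), crossprod(A, g)))
}

# A %*% t(W): the usual orientation for row-major batches of embeddings.
.tpMatmulT <- function(tape, a, w) {
  force(a); force(w)
  A <- tape$vals[[a]]; W <- tape$vals[[w]]
  .tpPush(tape, A %*% t(W), c(a, w),
          function(g) list(g %*% W, crossprod(g, A)))
}

.tpTanh <- function(tape, a) {
  force(a)
  V <- tanh(tape$vals[[a]])
  .tpPush(tape, V, a, function(g) list(g * (1 - V * V)))
}

.tpSigmoid <- function(tape, a) {
  force(a)
  V <- .sigmoid(tape$vals[[a]])
  .tpPush(tape, V, a, function(g) list(g * V * (1 - V)))
}

.tpRelu <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  .tpPush(tape, .relu(A), a, function(g) list(g * (A > 0)))
}

# Scale rows of A by a column vector s (n x 1).
.tpColScale <- function(tape, a, s) {
  force(a); force(s)
  A <- tape$vals[[a]]; sv <- as.numeric(tape$vals[[s]])
  .tpPush(tape, A * sv, c(a, s),
          function(g) list(g * sv, matrix(rowSums(g * A), ncol = 1L)))
}

# Group-sum of rows; `group` must take every value in 1..ngroups so the
# result rows are ordered 1..ngroups.
.tpRowsumBy <- function(tape, a, group, ngroups) {
  force(a)
  A <- tape$vals[[a]]
  group <- as.integer(group)
  V <- rowsum(A, group = group)
  stopifnot(nrow(V) == ngroups)
  .tpPush(tape, V, a, function(g) list(g[group, , drop = FALSE]))
}

# Scatter a column vector into a zero (nr x nc) matrix at (rows, cols);
# (rows, cols) pairs must be unique.
.tpScatter <- function(tape, a, rows, cols, nr, nc) {
  force(a)
  av <- as.numeric(tape$vals[[a]])
  V <- matrix(0, nr, nc)
  V[cbind(rows, cols)] <- av
  .tpPush(tape, V, a,
          function(g) list(matrix(g[cbind(rows, cols)], ncol = 1L)))
}

.tpScale <- function(tape, a, k) {
  force(a)
  .tpPush(tape, k * tape$vals[[a]], a, function(g) list(k * g))
}

.tpMean <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  n <- length(A)
  .tpPush(tape, matrix(mean(A), 1L, 1L), a,
          function(g) list(matrix(as.numeric(g) / n, nrow(A), ncol(A))))
}

# Per-row multi-class log-loss with a numerically stable log-sum-exp:
# loss_i = -S[i, ans_i] + log(sum_t exp(S[i, t])).
.tpLogLoss <- function(tape, s, answers) {
  force(s)
  S <- tape$vals[[s]]
  answers <- as.integer(answers)
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  loss <- lse - S[cbind(seq_along(answers), answers)]
  .tpPush(tape, matrix(loss, ncol = 1L), s, function(g) {
    P <- exp(S - lse)
    dS <- P * as.numeric(g)
    dS[cbind(seq_along(answers), answers)] <-
      dS[cbind(seq_along(answers), answers)] - as.numeric(g)
    list(dS)
  })
}

# Row sums of |A|^p (regularizer rows).
.tpAbsPowRowsum <- function(tape, a, p) {
  force(a)
  A <- tape$vals[[a]]
  .tpPush(tape, matrix(rowSums(abs(A)^p), ncol = 1L), a, function(g) {
    list((p * abs(A)^(p - 1) * sign(A)) * as.numeric(g))
  })
}

# Straight-through top-K gate: forward is a column of ones (hard selection
# already applied via gather); backward routes the gate gradient to the
# candidate scores through the soft relaxation recorded in `steps` (one
# entry per selection: candidate rows still in the running, softmax
# probabilities over them, the chosen row, and the gate row it feeds).
.tpStGate <- function(tape, s, steps, nSel, nCand) {
  force(s); force(steps); force(nSel); force(nCand)
  .tpPush(tape, matrix(1, nSel, 1L), s, function(g) {
    ds <- numeric(nCand)
    gv <- as.numeric(g)
    for (st in steps) {
      u <- gv[st$gateRow]
      psel <- st$p[st$selPos]
      contrib <- -u * psel * st$p
      contrib[st$selPos] <- contrib[st$selPos] + u * psel
      ds[st$rows] <- ds[st$rows] + contrib
    }
    list(matrix(ds, ncol = 1L))
  })
}

# Stack node values by rows; backward splits the gradient by row ranges.
.tpRbind <- function(tape, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tape$vals[[i]])
  counts <- vapply(vals, nrow, 0L)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  .tpPush(tape, do.call(rbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(j)
      g[starts[j] + seq_len(counts[j]) - 1L, , drop = FALSE])
  })
}

# Fused gated-cell (zero-cell LSTM) step: out = o * tanh(i * ctil) with
# i = sigmoid(X Wi' + H Ui' + bi), o = sigmoid(X Wo' + H Uo' + bo),
# ctil = tanh(X Wc' + H Uc' + bc). One tape node with a hand-derived
# backward replaces ~20 elementary nodes per application.
.tpLstm <- function(tape, x, h, wi, ui, bi, wo, uo, bo, wc, uc, bc) {
  force(x); force(h)
  X <- tape$vals[[x]]; H <- tape$vals[[h]]
  Wi <- tape$vals[[wi]]; Ui <- tape$vals[[ui]]
  Wo <- tape$vals[[wo]]; Uo <- tape$vals[[uo]]
  Wc <- tape$vals[[wc]]; Uc <- tape$vals[[uc]]
  n <- nrow(X)
  bias <- function(b) matrix(tape$vals[[b]], n, ncol(X), byrow = TRUE)
  i <- 1 / (1 + exp(-(X %*% t(Wi) + H %*% t(Ui) + bias(bi))))
  o <- 1 / (1 + exp(-(X %*% t(Wo) + H %*% t(Uo) + bias(bo))))
  ctil <- tanh(X %*% t(Wc) + H %*% t(Uc) + bias(bc))
  tc <- tanh(i * ctil)
  out <- o * tc
  .tpPush(tape, out, c(x, h, wi, ui, bi, wo, uo, bo, wc, uc, bc),
          function(g) {
            do <- g * tc
            dc <- g * o * (1 - tc * tc)
            di <- dc * ctil
            dctil <- dc * i
            dzi <- di * i * (1 - i)
            dzo <- do * o * (1 - o)
            dzc <- dctil * (1 - ctil * ctil)
            list(dzi %*% Wi + dzo %*% Wo + dzc %*% Wc,
                 dzi %*% Ui + dzo %*% Uo + dzc %*% Uc,
                 crossprod(dzi, X), crossprod(dzi, H), colSums(dzi),
                 crossprod(dzo, X), crossprod(dzo, H), colSums(dzo),
                 crossprod(dzc, X), crossprod(dzc, H), colSums(dzc))
          })
}

.tpBackward <- function(tape, id) {
  grads <- vector("list", tape$n)
  grads[[id]] <- matrix(1, 1L, 1L)
  for (i in seq.int(id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    back <- tape$backs[[i]]
    if (is.null(back)) next
    pg <- back(g)
    ps <- tape$parents[[i]]
    for (j in seq_along(ps)) {
      if (is.null(pg[[j]])) next
      k <- ps[j]
      grads[[k]] <- if (is.null(grads[[k]])) pg[[j]] else grads[[k]] + pg[[j]]
    }
  }
  grads
}
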