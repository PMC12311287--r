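#' Specification of a synthetic knowledge graph
#'
#' Two generator regimes share this spec: a planted low-rank CP tensor
#' (exercising the semantic branch) and compositional multi-hop relation
#' rules (exercising the propagation branch). Entity names carry
#' biomedical-style prefixes (DIS_/GEN_/CHEM_), purely cosmetically, to
#' exercise heterogeneous-looking vocabularies.
#'
#' @param nEntities number of entities.
#' @param nBaseRelations number of base relations.
#' @param cpRank rank of the planted CP factors (CP regime).
#' @param ruleSet list of rules, each `list(head = r, body = c(r1, r2, ...))`
#'   with body length 1-3 (rule regime).
#' @param density expected generated facts per entity (CP: emitted facts;
#'   rule: sampled body facts).
#' @param noiseRate fraction (of the generated facts) of spurious uniformly
#'   random facts injected, in `[0, 1)`.
#' @param splitFractions named numeric vector (train, valid, test), positive,
#'   summing to 1.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return a spec list (class `"syntheticSpec"`).
#' @export
syntheticSpec <- function(nEntities = 50L, nBaseRelations = 3L, cpRank = 4L,
                          ruleSet = list(list(head = 3L, body = c(1L, 2L))),
                          density = 8, noiseRate = 0.05,
                          splitFractions = c(train = 0.8, valid = 0.05,
                                             test = 0.15),
                          seed = 7L) {
  if (any(splitFractions <= 0) || abs(sum(splitFractions) - 1) > 1e-9)
    stop("split fractions must be positive and sum to 1")
  if (noiseRate < 0 || noiseRate >= 1) stop("noiseRate must lie in [0, 1)")
  for (rule in ruleSet) {
    if (!length(rule$body) %in% 1:3)
      stop("rule body length must be 1, 2 or 3")
    if (any(c(rule$head, rule$body) > nBaseRelations))
      stop("rule references unknown relation")
  }
  structure(list(nEntities = as.integer(nEntities),
                 nBaseRelations = as.integer(nBaseRelations),
                 cpRank = as.integer(cpRank), ruleSet = ruleSet,
                 density = density, noiseRate = noiseRate,
                 splitFractions = splitFractions, seed = as.integer(seed)),
            class = "syntheticSpec")
}

.entityNamesFor <- function(n) {
  prefix <- c("DIS", "GEN", "CHEM")[(seq_len(n) - 1L) %% 3L + 1L]
  sprintf("%s_%04d", prefix, seq_len(n))
}

.relationNamesFor <- function(n) sprintf("rel_%02d", seq_len(n))

.toNamed <- function(m, ents, rels) {
  data.frame(head = ents[m[, 1L]], relation = rels[m[, 2L]],
             tail = ents[m[, 3L]], stringsAsFactors = FALSE)
}

# Shuffle rows and split by fractions (train gets the remainder).
.splitRows <- function(n, fractions) {
  idx <- sample(n)
  nv <- floor(fractions[["valid"]] * n)
  nt <- floor(fractions[["test"]] * n)
  list(valid = idx[seq_len(nv)],
       test = idx[nv + seq_len(nt)],
       train = idx[-seq_len(nv + nt)])
}

#' Generate a knowledge graph with planted low-rank CP structure
#'
#' Factor matrices of rank `cpRank` are drawn from a seeded standard normal;
#' the triple (h, r, t) is emitted exactly when its planted trilinear score
#' exceeds the quantile threshold that yields `density * nEntities` facts.
#' The emitted facts are split into train/valid/test by the spec fractions.
#'
#' @param spec a [syntheticSpec()].
#' @return list with character-triple data.frames `train`, `valid`, `test`,
#'   an empty `facts` background set, the `planted` factors and threshold,
#'   and the `spec`.
#' @export
generateCpKG <- function(spec) {
  if (spec$cpRank < 1L) stop("cpRank must be at least 1")
  nV <- spec$nEntities; nR <- spec$nBaseRelations; rk <- spec$cpRank
  target <- round(spec$density * nV)
  total <- as.double(nV) * nR * nV
  if (target > total)
    stop("density unreachable: graph too small for ", target, " facts")
  .withSeed(spec$seed, {
    A <- matrix(stats::rnorm(nV * rk), nV, rk)
    R <- matrix(stats::rnorm(nR * rk), nR, rk)
    Bm <- matrix(stats::rnorm(nV * rk), nV, rk)
    # scores for all (h, r, t), h-major then r then t
    sc <- numeric(total)
    pos <- 0L
    for (r in seq_len(nR)) {
      S <- (A * matrix(R[r, ], nV, rk, byrow = TRUE)) %*% t(Bm)
      sc[pos + seq_len(nV * nV)] <- as.numeric(t(S))  # (h, t) pairs, h-major
      pos <- pos + nV * nV
    }
    thr <- if (target == total) -Inf
           else stats::quantile(sc, probs = 1 - target / total, names = FALSE,
                                type = 1L)
    keep <- which(sc > thr)
    r <- (keep - 1L) %/% (nV * nV) + 1L
    rem <- (keep - 1L) %% (nV * nV)
    h <- rem %/% nV + 1L
    t <- rem %% nV + 1L
    m <- cbind(h, r, t)
    ents <- .entityNamesFor(nV); rels <- .relationNamesFor(nR)
    sp <- .splitRows(nrow(m), spec$splitFractions)
    list(train = .toNamed(m[sp$train, , drop = FALSE], ents, rels),
         valid = .toNamed(m[sp$valid, , drop = FALSE], ents, rels),
         test = .toNamed(m[sp$test, , drop = FALSE], ents, rels),
         facts = .toNamed(.emptyTriples(), ents, rels),
         planted = list(A = A, R = R, B = Bm, threshold = thr),
         spec = spec)
  })
}

# Sample `count` distinct (h, t) pairs with h != t.
.sampleEdges <- function(nV, count) {
  got <- .emptyTriples()[, c(1L, 3L), drop = FALSE]
  seen <- double(0)
  while (nrow(got) < count) {
    need <- (count - nrow(got)) * 2L
    h <- sample.int(nV, need, replace = TRUE)
    t <- sample.int(nV, need, replace = TRUE)
    ok <- h != t
    key <- (as.double(h) - 1) * nV + t
    fresh <- ok & !duplicated(key) & !(key %in% seen)
    got <- rbind(got, cbind(h[fresh], t[fresh]))
    seen <- c(seen, key[fresh])
  }
  got[seq_len(count), , drop = FALSE]
}

#' Generate a knowledge graph with compositional multi-hop rules
#'
#' Random base facts are sampled for every relation appearing in a rule
#' body; every rule-head triple implied by composing body facts is
#' materialized. A seeded random fraction of the rule-head triples (the
#' valid and test fractions of the spec) is held out as evaluation queries
#' and removed from the graph; the remainder becomes the training queries.
#' Spurious uniformly random facts are injected at `noiseRate` (never
#' colliding with held-out triples, so evaluation queries stay unleaked).
#' Body and noise facts are returned as background facts.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `train`, `valid`, `test` (rule-head query splits),
#'   `facts` (body + noise background facts), `heldOut` (valid + test
#'   triples), and the `spec`.
#' @export
generateRuleKG <- function(spec) {
  nV <- spec$nEntities
  bodyRels <- sort(unique(unlist(lapply(spec$ruleSet, `[[`, "body"))))
  if (!length(bodyRels)) {
    # pure-noise KG: no rules, no held-out triples
    return(.withSeed(spec$seed, {
      nNoise <- round(spec$noiseRate * spec$density * nV)
      ents <- .entityNamesFor(nV); rels <- .relationNamesFor(spec$nBaseRelations)
      e <- .sampleEdges(nV, nNoise)
      noise <- cbind(e[, 1L], sample.int(spec$nBaseRelations, nNoise,
                                         replace = TRUE), e[, 2L])
      empty <- .toNamed(.emptyTriples(), ents, rels)
      list(train = empty, valid = empty, test = empty,
           facts = .toNamed(.asTripleMatrix(noise), ents, rels),
           heldOut = empty, spec = spec)
    }))
  }
  .withSeed(spec$seed, {
    perRel <- round(spec$density * nV / length(bodyRels))
    body <- do.call(rbind, lapply(bodyRels, function(r) {
      e <- .sampleEdges(nV, perRel)
      cbind(e[, 1L], r, e[, 2L])
    }))
    body <- .asTripleMatrix(body)

    # materialize rule heads by composing body facts along each rule body
    heads <- list()
    for (rule in spec$ruleSet) {
      pairs <- body[body[, 2L] == rule$body[1L], c(1L, 3L), drop = FALSE]
      for (r in rule$body[-1L]) {
        nxt <- body[body[, 2L] == r, c(1L, 3L), drop = FALSE]
        hits <- merge(data.frame(a = pairs[, 1L], b = pairs[, 2L]),
                      data.frame(b = nxt[, 1L], c = nxt[, 2L]), by = "b")
        pairs <- as.matrix(hits[, c("a", "c")])
      }
      if (nrow(pairs)) heads[[length(heads) + 1L]] <-
          cbind(pairs[, 1L], rule$head, pairs[, 2L])
    }
    heads <- unique(.asTripleMatrix(do.call(rbind, heads)))
    ord <- order(heads[, 1L], heads[, 2L], heads[, 3L])
    heads <- heads[ord, , drop = FALSE]

    sp <- .splitRows(nrow(heads), spec$splitFractions)
    heldKeys <- .tripleKey(heads[c(sp$valid, sp$test), , drop = FALSE],
                           nV, spec$nBaseRelations)
    bodyKeys <- .tripleKey(body, nV, spec$nBaseRelations)

    nNoise <- round(spec$noiseRate * (nrow(body) + nrow(heads)))
    noise <- .emptyTriples()
    if (nNoise > 0L) {
      bad <- c(heldKeys, bodyKeys)
      while (nrow(noise) < nNoise) {
        need <- (nNoise - nrow(noise)) * 2L
        cand <- cbind(sample.int(nV, need, replace = TRUE),
                      sample.int(spec$nBaseRelations, need, replace = TRUE),
                      sample.int(nV, need, replace = TRUE))
        keys <- .tripleKey(cand, nV, spec$nBaseRelations)
        keep <- !(keys %in% bad) & !duplicated(keys) & cand[, 1L] != cand[, 3L]
        noise <- rbind(noise, cand[keep, , drop = FALSE])
        bad <- c(bad, keys[keep])
      }
      noise <- .asTripleMatrix(noise[seq_len(nNoise), , drop = FALSE])
    }

    ents <- .entityNamesFor(nV); rels <- .relationNamesFor(spec$nBaseRelations)
    list(train = .toNamed(heads[sp$train, , drop = FALSE], ents, rels),
         valid = .toNamed(heads[sp$valid, , drop = FALSE], ents, rels),
         test = .toNamed(heads[sp$test, , drop = FALSE], ents, rels),
         facts = .toNamed(rbind(body, noise), ents, rels),
         heldOut = .toNamed(heads[c(sp$valid, sp$test), , drop = FALSE],
                            ents, rels),
         spec = spec)
  })
}

#' Write a generated knowledge graph as split files
#'
#' Emits `train.txt`, `valid.txt`, `test.txt` and `facts.txt` in the
#' tab-separated triple dialect plus a `manifest.json` recording the spec,
#' seed, per-file counts, and the relation-index layout. Output is
#' byte-identical across runs for the same spec.
#'
#' @param gen result of [generateCpKG()] or [generateRuleKG()].
#' @param outDir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
writeSplits <- function(gen, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("train", "valid", "test", "facts"))
    writeTriples(gen[[f]], file.path(outDir, paste0(f, ".txt")))
  spec <- gen$spec
  manifest <- list(
    spec = list(nEntities = spec$nEntities,
                nBaseRelations = spec$nBaseRelations, cpRank = spec$cpRank,
                ruleSet = lapply(spec$ruleSet, function(r)
                  list(head = r$head, body = as.integer(r$body))),
                density = spec$density, noiseRate = spec$noiseRate,
                splitFractions = as.list(spec$splitFractions),
                seed = spec$seed),
    counts = list(train = nrow(gen$train), valid = nrow(gen$valid),
                  test = nrow(gen$test), facts = nrow(gen$facts)),
    relationLayout = "base 1..n, inverse n+1..2n, identity 2n+1 (1-based)")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
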