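#' Read tab-separated triples
#'
#' Reads a plain-text triple file: UTF-8, one `head<TAB>relation<TAB>tail`
#' per line, no header. Empty lines are skipped; triples are returned in file
#' order without deduplication.
#'
#' @param path path to the file.
#' @return a data.frame with character columns `head`, `relation`, `tail`.
#' @examples
#' f <- tempfile()
#' writeLines("D1\tdisease_gene\tG7", f)
#' readTriples(f)
#' @export
readTriples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(keep)[which(nf != 3L)[1L]]
    stop(sprintf("parse error at line %d of %s: expected 3 tab-separated fields, got %d",
                 bad, path, nf[nf != 3L][1L]))
  }
  if (!length(fields))
    return(data.frame(head = character(0), relation = character(0),
                      tail = character(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, fields)
  data.frame(head = m[, 1L], relation = m[, 2L], tail = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Write triples as a tab-separated file
#'
#' Inverse of [readTriples()]; writes UTF-8, LF line endings, no header.
#'
#' @param triples data.frame with columns `head`, `relation`, `tail`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeTriples <- function(triples, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(triples))
    writeLines(paste(triples$head, triples$relation, triples$tail, sep = "\t"),
               con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Build an entity/relation vocabulary from raw triples
#'
#' Entities are the sorted union of heads and tails, base relations the
#' sorted unique relation strings (radix/byte order, so the result is
#' locale-independent and deterministic given the input).
#'
#' @param rawTriples data.frame of character triples (as from
#'   [readTriples()]), or a list of such data.frames whose union is used.
#' @return a [Vocabulary-class].
#' @export
buildVocab <- function(rawTriples) {
  if (is.data.frame(rawTriples)) rawTriples <- list(rawTriples)
  ents <- .radixSort(unique(unlist(lapply(rawTriples,
                                          function(d) c(d$head, d$tail)))))
  rels <- .radixSort(unique(unlist(lapply(rawTriples,
                                          function(d) d$relation))))
  new("Vocabulary", entities = as.character(ents), relations = as.character(rels))
}

# Resolve string triples to an integer triple matrix against a vocabulary.
.resolveTriples <- function(triples, vocab) {
  if (!nrow(triples)) return(.emptyTriples())
  h <- match(triples$head, vocab@entities)
  r <- match(triples$relation, vocab@relations)
  t <- match(triples$tail, vocab@entities)
  if (anyNA(h) || anyNA(t)) {
    bad <- unique(c(triples$head[is.na(h)], triples$tail[is.na(t)]))
    stop("unknown entity name(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyNA(r))
    stop("unknown relation name(s): ",
         paste(utils::head(unique(triples$relation[is.na(r)]), 5L), collapse = ", "))
  .asTripleMatrix(cbind(h, r, t))
}

# Build the sorted fact matrix + per-head row index from base facts.
.indexFacts <- function(facts, nV) {
  ord <- order(facts[, 1L], facts[, 2L], facts[, 3L])
  facts <- facts[ord, , drop = FALSE]
  cnt <- tabulate(facts[, 1L], nbins = nV)
  end <- cumsum(cnt)
  start <- end - cnt + 1L
  list(facts = .asTripleMatrix(facts),
       headIndex = list(start = as.integer(start), end = as.integer(end)))
}

#' Augment raw facts with reverse and identity relations
#'
#' For every (deduplicated) base fact (h, r, t), the inverse fact
#' (t, r_inv, h) is added; every entity receives one identity self-loop.
#' Relation indices: base `1..n`, inverse `n+1..2n`, identity `2n+1`. The
#' augmented fact count is `2 * #unique base facts + |V|`.
#'
#' @param rawFacts data.frame of character triples forming the graph
#'   structure.
#' @param vocab a [Vocabulary-class] resolving all names in `rawFacts`.
#' @param splits optional named list of character triple data.frames
#'   (`train`, `valid`, `test`) stored as query splits (base relations).
#' @return a [KnowledgeGraph-class].
#' @examples
#' v <- buildVocab(data.frame(head = "a", relation = "r", tail = "b"))
#' kg <- augmentGraph(data.frame(head = "a", relation = "r", tail = "b"), v)
#' nrow(kg@facts)  # 1 base + 1 inverse + 2 identity loops = 4
#' @export
augmentGraph <- function(rawFacts, vocab, splits = list()) {
  n <- length(vocab@relations)
  nV <- length(vocab@entities)
  base <- .resolveTriples(rawFacts, vocab)
  base <- unique(base)
  inv <- if (nrow(base)) cbind(base[, 3L], base[, 2L] + n, base[, 1L])
         else .emptyTriples()
  ident <- cbind(seq_len(nV), rep(2L * n + 1L, nV), seq_len(nV))
  all <- .asTripleMatrix(rbind(base, .asTripleMatrix(inv), .asTripleMatrix(ident)))
  ix <- .indexFacts(all, nV)
  new("KnowledgeGraph", vocab = vocab, nBaseRelations = as.integer(n),
      facts = ix$facts, headIndex = ix$headIndex,
      splits = lapply(splits, .resolveTriples, vocab = vocab))
}

#' Load a knowledge graph from a split directory
#'
#' Expects `train.txt`, `valid.txt`, `test.txt` and optionally `facts.txt`
#' (background facts that shape the graph but are not training queries) in
#' the tab-separated dialect of [readTriples()]. The vocabulary is built from
#' the union of all files (transductive setting), and the augmented graph
#' structure is formed from the training triples plus background facts;
#' validation and test triples enter only as query splits.
#'
#' @param dir directory containing the split files.
#' @return a [KnowledgeGraph-class].
#' @export
loadKnowledgeGraph <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readTriples(p)
    else data.frame(head = character(0), relation = character(0),
                    tail = character(0), stringsAsFactors = FALSE)
  }
  train <- rd("train.txt"); valid <- rd("valid.txt"); test <- rd("test.txt")
  facts <- rd("facts.txt")
  vocab <- buildVocab(list(train, valid, test, facts))
  augmentGraph(rbind(train, facts), vocab,
               splits = list(train = train, valid = valid, test = test))
}

#' Outgoing edges of a node set
#'
#' Returns exactly the augmented facts whose head lies in `nodes`, sorted by
#' (head, relation, tail).
#'
#' @param kg a [KnowledgeGraph-class].
#' @param nodes integer vector of entity indices.
#' @return integer triple matrix.
#' @export
outgoingEdges <- function(kg, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) && (min(nodes) < 1L || max(nodes) > numEntities(kg)))
    stop("node index out of range")
  if (!length(nodes)) return(.emptyTriples())
  st <- kg@headIndex$start[nodes]
  en <- kg@headIndex$end[nodes]
  keep <- st <= en
  if (!any(keep)) return(.emptyTriples())
  rows <- sequence(en[keep] - st[keep] + 1L, from = st[keep])
  kg@facts[rows, , drop = FALSE]
}

#' Known answers of a query for filtered ranking
#'
#' All entities `t` such that the triple (qe, qr, t) is true in any of the
#' train/valid/test splits. For an inverse relation `qr` the base splits are
#' searched in the reverse direction; for the identity relation the answer is
#' the query entity itself.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param qe query entity index.
#' @param qr query relation index (augmented layout).
#' @return sorted integer vector of entity indices.
#' @export
knownAnswers <- function(kg, qe, qr) {
  n <- kg@nBaseRelations
  if (qr == 2L * n + 1L) return(as.integer(qe))
  ans <- integer(0)
  for (s in kg@splits) {
    if (!nrow(s)) next
    if (qr <= n) {
      ans <- c(ans, s[s[, 1L] == qe & s[, 2L] == qr, 3L])
    } else {
      ans <- c(ans, s[s[, 3L] == qe & s[, 2L] == qr - n, 1L])
    }
  }
  sort(unique(as.integer(ans)))
}
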