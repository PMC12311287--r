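# Small fixtures built in code, shared across test files.

# A tiny named-triple data.frame.
tinyTriples <- function() {
  data.frame(head = c("D1", "D1", "G2", "G2", "C3"),
             relation = c("disease_gene", "disease_gene", "gene_chem",
                          "gene_chem", "chem_dis"),
             tail = c("G1", "G2", "C3", "C4", "D2"),
             stringsAsFactors = FALSE)
}

# A random base-fact set over nV entities and nR relations (no self-loops,
# deduplicated), as a named-triple data.frame.
randomTriples <- function(nV, nR, nFacts, seed) {
  set.seed(seed)
  ents <- sprintf("e%02d", seq_len(nV))
  rels <- sprintf("r%d", seq_len(nR))
  h <- sample.int(nV, nFacts * 3L, replace = TRUE)
  t <- sample.int(nV, nFacts * 3L, replace = TRUE)
  r <- sample.int(nR, nFacts * 3L, replace = TRUE)
  keep <- which(h != t)
  keep <- keep[!duplicated(cbind(h, r, t)[keep, , drop = FALSE])]
  keep <- keep[seq_len(min(nFacts, length(keep)))]
  data.frame(head = ents[h[keep]], relation = rels[r[keep]],
             tail = ents[t[keep]], stringsAsFactors = FALSE)
}

# A random augmented KnowledgeGraph whose train split is its own base facts.
randomKG <- function(nV = 12, nR = 2, nFacts = 30, seed = 1) {
  tr <- randomTriples(nV, nR, nFacts, seed)
  v <- buildVocab(tr)
  augmentGraph(tr, v, splits = list(train = tr))
}

# A small chain graph a -r-> b -r-> c -r-> d.
chainKG <- function() {
  tr <- data.frame(head = c("a", "b", "c"), relation = "r",
                   tail = c("b", "c", "d"), stringsAsFactors = FALSE)
  augmentGraph(tr, buildVocab(tr), splits = list(train = tr))
}

# An untrained model over a KG with reproducible parameters.
tinyModel <- function(kg, D = 4, nLayers = 2, K = 50, seed = 9, ...) {
  cfg <- kgConfig(D = D, nLayers = nLayers, K = K, seed = seed,
                  initScale = 0.3, ...)
  newKGModel(kg, cfg)
}

withAblation <- function(model, variant) {
  cfg <- applyAblation(model@config, variant)
  m <- newKGModel2(model, cfg)
  m
}

# Rebuild a model keeping dims but replacing config (re-inits params so
# random_query gains its frozen matrices).
newKGModel2 <- function(model, cfg) {
  p <- kgfusion:::.initParams(model@dims$nV, model@dims$nR, cfg)
  for (nm in intersect(names(p), names(model@params)))
    p[[nm]] <- model@params[[nm]]
  methods::new("KGModel", params = p, config = cfg, dims = model@dims,
               log = model@log)
}

# helper: all permutations of a vector (small n only)
combinat_perms <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- combinat_perms(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
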