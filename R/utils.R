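# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.radixSort <- function(x) sort(x, method = "radix")

.relu <- function(x) x * (x > 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. With seed = NULL, evaluates as-is.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic derived seeds, kept inside the 32-bit integer range.
.deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

# Encode integer triples as scalar keys for set operations (exact for the
# graph sizes this package targets: doubles are exact below 2^53).
.tripleKey <- function(f, nV, nR) {
  (as.double(f[, 1L]) - 1) * nR * nV + (as.double(f[, 2L]) - 1) * nV +
    as.double(f[, 3L])
}

.gumbel <- function(n) -log(-log(stats::runif(n)))

.emptyTriples <- function() {
  matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("head", "relation", "tail")))
}

.asTripleMatrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  colnames(m) <- c("head", "relation", "tail")
  m
}
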