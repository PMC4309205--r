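# Internal helpers shared across modules: mixed-radix state indexing,
# deterministic level grids, and scoped RNG.

# Mixed-radix weights for a vector of cardinalities (first position varies
# fastest, matching level_grid()).
mr_weights <- function(card) {
  if (length(card) == 0L) return(numeric(0))
  cumprod(c(1, card[-length(card)]))
}

# 1-based index of a level assignment (vector or row matrix) in the grid
# defined by `card`.
mr_index <- function(levels, card) {
  w <- mr_weights(card)
  if (is.matrix(levels)) {
    if (ncol(levels) == 0L) return(rep(1L, nrow(levels)))
    as.integer(round(levels %*% w)) + 1L
  } else {
    if (length(levels) == 0L) return(1L)
    as.integer(round(sum(levels * w))) + 1L
  }
}

# All level combinations for cardinalities `card`, one row per combination,
# first column varying fastest.  Zero variables yield the single empty
# assignment (one row, zero columns).
level_grid <- function(card, names = NULL) {
  if (length(card) == 0L) {
    g <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    g <- as.matrix(expand.grid(lapply(card, function(k) 0:(k - 1L)),
                               KEEP.OUT.ATTRS = FALSE))
    storage.mode(g) <- "integer"
  }
  if (!is.null(names)) colnames(g) <- names else colnames(g) <- NULL
  rownames(g) <- NULL
  g
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_guard <- function(msg) {
  stop(structure(class = c("logimc_guard_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_parse <- function(msg) {
  stop(structure(class = c("logimc_parse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
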