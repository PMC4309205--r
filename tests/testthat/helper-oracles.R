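# Independent brute-force oracles.  These deliberately avoid the package's
# algorithmic paths: stable states by full-grid sweep, reachability by
# Warshall closure on explicit adjacency matrices, attractors by mutual
# reachability, ARCTL by matrix reachability / cycle detection rather than
# fixpoint iteration.

ocard <- function(model) setNames(model$components$max_level + 1L,
                                  model$components$name)

ogrid <- function(card) {
  if (length(card) == 0L) {
    m <- matrix(integer(0), nrow = 1L, ncol = 0L)
    return(m)
  }
  g <- as.matrix(expand.grid(lapply(card, function(k) 0:(k - 1L)),
                             KEEP.OUT.ATTRS = FALSE))
  storage.mode(g) <- "integer"
  colnames(g) <- names(card)
  g
}

# All full stable states (internal + inputs), one row per state.
oracle_stable_states <- function(model) {
  card <- ocard(model)
  g <- ogrid(card)
  internal <- model$components$name[!model$components$is_input]
  ok <- rep(TRUE, nrow(g))
  for (nm in internal)
    ok <- ok & eval_rule(model$rules[[nm]], g) == g[, nm]
  g[ok, , drop = FALSE]
}

# Boolean reflexive-transitive closure by repeated squaring.
oclosure <- function(A) {
  n <- nrow(A)
  R <- A | diag(n) > 0
  repeat {
    R2 <- R | (R %*% R) > 0
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

# Asynchronous adjacency matrix over the full internal grid for one fixed
# input valuation (unit-step updating recomputed from the rules).
oracle_adjacency <- function(model, inputs) {
  internal <- model$components$name[!model$components$is_input]
  card <- ocard(model)[internal]
  g <- ogrid(card)
  n <- nrow(g)
  key <- apply(g, 1L, paste, collapse = ",")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    full <- c(g[i, ], inputs)
    for (nm in internal) {
      tgt <- eval_rule(model$rules[[nm]], full)
      if (tgt != full[[nm]]) {
        s2 <- g[i, ]
        s2[nm] <- s2[nm] + sign(tgt - full[[nm]])
        adj[i, match(paste(s2, collapse = ","), key)] <- TRUE
      }
    }
  }
  list(states = g, adj = adj)
}

# Attractors (terminal SCCs) from an adjacency matrix; returns a sorted list
# of sorted state-row index vectors.
oracle_terminal_scc <- function(adj) {
  R <- oclosure(adj)
  n <- nrow(adj)
  mutual <- R & t(R)
  seen <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    scc <- which(mutual[i, ])
    seen[scc] <- TRUE
    succ <- which(colSums(adj[scc, , drop = FALSE]) > 0)
    if (all(succ %in% scc)) out[[length(out) + 1L]] <- sort(scc)
  }
  out[order(vapply(out, `[`, integer(1), 1L))]
}

# Per-valuation adjacency matrices for the labeled transition system.
oracle_lts_adjs <- function(model) {
  ins <- model$components$name[model$components$is_input]
  card_in <- ocard(model)[ins]
  vals <- ogrid(card_in)
  lapply(seq_len(nrow(vals)), function(j) {
    v <- if (length(ins)) setNames(vals[j, ], ins) else integer(0)
    oracle_adjacency(model, v)$adj
  })
}

o_union_adj <- function(adjs, alpha_vec) {
  keep <- which(alpha_vec)
  if (length(keep) == 0L)
    return(matrix(FALSE, nrow(adjs[[1]]), ncol(adjs[[1]])))
  Reduce(`|`, adjs[keep])
}

# EAF(alpha)(phi): states reaching a phi-state through alpha-edges
# (zero-length paths count).
oracle_EAF <- function(adjs, alpha_vec, phi) {
  A <- o_union_adj(adjs, alpha_vec)
  drop(oclosure(A) %*% phi) > 0
}

# EAG(alpha)(phi): a maximal alpha-path staying in phi — either reaches an
# alpha-deadlock inside phi or a cycle inside phi.
oracle_EAG <- function(adjs, alpha_vec, phi) {
  A <- o_union_adj(adjs, alpha_vec)
  H <- A & outer(phi, phi, `&`)
  RH <- oclosure(H)
  dead <- rowSums(A) == 0
  on_cycle <- diag(H %*% RH) > 0
  good <- phi & (dead | on_cycle)
  phi & (drop(RH %*% good) > 0)
}

# EAU(alpha)(phi U psi): reach psi through phi-states along alpha-edges.
oracle_EAU <- function(adjs, alpha_vec, phi, psi) {
  A <- o_union_adj(adjs, alpha_vec)
  Ar <- A & matrix(phi, nrow(A), ncol(A))  # only phi-states may move on
  reach_psi <- drop(oclosure(Ar) %*% psi) > 0
  psi | (phi & reach_psi)
}

# ---- helpers for comparing package output with oracles --------------------

# Canonical sorted key set for a matrix of states.
state_keys <- function(m) sort(apply(m, 1L, paste, collapse = ","))

# unique() over rows that keeps a single empty row for zero-column matrices
# (the projection of any state set onto zero components is one empty state).
proj_unique <- function(m) {
  if (ncol(m) == 0L) return(m[seq_len(min(1L, nrow(m))), , drop = FALSE])
  unique(m)
}

# Deep model equivalence (components, rules, interactions).
models_equivalent <- function(m1, m2) {
  isTRUE(all.equal(m1$components, m2$components)) &&
    isTRUE(all.equal(m1$interactions, m2$interactions)) &&
    setequal(names(m1$rules), names(m2$rules)) &&
    all(vapply(names(m1$rules), function(nm) {
      r1 <- m1$rules[[nm]]; r2 <- m2$rules[[nm]]
      identical(r1$regulators, r2$regulators) &&
        identical(r1$card, r2$card) && identical(r1$outputs, r2$outputs)
    }, logical(1)))
}

# Random-model parameter draw used by the oracle batteries: small enough
# for O(n^3) matrix oracles, occasionally multivalued.
draw_battery_model <- function(seed) {
  set.seed(seed)
  n_int <- sample(2:4, 1L)
  n_in <- sample(0:2, 1L)
  maxes <- sample(c(1L, 1L, 1L, 2L), n_int + n_in, replace = TRUE)
  random_model(n_int, n_in, maxes, seed = seed + 13L)
}

# A random partial internal assignment (possibly empty -> TRUE pattern).
draw_pattern <- function(model, seed) {
  set.seed(seed)
  internal <- model$components$name[!model$components$is_input]
  k <- sample(0:length(internal), 1L)
  if (k == 0L) return(setNames(integer(0), character(0)))
  who <- sample(internal, k)
  card <- ocard(model)
  setNames(vapply(who, function(nm) sample.int(card[nm], 1L) - 1L,
                  integer(1)), who)
}

pattern_vec <- function(lts, p) {
  ok <- rep(TRUE, nrow(lts$states))
  for (nm in names(p)) ok <- ok & lts$states[, nm] == p[[nm]]
  ok
}

# A random input restriction with its valuation vector.
draw_alpha <- function(model, lts, seed) {
  set.seed(seed)
  ins <- model$components$name[model$components$is_input]
  n_val <- nrow(lts$valuations)
  if (length(ins) == 0L || runif(1) < 0.25)
    return(list(alpha = alpha_true(), vec = rep(TRUE, n_val)))
  nm <- sample(ins, 1L)
  lev <- sample.int(ocard(model)[nm], 1L) - 1L
  a <- alpha_atom(nm, "=", lev)
  vec <- lts$valuations[, nm] == lev
  if (runif(1) < 0.3) {
    a <- alpha_not(a); vec <- !vec
  }
  list(alpha = a, vec = vec)
}
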