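# Independent Monte-Carlo random walker used as the oracle for the linear
# solver. Simulates damped walks step by step on a directed weight matrix:
# from node u the walker dissipates with probability 1 - damping (or with
# certainty when u has no outgoing weight), otherwise moves to v with
# probability proportional to W[u, v]. Walks stop on dissipation or on
# entering a sink. All walks are simulated simultaneously (vectorized over
# the active set), which is an implementation detail only - each walk is an
# independent trajectory.

mcWalks <- function(W, damping, source, sinks, nWalks, seed,
                    maxSteps = 10000L) {
  W <- as.matrix(W)
  nodes <- rownames(W)
  n <- length(nodes)
  srcIdx <- match(source, nodes)
  sinkIdx <- match(sinks, nodes)
  rowTot <- rowSums(W)
  P <- W / ifelse(rowTot > 0, rowTot, 1)
  cum <- t(apply(P, 1L, cumsum))
  cum[rowTot > 0, n] <- 1  # guard against cumulative rounding
  set.seed(seed)
  state <- rep(srcIdx, nWalks)
  active <- rep(TRUE, nWalks)
  absorbedAt <- integer(nWalks)
  visits <- matrix(0L, nWalks, n, dimnames = list(NULL, nodes))
  if (!(srcIdx %in% sinkIdx)) visits[, srcIdx] <- 1L
  for (step in seq_len(maxSteps)) {
    idx <- which(active)
    if (!length(idx)) break
    s <- state[idx]
    u <- runif(length(idx))
    die <- u >= damping | rowTot[s] == 0
    active[idx[die]] <- FALSE
    movers <- idx[!die]
    if (!length(movers)) next
    sm <- state[movers]
    r <- runif(length(movers))
    nxt <- max.col(cum[sm, , drop = FALSE] >= r, ties.method = "first")
    hitSink <- nxt %in% sinkIdx
    absorbedAt[movers[hitSink]] <- nxt[hitSink]
    active[movers[hitSink]] <- FALSE
    alive <- movers[!hitSink]
    if (length(alive)) {
      state[alive] <- nxt[!hitSink]
      ij <- cbind(alive, nxt[!hitSink])
      visits[ij] <- visits[ij] + 1L
    }
  }
  stopifnot(!any(active))  # no walk may hit the step cap
  list(nodes = nodes, visits = visits, absorbedAt = absorbedAt)
}

# Expected-visit estimates (emitting model) with per-node standard errors.
mcEmitting <- function(W, damping, source, sinks, nWalks, seed) {
  w <- mcWalks(W, damping, source, sinks, nWalks, seed)
  list(mean = colMeans(w$visits),
       se = apply(w$visits, 2L, sd) / sqrt(nWalks))
}

# Absorption-probability estimate for one start node.
mcAbsorbing <- function(W, damping, start, sinks, nWalks, seed) {
  w <- mcWalks(W, damping, start, sinks, nWalks, seed)
  p <- mean(w$absorbedAt != 0L)
  list(p = p, se = sqrt(p * (1 - p) / nWalks))
}

# Conditioned expected visits (channel model): visits averaged over walks
# absorbed at the sink.
mcChannel <- function(W, damping, source, sink, nWalks, seed) {
  w <- mcWalks(W, damping, source, sink, nWalks, seed)
  sel <- w$absorbedAt == match(sink, w$nodes)
  nCond <- sum(sel)
  stopifnot(nCond > 0L)
  v <- w$visits[sel, , drop = FALSE]
  list(mean = colMeans(v),
       se = apply(v, 2L, sd) / sqrt(nCond),
       nConditioned = nCond)
}

# |estimate - exact| <= 3 SE, with an epsilon for exactly-deterministic
# entries (SE 0 where estimate and truth agree identically).
expect_within_3se <- function(exact, est, se, label = "node") {
  ok <- abs(est - exact) <= 3 * se + 1e-9
  expect(all(ok), sprintf(
    "%s estimates outside 3 SE: %s", label,
    paste(names(exact)[!ok], collapse = ", ")))
}
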