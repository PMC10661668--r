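# shared fixtures and independent brute-force oracles

mediumPBS <- Electrolyte(1.5)

tinySpec <- function(nFrames = 200, seed = 1)
  MovieSpec(height = 64, width = 64, nFrames = nFrames, seed = seed)

# O(n*w) sliding-window median, written independently of rollingMedian():
# explicit loop, same centered-shrinking contract
bruteRollMedian <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- t - floor(w / 2)
    hi <- t + ceiling(w / 2) - 1
    if (lo < 1) lo <- 1
    if (hi > n) hi <- n
    out[t] <- median(x[lo:hi])
  }
  out
}

# brute-force grayscale morphological opening with a flat k x k square
# structuring element (odd k), min-then-max over the window, replicated edges
bruteOpening <- function(img, k) {
  stopifnot(k %% 2 == 1)
  h <- nrow(img); w <- ncol(img); r <- (k - 1) / 2
  win <- function(m, i, j, f)
    f(m[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)])
  er <- img
  for (i in seq_len(h)) for (j in seq_len(w)) er[i, j] <- win(img, i, j, min)
  di <- er
  for (i in seq_len(h)) for (j in seq_len(w)) di[i, j] <- win(er, i, j, max)
  di
}

# sum of signed currents into every node of a solved network
nodeResiduals <- function(sol, source) {
  nodes <- unique(c(sol$from, sol$to, source$from, source$to))
  res <- setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(sol))) {
    res[sol$from[k]] <- res[sol$from[k]] - sol$current[k]
    res[sol$to[k]] <- res[sol$to[k]] + sol$current[k]
  }
  res[source$from] <- res[source$from] + source$current
  res[source$to] <- res[source$to] - source$current
  res
}

# random connected resistor network: a node chain plus random chords
randomNetwork <- function(nNodes, nExtra, current = 1e-3) {
  nodes <- paste0("n", seq_len(nNodes))
  ed <- data.frame(from = nodes[-nNodes], to = nodes[-1],
                   resistance = runif(nNodes - 1, 10, 5000),
                   label = NA_character_)
  for (k in seq_len(nExtra)) {
    ij <- sort(sample.int(nNodes, 2))
    ed <- rbind(ed, data.frame(from = nodes[ij[1]], to = nodes[ij[2]],
                               resistance = runif(1, 10, 5000),
                               label = NA_character_))
  }
  ResistorNetwork(ed, list(from = nodes[1], to = nodes[nNodes],
                           current = current))
}

# TraceSet with a hand-designed dff layer, for exercising spike calling
traceSetWithDff <- function(dff, frameInterval = 0.12) {
  arr <- array(rep(100, length(dff)), dim = c(1, 1, length(dff)))
  mask <- matrix(1L, 1, 1)
  ts <- extractTraces(arr, mask, frameInterval = frameInterval)
  SummarizedExperiment::assays(ts)[["trend"]] <-
    matrix(100, 1, length(dff), dimnames = list("roi1", NULL))
  SummarizedExperiment::assays(ts)[["dff"]] <-
    matrix(dff, 1, length(dff), dimnames = list("roi1", NULL))
  ts
}

# clustered two-condition rate table with a per-culture shift
clusteredRates <- function(nCultures = 4, nPerCulture = 10, delta = 0,
                           sdWithin = 0.2, sdCulture = 0.1, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cond in c("baseline", "treatment")) {
    for (cu in seq_len(nCultures)) {
      mu <- 1 + rnorm(1, 0, sdCulture) + if (cond == "treatment") delta else 0
      rows[[length(rows) + 1L]] <- data.frame(
        value = rnorm(nPerCulture, mu, sdWithin),
        neuron = paste0(cond, "_c", cu, "_n", seq_len(nPerCulture)),
        culture = paste0("culture", cu), condition = cond)
    }
  }
  do.call(rbind, rows)
}
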