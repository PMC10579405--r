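## Neighbour-graph embedding of cytometry events.
##
## The pipeline projects normalised events into a low-dimensional space in
## three steps: (1) an exact k-nearest-neighbour graph under the Euclidean
## metric, converted to fuzzy edge weights by per-point kernel calibration
## (each point's kernel bandwidth is tuned so its effective neighbour count
## is log2(k), then weights are symmetrised w_ij + w_ji - w_ij*w_ji);
## (2) a spectral initialisation from the leading eigenvectors of the
## normalised graph adjacency, computed by deflated orthogonal iteration;
## (3) batch gradient refinement that pulls edge pairs together under the
## min-dist calibrated kernel 1/(1 + a d^(2b)) and pushes sampled
## non-neighbour pairs apart. All stochastic steps derive from one seed, and
## the computation is single-threaded, so results are reproducible.

## exact kNN by blocked brute force; returns index and distance matrices
knn_exact <- function(X, k, block = 1024L) {
  n <- nrow(X)
  k <- min(k, n - 1)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(X^2)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1, n)
    D2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    D2[cbind(seq_along(rows), rows)] <- Inf  # exclude self
    for (j in seq_along(rows)) {
      o <- order(D2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(pmax(D2[j, o], 0))
    }
  }
  list(idx = idx, dist = dst)
}

## per-point bandwidth calibration: sum_j exp(-(d_ij - rho_i)/sigma_i) =
## log2(k), rho_i = distance to the nearest neighbour
smooth_knn_weights <- function(knn, n_iter = 64) {
  n <- nrow(knn$idx); k <- ncol(knn$idx)
  target <- log2(k)
  rho <- knn$dist[, 1]
  d <- pmax(knn$dist - rho, 0)
  sigma <- rep(1, n)
  lo <- rep(0, n); hi <- rep(Inf, n)
  for (it in seq_len(n_iter)) {
    s <- rowSums(exp(-d / sigma))
    too_high <- s > target
    hi[too_high] <- sigma[too_high]
    lo[!too_high] <- sigma[!too_high]
    sigma <- ifelse(is.finite(hi), (lo + hi) / 2, sigma * 2)
  }
  exp(-d / sigma)
}

## symmetrised sparse edge list from directed fuzzy weights
fuzzy_graph <- function(knn, w) {
  n <- nrow(knn$idx)
  i <- rep(seq_len(n), ncol(knn$idx))
  j <- as.vector(knn$idx)
  key <- (pmin(i, j) - 1) * n + pmax(i, j)
  ## fuzzy union w1 + w2 - w1*w2 where both directed edges exist
  dir1 <- tapply(as.vector(w), key, max)
  dir2 <- tapply(as.vector(w), key, min)
  cnt <- tapply(as.vector(w), key, length)
  wsym <- ifelse(cnt > 1, dir1 + dir2 - dir1 * dir2, dir1)
  key <- as.numeric(names(wsym))
  data.frame(i = as.integer((key - 1) %/% n + 1),
             j = as.integer((key - 1) %% n + 1),
             w = as.numeric(wsym))
}

## leading eigenvectors of the degree-normalised adjacency by orthogonal
## iteration with deflation of the trivial (constant) direction
spectral_init <- function(edges, n, n_components, n_iter = 150, seed = 1) {
  deg <- numeric(n)
  agg_i <- tapply(edges$w, edges$i, sum)
  agg_j <- tapply(edges$w, edges$j, sum)
  deg[as.integer(names(agg_i))] <- deg[as.integer(names(agg_i))] + agg_i
  deg[as.integer(names(agg_j))] <- deg[as.integer(names(agg_j))] + agg_j
  dinv <- 1 / sqrt(pmax(deg, 1e-12))
  wn <- edges$w * dinv[edges$i] * dinv[edges$j]
  matvec <- function(v) {
    out <- numeric(n)
    p <- wn * v[edges$j]
    q <- wn * v[edges$i]
    ai <- rowsum(p, edges$i); out[as.integer(rownames(ai))] <- ai
    aj <- rowsum(q, edges$j)
    out[as.integer(rownames(aj))] <- out[as.integer(rownames(aj))] + aj
    out
  }
  triv <- dinv * sqrt(pmax(deg, 1e-12))  # constant direction in norm'd space
  triv <- triv / sqrt(sum(triv^2))
  V <- withr::with_seed(seed, matrix(stats::rnorm(n * n_components), n))
  for (it in seq_len(n_iter)) {
    V <- apply(V, 2, matvec)
    V <- V - outer(triv, colSums(triv * V))  # deflate trivial eigenvector
    V <- qr.Q(qr(V))
  }
  Y <- V
  ## scale to a modest initial spread
  Y <- scale(Y, scale = FALSE)
  Y * (10 / max(abs(Y)))
}

## min-dist kernel calibration: least-squares fit of 1/(1+a d^(2b)) to the
## target curve exp(-(d - min_dist)) for d > min_dist, 1 otherwise
fit_ab <- function(min_dist, spread = 1) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d < min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  p <- stats::optim(c(log(1.6), log(0.9)), obj)$par
  c(a = exp(p[1]), b = exp(p[2]))
}

## batch attraction/repulsion refinement of the initial layout
refine_embedding <- function(Y, edges, n_epochs, a, b, seed,
                             learning_rate = 0.3, neg_ratio = 3) {
  n <- nrow(Y)
  m <- nrow(edges)
  withr::with_seed(seed + 1L, {
    for (epoch in seq_len(n_epochs)) {
      alpha <- learning_rate * (1 - (epoch - 1) / n_epochs)
      diff <- Y[edges$i, , drop = FALSE] - Y[edges$j, , drop = FALSE]
      d2 <- rowSums(diff^2) + 1e-9
      ## attractive gradient of log(1/(1+a d^(2b))) wrt d2, weighted by w
      coef <- edges$w * (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
      g <- diff * coef
      upd <- rowsum(rbind(g, -g), c(edges$i, edges$j))
      ridx <- as.integer(rownames(upd))
      Y[ridx, ] <- Y[ridx, ] + alpha * upd
      ## repulsion against sampled non-neighbour pairs
      nneg <- neg_ratio * m
      ni <- sample.int(n, nneg, replace = TRUE)
      nj <- sample.int(n, nneg, replace = TRUE)
      ok <- ni != nj
      ni <- ni[ok]; nj <- nj[ok]
      diff <- Y[ni, , drop = FALSE] - Y[nj, , drop = FALSE]
      d2 <- rowSums(diff^2) + 1e-9
      coef <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
      g <- diff * pmin(coef, 4)
      upd <- rowsum(g, ni)
      ridx <- as.integer(rownames(upd))
      Y[ridx, ] <- Y[ridx, ] + alpha * upd
    }
  })
  Y
}

#' Embed events into a 3-D neighbour-graph space
#'
#' Nonlinear low-dimensional projection of normalised events used by the
#' gating and classification steps: a fuzzy 25-nearest-neighbour graph under
#' the Euclidean metric is laid out in three dimensions (spectral
#' initialisation, then attraction/repulsion refinement with a 0.1
#' minimum-distance kernel). Optional labels supervise the layout by
#' down-weighting edges that cross label boundaries, which tightens
#' same-label populations in the training space used for species
#' assignment.
#'
#' @param events a normalised event table (see [normalize_events()]) or a
#'   numeric matrix of coordinates.
#' @param channels channel columns to use; defaults to the `"channels"`
#'   attribute left by [normalize_events()].
#' @param n_neighbors neighbour count of the graph (default 25). Reduced
#'   with a warning when fewer events are available.
#' @param min_dist minimum-distance parameter of the layout kernel
#'   (default 0.1).
#' @param n_components embedding dimensionality (default 3).
#' @param n_epochs refinement epochs.
#' @param seed integer seed; the same input and seed give identical output.
#' @param y optional factor of labels for supervised layout.
#' @param supervision_weight factor applied to cross-label edge weights when
#'   `y` is supplied (0 = severed, 1 = unsupervised).
#' @return Numeric matrix (events x `n_components`) with attributes
#'   `"edges"` (the fuzzy graph) and `"ab"` (kernel constants), needed to
#'   reproject new events.
#' @export
embed_events <- function(events, channels = attr(events, "channels"),
                         n_neighbors = 25, min_dist = 0.1, n_components = 3,
                         n_epochs = 200, seed = 1, y = NULL,
                         supervision_weight = 0.1) {
  X <- if (is.matrix(events)) events else {
    if (is.null(channels)) stop("normalise events first or supply channels")
    as.matrix(events[channels])
  }
  n <- nrow(X)
  if (n <= n_neighbors) {
    warning("fewer events than n_neighbors; reducing to ", n - 1)
    n_neighbors <- n - 1
  }
  if (n_neighbors < 2) stop("need at least 3 events to embed")
  knn <- knn_exact(X, n_neighbors)
  w <- smooth_knn_weights(knn)
  edges <- fuzzy_graph(knn, w)
  if (!is.null(y)) {
    y <- as.factor(y)
    cross <- y[edges$i] != y[edges$j]
    edges$w[cross] <- edges$w[cross] * supervision_weight
  }
  ab <- fit_ab(min_dist)
  Y <- spectral_init(edges, n, n_components, seed = seed)
  Y <- refine_embedding(Y, edges, n_epochs, ab["a"], ab["b"], seed = seed)
  dimnames(Y) <- list(NULL, paste0("E", seq_len(n_components)))
  attr(Y, "edges") <- edges
  attr(Y, "ab") <- ab
  attr(Y, "X") <- X
  Y
}

#' Project new events into an existing embedding
#'
#' Out-of-sample extension: each new event is placed at the
#' similarity-weighted average of the embedding coordinates of its `k`
#' nearest reference events in channel space.
#'
#' @param new_X numeric matrix of normalised channel coordinates for the new
#'   events (same channels as the reference).
#' @param ref_embedding embedding returned by [embed_events()] (carries the
#'   reference channel matrix as an attribute).
#' @param k neighbours used for placement.
#' @return Matrix of embedding coordinates for the new events.
#' @export
project_events <- function(new_X, ref_embedding, k = 10) {
  refX <- attr(ref_embedding, "X")
  if (is.null(refX)) stop("ref_embedding lacks its reference coordinates")
  if (nrow(new_X) == 0)
    return(matrix(numeric(0), 0, ncol(ref_embedding),
                  dimnames = list(NULL, colnames(ref_embedding))))
  k <- min(k, nrow(refX))
  sqr <- rowSums(refX^2)
  out <- matrix(0, nrow(new_X), ncol(ref_embedding))
  block <- 1024L
  for (start in seq(1, nrow(new_X), by = block)) {
    rows <- start:min(start + block - 1, nrow(new_X))
    D2 <- outer(rowSums(new_X[rows, , drop = FALSE]^2), sqr, "+") -
      2 * tcrossprod(new_X[rows, , drop = FALSE], refX)
    for (j in seq_along(rows)) {
      o <- order(D2[j, ])[seq_len(k)]
      wts <- 1 / (sqrt(pmax(D2[j, o], 0)) + 1e-6)
      wts <- wts / sum(wts)
      out[rows[j], ] <- colSums(ref_embedding[o, , drop = FALSE] * wts)
    }
  }
  colnames(out) <- colnames(ref_embedding)
  out
}
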