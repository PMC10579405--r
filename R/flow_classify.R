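#' Assign species labels to co-culture live events
#'
#' Supervised species assignment: up to `n_training` live events are drawn
#' from each monoculture reference replicate and embedded into a labeled
#' training space (label-supervised neighbour-graph layout). Co-culture live
#' events are reprojected into that space and labeled by a distance-weighted
#' k-nearest-neighbour vote (k = 50) under the Mahalanobis metric of the
#' training embedding. Per-event vote margins are returned as a confidence
#' measure.
#'
#' @param co_events live co-culture event table (raw channel intensities).
#' @param mono_refs named list `list(BT = ..., RI = ...)` of live
#'   monoculture reference event tables; each may optionally carry a
#'   `replicate` column, in which case `n_training` events are drawn per
#'   replicate before pooling.
#' @param n_training training events drawn per reference replicate.
#' @param k neighbours in the vote (default 50).
#' @param seed integer seed controlling sampling and the embedding.
#' @param channels channel columns.
#' @return Data.frame with one row per co-culture event: `species`
#'   (factor BT/RI) and `margin` (winning vote share in (0.5, 1]); empty
#'   input gives an empty result. The training embedding is attached as an
#'   attribute.
#' @export
classify_species <- function(co_events, mono_refs, n_training = 5000,
                             k = 50, seed = 1,
                             channels = c("FSC", "SSC", "FL_SG", "FL_PI")) {
  if (!all(c("BT", "RI") %in% names(mono_refs)))
    stop("mono_refs must contain both BT and RI reference tables")
  draw <- function(tab, species) {
    if (is.null(tab) || nrow(tab) == 0)
      stop("empty monoculture reference for ", species)
    reps <- if ("replicate" %in% names(tab)) split(tab, tab$replicate)
            else list(tab)
    withr::with_seed(seed, {
      out <- lapply(reps, function(r) {
        n <- min(n_training, nrow(r))
        r[sample.int(nrow(r), n), channels, drop = FALSE]
      })
      do.call(rbind, out)
    })
  }
  train_bt <- draw(mono_refs$BT, "BT")
  train_ri <- draw(mono_refs$RI, "RI")
  if (nrow(train_bt) < k || nrow(train_ri) < k)
    stop("need at least ", k, " training events per species")
  labels <- factor(rep(c("BT", "RI"), c(nrow(train_bt), nrow(train_ri))))
  n_co <- nrow(co_events)
  if (n_co == 0) {
    res <- data.frame(species = factor(character(0), levels = c("BT", "RI")),
                      margin = numeric(0))
    return(res)
  }
  ## joint normalisation so training and co events share channel scales
  pool <- rbind(train_bt, train_ri, co_events[channels])
  pool_n <- normalize_events(pool, channels)
  Xn <- as.matrix(pool_n[attr(pool_n, "channels")])
  n_train <- nrow(train_bt) + nrow(train_ri)
  X_train <- Xn[seq_len(n_train), , drop = FALSE]
  X_co <- Xn[n_train + seq_len(n_co), , drop = FALSE]

  train_emb <- embed_events(X_train, seed = seed, y = labels)
  co_emb <- project_events(X_co, train_emb)

  ## Mahalanobis metric: whiten by the training-embedding covariance
  S <- stats::cov(train_emb)
  W <- solve(chol(S))
  Tw <- train_emb %*% W
  Cw <- co_emb %*% W

  vote_bt <- numeric(n_co)
  sqt <- rowSums(Tw^2)
  block <- 1024L
  is_bt <- labels == "BT"
  for (start in seq(1, n_co, by = block)) {
    rows <- start:min(start + block - 1, n_co)
    D2 <- outer(rowSums(Cw[rows, , drop = FALSE]^2), sqt, "+") -
      2 * tcrossprod(Cw[rows, , drop = FALSE], Tw)
    for (j in seq_along(rows)) {
      o <- order(D2[j, ])[seq_len(k)]
      wts <- 1 / (sqrt(pmax(D2[j, o], 0)) + 1e-9)
      vote_bt[rows[j]] <- sum(wts[is_bt[o]]) / sum(wts)
    }
  }
  species <- factor(ifelse(vote_bt >= 0.5, "BT", "RI"), levels = c("BT", "RI"))
  res <- data.frame(species = species,
                    margin = pmax(vote_bt, 1 - vote_bt))
  attr(res, "train_embedding") <- train_emb
  attr(res, "train_labels") <- labels
  res
}

#' Absolute population densities from event counts
#'
#' Converts per-category (and, for co-cultures, per-species) event counts to
#' absolute densities of the undiluted culture:
#' density (cells/ul) = events / acquired volume (ul) x dilution factor.
#' The study acquired 1 min at 10 ul/min, i.e. 10 ul, at dilutions 1:10
#' (early time points) or 1:200.
#'
#' @param classified event table carrying a `category` column and optionally
#'   a `species` column for live co-culture events.
#' @param dilution dilution factor (> 0).
#' @param acquisition_volume_ul acquired volume in ul (> 0).
#' @return Data.frame with `population`, `events` and `density_cells_per_ul`.
#' @export
#' @examples
#' tab <- data.frame(category = rep("live", 50000))
#' count_populations(tab, dilution = 200, acquisition_volume_ul = 10)
count_populations <- function(classified, dilution, acquisition_volume_ul) {
  if (is.null(dilution) || dilution <= 0) stop("dilution must be > 0")
  if (is.null(acquisition_volume_ul) || acquisition_volume_ul <= 0)
    stop("acquisition volume must be > 0")
  pop <- as.character(classified$category)
  if ("species" %in% names(classified)) {
    live <- pop == "live" & !is.na(classified$species)
    pop[live] <- paste0("live_", as.character(classified$species[live]))
  }
  counts <- table(pop)
  data.frame(population = names(counts),
             events = as.integer(counts),
             density_cells_per_ul = as.numeric(counts) /
               acquisition_volume_ul * dilution,
             row.names = NULL)
}
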