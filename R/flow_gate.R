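#' Estimate a gating threshold from a bimodal intensity distribution
#'
#' Finds the minimum-density valley between the two largest modes of a
#' kernel density estimate of the (asinh-transformed, standardised) channel
#' values; used as the default SG/PI positivity threshold when no explicit
#' value is supplied.
#'
#' @param x numeric channel values (pooled across samples).
#' @return The threshold location. Errors if the density has fewer than two
#'   modes.
#' @export
estimate_gate_threshold <- function(x, adjust = 3) {
  d <- stats::density(x, n = 512, adjust = adjust)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  is_max <- is_max[y[is_max] >= 0.01 * max(y)]  # ignore numerical ripples
  if (length(is_max) < 2)
    stop("channel distribution is not bimodal; supply a threshold explicitly")
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  valley <- seq(top2[1], top2[2])
  d$x[valley[which.min(y[valley])]]
}

#' Flag sample events overlapping the blank population
#'
#' Implements blank removal in embedding space: every blank event defines a
#' ball whose radius is proportional to the local blank density (estimated
#' from the distance to its k-th nearest blank neighbour), and sample events
#' falling inside any ball are flagged as blank. Scaling the radius with the
#' local density means a dense blank population claims its surroundings
#' while isolated blank events (e.g. carryover cells in a blank run) claim
#' almost nothing.
#'
#' @param sample_emb embedding coordinates of the sample events.
#' @param blank_emb embedding coordinates of the blank events; may have zero
#'   rows, in which case nothing is flagged.
#' @param density_radius_scale proportionality constant between the local
#'   density score and the ball radius.
#' @param k_density neighbour count of the local density estimate; it should
#'   exceed the plausible number of carryover cell events in a blank run so
#'   that carryover regions register as low-density.
#' @return Logical vector over sample events: `TRUE` = inside the blank
#'   region.
#' @export
remove_blank_overlap <- function(sample_emb, blank_emb,
                                 density_radius_scale = 1.5, k_density = 50) {
  n_s <- nrow(sample_emb)
  n_b <- nrow(blank_emb)
  if (n_b == 0) return(rep(FALSE, n_s))
  k <- min(k_density, n_b - 1)
  if (k < 1) return(rep(FALSE, n_s))
  ## d_k: distance from each blank event to its k-th blank neighbour
  bb <- knn_exact(blank_emb, k)
  dk <- bb$dist[, k]
  ## density score relative to the typical blank neighbourhood: dense
  ## regions (small dk) get radius ~ scale * typical spacing; sparse
  ## outliers get a vanishing radius
  dk_med <- stats::median(dk)
  ## 3-D density is ~ 1/dk^3; normalise by the typical blank neighbourhood
  radius <- density_radius_scale * dk_med * (dk_med / pmax(dk, 1e-12))^3
  radius <- pmin(radius, 3 * density_radius_scale * dk_med)
  ## blank events in clearly sparse regions are carryover cells, not
  ## background: they claim no area at all
  radius[dk > 1.5 * dk_med] <- 0
  flagged <- rep(FALSE, n_s)
  sqb <- rowSums(blank_emb^2)
  block <- 2048L
  for (start in seq(1, n_s, by = block)) {
    rows <- start:min(start + block - 1, n_s)
    D2 <- outer(rowSums(sample_emb[rows, , drop = FALSE]^2), sqb, "+") -
      2 * tcrossprod(sample_emb[rows, , drop = FALSE], blank_emb)
    inside <- sweep(D2, 2, radius^2, "<=")
    flagged[rows] <- rowSums(inside) > 0
  }
  flagged
}

#' Gate events into live / inviable / debris / blank categories
#'
#' Joint category assignment for a sample run and its blank control:
#' sample and blank events are embedded together, sample events overlapping
#' the blank population are flagged (see [remove_blank_overlap()]), and the
#' rest are gated on the stain channels — PI positive means membrane-damaged
#' (inviable) regardless of SG; SG positive and PI negative means live;
#' double-negative means debris. Thresholds default to the valley between
#' the two main modes of each stain channel.
#'
#' @param events raw sample event table with the four channel columns.
#' @param blanks raw blank-run event table (same columns); may be empty.
#' @param sg_threshold,pi_threshold positivity thresholds on the normalised
#'   SG and PI channels; estimated from the pooled data when `NULL`.
#' @param density_radius_scale passed to [remove_blank_overlap()].
#' @param seed embedding seed.
#' @param channels channel columns.
#' @return List with `events` (the sample table plus a `category` factor
#'   over live/inviable/debris/blank), `embedding` (sample embedding
#'   coordinates), `blank_embedding`, and the thresholds used.
#' @export
gate_categories <- function(events, blanks,
                            sg_threshold = NULL, pi_threshold = NULL,
                            density_radius_scale = 1.5, seed = 1,
                            channels = c("FSC", "SSC", "FL_SG", "FL_PI")) {
  if (!all(c("FL_SG", "FL_PI") %in% names(events)))
    stop("events must contain FL_SG and FL_PI channels")
  n_s <- nrow(events)
  n_b <- if (is.null(blanks)) 0L else nrow(blanks)
  pool <- rbind(events[channels],
                if (n_b) blanks[channels])
  pool_n <- normalize_events(pool, channels)
  X <- as.matrix(pool_n[attr(pool_n, "channels")])
  emb <- embed_events(X, n_neighbors = 25, seed = seed)
  s_emb <- emb[seq_len(n_s), , drop = FALSE]
  b_emb <- emb[n_s + seq_len(n_b), , drop = FALSE]
  is_blank <- remove_blank_overlap(s_emb, b_emb, density_radius_scale)

  sg <- X[seq_len(n_s), "FL_SG"]
  pi <- X[seq_len(n_s), "FL_PI"]
  if (is.null(sg_threshold)) sg_threshold <- estimate_gate_threshold(sg)
  if (is.null(pi_threshold)) pi_threshold <- estimate_gate_threshold(pi)

  category <- rep("debris", n_s)
  category[pi > pi_threshold] <- "inviable"
  category[pi <= pi_threshold & sg > sg_threshold] <- "live"
  category[is_blank] <- "blank"
  events$category <- factor(category,
                            levels = c("live", "inviable", "debris", "blank"))
  list(events = events, embedding = s_emb, blank_embedding = b_emb,
       sg_threshold = sg_threshold, pi_threshold = pi_threshold)
}
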