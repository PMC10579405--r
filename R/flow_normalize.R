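#' Variance-stabilising normalisation of cytometry channels
#'
#' Applies the inverse hyperbolic sine transform per channel, then
#' standardises each channel to zero mean and unit variance. asinh is the
#' standard cytometry variance-stabilising transform: it is logarithmic for
#' large intensities but defined at (and linear near) zero. A plain arcsine
#' variant is offered for completeness but requires intensities in `[0, 1]`
#' and is not the default.
#'
#' @param events an event table (data.frame) containing the channel columns.
#' @param channels channel column names; default the four study channels.
#' @param method `"asinh"` (default) or `"arcsine"`.
#' @param cofactor asinh cofactor: the transform is `asinh(x / cofactor)`.
#' @return The event table with the channel columns replaced by their
#'   transformed, standardised values. Channels with zero variance are
#'   dropped with a warning; the retained channel set is recorded in the
#'   `"channels"` attribute.
#' @export
normalize_events <- function(events,
                             channels = c("FSC", "SSC", "FL_SG", "FL_PI"),
                             method = c("asinh", "arcsine"), cofactor = 1) {
  method <- match.arg(method)
  if (nrow(events) < 2) stop("need at least 2 events")
  channels <- intersect(channels, names(events))
  if (length(channels) < 2) stop("need at least 2 channel columns")
  X <- as.matrix(events[channels])
  if (any(!is.finite(X))) stop("non-finite channel intensities")
  X <- switch(method,
              asinh = asinh(X / cofactor),
              arcsine = {
                if (any(X < 0) || any(X > 1))
                  stop("arcsine transform requires intensities in [0, 1]")
                asin(sqrt(X))
              })
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    dropped <- channels[sds == 0]
    warning("dropping zero-variance channel(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    channels <- channels[sds > 0]
    events <- events[setdiff(names(events), dropped)]
  }
  X <- scale(X)
  events[channels] <- X
  attr(events, "channels") <- channels
  attr(events, "normalized") <- TRUE
  events
}
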