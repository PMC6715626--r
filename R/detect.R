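#' Temporal moving-average filter
#'
#' Per-pixel centered moving average over frames; at the stack edges the
#' window is truncated to the available frames. Used to suppress frame
#' noise before projection and spot detection. Event timing downstream is
#' always taken from the unfiltered stack.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param window Odd window length in frames (>= 1).
#' @return A filtered \code{image_stack} with identical dimensions.
#' @export
moving_average_filter <- function(stack, window = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  if (window < 1 || window %% 2 == 0)
    stop("window must be a positive odd frame count")
  if (window == 1) return(stack)
  A <- stack$frames
  nf <- dim(A)[3]
  h <- (window - 1L) / 2L
  out <- array(0, dim = dim(A))
  for (j in seq_len(nf)) {
    lo <- max(1L, j - h); hi <- min(nf, j + h)
    out[, , j] <- rowSums(A[, , lo:hi, drop = FALSE], dims = 2) /
      (hi - lo + 1L)
  }
  image_stack(out, stack$channel, stack$optics)
}

#' Maximum-intensity projection
#'
#' Projects the per-pixel maximum over all frames onto a single image, so
#' that every vesicle that was ever present appears once.
#'
#' @param stack A nonempty \code{\link{image_stack}}.
#' @return Numeric matrix (same frame size).
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_frames(stack) < 1) stop("stack is empty")
  A <- stack$frames
  out <- A[, , 1]
  for (j in seq_len(dim(A)[3])[-1]) out <- pmax(out, A[, , j])
  out
}

#' Detect particles in a projected image
#'
#' Smooths the image with a Gaussian matched to the PSF, estimates a robust
#' background (median) and spread (MAD), and returns the integer pixel
#' centers of local maxima exceeding
#' \code{median + threshold_sigma * MAD}. Maxima closer than
#' \code{min_separation} pixels are merged, keeping the brighter.
#'
#' @param image Numeric matrix (e.g. a \code{\link{max_projection}}).
#' @param threshold_sigma Detection threshold in robust SDs (> 0).
#' @param min_separation Minimum center separation, pixels.
#' @param psf_sigma Gaussian smoothing sigma, pixels.
#' @return Integer matrix with columns \code{row}, \code{col} (1-based
#'   pixel centers), zero rows when nothing is found.
#' @export
detect_particles <- function(image, threshold_sigma = 5,
                             min_separation = 3, psf_sigma = 1) {
  if (threshold_sigma <= 0) stop("threshold_sigma must be > 0")
  sm <- EBImage::gblur(image, sigma = psf_sigma)
  thr <- stats::median(sm) + threshold_sigma * stats::mad(sm)
  nr <- nrow(sm); nc <- ncol(sm)
  cand <- which(sm > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr &
               cand[, 2] > 1 & cand[, 2] < nc, , drop = FALSE]
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
    is_max[i] <- sm[r, c] >= max(nb)
  }
  pk <- cand[is_max, , drop = FALSE]
  if (nrow(pk) == 0)
    return(cbind(row = integer(0), col = integer(0)))
  amp <- sm[pk]
  ord <- order(amp, decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    prev <- pk[keep, , drop = FALSE]
    if (nrow(prev) == 0 ||
        all((prev[, 1] - pk[i, 1])^2 + (prev[, 2] - pk[i, 2])^2 >=
            min_separation^2))
      keep[i] <- TRUE
  }
  out <- pk[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  storage.mode(out) <- "integer"
  out[order(out[, "row"], out[, "col"]), , drop = FALSE]
}

#' Construct a particle trace
#'
#' @param particle_id Integer id.
#' @param row,col 1-based pixel center.
#' @param central Central-pixel intensity series.
#' @param roi_mean Mean intensity over the 5x5 ROI.
#' @param frame_interval Frame interval, s.
#' @return An object of class \code{"particle_trace"}.
#' @export
new_particle_trace <- function(particle_id, row, col, central, roi_mean,
                               frame_interval) {
  stopifnot(length(central) == length(roi_mean))
  structure(list(particle_id = particle_id, row = row, col = col,
                 central = as.numeric(central),
                 roi_mean = as.numeric(roi_mean),
                 frame_interval = frame_interval,
                 times = (seq_along(central) - 1) * frame_interval),
            class = "particle_trace")
}

#' @export
print.particle_trace <- function(x, ...) {
  cat(sprintf("particle_trace #%s at (%s, %s): %d frames @ %g s\n",
              x$particle_id, x$row, x$col, length(x$central),
              x$frame_interval))
  invisible(x)
}

#' Extract intensity traces at detected positions
#'
#' For each position, reads the central-pixel series and the mean over the
#' 5x5-pixel area centered on it, from the (unfiltered) stack. Positions
#' whose 5x5 ROI would leave the frame are skipped with a warning.
#'
#' @param stack An \code{\link{image_stack}} (use the raw stack, not the
#'   filtered one: filtering blurs onsets).
#' @param positions Matrix with columns \code{row}, \code{col} (1-based).
#' @return List of \code{particle_trace}, in position order.
#' @export
extract_traces <- function(stack, positions) {
  stopifnot(inherits(stack, "image_stack"))
  A <- stack$frames
  nr <- dim(A)[1]; nc <- dim(A)[2]
  out <- list()
  for (i in seq_len(nrow(positions))) {
    r <- positions[i, "row"]; c <- positions[i, "col"]
    if (r < 3 || r > nr - 2 || c < 3 || c > nc - 2) {
      warning(sprintf("position (%d, %d) too close to frame edge; skipped",
                      r, c))
      next
    }
    roi <- A[(r - 2):(r + 2), (c - 2):(c + 2), , drop = FALSE]
    out[[length(out) + 1L]] <-
      new_particle_trace(particle_id = i, row = r, col = c,
                         central = A[r, c, ],
                         roi_mean = colMeans(matrix(roi, nrow = 25)),
                         frame_interval = stack$optics$frame_interval)
  }
  out
}
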