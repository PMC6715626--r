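#' Time-ordered image stack
#'
#' Container for a recorded or simulated movie: a 3D array of non-negative
#' intensities indexed \code{[row, col, frame]}, a channel tag, and the
#' \code{\link{optics_config}} it was acquired with.
#'
#' @param frames Numeric 3D array \code{[row, col, frame]}, intensities
#'   >= 0.
#' @param channel \code{"label"} or \code{"calcium_indicator"}.
#' @param optics An \code{\link{optics_config}}.
#' @return An object of class \code{"image_stack"}.
#' @export
image_stack <- function(frames, channel = c("label", "calcium_indicator"),
                        optics = optics_config()) {
  channel <- match.arg(channel)
  if (length(dim(frames)) != 3) stop("frames must be a 3D array")
  if (any(frames < 0)) stop("intensities must be >= 0")
  structure(list(frames = frames, channel = channel, optics = optics),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack [%s]: %d x %d px, %d frames @ %g s\n",
              x$channel, d[1], d[2], d[3], x$optics$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An \code{image_stack}.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Frame sample times of a stack
#' @param stack An \code{image_stack}.
#' @return Numeric vector of times (s), first frame at t = 0.
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$optics$frame_interval
}
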