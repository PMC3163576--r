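#' Ordered stack of digitized RGB histology sections
#'
#' Section index 1 corresponds to the reference cutting plane. Sections are
#' stored as \code{(nx, ny, 3)} arrays (intensities 0-255); differing shapes
#' are padded symmetrically with the background value. All world units are
#' mm: micrometer inputs are converted on construction.
#'
#' @param sections list of \code{(nx, ny, 3)} arrays.
#' @param pixel_size in-plane pixel size.
#' @param interval physical distance between consecutive sections.
#' @param thickness physical thickness of each section (metadata only).
#' @param units units of the three sizes, converted to mm internally.
#' @param pad_value background value used when padding to a common shape.
#' @return an object of class \code{section_stack}.
#' @export
section_stack <- function(sections, pixel_size, interval, thickness = NULL,
                          units = c("mm", "um"), pad_value = 255) {
  units <- match.arg(units)
  k <- if (units == "um") 1e-3 else 1
  stopifnot(length(sections) >= 1, interval > 0, pixel_size > 0)
  for (s in sections)
    if (length(dim(s)) != 3L || dim(s)[3] != 3L)
      stop("each section must be an (nx, ny, 3) RGB array")
  shapes <- vapply(sections, function(s) dim(s)[1:2], integer(2))
  target <- c(max(shapes[1, ]), max(shapes[2, ]))
  sections <- lapply(sections, pad_section, target = target,
                     pad_value = pad_value)
  structure(list(sections = sections, pixel_size = pixel_size * k,
                 interval = interval * k,
                 thickness = if (is.null(thickness)) NA_real_ else thickness * k),
            class = "section_stack")
}

pad_section <- function(s, target, pad_value) {
  d <- dim(s)
  if (all(d[1:2] == target)) return(s)
  out <- array(pad_value, c(target, d[3]))
  off <- floor((target - d[1:2]) / 2)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), ] <- s
  out
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$sections[[1]])
  cat(sprintf(paste0("<section_stack> %d sections of %d x %d px, pixel size ",
                     "%.4g mm, interval %.4g mm\n"),
              length(x$sections), d[1], d[2], x$pixel_size, x$interval))
  invisible(x)
}

#' Extract one color channel from every section
#'
#' @param stack a \code{\link{section_stack}}.
#' @param channel color channel name.
#' @return list of 2D matrices, preserving pixel size as an attribute.
#' @export
extract_channel <- function(stack, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  ci <- match(channel, c("red", "green", "blue"))
  out <- lapply(stack$sections, function(s) s[, , ci])
  attr(out, "pixel_size") <- stack$pixel_size
  out
}
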