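## Pseudocolor stroke-order rendering: each stroke polyline is drawn in a
## color determined solely by its index, later strokes overdrawing earlier
## ones, so drawing strategy (element order, retracing) is readable at a
## glance. Rasterization is done in-package (integer Bresenham lines into an
## RGB array written with png::writePNG) so output is byte-identical across
## runs and platforms.

#' Stroke-order colors
#'
#' `n` colors sampled uniformly along a fixed sequential multi-hue colormap
#' (viridis: monotone lightness, so stroke order reads as a light-dark
#' progression). Deterministic; `n = 1` gives the colormap start, `n = 2`
#' its endpoints.
#'
#' @param n Number of strokes (`>= 0`).
#' @return Character vector of `n` hex colors.
#' @export
#' @examples
#' strokeOrderColors(3)
strokeOrderColors <- function(n) {
  if (n == 0) return(character())
  if (n == 1) return(grDevices::hcl.colors(2, "Viridis")[1])
  cols <- grDevices::hcl.colors(n, "Viridis")
  ## 8-bit quantization can collide for large n; resolve deterministically
  ## with the smallest blue-channel nudge that keeps every color unique
  if (anyDuplicated(cols)) {
    m <- grDevices::col2rgb(cols)
    seen <- character()
    for (i in seq_len(ncol(m))) {
      hex <- grDevices::rgb(m[1, i], m[2, i], m[3, i], maxColorValue = 255)
      while (hex %in% seen) {
        m[3, i] <- (m[3, i] + 1L) %% 256L
        hex <- grDevices::rgb(m[1, i], m[2, i], m[3, i],
                              maxColorValue = 255)
      }
      seen <- c(seen, hex)
      cols[i] <- hex
    }
  }
  cols
}

.drawLine <- function(raster, x0, y0, x1, y1, rgb, thick = 1L) {
  ## integer Bresenham; coordinates are 1-based raster column/row
  h <- dim(raster)[1]; w <- dim(raster)[2]
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  x <- x0; y <- y0
  repeat {
    xs <- max(1L, x - thick %/% 2L):min(w, x + thick %/% 2L)
    ys <- max(1L, y - thick %/% 2L):min(h, y + thick %/% 2L)
    for (k in 1:3) raster[ys, xs, k] <- rgb[k]
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  raster
}

#' Render a session as a pseudocolor stroke-order image
#'
#' Strokes are drawn in index order on a white canvas mirroring the
#' 2160 x 1620 tablet aspect, scaled to `width` pixels; the color of each
#' stroke depends only on its index and the total stroke count. Pure
#' function of the session: two renders of the same session are
#' byte-identical.
#'
#' @param session A [DrawingSession-class].
#' @param width Canvas width in pixels (height follows the 4:3 aspect).
#' @param path Optional PNG output path.
#' @param thickness Line thickness in pixels.
#' @return A [PseudocolorImage-class] (invisibly when `path` is given).
#' @export
renderPseudocolor <- function(session, width = 540L, path = NULL,
                              thickness = 3L) {
  width <- as.integer(width)
  height <- as.integer(round(width * 1620 / 2160))
  raster <- array(1, dim = c(height, width, 3)) # white background
  st <- session@strokes
  n <- nrow(st)
  cols <- strokeOrderColors(n)
  if (!n) warning("empty session: rendering a blank canvas")
  sx <- (width - 1) / 2160
  sy <- (height - 1) / 1620
  ev <- session@events
  for (i in seq_len(n)) {
    rgb <- as.numeric(grDevices::col2rgb(cols[i])) / 255
    idx <- st$start[i]:st$end[i]
    px <- pmin(width, pmax(1L, as.integer(round(ev$x[idx] * sx)) + 1L))
    py <- pmin(height, pmax(1L, as.integer(round(ev$y[idx] * sy)) + 1L))
    if (length(idx) == 1L) {
      raster <- .drawLine(raster, px, py, px, py, rgb, thickness)
    } else {
      for (j in seq_len(length(idx) - 1L)) {
        raster <- .drawLine(raster, px[j], py[j], px[j + 1L], py[j + 1L],
                            rgb, thickness)
      }
    }
  }
  img <- new("PseudocolorImage", raster = raster, colors = cols,
             width = width, height = height)
  if (!is.null(path)) {
    png::writePNG(raster, path)
    return(invisible(img))
  }
  img
}
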