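# Overlapping tile grid over a WSI.  Tiles of size s x s with 50% overlap
# per direction: origins at (i*s/2, j*s/2), i.e. centers at s(1+i)/2.
# The interior of a tile is its central quarter-area region
# [s/4, 3s/4) x [s/4, 3s/4) in tile-local coordinates; interiors of the grid
# are mutually disjoint in the WSI frame and consecutive interiors abut.

#' Downsample an image by block averaging
#'
#' Reduces resolution by an integer factor per direction; each output pixel
#' is the mean of a `factor` x `factor` input block (8-bit inputs are
#' rounded half-up back to integers).  Trailing rows/columns that do not
#' fill a block are dropped.  A `resolution_nm_per_px` attribute, if
#' present, is multiplied by `factor`.
#'
#' @param image matrix (grayscale) or H x W x C array, values 0..255.
#' @param factor integer >= 1.
#' @return downsampled image of the same kind.
#' @export
downsample <- function(image, factor) {
  if (!is.numeric(factor) || factor < 1 || factor != round(factor))
    stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  res <- attr(image, "resolution_nm_per_px")
  if (factor == 1L) return(image)
  pool1 <- function(m) {
    H <- (nrow(m) %/% factor) * factor
    W <- (ncol(m) %/% factor) * factor
    m <- m[seq_len(H), seq_len(W), drop = FALSE]
    a <- array(m, dim = c(factor, H / factor, factor, W / factor))
    colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
  }
  if (length(dim(image)) == 3) {
    out <- vapply(seq_len(dim(image)[3]),
                  function(c) pool1(image[, , c]),
                  matrix(0, nrow(image) %/% factor, ncol(image) %/% factor))
  } else {
    out <- pool1(image)
  }
  out <- floor(out + 0.5)  # round half up to 8-bit levels
  if (!is.null(res)) attr(out, "resolution_nm_per_px") <- res * factor
  out
}

#' Build the overlapping tile grid
#'
#' Tiles of size `s` x `s` at origins `(i*s/2, j*s/2)` for integer
#' `i, j >= 0`, keeping only tiles fully contained in the image (no
#' padding at borders).
#'
#' @param image_extent `c(width, height)` in pixels.
#' @param s tile edge length in pixels; must be even and fit the image.
#' @return A `tile_grid`: data.frame with columns `tile_id`, `x_origin`,
#'   `y_origin`, plus attributes `s` and `image_extent`.
#' @export
make_tile_grid <- function(image_extent, s) {
  W <- image_extent[1]; H <- image_extent[2]
  if (s %% 2 != 0) stop("tile size s must be even")
  if (s > min(W, H)) stop("tile size s exceeds image extent")
  xo <- seq(0, W - s, by = s / 2)
  yo <- seq(0, H - s, by = s / 2)
  g <- expand.grid(x_origin = xo, y_origin = yo)
  g <- g[order(g$y_origin, g$x_origin), ]
  g <- data.frame(tile_id = seq_len(nrow(g)),
                  x_origin = g$x_origin, y_origin = g$y_origin)
  structure(g, s = s, image_extent = as.numeric(image_extent),
            class = c("tile_grid", "data.frame"))
}

#' Tile interiors in WSI coordinates
#'
#' The interior of a tile is the half-open central region
#' `[origin + s/4, origin + 3s/4)` per direction.
#'
#' @param grid a [make_tile_grid()] result.
#' @return data.frame `tile_id, x_min, y_min, x_max, y_max`.
#' @export
tile_interiors <- function(grid) {
  s <- attr(grid, "s")
  data.frame(tile_id = grid$tile_id,
             x_min = grid$x_origin + s / 4, y_min = grid$y_origin + s / 4,
             x_max = grid$x_origin + 3 * s / 4,
             y_max = grid$y_origin + 3 * s / 4)
}

#' Classify tiles as "with box" / "without box"
#'
#' A tile is "with box" if at least one box annotation has its center
#' inside the tile's interior (half-open, so a center on a shared interior
#' boundary belongs to exactly one tile).
#'
#' @param grid a [make_tile_grid()] result.
#' @param set an [annotation_set()] with box annotations.
#' @return logical vector, one flag per tile of `grid`.
#' @export
classify_tiles <- function(grid, set) {
  b <- ann_boxes(set)
  cx <- (b$x_min + b$x_max) / 2
  cy <- (b$y_min + b$y_max) / 2
  it <- tile_interiors(grid)
  vapply(seq_len(nrow(it)), function(i) {
    any(cx >= it$x_min[i] & cx < it$x_max[i] &
        cy >= it$y_min[i] & cy < it$y_max[i])
  }, logical(1))
}

#' Sample a balanced (50:50) set of tiles
#'
#' Keeps the minority class of `with_box` entirely and subsamples the
#' majority class uniformly without replacement to the same count.
#'
#' @param grid a [make_tile_grid()] result.
#' @param with_box logical per tile, from [classify_tiles()].
#' @param seed integer RNG seed; the selection is deterministic given it.
#' @return data.frame of the selected grid rows plus a `with_box` column,
#'   balanced exactly.
#' @export
sample_balanced <- function(grid, with_box, seed) {
  stopifnot(length(with_box) == nrow(grid))
  iw <- which(with_box); iwo <- which(!with_box)
  if (length(iw) == 0 || length(iwo) == 0)
    stop("cannot balance: one tile class is empty")
  n <- min(length(iw), length(iwo))
  pick <- function(idx) {
    if (length(idx) == n) return(idx)
    withr_seed <- seed  # local RNG scope, do not disturb global state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(withr_seed)
    sort(sample(idx, n))
  }
  sel <- sort(c(pick(iw), pick(iwo)))
  out <- as.data.frame(grid)[sel, ]
  out$with_box <- with_box[sel]
  rownames(out) <- NULL
  out
}

#' Extract a tile image
#'
#' Pixel-exact crop of the tile region from the WSI raster.
#'
#' @param wsi matrix or H x W x C array.
#' @param grid a [make_tile_grid()] result.
#' @param tile_id tile to extract.
#' @return `s` x `s` (x C) crop.
#' @export
extract_tile_image <- function(wsi, grid, tile_id) {
  r <- grid[grid$tile_id == tile_id, ]
  if (nrow(r) != 1) stop("unknown tile id: ", tile_id)
  s <- attr(grid, "s")
  ry <- (r$y_origin + 1):(r$y_origin + s)
  rx <- (r$x_origin + 1):(r$x_origin + s)
  if (length(dim(wsi)) == 3) wsi[ry, rx, , drop = FALSE] else wsi[ry, rx, drop = FALSE]
}
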