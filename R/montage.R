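#' Electrode montage: name to 2D grid-cell map
#'
#' @param height,width grid dimensions in cells.
#' @param placement named list of integer pairs `c(row, col)` (0-based) or
#'   an n x 2 matrix with electrode names as rownames. Row 0 is the frontal
#'   (top) row, column 0 the left hemisphere.
#' @return Object of class `eeg_montage` with `height`, `width` and
#'   `placement` (n x 2 integer matrix, rownames = electrode names).
#' @export
montage <- function(height, width, placement) {
  if (is.list(placement))
    placement <- do.call(rbind, placement)
  placement <- as.matrix(placement)
  storage.mode(placement) <- "integer"
  if (ncol(placement) != 2) stop("placement must give (row, col) pairs")
  if (is.null(rownames(placement)) || anyDuplicated(rownames(placement)))
    stop("placement must have unique electrode names")
  if (any(placement[, 1] < 0) || any(placement[, 1] >= height) ||
      any(placement[, 2] < 0) || any(placement[, 2] >= width))
    stop("placement coordinates out of the [0,height) x [0,width) grid")
  cell <- placement[, 1] * width + placement[, 2]
  if (anyDuplicated(cell))
    stop("two electrodes mapped to the same grid cell: ",
         paste(rownames(placement)[cell %in% cell[duplicated(cell)]],
               collapse = ", "))
  colnames(placement) <- c("row", "col")
  structure(list(height = as.integer(height), width = as.integer(width),
                 placement = placement),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d x %d grid, %d electrodes placed (%d empty cells)\n",
              x$height, x$width, nrow(x$placement),
              x$height * x$width - nrow(x$placement)))
  invisible(x)
}

#' The default 9 x 9 montage for the 62-channel cap
#'
#' Hard-coded grid placement of the canonical 62 electrodes
#' ([channels_62()]) on a 9 x 9 grid: the prefrontal triple FP1/FPZ/FP2 in
#' row 0 at columns 3-5, AF3/AF4 in row 1 at columns 2 and 6, five dense
#' rows of nine electrodes (frontal through parietal) in rows 2-6, the
#' parieto-occipital row split across columns 0-2, 4 and 6-8 of row 7, and
#' CB1/O1/OZ/O2/CB2 in row 8 at columns 2-6. The remaining 19 cells carry
#' no electrode and are zero-filled when tensorising.
#'
#' @return An `eeg_montage` with `height = width = 9` and 62 placements.
#' @export
#' @examples
#' default_montage_62()
default_montage_62 <- function() {
  rows <- c(rep(0L, 3), rep(1L, 2),
            rep(2:6, each = 9),
            rep(7L, 7), rep(8L, 5))
  cols <- c(3:5, c(2L, 6L),
            rep(0:8, times = 5),
            c(0L, 1L, 2L, 4L, 6L, 7L, 8L), 2:6)
  pl <- cbind(rows, cols)
  rownames(pl) <- channels_62()
  montage(9, 9, pl)
}

#' Read / write a montage JSON file
#'
#' File format: a JSON object with integer `height`, `width` and
#' `placement`, a map from electrode name to a 0-based `[row, col]` pair.
#' Duplicate cells and out-of-range coordinates are rejected on load.
#'
#' @param file path to a montage JSON file.
#' @return `load_montage`: an `eeg_montage`. `save_montage`: `file`,
#'   invisibly.
#' @export
load_montage <- function(file) {
  j <- jsonlite::fromJSON(file)
  if (is.null(j$height) || is.null(j$width) || is.null(j$placement))
    stop("montage file must contain height, width and placement")
  montage(j$height, j$width,
          lapply(j$placement, function(p) as.integer(p)))
}

#' @rdname load_montage
#' @param m an `eeg_montage` to write.
#' @export
save_montage <- function(m, file) {
  stopifnot(inherits(m, "eeg_montage"))
  pl <- stats::setNames(
    lapply(seq_len(nrow(m$placement)), function(i) unname(m$placement[i, ])),
    rownames(m$placement))
  jsonlite::write_json(list(height = m$height, width = m$width,
                            placement = pl),
                       file, auto_unbox = TRUE)
  invisible(file)
}

#' Map channel-band features onto the montage grid
#'
#' Produces, for every epoch, an `H x W x F` tensor (`F` = number of
#' bands) with `grid[r, c, f]` equal to the feature of the electrode
#' placed at cell `(r, c)` and exactly zero at cells without electrodes.
#' Placement is keyed by electrode name, so the input channel order is
#' irrelevant.
#'
#' @param tfs a [extract_tfs()] result (or any `tfs_matrix`).
#' @param montage an `eeg_montage`; every TFS channel must be placed in it.
#' @return Object of class `spatial_tensor_set`: `grid` (array
#'   epochs x H x W x F), `montage`, `band_set`, `method`, `meta`.
#' @export
tensorize <- function(tfs, montage = default_montage_62()) {
  stopifnot(inherits(tfs, "tfs_matrix"), inherits(montage, "eeg_montage"))
  missing <- setdiff(tfs$channel_names, rownames(montage$placement))
  if (length(missing))
    stop("channels absent from the montage: ", paste(missing, collapse = ", "))
  d <- dim(tfs$values)
  grid <- array(0, dim = c(d[1], montage$height, montage$width, d[3]))
  for (j in seq_len(d[2])) {
    rc <- montage$placement[tfs$channel_names[j], ]
    grid[, rc[1] + 1L, rc[2] + 1L, ] <- tfs$values[, j, ]
  }
  structure(list(grid = grid, montage = montage, band_set = tfs$band_set,
                 method = tfs$method, meta = tfs$meta),
            class = "spatial_tensor_set")
}

#' @export
print.spatial_tensor_set <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<spatial_tensor_set> %d epochs x %d x %d x %d (%s features)\n",
              d[1], d[2], d[3], d[4], x$method))
  invisible(x)
}

#' Recover channel-band features from spatial tensors
#'
#' Exact inverse of [tensorize()] on placed cells: reads the montage cells
#' back into an epochs x channels x bands array; values at non-electrode
#' cells are ignored.
#'
#' @param tensors a `spatial_tensor_set`.
#' @param montage montage to read with (default: the one stored in
#'   `tensors`); its grid size must match.
#' @return Array epochs x channels x bands, channels in montage placement
#'   order (dimnames carry the names).
#' @export
detensorize <- function(tensors, montage = NULL) {
  stopifnot(inherits(tensors, "spatial_tensor_set"))
  montage <- montage %||% tensors$montage
  d <- dim(tensors$grid)
  if (montage$height != d[2] || montage$width != d[3])
    stop("montage grid size does not match the tensor")
  nch <- nrow(montage$placement)
  out <- array(0, dim = c(d[1], nch, d[4]),
               dimnames = list(NULL, rownames(montage$placement),
                               tensors$band_set$name))
  for (j in seq_len(nch)) {
    rc <- montage$placement[j, ]
    out[, j, ] <- tensors$grid[, rc[1] + 1L, rc[2] + 1L, ]
  }
  out
}
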