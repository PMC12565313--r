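#' Read a radiometric temperature grid
#'
#' Parses a plain-text matrix of surface temperatures in degC, the dialect
#' used by public radiometric breast-thermography archives: one image row per
#' line, values separated by whitespace or semicolons. Files that use a
#' decimal comma (and contain no `.` anywhere) are normalized by replacing
#' `,` with `.`. No scaling is applied; values are taken as degC.
#'
#' The package convention is 1-based `(row, col)` indexing with row 1 at the
#' top, matching raster file order.
#'
#' @param path Path to the text file.
#' @return A numeric matrix of class `thermogram` (`M` rows x `N` cols).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("20 21", "22 23"), f)
#' read_temperature_grid(f)
read_temperature_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty temperature file: ", path)
  if (!any(grepl(".", lines, fixed = TRUE)) &&
      any(grepl(",", lines, fixed = TRUE))) {
    lines <- gsub(",", ".", lines, fixed = TRUE)
  }
  tokens <- strsplit(trimws(lines), "[;[:space:]]+")
  n <- length(tokens[[1]])
  widths <- lengths(tokens)
  if (any(widths != n)) {
    bad <- which(widths != n)[1]
    stop("ragged row in ", path, ": line ", bad, " has ", widths[bad],
         " values, expected ", n)
  }
  values <- suppressWarnings(as.numeric(unlist(tokens)))
  if (anyNA(values)) {
    bad <- which(is.na(values))[1]
    stop("non-numeric token '", unlist(tokens)[bad], "' in ", path)
  }
  if (any(!is.finite(values))) stop("non-finite temperature in ", path)
  grid <- matrix(values, nrow = length(tokens), ncol = n, byrow = TRUE)
  class(grid) <- c("thermogram", class(grid))
  grid
}

#' Read a binary breast mask
#'
#' Accepts a bilevel/grayscale PNG or a numeric text grid; any value
#' strictly greater than zero is in-mask (so 1 and 255 both count).
#'
#' @param path Path to a PNG or plain-text numeric grid.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img > 0)
  }
  grid <- read_temperature_grid(path)
  unclass(grid) > 0
}

mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0) stop("mask is empty")
  list(rows = range(rows), cols = range(cols))
}

new_breast_sample <- function(crop, mask, side, subject_id, label) {
  structure(
    list(pixels = crop[mask], crop = crop, mask = mask, side = side,
         subject_id = subject_id, label = label),
    class = "breast_sample"
  )
}

#' @export
print.breast_sample <- function(x, ...) {
  cat("<breast_sample> ", x$subject_id %||% "?", " ", x$side, " (",
      length(x$pixels), " px, label ", x$label %||% "unknown", ")\n", sep = "")
  invisible(x)
}

#' Split a masked thermogram into left and right breast samples
#'
#' The division column is the midpoint of the mask's horizontal bounding box
#' (so off-centre subjects split correctly); columns strictly left of the
#' division go to the left sample and the rest to the right. For a bounding
#' box spanning 20 columns this yields 10 columns per side. Set
#' `division = "image"` to divide at the image midline instead. The division
#' column itself is assigned to the right sample (half-open convention).
#' A mask confined entirely to one half of the image (a single remaining
#' breast) raises a "unilateral mask" error so such samples can be excluded
#' upstream.
#'
#' @param thermogram A `thermogram` (or plain numeric matrix), degC.
#' @param mask Logical (or 0/1) matrix of the same dimensions covering both
#'   breasts.
#' @param subject_id,labels Optional subject identifier and length-2
#'   `c(left, right)` labels (`"NA"`/`"A"`) attached to the samples.
#' @param division `"mask"` (bounding-box midpoint, default) or `"image"`.
#' @return A list with `breast_sample` elements `left` and `right`; each
#'   carries the masked rectangular crop of its side, the in-mask pixel
#'   multiset, side, subject id and label.
#' @export
split_breasts <- function(thermogram, mask, subject_id = NA_character_,
                          labels = c(NA_character_, NA_character_),
                          division = c("mask", "image")) {
  division <- match.arg(division)
  mask <- mask > 0
  if (!all(dim(thermogram) == dim(mask))) {
    stop("thermogram (", paste(dim(thermogram), collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"),
         ") dimensions differ")
  }
  if (!any(mask)) stop("mask is empty")
  # a two-breast mask must straddle the image's vertical midline; a mask
  # confined to one half (e.g. post-amputation) cannot be split per breast
  occupied <- range(which(colSums(mask) > 0))
  mid <- (ncol(mask) + 1) / 2
  if (occupied[2] < mid) {
    stop("unilateral mask: no in-mask pixels on the right half of the image")
  }
  if (occupied[1] > mid) {
    stop("unilateral mask: no in-mask pixels on the left half of the image")
  }
  div <- if (division == "mask") {
    bb <- mask_bbox(mask)
    # 0-based: floor((cmin + cmax + 1) / 2); +1 converts to 1-based column
    floor(((bb$cols[1] - 1) + (bb$cols[2] - 1) + 1) / 2) + 1
  } else {
    floor(ncol(mask) / 2) + 1
  }

  left_mask <- mask; left_mask[, seq_len(ncol(mask)) >= div] <- FALSE
  right_mask <- mask; right_mask[, seq_len(ncol(mask)) < div] <- FALSE
  if (!any(left_mask) || !any(right_mask)) {
    empty <- if (!any(left_mask)) "left" else "right"
    stop("unilateral mask: no in-mask pixels on the ", empty,
         " side of column ", div)
  }

  crop_side <- function(m, side) {
    bb <- mask_bbox(m)
    rows <- bb$rows[1]:bb$rows[2]
    cols <- bb$cols[1]:bb$cols[2]
    new_breast_sample(
      crop = unclass(thermogram)[rows, cols, drop = FALSE],
      mask = m[rows, cols, drop = FALSE],
      side = side, subject_id = subject_id,
      label = if (side == "left") labels[1] else labels[2]
    )
  }
  list(left = crop_side(left_mask, "left"),
       right = crop_side(right_mask, "right"))
}
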