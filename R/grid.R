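#' The 24-2 test grid (right-eye orientation)
#'
#' Standard automated perimetry's 24-2 pattern places 54 stimulus locations
#' on a 6 degree lattice covering the central 24 degrees, with the nasal
#' step extension to 27 degrees at `y = +/-3` (nasal is `x = -27` in
#' right-eye orientation; positive `x` is temporal). The two locations that
#' fall on the physiologic blind spot of a right eye, `(15, 3)` and
#' `(15, -3)`, are excluded, leaving the 52 points used throughout this
#' package: every visual field is treated as a 52-point vector in this
#' fixed ordering.
#'
#' The frozen index convention is row-major from the superior row
#' (`y = 21`) down to the inferior row (`y = -21`), with `x` ascending
#' within each row. Row lengths after blind-spot exclusion are
#' 4, 6, 8, 8, 8, 8, 6, 4.
#'
#' @return A data frame with 52 rows and columns `index`, `x`, `y` (degrees
#'   of visual angle, right-eye orientation; positive `x` temporal).
#' @examples
#' g <- vf_grid()
#' nrow(g)  # 52
#' @export
vf_grid <- function() {
  rows <- list(
    c(21, -9, 9), c(15, -15, 15), c(9, -21, 21),
    c(3, -27, 21), c(-3, -27, 21),
    c(-9, -21, 21), c(-15, -15, 15), c(-21, -9, 9)
  )
  pts <- do.call(rbind, lapply(rows, function(r) {
    x <- seq(r[2], r[3], by = 6L)
    cbind(x = x, y = r[1])
  }))
  pts <- pts[!(pts[, "x"] == 15 & abs(pts[, "y"]) == 3), , drop = FALSE]
  data.frame(index = seq_len(nrow(pts)), x = pts[, "x"], y = pts[, "y"])
}

#' Mirror permutation about the vertical midline
#'
#' Maps each grid location `(x, y)` to `(-x, y)`. Because locations within a
#' row are stored with `x` ascending and a left eye's location set is the
#' exact mirror image of the right eye's (its blind-spot exclusions sit at
#' `x = -15`), the mirror amounts to reversing the order of values within
#' each horizontal row. The permutation is an involution.
#'
#' @param grid Grid as returned by [vf_grid()].
#' @return Integer vector `p` of length 52: position `i` of the mirrored
#'   field takes the value at position `p[i]` of the original.
#' @export
mirror_permutation <- function(grid = vf_grid()) {
  p <- integer(nrow(grid))
  for (yy in unique(grid$y)) {
    idx <- which(grid$y == yy)
    p[idx] <- rev(idx)
  }
  p
}

loc_cols <- function() sprintf("loc_%02d", 1:52)
td_cols <- function() sprintf("td_%02d", 1:52)
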