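#' Fixed-bin-number gray-level discretization
#'
#' Maps the intensities of an ROI onto integer gray levels \code{1..Ng} with
#' the fixed-bin-number (FBN) rule
#' \deqn{g(x) = \lceil N_g (x - x_{min}) / (x_{max} - x_{min}) \rceil}
#' with \eqn{g(x_{min}) = 1}. FBN is the appropriate scheme for
#' arbitrary-unit (count) images such as perfusion SPECT, where absolute
#' intensities carry no physical calibration: every non-constant ROI attains
#' both level 1 and level \code{Ng}, making subjects comparable. A constant
#' ROI maps all voxels to level 1.
#'
#' @param grid 3D numeric array of intensities.
#' @param mask 3D logical array, same shape as \code{grid}; the ROI.
#' @param ng number of gray levels (>= 2).
#' @return A \code{DiscretizedROI}: a list with \code{levels} (3D integer
#'   array, \code{NA} outside the ROI, cropped to the ROI bounding box),
#'   \code{ng}, and \code{n_voxels}.
#' @examples
#' g <- array(c(0, 2.5, 5, 7.5, 10, 0, 0, 0), dim = c(2, 2, 2))
#' m <- array(c(rep(TRUE, 5), rep(FALSE, 3)), dim = c(2, 2, 2))
#' sort(unique(as.vector(discretizeFBN(g, m, 4)$levels)))
#' @export
discretizeFBN <- function(grid, mask, ng) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  if (!identical(dim(grid), dim(mask)))
    stop("mask shape does not match grid shape")
  if (ng < 2) stop("ng must be at least 2")
  mask <- mask & !is.na(grid)
  if (!any(mask)) stop("empty mask: no voxels to discretize")
  v <- grid[mask]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lev <- rep(1L, length(v))
  } else {
    lev <- as.integer(ceiling(ng * (v - rng[1]) / (rng[2] - rng[1])))
    lev[lev < 1L] <- 1L            # x == min maps to level 1
    lev[lev > ng] <- ng            # guard against fp overshoot at the top
  }
  full <- array(NA_integer_, dim(grid))
  full[mask] <- lev
  cropDiscretized(full, as.integer(ng))
}

## Crop a level array (NA outside ROI) to its bounding box, keeping a 0-voxel
## margin; texture builders pad as needed themselves.
cropDiscretized <- function(levels, ng) {
  d <- dim(levels)
  inroi <- !is.na(levels)
  ix <- range(which(apply(inroi, 1, any)))
  iy <- range(which(apply(inroi, 2, any)))
  iz <- range(which(apply(inroi, 3, any)))
  lev <- levels[ix[1]:ix[2], iy[1]:iy[2], iz[1]:iz[2], drop = FALSE]
  structure(list(levels = lev, ng = ng, n_voxels = sum(inroi)),
            class = "DiscretizedROI")
}

#' @export
print.DiscretizedROI <- function(x, ...) {
  cat(sprintf("DiscretizedROI: %d voxels, Ng = %d, bounding box %s\n",
              x$n_voxels, x$ng, paste(dim(x$levels), collapse = "x")))
  invisible(x)
}
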