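## 3D texture-matrix construction for discretized ROIs.
##
## All builders operate on a DiscretizedROI (integer levels 1..Ng, NA outside
## the ROI, cropped to the ROI bounding box). Conventions:
##   * GLCM / GLRLM: the 13 unique 3D directions at Chebyshev distance 1;
##     GLCM symmetrized per direction.
##   * GLSZM / GLDZM: zones are 26-connected same-level components; the zone
##     distance is the minimal Chebyshev distance of any zone voxel to a
##     non-ROI voxel (boundary voxels have distance 1).
##   * NGTDM / NGLDM: 26-voxel neighbourhood (Chebyshev distance 1); the
##     NGLDM coarseness (level-difference) parameter is 0.
## Matrices hold raw nonnegative integer counts; probability normalization
## happens at feature-evaluation time.

## The 13 unique displacement vectors (one per opposite pair of the 26).
offsets13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(g[keep, , drop = FALSE])
}

offsets26 <- function() {
  o <- offsets13()
  rbind(o, -o)
}

## Aligned subarrays across an offset: indices where both v[i] and v[i+o]
## fall inside the array. Returns the two index-range lists.
offsetRanges <- function(d, o) {
  fa <- pmax(1L, 1L - o)
  ta <- pmin(d, d - o)
  if (any(ta < fa)) return(NULL)
  list(a = lapply(1:3, function(k) fa[k]:ta[k]),
       b = lapply(1:3, function(k) (fa[k] + o[k]):(ta[k] + o[k])))
}

subarr <- function(x, idx) x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

## Level pairs across one offset (both endpoints inside the ROI).
levelPairs <- function(lev, o) {
  r <- offsetRanges(dim(lev), o)
  if (is.null(r)) return(list(a = integer(0), b = integer(0)))
  a <- subarr(lev, r$a); b <- subarr(lev, r$b)
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

## ---- GLCM --------------------------------------------------------------

glcmDirection <- function(lev, ng, o) {
  p <- levelPairs(lev, o)
  m <- matrix(tabulate((p$a - 1L) * ng + p$b, nbins = ng * ng),
              nrow = ng, ncol = ng, byrow = TRUE)
  m + t(m)   # symmetric co-occurrences
}

glcmMatrices <- function(droi) {
  offs <- offsets13()
  lapply(seq_len(nrow(offs)), function(i)
    glcmDirection(droi$levels, droi$ng, offs[i, ]))
}

## ---- GLRLM -------------------------------------------------------------

## Runs along direction o: voxels are grouped into lines via an integer
## anchor (constant along a line), ordered by the signed step coordinate t;
## consecutive same-level voxels with step gap o.o form one run.
glrlmDirection <- function(lev, ng, o) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  lv <- lev[!is.na(lev)]
  oo <- sum(o * o)
  tt <- as.vector(idx %*% o)
  anc <- idx * oo - outer(tt, o)            # integer anchor, constant on line
  key <- ((anc[, 1] + 2048) * 4096 + (anc[, 2] + 2048)) * 4096 +
    (anc[, 3] + 2048)
  ord <- order(key, tt)
  k <- key[ord]; t2 <- tt[ord]; l2 <- lv[ord]
  m <- length(k)
  newrun <- c(TRUE,
              k[-1] != k[-m] | (t2[-1] - t2[-m]) != oo | l2[-1] != l2[-m])
  runid <- cumsum(newrun)
  len <- tabulate(runid)
  levrun <- l2[newrun]
  rmax <- max(len)
  matrix(tabulate((levrun - 1L) * rmax + len, nbins = ng * rmax),
         nrow = ng, ncol = rmax, byrow = TRUE)
}

glrlmMatrices <- function(droi) {
  offs <- offsets13()
  lapply(seq_len(nrow(offs)), function(i)
    glrlmDirection(droi$levels, droi$ng, offs[i, ]))
}

## ---- zone decomposition (shared by GLSZM / GLDZM) ----------------------

## Chebyshev distance map to the nearest non-ROI voxel (>= 1 on the ROI),
## by iterative erosion with the full 3x3x3 structuring element. Voxels
## outside the cropped bounding box count as non-ROI.
chebyshevDistanceMap <- function(inroi) {
  d <- dim(inroi)
  dist <- array(NA_integer_, d)
  cur <- inroi
  offs <- offsets26()
  k <- 1L
  while (any(cur)) {
    interior <- cur
    for (i in seq_len(nrow(offs))) {
      o <- offs[i, ]
      shifted <- array(FALSE, d)
      r <- offsetRanges(d, o)
      if (!is.null(r)) {
        sa <- subarr(cur, r$b)
        shifted[r$a[[1]], r$a[[2]], r$a[[3]]] <- sa
      }
      interior <- interior & shifted
      if (!any(interior)) break
    }
    boundary <- cur & !interior
    dist[boundary] <- k
    cur <- interior
    k <- k + 1L
  }
  dist
}

## 26-connected same-level components. Returns, per ROI voxel, a zone id,
## plus per-zone level / size / minimal boundary distance.
zoneDecomposition <- function(droi) {
  lev <- droi$levels
  d <- dim(lev)
  inroi <- !is.na(lev)
  lin <- array(seq_len(prod(d)), d)
  offs <- offsets13()
  ea <- vector("list", nrow(offs)); eb <- ea
  for (i in seq_len(nrow(offs))) {
    r <- offsetRanges(d, offs[i, ])
    if (is.null(r)) next
    a <- subarr(lev, r$a); b <- subarr(lev, r$b)
    keep <- !is.na(a) & !is.na(b) & a == b
    ea[[i]] <- subarr(lin, r$a)[keep]
    eb[[i]] <- subarr(lin, r$b)[keep]
  }
  verts <- lin[inroi]
  comp <- connectedComponents(verts, unlist(ea), unlist(eb))
  zlev <- lev[inroi]
  sizes <- tabulate(comp)
  zone_level <- integer(max(comp))
  zone_level[comp] <- zlev                 # consistent within a zone
  dmap <- chebyshevDistanceMap(inroi)
  zone_dist <- vapply(split(dmap[inroi], comp), min, integer(1))
  list(zone_level = zone_level, zone_size = sizes,
       zone_distance = as.integer(zone_dist), n_zones = max(comp))
}

## Union-find over an explicit edge list; vertices are arbitrary integer
## ids. Returns compact component ids (1..k) in the order of `verts`.
connectedComponents <- function(verts, from, to) {
  id <- seq_along(verts)
  pos <- integer(max(verts))
  pos[verts] <- id
  parent <- id
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(from)) {
    f <- pos[from]; t <- pos[to]
    for (e in seq_along(f)) {
      rf <- findRoot(f[e]); rt <- findRoot(t[e])
      if (rf != rt) parent[max(rf, rt)] <- min(rf, rt)
    }
  }
  roots <- vapply(id, findRoot, integer(1))
  match(roots, unique(roots))
}

glszmMatrix <- function(zones, ng) {
  zmax <- max(zones$zone_size)
  matrix(tabulate((zones$zone_level - 1L) * zmax + zones$zone_size,
                  nbins = ng * zmax),
         nrow = ng, ncol = zmax, byrow = TRUE)
}

gldzmMatrix <- function(zones, ng) {
  dmax <- max(zones$zone_distance)
  matrix(tabulate((zones$zone_level - 1L) * dmax + zones$zone_distance,
                  nbins = ng * dmax),
         nrow = ng, ncol = dmax, byrow = TRUE)
}

## ---- NGTDM / NGLDM -----------------------------------------------------

## Per-voxel neighbour sums over the 26-neighbourhood, restricted to ROI.
neighbourStats <- function(lev) {
  d <- dim(lev)
  nsum <- array(0, d)       # sum of neighbour levels
  ncnt <- array(0L, d)      # number of in-ROI neighbours
  neq <- array(0L, d)       # number of equal-level neighbours
  offs <- offsets26()
  for (i in seq_len(nrow(offs))) {
    r <- offsetRanges(d, offs[i, ])
    if (is.null(r)) next
    a <- subarr(lev, r$a); b <- subarr(lev, r$b)
    keep <- !is.na(a) & !is.na(b)
    add <- array(0, dim(a)); add[keep] <- b[keep]
    nsum[r$a[[1]], r$a[[2]], r$a[[3]]] <-
      subarr(nsum, r$a) + add
    cnt <- array(0L, dim(a)); cnt[keep] <- 1L
    ncnt[r$a[[1]], r$a[[2]], r$a[[3]]] <-
      subarr(ncnt, r$a) + cnt
    eq <- array(0L, dim(a)); eq[keep & a == b] <- 1L
    neq[r$a[[1]], r$a[[2]], r$a[[3]]] <-
      subarr(neq, r$a) + eq
  }
  list(nsum = nsum, ncnt = ncnt, neq = neq)
}

## NGTDM: per level i, n_i = #voxels with >= 1 valid neighbour, s_i = sum of
## |level - mean neighbour level| over those voxels.
ngtdmTable <- function(droi, nb = NULL) {
  lev <- droi$levels
  if (is.null(nb)) nb <- neighbourStats(lev)
  inroi <- !is.na(lev)
  valid <- inroi & nb$ncnt > 0L
  l <- lev[valid]
  dev <- abs(l - nb$nsum[valid] / nb$ncnt[valid])
  n_i <- tabulate(l, nbins = droi$ng)
  s_i <- numeric(droi$ng)
  agg <- tapply(dev, l, sum)
  s_i[as.integer(names(agg))] <- agg
  data.frame(level = seq_len(droi$ng), n = n_i, s = s_i)
}

## NGLDM: dependence count k = number of 26-neighbours with identical level
## (coarseness parameter 0); matrix entry (i, k + 1).
ngldmMatrix <- function(droi, nb = NULL) {
  lev <- droi$levels
  if (is.null(nb)) nb <- neighbourStats(lev)
  inroi <- !is.na(lev)
  l <- lev[inroi]
  k <- nb$neq[inroi] + 1L       # column index = dependence count + 1
  kmax <- max(k)
  matrix(tabulate((l - 1L) * kmax + k, nbins = droi$ng * kmax),
         nrow = droi$ng, ncol = kmax, byrow = TRUE)
}

#' Compute all 3D texture matrices of a discretized ROI
#'
#' Builds the per-direction GLCM and GLRLM stacks (13 unique directions at
#' Chebyshev distance 1, GLCM symmetrized), the zone-based GLSZM and GLDZM
#' (26-connected zones; distance = minimal Chebyshev distance to a non-ROI
#' voxel), and the neighbourhood NGTDM table and NGLDM matrix (26-voxel
#' neighbourhood, dependence coarseness 0). Entries are raw counts.
#'
#' @param droi a \code{DiscretizedROI} from [discretizeFBN()].
#' @return A list with elements \code{glcm} (list of 13 matrices),
#'   \code{glrlm} (list of 13), \code{glszm}, \code{gldzm}, \code{ngtdm}
#'   (data.frame \code{level,n,s}), \code{ngldm}, \code{ng},
#'   \code{n_voxels}.
#' @export
computeMatrices <- function(droi) {
  stopifnot(inherits(droi, "DiscretizedROI"))
  nb <- neighbourStats(droi$levels)
  zones <- zoneDecomposition(droi)
  list(glcm = glcmMatrices(droi),
       glrlm = glrlmMatrices(droi),
       glszm = glszmMatrix(zones, droi$ng),
       gldzm = gldzmMatrix(zones, droi$ng),
       ngtdm = ngtdmTable(droi, nb),
       ngldm = ngldmMatrix(droi, nb),
       ng = droi$ng, n_voxels = droi$n_voxels)
}
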