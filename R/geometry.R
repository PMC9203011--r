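#' @useDynLib crusparks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Lattice constant of the RyR array (centre-to-centre spacing, nm).
RYR_LATTICE_NM <- 36

#' RyR cluster layouts
#'
#' Builds one of the five built-in ryanodine-receptor (RyR) cluster layouts
#' or wraps a custom position table.  Positions live on a 36-nm lattice on
#' the junctional SR plane; every built-in layout holds exactly 50 channels
#' and differs only in how they are arranged: `G1` is a compact,
#' near-circular cluster, `G2` an oblong single cluster, `G3`--`G5` split
#' the same 50 channels into 2, 3 and 12 sub-clusters to emulate the
#' cluster dispersion seen in failing cardiomyocytes.
#'
#' @param geometry one of `"G1".."G5"`, ignored when `positions` is given.
#' @param positions optional data frame with columns `x_nm`, `y_nm` for a
#'   custom layout (e.g. the 30-RyR variants).  Positions are interpreted as
#'   channel centres in nm; the layout is re-centred when gridded.
#' @return an object of class `cru_layout` with elements `positions`
#'   (data frame `x_nm`, `y_nm`), `geometry_id`, `n_ryr`, `subcluster`
#'   (integer membership under 36-nm lattice adjacency) and
#'   `n_subclusters`.
#' @examples
#' lay <- build_layout("G3")
#' lay$n_subclusters  # 2
#' @export
build_layout <- function(geometry = c("G1", "G2", "G3", "G4", "G5"),
                         positions = NULL) {
  a <- RYR_LATTICE_NM
  if (is.null(positions)) {
    geometry <- match.arg(geometry)
    ij <- switch(geometry,
      G1 = layout_compact_disc(50),
      G2 = layout_blocks(list(c(0, 0)), 10, 5),
      G3 = layout_blocks(list(c(0, 0), c(7, 0)), 5, 5),
      G4 = rbind(layout_blocks(list(c(0, 0), c(7, 0), c(14, 0)), 4, 4),
                 c(0, 4), c(7, 4)),
      G5 = {
        org <- expand.grid(x = c(0L, 5L, 10L, 15L), y = c(0L, 5L, 10L))
        base <- do.call(rbind, lapply(seq_len(nrow(org)), function(i)
          layout_blocks(list(c(org$x[i], org$y[i])), 2, 2)))
        rbind(base, c(2, 0), c(17, 10))
      })
    pos <- data.frame(x_nm = ij[, 1] * a, y_nm = ij[, 2] * a)
    id <- geometry
  } else {
    pos <- as.data.frame(positions)
    if (!all(c("x_nm", "y_nm") %in% names(pos)))
      stop("custom layouts need columns 'x_nm' and 'y_nm'")
    pos <- data.frame(x_nm = as.numeric(pos$x_nm), y_nm = as.numeric(pos$y_nm))
    id <- "custom"
  }
  if (nrow(pos) > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin < a - 1e-9)
      stop("geometry error: RyR centres closer than ", a, " nm (overlap)")
  }
  sub <- subcluster_membership(pos)
  structure(list(positions = pos, geometry_id = id, n_ryr = nrow(pos),
                 subcluster = sub,
                 n_subclusters = if (nrow(pos)) max(sub) else 0L),
            class = "cru_layout")
}

# 50 lattice points closest to the origin; deterministic tie-break by
# (x, y) order so the layout is reproducible.
layout_compact_disc <- function(n_ryr) {
  r <- 6
  g <- expand.grid(x = -r:r, y = -r:r)
  g <- g[order(g$x^2 + g$y^2, g$x, g$y), ]
  as.matrix(g[seq_len(n_ryr), c("x", "y")])
}

# rectangular blocks of lattice points at the given origins
layout_blocks <- function(origins, w, h) {
  do.call(rbind, lapply(origins, function(o)
    as.matrix(expand.grid(x = o[1] + 0:(w - 1), y = o[2] + 0:(h - 1)))))
}

# Connected components under 8-neighbour lattice adjacency (centres within
# 36 * sqrt(2) nm).
subcluster_membership <- function(pos) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(pos))
  adj <- d <= RYR_LATTICE_NM * sqrt(2) + 1e-6
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Per-RyR neighbour counts
#'
#' A neighbour is another channel whose centre lies within one lattice
#' diagonal (36 * sqrt(2) nm), i.e. the 8-neighbourhood on the RyR lattice.
#'
#' @param layout a [build_layout()] object.
#' @return list with `counts` (integer per RyR) and `histogram` (a table of
#'   counts).
#' @export
neighbor_histogram <- function(layout) {
  stopifnot(inherits(layout, "cru_layout"))
  pos <- layout$positions
  if (nrow(pos) == 1) {
    counts <- 0L
  } else {
    d <- as.matrix(stats::dist(pos))
    counts <- as.integer(rowSums(d <= RYR_LATTICE_NM * sqrt(2) + 1e-6) - 1L)
  }
  list(counts = counts, histogram = table(factor(counts, levels = 0:max(8, counts))))
}

#' Desk-scale study layouts
#'
#' Two 16-RyR layouts sized for coarse verification grids: `"compact"` is
#' a single 4 x 4 cluster; `"dispersed"` splits the same 16 channels into
#' four 2 x 2 sub-clusters whose facing channels sit 72 nm apart (twice
#' the lattice constant), the regime where spark success requires release
#' to jump between sub-clusters.  They scale the compact-versus-dispersed
#' contrast of the 50-RyR geometries down to sizes a single CPU can batch.
#'
#' @param kind `"compact"` or `"dispersed"`.
#' @return a `cru_layout`.
#' @export
desk_layout <- function(kind = c("compact", "dispersed")) {
  kind <- match.arg(kind)
  a <- RYR_LATTICE_NM
  ij <- if (kind == "compact") {
    as.matrix(expand.grid(x = 0:3, y = 0:3))
  } else {
    org <- rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3))
    do.call(rbind, lapply(seq_len(4), function(i)
      as.matrix(expand.grid(x = org[i, 1] + 0:1, y = org[i, 2] + 0:1))))
  }
  build_layout(positions = data.frame(x_nm = ij[, 1] * a, y_nm = ij[, 2] * a))
}

#' Read a custom layout from CSV
#'
#' Expects a header `x_nm,y_nm`, one RyR centre per row.
#' @param path path to the CSV file.
#' @return a `cru_layout` object.
#' @export
read_layout_csv <- function(path) {
  build_layout(positions = utils::read.csv(path))
}

# voxel label codes shared with the C++ core
LAB_CYT <- 0L; LAB_JSR <- 1L; LAB_NSR <- 2L; LAB_TT <- 3L

#' Build the voxelized simulation domain
#'
#' Discretizes the calcium release unit into a cube of `n^3` voxels of side
#' `dx_nm`.  The junctional SR (jSR) is a one-voxel slab beneath the RyR
#' plane, padded laterally by one receptor width (36 nm) around the
#' cluster; a one-voxel cleft separates the jSR membrane from the t-tubule
#' exclusion zone above it.  The network SR (nSR) is a regular lattice
#' frame of one-voxel bars spanning the cytosol, luminally connected to the
#' jSR, whose cytosol-facing faces carry the SERCA flux.
#'
#' @param layout a [build_layout()] object; the layout centroid is placed
#'   at the domain centre.
#' @param n voxels per axis (default 84).
#' @param dx_nm voxel side in nm (default 12).
#' @param nsr_spacing lattice frame pitch of the nSR bars, in voxels.  The
#'   default (`NULL`) keeps the physical pitch of the reference domain,
#'   168 nm (14 voxels at 12 nm), whatever the voxel size.
#' @param serca_area_range acceptable total SERCA face area in um^2; a
#'   computed area outside the range triggers a warning, not an error,
#'   since reduced desk-scale grids cannot reach the reference area.
#' @param tt include the t-tubule exclusion slab (default TRUE).
#' @return an object of class `cru_grid`: voxel `labels` (n x n x n integer
#'   array; 0 cytosol, 1 jSR, 2 nSR, 3 t-tubule exclusion), per-channel
#'   RyR face pairs, SERCA face pairs, areas and volume bookkeeping.
#' @export
build_grid <- function(layout, n = 84L, dx_nm = 12,
                       nsr_spacing = NULL, serca_area_range = c(4.54, 4.85),
                       tt = TRUE) {
  stopifnot(inherits(layout, "cru_layout"))
  n <- as.integer(n)
  a <- RYR_LATTICE_NM
  if (is.null(nsr_spacing)) nsr_spacing <- max(3L, as.integer(round(168 / dx_nm)))
  s <- as.integer(nsr_spacing)
  zj <- n %/% 2L                      # 0-based z-index of the jSR slab
  off <- (s %/% 2L) %% s              # keep frame planes off the cube faces

  # channel centres in domain coordinates (nm), centroid at the cube centre
  pos <- layout$positions
  ctr <- c(mean(pos$x_nm), mean(pos$y_nm))
  half <- n * dx_nm / 2
  cx <- pos$x_nm - ctr[1] + half
  cy <- pos$y_nm - ctr[2] + half

  centers <- (seq_len(n) - 0.5) * dx_nm   # voxel-centre coordinates, nm
  # align the RyR lattice with voxel centres (all channels share one
  # offset because 36 is a multiple of dx), so footprints are symmetric
  # and never straddle voxel boundaries
  snap <- function(v) {
    if (length(v) == 0) return(v)
    v + (centers[which.min(abs(centers - v[1]))] - v[1])
  }
  if (a %% dx_nm == 0) { cx <- snap(cx); cy <- snap(cy) }
  pad <- a + a / 2                        # receptor half-width + padding

  # lateral footprint masks (n x n logical)
  in_squares <- function(halfwidth) {
    m <- matrix(FALSE, n, n)
    for (k in seq_along(cx)) {
      ix <- which(abs(centers - cx[k]) <= halfwidth + 1e-9)
      iy <- which(abs(centers - cy[k]) <= halfwidth + 1e-9)
      m[ix, iy] <- TRUE
    }
    m
  }
  foot_pad <- in_squares(pad)             # jSR footprint (padded)
  if (layout$n_ryr > 0) {
    if (!any(foot_pad))
      stop("layout does not intersect the domain; increase n or dx_nm")
    rng <- range(which(foot_pad, arr.ind = TRUE))
    if (rng[1] <= 1 || rng[2] >= n)
      stop("layout (plus jSR padding) exceeds the domain")
  }
  if (zj + 3L > n - 1L)
    stop("domain too shallow for the jSR/cleft/t-tubule stack")

  labels <- array(LAB_CYT, dim = c(n, n, n))
  labels[, , zj + 1L][foot_pad] <- LAB_JSR          # R indices are 1-based
  if (tt) labels[, , zj + 3L][foot_pad] <- LAB_TT   # cleft voxel between

  # nSR lattice frame: voxels with >= 2 coordinates on the frame planes
  onp <- (seq_len(n) - 1L) %% s == off
  OX <- array(onp, dim = c(n, n, n))
  OY <- aperm(OX, c(2, 1, 3))
  OZ <- aperm(OX, c(3, 2, 1))
  frame <- (OX & OY) | (OX & OZ) | (OY & OZ)
  # keep the cleft and the t-tubule stack free above the jSR footprint
  blocked <- array(FALSE, dim = c(n, n, n))
  blocked[, , zj + 2L][foot_pad] <- TRUE
  if (tt) blocked[, , zj + 3L][foot_pad] <- TRUE
  frame[blocked] <- FALSE
  frame[labels == LAB_JSR] <- FALSE
  labels[frame] <- LAB_NSR

  # luminal connectors: one stalk along z per jSR footprint component,
  # dropped from the slab underside to the cube floor.  Stalks belong to
  # the junctional compartment and carry no pump (their faces are excluded
  # from the SERCA set below).
  comp <- subcluster_components(foot_pad)
  connector <- integer(0)
  for (cc in comp) {
    # voxel of the component nearest its centroid
    cxy <- round(colMeans(cc))
    d2 <- (cc[, 1] - cxy[1])^2 + (cc[, 2] - cxy[2])^2
    v <- cc[which.min(d2), ]
    for (z in seq_len(zj)) {              # z = 0 .. zj-1 (1-based 1..zj)
      if (labels[v[1], v[2], z] == LAB_CYT) {
        labels[v[1], v[2], z] <- LAB_NSR
        connector <- c(connector, v[1] + n * ((v[2] - 1L) + n * (z - 1L)))
      }
    }
  }

  idx3 <- function(x, y, z) x + n * ((y - 1L) + n * (z - 1L)) # 1-based linear

  # RyR faces: SR-side voxel in the slab, cytosolic cleft voxel above
  ryr_cyt <- vector("list", layout$n_ryr)
  ryr_sr <- vector("list", layout$n_ryr)
  for (k in seq_along(cx)) {
    # half-open window: a voxel belongs to at most one channel footprint
    ix <- which(centers - cx[k] >= -a / 2 - 1e-9 & centers - cx[k] < a / 2 - 1e-9)
    iy <- which(centers - cy[k] >= -a / 2 - 1e-9 & centers - cy[k] < a / 2 - 1e-9)
    g <- expand.grid(x = ix, y = iy)
    ryr_sr[[k]] <- idx3(g$x, g$y, zj + 1L)
    ryr_cyt[[k]] <- idx3(g$x, g$y, zj + 2L)
    if (length(g$x) == 0) stop("RyR footprint contains no voxel; dx_nm too coarse")
    stopifnot(all(labels[cbind(g$x, g$y, zj + 1L)] == LAB_JSR))
    if (!all(labels[cbind(g$x, g$y, zj + 2L)] == LAB_CYT))
      stop("RyR cleft voxels are blocked")
  }

  # SERCA faces: nSR voxel / cytosol neighbour pairs (connector stalks
  # excluded -- they are junctional plumbing, not pump-bearing membrane)
  sf <- sr_cyt_faces(labels, n, LAB_NSR)
  sf <- sf[!(sf[, "sr"] %in% connector), , drop = FALSE]
  area_serca <- nrow(sf) * (dx_nm / 1000)^2
  if (area_serca < serca_area_range[1] || area_serca > serca_area_range[2])
    warning(sprintf(
      "SERCA face area %.3f um^2 outside [%.2f, %.2f] um^2 at this resolution",
      area_serca, serca_area_range[1], serca_area_range[2]))

  nvox <- tabulate(as.vector(labels) + 1L, nbins = 4L)
  grid <- structure(list(
    n = n, dx_nm = dx_nm, dx_um = dx_nm / 1000,
    labels = labels, layout = layout,
    ryr_cyt = ryr_cyt, ryr_sr = ryr_sr,
    serca_faces = sf,
    serca_area_um2 = area_serca,
    jsr_voxels = which(labels == LAB_JSR),
    nsr_voxels = which(labels == LAB_NSR),
    n_cyt = nvox[1], n_jsr = nvox[2], n_nsr = nvox[3], n_tt = nvox[4],
    sr_volume_fraction = (nvox[2] + nvox[3]) / sum(nvox),
    nsr_spacing = s
  ), class = "cru_grid")
  if (!sr_connected(grid))
    warning("SR voxel set is not a single connected component")
  grid
}

# connected (x, y) components of a logical footprint mask, 8-adjacency;
# returns a list of index matrices
subcluster_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  comp <- integer(nrow(idx))
  cur <- 0L
  key <- paste(idx[, 1], idx[, 2])
  lookup <- seq_len(nrow(idx))
  names(lookup) <- key
  for (i in seq_len(nrow(idx))) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      nb <- expand.grid(x = idx[v, 1] + (-1:1), y = idx[v, 2] + (-1:1))
      hit <- lookup[paste(nb$x, nb$y)]
      hit <- hit[!is.na(hit)]
      queue <- c(queue, hit[comp[hit] == 0L])
    }
  }
  lapply(seq_len(cur), function(k) idx[comp == k, , drop = FALSE])
}

# face pairs (cyt_idx, sr_idx) between voxels of SR label `lab` and cytosol
sr_cyt_faces <- function(labels, n, lab) {
  sr <- which(labels == lab)
  if (length(sr) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("cyt", "sr"))))
  x <- ((sr - 1L) %% n) + 1L
  y <- ((sr - 1L) %/% n) %% n + 1L
  z <- (sr - 1L) %/% (n * n) + 1L
  out <- list()
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (d in seq_len(6)) {
    xx <- x + shifts[d, 1]; yy <- y + shifts[d, 2]; zz <- z + shifts[d, 3]
    ok <- xx >= 1 & xx <= n & yy >= 1 & yy <= n & zz >= 1 & zz <= n
    nb <- xx[ok] + n * ((yy[ok] - 1L) + n * (zz[ok] - 1L))
    hit <- labels[nb] == LAB_CYT
    out[[d]] <- cbind(cyt = nb[hit], sr = sr[ok][hit])
  }
  do.call(rbind, out)
}

# is the SR voxel set (jSR + nSR) one 6-connected component?
# (vectorized frontier flood fill; linear in the number of SR voxels)
sr_connected <- function(grid) {
  n <- grid$n
  is_sr <- grid$labels == LAB_JSR | grid$labels == LAB_NSR
  sr <- which(is_sr)
  if (length(sr) <= 1) return(TRUE)
  x <- ((sr - 1L) %% n)
  y <- ((sr - 1L) %/% n) %% n
  z <- (sr - 1L) %/% (n * n)
  coord <- array(0L, dim = c(n, n, n))
  coord[sr] <- seq_along(sr)   # voxel linear index -> SR slot
  seen <- logical(length(sr))
  frontier <- 1L
  seen[1L] <- TRUE
  shifts <- rbind(c(1L,0L,0L), c(-1L,0L,0L), c(0L,1L,0L),
                  c(0L,-1L,0L), c(0L,0L,1L), c(0L,0L,-1L))
  while (length(frontier)) {
    nxt <- integer(0)
    for (d in seq_len(6)) {
      xx <- x[frontier] + shifts[d, 1]
      yy <- y[frontier] + shifts[d, 2]
      zz <- z[frontier] + shifts[d, 3]
      ok <- xx >= 0L & xx < n & yy >= 0L & yy < n & zz >= 0L & zz < n
      j <- coord[xx[ok] + n * (yy[ok] + n * zz[ok]) + 1L]
      j <- unique(j[j > 0L & !seen[pmax(j, 1L)]])
      j <- j[!seen[j]]
      if (length(j)) { seen[j] <- TRUE; nxt <- c(nxt, j) }
    }
    frontier <- nxt
  }
  all(seen)
}

#' Homogeneous box domain
#'
#' A cube consisting entirely of cytosol, with no SR, channels or pump
#' faces.  Used for numerical verification (diffusion-operator oracles,
#' single-voxel reaction integration) where the labelled geometry would
#' get in the way.
#'
#' @param n voxels per axis.
#' @param dx_nm voxel side, nm.
#' @return a `cru_grid` whose label array is all cytosol.
#' @export
box_grid <- function(n, dx_nm = 100) {
  n <- as.integer(n)
  empty_layout <- build_layout(positions = data.frame(x_nm = numeric(0),
                                                      y_nm = numeric(0)))
  structure(list(
    n = n, dx_nm = dx_nm, dx_um = dx_nm / 1000,
    labels = array(LAB_CYT, dim = c(n, n, n)),
    layout = empty_layout,
    ryr_cyt = list(), ryr_sr = list(),
    serca_faces = matrix(integer(0), 0, 2,
                         dimnames = list(NULL, c("cyt", "sr"))),
    serca_area_um2 = 0,
    jsr_voxels = integer(0), nsr_voxels = integer(0),
    n_cyt = n^3, n_jsr = 0L, n_nsr = 0L, n_tt = 0L,
    sr_volume_fraction = 0, nsr_spacing = NA_integer_
  ), class = "cru_grid")
}

#' Grid summary
#'
#' Voxel counts, membrane areas and SR volume fraction of a built grid, as
#' a list that serializes cleanly to JSON.
#' @param grid a [build_grid()] object.
#' @param json if TRUE return a JSON string instead of a list.
#' @export
grid_summary <- function(grid, json = FALSE) {
  stopifnot(inherits(grid, "cru_grid"))
  a_face <- grid$dx_um^2
  ryr_faces <- sum(lengths(grid$ryr_cyt))
  out <- list(
    n_voxels_per_axis = grid$n,
    dx_nm = grid$dx_nm,
    n_cytosol = grid$n_cyt, n_jsr = grid$n_jsr, n_nsr = grid$n_nsr,
    n_tt_excluded = grid$n_tt,
    n_ryr = grid$layout$n_ryr,
    ryr_face_area_um2 = ryr_faces * a_face,
    serca_area_um2 = grid$serca_area_um2,
    sr_volume_fraction = grid$sr_volume_fraction
  )
  if (json) jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA) else out
}

#' @export
print.cru_layout <- function(x, ...) {
  cat(sprintf("<cru_layout %s: %d RyRs in %d sub-cluster(s)>\n",
              x$geometry_id, x$n_ryr, x$n_subclusters))
  invisible(x)
}

#' @export
print.cru_grid <- function(x, ...) {
  cat(sprintf(
    "<cru_grid %d^3 voxels @ %g nm | cyt %d, jSR %d, nSR %d, tt %d | SERCA %.3f um^2>\n",
    x$n, x$dx_nm, x$n_cyt, x$n_jsr, x$n_nsr, x$n_tt, x$serca_area_um2))
  invisible(x)
}
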