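# Geodesic solvent-accessible surface distances between reactive
# side-chain atoms. The solvent-excluded volume is discretized on a cubic
# voxel grid inflated by the probe radius plus a cross-linker half-thickness,
# and the geodesic is the 26-connected shortest path through unblocked
# voxels (Dijkstra, Euclidean step weights). Straight-line (Euclidean)
# distances systematically underestimate how far a cross-linker must
# travel around the protein surface; the geodesic does not.

# Fixed van der Waals radii (angstrom) by element.
.vdw <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

#' Build a solvent-accessibility voxel grid
#'
#' A voxel is blocked when its center lies within
#' `vdW + probe_radius + linker_radius` of any backbone heavy atom of the
#' model (N, CA, C, O): the inflation keeps the path of the cross-linker's
#' own thickness off the protein surface. Reactive side-chain pseudo-atoms
#' do not block — the linker attaches to them, so they cannot obstruct
#' their own path. Grid bounds are the model bounding box plus
#' `2 * (probe_radius + linker_radius) + 5` angstrom of margin.
#'
#' @param model a [protein_model()].
#' @param voxel edge length in angstrom (0.5 to 2.0).
#' @param probe_radius solvent probe radius (default 1.4, water).
#' @param linker_radius cross-linker half-thickness (default 2.5, roughly
#'   half the girth of an NHS-ester reagent).
#' @return object of class `sasd_grid`.
#' @export
build_accessibility_grid <- function(model, voxel = 1.0, probe_radius = 1.4,
                                     linker_radius = 2.5) {
  stopifnot(voxel >= 0.5, voxel <= 2.0)
  atoms <- rbind(model$N, model$CA, model$C, model$O)
  elem <- rep(c("N", "C", "C", "O"), each = n_residues(model))
  keep <- !apply(atoms, 1L, anyNA)
  atoms <- atoms[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(atoms) == 0L) stop("model has no atoms with coordinates")
  inflate <- probe_radius + linker_radius
  margin <- 2 * inflate + 5
  lo <- apply(atoms, 2, min) - margin
  hi <- apply(atoms, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  blocked <- array(FALSE, dims)
  radii <- .vdw[elem] + inflate
  for (a in seq_len(nrow(atoms))) {
    r <- radii[a]
    ctr <- (atoms[a, ] - lo) / voxel + 1   # fractional grid coordinates
    rg <- r / voxel
    i0 <- pmax(1L, as.integer(floor(ctr - rg)))
    i1 <- pmin(dims, as.integer(ceiling(ctr + rg)))
    xs <- i0[1]:i1[1]; ys <- i0[2]:i1[2]; zs <- i0[3]:i1[3]
    dx2 <- (xs - ctr[1])^2; dy2 <- (ys - ctr[2])^2; dz2 <- (zs - ctr[3])^2
    within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rg^2
    blocked[xs, ys, zs] <- blocked[xs, ys, zs] | within
  }
  structure(list(origin = lo, voxel = voxel, dims = dims, blocked = blocked,
                 probe_radius = probe_radius, linker_radius = linker_radius),
            class = "sasd_grid")
}

#' @export
print.sasd_grid <- function(x, ...) {
  cat("<sasd_grid> ", paste(x$dims, collapse = " x "), " voxels @ ",
      x$voxel, " A; ", round(100 * mean(x$blocked), 1), "% blocked\n",
      sep = "")
  invisible(x)
}

# 26-connectivity shift set: 13 lexicographically positive offsets (each
# undirected edge enumerated once).
.shifts26 <- local({
  s <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- s[!(s$dx == 0 & s$dy == 0 & s$dz == 0), ]
  s[s$dz > 0 | (s$dz == 0 & s$dy > 0) |
      (s$dz == 0 & s$dy == 0 & s$dx > 0), ]
})

# Attach the free-voxel graph (igraph, Euclidean step weights) to a grid;
# cached so repeated pair queries reuse it.
.grid_graph <- function(grid) {
  if (!is.null(grid$graph)) return(grid)
  free <- !grid$blocked
  d <- grid$dims
  id <- array(0L, d)
  id[free] <- seq_len(sum(free))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(.shifts26))) {
    dx <- .shifts26$dx[r]; dy <- .shifts26$dy[r]; dz <- .shifts26$dz[r]
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
    a <- id[xs, ys, zs, drop = FALSE]
    b <- id[xs + dx, ys + dy, zs + dz, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (any(ok)) {
      from <- c(from, a[ok]); to <- c(to, b[ok])
      w <- c(w, rep(grid$voxel * sqrt(dx^2 + dy^2 + dz^2), sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = sum(free), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  grid$graph <- g
  grid$id <- id
  grid$free_coords <- which(free, arr.ind = TRUE)  # rows ordered by id
  grid
}

.voxel_center <- function(grid, ijk) {
  sweep((ijk - 1) * grid$voxel, 2, grid$origin, `+`)
}

# Nearest unblocked voxel within `reach` of point `p`; NA when none
# (endpoint buried deeper than the probe + linker can reach).
.snap_endpoint <- function(grid, p, reach) {
  ctr <- (p - grid$origin) / grid$voxel + 1
  rg <- reach / grid$voxel
  i0 <- pmax(1L, as.integer(floor(ctr - rg)))
  i1 <- pmin(grid$dims, as.integer(ceiling(ctr + rg)))
  best <- NA_integer_; bestd <- Inf
  for (x in i0[1]:i1[1]) for (y in i0[2]:i1[2]) for (z in i0[3]:i1[3]) {
    if (grid$blocked[x, y, z]) next
    d2 <- sum(((c(x, y, z) - ctr) * grid$voxel)^2)
    if (d2 < bestd && sqrt(d2) <= reach) {
      bestd <- d2
      best <- grid$id[x, y, z]
    }
  }
  best
}

#' Euclidean reference distances for a residue pair
#'
#' @param model a [protein_model()].
#' @param pos_a,pos_b author residue numbers.
#' @return named vector: `ca` (CA-CA) and `reactive` (reactive-atom pair),
#'   in angstrom.
#' @export
euclidean_distances <- function(model, pos_a, pos_b) {
  ra <- residue_row(model, pos_a); rb <- residue_row(model, pos_b)
  if (is.na(ra) || is.na(rb)) stop("position outside model")
  if (anyNA(model$CA[ra, ]) || anyNA(model$CA[rb, ])) stop("missing CA atom")
  out <- c(ca = vnorm(model$CA[ra, ] - model$CA[rb, ]), reactive = NA_real_)
  if (!anyNA(model$reactive[ra, ]) && !anyNA(model$reactive[rb, ])) {
    out["reactive"] <- vnorm(model$reactive[ra, ] - model$reactive[rb, ])
  }
  out
}

#' Geodesic solvent-accessible surface distance
#'
#' Shortest 26-connected path through unblocked voxels between the voxels
#' nearest the two reactive atoms. Each endpoint snaps to the nearest
#' unblocked voxel within `probe_radius + linker_radius` of the atom;
#' endpoints with no such voxel give status `"buried_endpoint"`, and pairs
#' with no unblocked path give `"unreachable"`.
#'
#' @param model a [protein_model()].
#' @param pos_a,pos_b author residue numbers; both must carry the reactive
#'   atom.
#' @param grid optional pre-built [build_accessibility_grid()] (with or
#'   without a cached path graph); built on demand otherwise.
#' @param ... grid parameters (`voxel`, `probe_radius`, `linker_radius`)
#'   when `grid` is not supplied.
#' @return object of class `sasd_result`: list with `euclidean_ca`,
#'   `euclidean_reactive`, `geodesic` (angstrom or `NA`), `status`
#'   (`"ok"`, `"buried_endpoint"`, `"unreachable"`), `path` (polyline
#'   matrix of voxel centers), and the `grid` (graph cached) for reuse.
#' @export
geodesic_sasd <- function(model, pos_a, pos_b, grid = NULL, ...) {
  ra <- residue_row(model, pos_a); rb <- residue_row(model, pos_b)
  if (is.na(ra) || is.na(rb)) stop("position outside model")
  pa <- model$reactive[ra, ]; pb <- model$reactive[rb, ]
  if (anyNA(pa) || anyNA(pb)) stop("reactive atom missing on one endpoint")
  if (is.null(grid)) grid <- build_accessibility_grid(model, ...)
  grid <- .grid_graph(grid)
  eu <- euclidean_distances(model, pos_a, pos_b)
  reach <- grid$probe_radius + grid$linker_radius
  va <- .snap_endpoint(grid, pa, reach)
  vb <- .snap_endpoint(grid, pb, reach)
  res <- list(euclidean_ca = unname(eu["ca"]),
              euclidean_reactive = unname(eu["reactive"]),
              geodesic = NA_real_, status = "ok", path = NULL, grid = grid)
  if (is.na(va) || is.na(vb)) {
    res$status <- "buried_endpoint"
    class(res) <- "sasd_result"
    return(res)
  }
  sp <- igraph::shortest_paths(grid$graph, from = va, to = vb,
                               weights = igraph::E(grid$graph)$weight,
                               output = "both")
  if (length(sp$vpath[[1]]) == 0L && va != vb) {
    res$status <- "unreachable"
    class(res) <- "sasd_result"
    return(res)
  }
  ca_va <- .voxel_center(grid, matrix(grid$free_coords[va, ], 1))
  ca_vb <- .voxel_center(grid, matrix(grid$free_coords[vb, ], 1))
  graph_len <- if (va == vb) 0 else sum(sp$epath[[1]]$weight)
  # full polyline: atom a -> snapped voxel -> ... -> snapped voxel -> atom b,
  # so the reported geodesic can never undercut the straight-line distance
  res$geodesic <- vnorm(pa - ca_va) + graph_len + vnorm(ca_vb - pb)
  vp <- as.integer(sp$vpath[[1]])
  mid <- if (length(vp)) {
    .voxel_center(grid, grid$free_coords[vp, , drop = FALSE])
  } else rbind(ca_va)
  res$path <- rbind(pa, mid, pb)
  class(res) <- "sasd_result"
  res
}

#' @export
print.sasd_result <- function(x, ...) {
  cat("<sasd_result> status=", x$status,
      "  CA-CA=", round(x$euclidean_ca, 2),
      "  reactive=", round(x$euclidean_reactive, 2),
      "  geodesic=", ifelse(is.na(x$geodesic), "NA", round(x$geodesic, 2)),
      " A\n", sep = "")
  invisible(x)
}

#' Surface distances for many residue pairs of one model
#'
#' Builds the accessibility grid and its path graph once and evaluates all
#' pairs against it.
#'
#' @param model a [protein_model()].
#' @param pairs data frame with columns `pos_a`, `pos_b`.
#' @inheritParams build_accessibility_grid
#' @return data frame: `pos_a`, `pos_b`, `spacing`, `euclidean_ca`,
#'   `euclidean_reactive`, `geodesic`, `status`.
#' @export
sasd_pairs <- function(model, pairs, voxel = 1.0, probe_radius = 1.4,
                       linker_radius = 2.5) {
  grid <- build_accessibility_grid(model, voxel, probe_radius, linker_radius)
  grid <- .grid_graph(grid)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- geodesic_sasd(model, pairs$pos_a[i], pairs$pos_b[i], grid = grid)
    data.frame(pos_a = pairs$pos_a[i], pos_b = pairs$pos_b[i],
               spacing = abs(pairs$pos_b[i] - pairs$pos_a[i]),
               euclidean_ca = r$euclidean_ca,
               euclidean_reactive = r$euclidean_reactive,
               geodesic = r$geodesic, status = r$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
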