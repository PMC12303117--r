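# --- triangulation primitives -------------------------------------------------

.tri_area2 <- function(nodes, tri) {
  # twice the signed area of one triangle (vertex index triple)
  a <- nodes[tri[1L], ]; b <- nodes[tri[2L], ]; c <- nodes[tri[3L], ]
  (b[1L] - a[1L]) * (c[2L] - a[2L]) - (c[1L] - a[1L]) * (b[2L] - a[2L])
}

.tri_areas2 <- function(nodes, tris) {
  ax <- nodes[tris[, 1L], 1L]; ay <- nodes[tris[, 1L], 2L]
  bx <- nodes[tris[, 2L], 1L]; by <- nodes[tris[, 2L], 2L]
  cx <- nodes[tris[, 3L], 1L]; cy <- nodes[tris[, 3L], 2L]
  (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
}

# strict incircle test: is p inside the circumcircle of CCW triangle (a,b,c)?
.incircle <- function(a, b, c, p) {
  m <- matrix(c(a[1L] - p[1L], a[2L] - p[2L], (a[1L] - p[1L])^2 + (a[2L] - p[2L])^2,
                b[1L] - p[1L], b[2L] - p[2L], (b[1L] - p[1L])^2 + (b[2L] - p[2L])^2,
                c[1L] - p[1L], c[2L] - p[2L], (c[1L] - p[1L])^2 + (c[2L] - p[2L])^2),
              3L, 3L, byrow = TRUE)
  det(m) > 1e-14 * max(abs(m[, 3L]))
}

.point_in_tri <- function(nodes, tri, p) {
  a <- nodes[tri[1L], ]; b <- nodes[tri[2L], ]; c <- nodes[tri[3L], ]
  s1 <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
  s2 <- (c[1L] - b[1L]) * (p[2L] - b[2L]) - (c[2L] - b[2L]) * (p[1L] - b[1L])
  s3 <- (a[1L] - c[1L]) * (p[2L] - c[2L]) - (a[2L] - c[2L]) * (p[1L] - c[1L])
  s1 >= 0 && s2 >= 0 && s3 >= 0
}

# ear-clipping triangulation of a simple CCW polygon; returns index triples
.ear_clip <- function(nodes) {
  n <- nrow(nodes)
  idx <- seq_len(n)
  tris <- matrix(0L, n - 2L, 3L)
  k <- 0L
  guard <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    clipped <- FALSE
    for (i in seq_len(m)) {
      ip <- idx[if (i == 1L) m else i - 1L]
      ic <- idx[i]
      inx <- idx[if (i == m) 1L else i + 1L]
      tri <- c(ip, ic, inx)
      if (.tri_area2(nodes, tri) <= 0) next # reflex or degenerate corner
      # the ear must contain no other polygon vertex
      others <- setdiff(idx, tri)
      ok <- TRUE
      for (j in others) {
        if (.point_in_tri(nodes, tri, nodes[j, ])) { ok <- FALSE; break }
      }
      if (!ok) next
      k <- k + 1L
      tris[k, ] <- tri
      idx <- idx[-i]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L) stop("ear clipping failed: polygon may be degenerate")
    }
  }
  k <- k + 1L
  tris[k, ] <- idx
  if (.tri_area2(nodes, tris[k, ]) < 0) tris[k, ] <- tris[k, c(1L, 3L, 2L)]
  tris[seq_len(k), , drop = FALSE]
}

# environment-based mutable mesh for incremental refinement
.flip_pass <- function(env, stack) {
  # stack: matrix of edges (u, v) to examine; Lawson flips propagate until
  # the stack empties. Boundary edges (one incident triangle) never flip.
  while (nrow(stack)) {
    u <- stack[1L, 1L]; v <- stack[1L, 2L]
    stack <- stack[-1L, , drop = FALSE]
    tris <- env$tris
    has_u <- tris[, 1L] == u | tris[, 2L] == u | tris[, 3L] == u
    has_v <- tris[, 1L] == v | tris[, 2L] == v | tris[, 3L] == v
    tt <- which(has_u & has_v)
    if (length(tt) != 2L) next
    t1 <- tris[tt[1L], ]; t2 <- tris[tt[2L], ]
    c1 <- setdiff(t1, c(u, v)); c2 <- setdiff(t2, c(u, v))
    if (length(c1) != 1L || length(c2) != 1L || c1 == c2) next
    a <- env$nodes[u, ]; b <- env$nodes[v, ]
    p <- env$nodes[c1, ]; q <- env$nodes[c2, ]
    # flip only if the quad is strictly convex: the diagonals pq and uv must
    # properly cross (each pair of opposite vertices on opposite sides)
    s1 <- (q[1L] - p[1L]) * (a[2L] - p[2L]) - (q[2L] - p[2L]) * (a[1L] - p[1L])
    s2 <- (q[1L] - p[1L]) * (b[2L] - p[2L]) - (q[2L] - p[2L]) * (b[1L] - p[1L])
    s3 <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
    s4 <- (b[1L] - a[1L]) * (q[2L] - a[2L]) - (b[2L] - a[2L]) * (q[1L] - a[1L])
    if (!(s1 * s2 < 0 && s3 * s4 < 0)) next
    t1c <- if (.tri_area2(env$nodes, t1) > 0) t1 else t1[c(1L, 3L, 2L)]
    if (!.incircle(env$nodes[t1c[1L], ], env$nodes[t1c[2L], ],
                   env$nodes[t1c[3L], ], q)) next
    n1 <- c(c1, u, c2); n2 <- c(c1, c2, v)
    if (.tri_area2(env$nodes, n1) < 0) n1 <- n1[c(1L, 3L, 2L)]
    if (.tri_area2(env$nodes, n2) < 0) n2 <- n2[c(1L, 3L, 2L)]
    env$tris[tt[1L], ] <- n1
    env$tris[tt[2L], ] <- n2
    stack <- rbind(stack, c(u, c1), c(u, c2), c(v, c1), c(v, c2))
  }
  invisible(NULL)
}

.all_interior_edges <- function(tris, n_boundary) {
  e <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  # boundary edges connect consecutive boundary vertices; all others may flip
  consec <- e[, 1L] <= n_boundary & e[, 2L] <= n_boundary &
    (e[, 2L] - e[, 1L] == 1L | (e[, 1L] == 1L & e[, 2L] == n_boundary))
  e[!consec, , drop = FALSE]
}

.smooth_interior <- function(env, n_boundary, n_iter = 2L) {
  tris <- env$tris
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3L, 1L)])
  adj <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                              x = 1, dims = rep(nrow(env$nodes), 2L))
  adj <- adj > 0
  deg <- Matrix::rowSums(adj)
  interior <- seq_len(nrow(env$nodes)) > n_boundary
  for (it in seq_len(n_iter)) {
    old <- env$nodes
    new <- as.matrix(adj %*% env$nodes) / deg
    env$nodes[interior, ] <- new[interior, ]
    if (any(.tri_areas2(env$nodes, env$tris) <= 0)) {
      env$nodes <- old
      break
    }
  }
  invisible(NULL)
}

#' Mesh a closed outline with triangular elements
#'
#' Triangulates the polygon exactly (ear clipping, so the mesh boundary is the
#' polygon itself and total element area equals the polygon area), converts to
#' a constrained Delaunay triangulation by Lawson edge flips, then refines by
#' inserting interior points at the centroids of the largest elements -- with
#' local Delaunay flips after each insertion -- until the element count
#' reaches `n_target` (each insertion adds exactly 2 elements, so the achieved
#' count is within 1 of the target). Interior nodes are Laplacian-smoothed.
#'
#' The four nodes clamped by the plate solver are the boundary nodes nearest
#' the minimum-x extreme (the proximal wing base); the loaded node is the
#' boundary node of maximum x (the apical tip).
#'
#' @param x An [outline] (resampled recommended); must be simple.
#' @param n_target Target element count (>= 50; default 2500).
#' @return A `"wing_mesh"`: `nodes` (n x 2), `triangles` (m x 3, CCW),
#'   `boundary` (logical per node), `base_nodes` (4 ids), `tip_node` (id).
#' @export
mesh_outline <- function(x, n_target = 2500L) {
  if (n_target < 50L) stop("n_target must be at least 50")
  x <- as_outline(x)
  if (is_self_intersecting(x)) {
    stop("cannot mesh a self-intersecting outline")
  }
  v <- orient_standard(x)$vertices
  nb <- nrow(v)
  env <- new.env(parent = emptyenv())
  env$nodes <- v
  env$tris <- .ear_clip(v)
  # Delaunay-ify the initial triangulation
  .flip_pass(env, .all_interior_edges(env$tris, nb))
  smooth_every <- 400L
  since_smooth <- 0L
  repeat {
    m <- nrow(env$tris)
    if (m + 1L >= n_target) break
    areas <- .tri_areas2(env$nodes, env$tris)
    t_big <- which.max(areas)
    tri <- env$tris[t_big, ]
    p <- colMeans(env$nodes[tri, ])
    pid <- nrow(env$nodes) + 1L
    env$nodes <- rbind(env$nodes, p)
    env$tris[t_big, ] <- c(tri[1L], tri[2L], pid)
    env$tris <- rbind(env$tris,
                      c(tri[2L], tri[3L], pid),
                      c(tri[3L], tri[1L], pid))
    .flip_pass(env, rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)]))
    since_smooth <- since_smooth + 1L
    if (since_smooth >= smooth_every) {
      .smooth_interior(env, nb, 1L)
      since_smooth <- 0L
    }
  }
  .smooth_interior(env, nb, 2L)
  .flip_pass(env, .all_interior_edges(env$tris, nb))
  .smooth_interior(env, nb, 2L)
  areas <- .tri_areas2(env$nodes, env$tris)
  if (any(areas <= 0)) stop("mesher failure: degenerate element produced")
  nodes <- unname(env$nodes)
  boundary <- seq_len(nrow(nodes)) <= nb
  bidx <- which(boundary)
  i_min <- bidx[which.min(nodes[bidx, 1L])]
  d <- sqrt((nodes[bidx, 1L] - nodes[i_min, 1L])^2 +
            (nodes[bidx, 2L] - nodes[i_min, 2L])^2)
  base_nodes <- bidx[order(d)[1:4]]
  tip_node <- bidx[which.max(nodes[bidx, 1L])]
  structure(list(nodes = nodes, triangles = env$tris, boundary = boundary,
                 base_nodes = base_nodes, tip_node = tip_node,
                 n_target = n_target),
            class = "wing_mesh")
}

#' @export
print.wing_mesh <- function(x, ...) {
  cat(sprintf("Wing mesh: %d nodes, %d triangles (%d boundary nodes)\n",
              nrow(x$nodes), nrow(x$triangles), sum(x$boundary)))
  invisible(x)
}

#' Total area of a mesh
#'
#' Sum of (positive) triangle areas; equals the polygon area of the meshed
#' outline because the mesh boundary is the polygon itself.
#'
#' @param mesh A `"wing_mesh"`.
#' @return Total area.
#' @export
mesh_area <- function(mesh) {
  sum(.tri_areas2(mesh$nodes, mesh$triangles)) / 2
}
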