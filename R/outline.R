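#' Construct a closed outline
#'
#' An outline is an ordered list of 2-D vertices describing a closed simple
#' polygon. Closure is implicit: the last vertex connects back to the first and
#' the first vertex is not repeated.
#'
#' @param x,y Numeric vectors of equal length (>= 3), or `x` a two-column
#'   matrix/data.frame of coordinates with `y` missing.
#' @return An object of class `"outline"`: a list with a `vertices` matrix
#'   (columns `x`, `y`).
#' @export
outline <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("coordinate matrix must have exactly 2 columns")
  } else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    m <- cbind(x, y)
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("outline coordinates must be finite")
  # drop a duplicated closing vertex and any consecutive duplicates
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop("an outline needs at least 3 distinct vertices")
  colnames(m) <- c("x", "y")
  rownames(m) <- NULL
  structure(list(vertices = m), class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("Closed outline: %d vertices, span %.4g, area %.4g\n",
              nrow(v), diff(range(v[, 1L])), polygon_area(x)))
  invisible(x)
}

as_outline <- function(x) {
  if (inherits(x, "outline")) x else outline(x)
}

#' Read a closed outline from a file
#'
#' Supports two plain-text dialects: `csv` (two numeric columns x,y, one vertex
#' per row, optional header) and `tps` (outline records: an `OUTLINES=`/
#' `POINTS=` block of coordinate pairs; landmark counts of zero are accepted).
#'
#' @param source Path to the file.
#' @param dialect `"csv"` or `"tps"`; default guessed from the file extension.
#' @return An [outline] with vertices in file order; no normalisation applied.
#' @export
read_outline <- function(source, dialect = c("auto", "csv", "tps")) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("file not found: ", source)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tps$", source, ignore.case = TRUE)) "tps" else "csv"
  }
  if (dialect == "csv") {
    first <- readLines(source, n = 1L)
    header <- grepl("[A-Za-z]", first)
    dat <- utils::read.csv(source, header = header)
    if (ncol(dat) < 2L) stop("CSV outline must have two columns (x, y)")
    xy <- suppressWarnings(cbind(as.numeric(dat[[1L]]), as.numeric(dat[[2L]])))
    bad <- which(!stats::complete.cases(xy))
    if (length(bad)) {
      stop(sprintf("non-numeric coordinate at line %d of %s",
                   bad[1L] + as.integer(header), source))
    }
    m <- xy
  } else {
    lines <- readLines(source)
    coord <- grepl("^\\s*[-+0-9.eE]+\\s+[-+0-9.eE]+\\s*$", lines)
    if (!any(coord)) stop("no coordinate pairs found in TPS file ", source)
    toks <- strsplit(trimws(lines[coord]), "\\s+")
    m <- t(vapply(toks, function(t) as.numeric(t[1:2]), numeric(2L)))
    if (anyNA(m)) {
      stop("non-numeric token at line ",
           which(coord)[which(is.na(m[, 1L] + m[, 2L]))[1L]], " of ", source)
    }
  }
  if (nrow(m) < 3L) stop("format error: fewer than 3 outline points in ", source)
  outline(m)
}

#' Write an outline to CSV
#'
#' Mirrors [read_outline]'s CSV dialect so files round-trip exactly.
#'
#' @param x An [outline].
#' @param path Output file path.
#' @export
write_outline <- function(x, path) {
  x <- as_outline(x)
  utils::write.csv(as.data.frame(x$vertices), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area of a closed outline
#'
#' Shoelace area of the implicitly closed vertex list (absolute value).
#'
#' @param x An [outline] or coordinate matrix.
#' @return Area in squared coordinate units.
#' @export
polygon_area <- function(x) {
  v <- as_outline(x)$vertices
  a <- abs(signed_area(v))
  if (a == 0) stop("degenerate polygon: zero area")
  a
}

#' Wing span of an outline
#'
#' Extent along x after standard orientation (base at minimum x, span along +x).
#'
#' @param x An [outline].
#' @param oriented If `TRUE` (default) the outline is passed through
#'   [orient_standard] first.
#' @return Span (max x - min x).
#' @export
wing_span <- function(x, oriented = TRUE) {
  x <- as_outline(x)
  if (oriented) x <- orient_standard(x)
  diff(range(x$vertices[, 1L]))
}

#' Centroid size of an outline
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared distances between each vertex and the vertex centroid.
#' Because the value depends on the number of points, compute it on outlines
#' resampled to a common point count (see [resample_equal_arclength]) when
#' comparing across specimens.
#'
#' @param x An [outline].
#' @return Centroid size (same units as the coordinates).
#' @export
centroid_size <- function(x) {
  v <- as_outline(x)$vertices
  ctr <- colMeans(v)
  sqrt(sum((v[, 1L] - ctr[1L])^2 + (v[, 2L] - ctr[2L])^2))
}

#' Standardise outline orientation
#'
#' Ensures counter-clockwise vertex order (signed area > 0), translates the
#' vertex centroid to the origin, and rotates the vertex sequence so traversal
#' starts at the minimum-x vertex (the wing base under the package's
#' orientation convention: base proximal at minimum x, span along +x).
#'
#' @param x An [outline].
#' @return The standardised [outline]. Idempotent.
#' @export
orient_standard <- function(x) {
  x <- as_outline(x)
  v <- x$vertices
  sa <- signed_area(v)
  if (sa == 0) stop("degenerate polygon: zero signed area")
  if (sa < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v <- sweep(v, 2L, colMeans(v))
  i0 <- which.min(v[, 1L])
  if (i0 > 1L) v <- v[c(i0:nrow(v), 1:(i0 - 1L)), , drop = FALSE]
  colnames(v) <- c("x", "y")
  rownames(v) <- NULL
  structure(list(vertices = v), class = "outline")
}

#' Resample an outline at equal arc-length intervals
#'
#' Places exactly `P` points on the closed polygon boundary at uniform
#' arc-length spacing, starting from the standard start vertex (minimum x after
#' [orient_standard]). The result carries class `c("resampled_outline",
#' "outline")`.
#'
#' @param x An [outline].
#' @param P Number of points (>= 8; default 150).
#' @param orient Standardise orientation first (default `TRUE`).
#' @return A resampled [outline] with `P` vertices.
#' @export
resample_equal_arclength <- function(x, P = 150L, orient = TRUE) {
  if (P < 8L) stop("P must be at least 8")
  x <- as_outline(x)
  if (orient) x <- orient_standard(x)
  v <- x$vertices
  vc <- rbind(v, v[1L, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  s <- per * (seq_len(P) - 1L) / P
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  t0 <- (s - cum[idx]) / seg[idx]
  out <- vc[idx, , drop = FALSE] + t0 * (vc[idx + 1L, , drop = FALSE] - vc[idx, , drop = FALSE])
  res <- outline(out)
  class(res) <- c("resampled_outline", "outline")
  res
}

# exact orientation predicate: sign of the cross product (b-a) x (c-a)
.orient <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

# do segments p1-p2 and p3-p4 intersect (proper crossing, touching, or
# collinear overlap)?
.seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) { # r collinear with p-q: does r lie on it?
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  if (d1 == 0 && on_seg(p3, p4, p1)) return(TRUE)
  if (d2 == 0 && on_seg(p3, p4, p2)) return(TRUE)
  if (d3 == 0 && on_seg(p1, p2, p3)) return(TRUE)
  if (d4 == 0 && on_seg(p1, p2, p4)) return(TRUE)
  FALSE
}

#' Test a closed outline for self-intersection
#'
#' `TRUE` iff any two non-adjacent edges of the closed polyline cross, touch at
#' a non-shared point, or overlap collinearly. Adjacent edges sharing an
#' endpoint never count. Uses exact sign-of-cross-product orientation
#' predicates with a sweep over x-sorted edges; grid shapes near the viability
#' boundary are often near-tangent, so collinear overlap counts as an
#' intersection.
#'
#' @param x An [outline].
#' @return Logical scalar.
#' @export
is_self_intersecting <- function(x) {
  v <- as_outline(x)$vertices
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  # per-edge bounding boxes for cheap rejection
  x1 <- v[, 1L]; y1 <- v[, 2L]
  x2 <- x1[nxt]; y2 <- y1[nxt]
  xmin <- pmin(x1, x2); xmax <- pmax(x1, x2)
  ymin <- pmin(y1, y2); ymax <- pmax(y1, y2)
  ord <- order(xmin)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (xmin[j] > xmax[i]) break
      if (abs(i - j) == 1L || abs(i - j) == n - 1L) next # adjacent edges
      if (ymin[j] > ymax[i] || ymax[j] < ymin[i]) next
      if (.seg_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}
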