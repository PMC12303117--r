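# shared geometric fixtures, built in code

unit_square <- function() outline(c(0, 1, 1, 0), c(0, 0, 1, 1))

rect_outline <- function(L = 4, w = 1) outline(c(0, L, L, 0), c(0, 0, w, w))

circle_outline <- function(r = 1, n = 1000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  outline(r * cos(th), r * sin(th))
}

ellipse_outline <- function(a = 2, b = 1, n = 1000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  outline(a * cos(th), b * sin(th))
}

# triangle tapering from full chord at the base to a point at the tip
taper_triangle <- function(tip_heavy = FALSE) {
  if (tip_heavy) outline(c(0, 1, 1), c(0, -0.5, 0.5))
  else outline(c(0, 1, 0), c(-0.5, 0, 0.5))
}

std_wing <- function(...) gen_wing_outline(wing_params(...), n_points = 200L)

# random simple-ish polygon by jittered radial construction (always simple)
random_star_polygon <- function(n = 12L) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.3, 1)
  outline(r * cos(th), r * sin(th))
}

# random (possibly self-intersecting) polygon
random_polygon <- function(n = 8L) {
  outline(stats::rnorm(n), stats::rnorm(n))
}

# O(n^2) all-pairs brute-force self-intersection oracle
brute_force_self_intersect <- function(o) {
  v <- o$vertices
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  seg_int <- function(p1, p2, p3, p4) {
    o1 <- function(a, b, c) {
      val <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      sign(val)
    }
    d1 <- o1(p3, p4, p1); d2 <- o1(p3, p4, p2)
    d3 <- o1(p1, p2, p3); d4 <- o1(p1, p2, p4)
    if (d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) {
      return(TRUE)
    }
    onseg <- function(p, q, r) {
      o1(p, q, r) == 0 &&
        r[1] >= min(p[1], q[1]) && r[1] <= max(p[1], q[1]) &&
        r[2] >= min(p[2], q[2]) && r[2] <= max(p[2], q[2])
    }
    onseg(p3, p4, p1) || onseg(p3, p4, p2) ||
      onseg(p1, p2, p3) || onseg(p1, p2, p4)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(i - j) == 1L || abs(i - j) == n - 1L) next
      if (seg_int(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}

# brute-force Goldberg ranking oracle: dominance matrix + repeated peeling
brute_force_ranks <- function(m, maximize) {
  m <- sweep(m, 2L, ifelse(maximize, 1, -1), "*")
  n <- nrow(m)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(m[i, ] >= m[j, ]) && any(m[i, ] > m[j, ])) {
        dom[i, j] <- TRUE
      }
    }
  }
  ranks <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  r <- 0L
  while (any(alive)) {
    r <- r + 1L
    nd <- vapply(seq_len(n), function(j) {
      alive[j] && !any(dom[alive, j])
    }, logical(1L))
    ranks[nd] <- r
    alive[nd] <- FALSE
  }
  ranks
}

# small ultrametric fixture tree ((A:1,B:1):1,C:2);
three_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

star_tree <- function(n = 16L, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, n)
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr
}
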