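#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree] with the validation the comparative
#' methods here require: branch lengths present and positive, unique tip
#' labels, at least 3 tips.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file ", path)
  validate_tree(tr)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree, min_tips = 3L) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) stop("all branch lengths must be positive")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (length(tree$tip.label) < min_tips) {
    stop("tree must have at least ", min_tips, " tips")
  }
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the Brownian-motion covariance structure.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric positive-definite matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  ape::vcv(tree)
}

# match a trait matrix (rows = taxa) to the tree tips; errors on tips absent
# from the traits, drops trait rows absent from the tree
.match_traits <- function(tree, traits) {
  Y <- as.matrix(traits)
  if (is.null(rownames(Y))) stop("trait matrix must have taxon row names")
  miss <- setdiff(tree$tip.label, rownames(Y))
  if (length(miss)) {
    stop("tips missing from trait matrix: ", paste(miss, collapse = ", "))
  }
  Y[tree$tip.label, , drop = FALSE]
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Maximum-likelihood (generalised least squares) estimates of internal-node
#' states per trait. The root estimate is the phylogenetic mean
#' `(1' C^-1 1)^-1 1' C^-1 Y`; other nodes condition on the tips through the
#' shared path-length covariances, which is also the re-rooted phylogenetic
#' mean at each node.
#'
#' @param tree An [ape::phylo] tree.
#' @param traits Matrix (taxa x traits) with taxon row names covering every
#'   tip.
#' @return Matrix of internal-node states (rows named by ape node number,
#'   `n_tips + 1` = root), one column per trait.
#' @export
asr_bm <- function(tree, traits) {
  validate_tree(tree, min_tips = 2L)
  Y <- .match_traits(tree, traits)
  n <- length(tree$tip.label)
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  one <- rep(1, n)
  denom <- sum(Cinv)
  root <- drop(crossprod(one, Cinv %*% Y)) / denom
  # shared path lengths between each internal node and each tip
  nn <- tree$Nnode
  d_all <- ape::dist.nodes(tree)
  depth <- ape::node.depth.edgelength(tree)
  root_id <- n + 1L
  internal <- root_id:(n + nn)
  anc <- matrix(NA_real_, nn, ncol(Y),
                dimnames = list(internal, colnames(Y)))
  Yc <- sweep(Y, 2L, root)
  for (k in seq_along(internal)) {
    node <- internal[k]
    if (node == root_id) {
      anc[k, ] <- root
      next
    }
    # shared path(node, tip_i) = (depth(node) + depth(tip) - dist(node, tip))/2
    cv <- (depth[node] + depth[seq_len(n)] - d_all[node, seq_len(n)]) / 2
    anc[k, ] <- root + drop(crossprod(cv, Cinv %*% Yc))
  }
  anc
}

#' Phylomorphospace coordinates
#'
#' Projects tips (their empirical scores) and Brownian-motion reconstructed
#' ancestors (internal-node coefficient estimates projected through the shape
#' space) into the (PC1, PC2) plane, together with the tree's edge list.
#' Taxa present in the trait data but absent from the tree are included as
#' unconnected (`"unplaced"`) points.
#'
#' @param tree An [ape::phylo] tree.
#' @param traits Coefficient matrix (taxa x coefficients), taxon row names;
#'   may contain more taxa than the tree has tips.
#' @param space A fitted `"shape_space"` (fitted on all empirical shapes).
#' @return List with `points` (data.frame: node_id, label, type, pc1, pc2)
#'   and `edges` (data.frame: parent, child), mirroring the tree topology.
#' @export
phylomorphospace <- function(tree, traits, space) {
  validate_tree(tree)
  Y <- as.matrix(traits)
  if (is.null(rownames(Y))) stop("trait matrix must have taxon row names")
  in_tree <- rownames(Y) %in% tree$tip.label
  anc <- asr_bm(tree, Y[in_tree, , drop = FALSE])
  n <- length(tree$tip.label)
  tip_scores <- project(Y[tree$tip.label, , drop = FALSE], space)
  anc_scores <- project(anc, space)
  pts <- data.frame(
    node_id = c(seq_len(n), as.integer(rownames(anc))),
    label = c(tree$tip.label, rep(NA_character_, nrow(anc))),
    type = c(rep("tip", n), rep("internal", nrow(anc))),
    pc1 = c(tip_scores[, 1L], anc_scores[, 1L]),
    pc2 = c(tip_scores[, 2L], anc_scores[, 2L]))
  if (any(!in_tree)) {
    un <- project(Y[!in_tree, , drop = FALSE], space)
    pts <- rbind(pts, data.frame(
      node_id = NA_integer_, label = rownames(Y)[!in_tree],
      type = "unplaced", pc1 = un[, 1L], pc2 = un[, 2L]))
  }
  list(points = pts,
       edges = data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L]))
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' The multivariate generalisation of Blomberg's K: the ratio of observed to
#' Brownian-motion-expected phylogenetic signal,
#' \deqn{K = \frac{tr(E'E) / tr(E'C^{-1}E)}{(tr(C) - N / (1'C^{-1}1)) / (N-1)}}
#' with `E` the trait matrix centred on the phylogenetic mean. K = 1 is the
#' Brownian-motion expectation; K < 1 indicates weaker signal than expected.
#' Significance is assessed by permuting trait rows across tips; the p-value
#' uses the add-one correction, so its floor is `1 / (n_iterations + 1)`.
#'
#' @param tree An [ape::phylo] tree (>= 4 tips).
#' @param traits Matrix (taxa x traits), taxon row names covering every tip.
#' @param n_iterations Permutations (default 9999).
#' @param seed Integer seed for the permutations.
#' @return A `"phylo_signal"` list: `K`, `p_value`, `n_iterations`.
#' @export
kmult <- function(tree, traits, n_iterations = 9999L, seed = 1L) {
  validate_tree(tree)
  if (length(tree$tip.label) < 4L) stop("K_mult requires at least 4 tips")
  Y <- .match_traits(tree, traits)
  if (all(apply(Y, 2L, stats::var) == 0)) stop("traits have zero variance")
  n <- nrow(Y)
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  denom_scale <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  k_stat <- function(Ym) {
    a <- drop(crossprod(rep(1, n), Cinv %*% Ym)) / sum(Cinv)
    E <- sweep(Ym, 2L, a)
    num <- sum(E * E)
    den <- sum(E * (Cinv %*% E))
    (num / den) / denom_scale
  }
  K_obs <- k_stat(Y)
  p <- NA_real_
  if (n_iterations > 0L) {
    perms <- .with_seed(seed, {
      replicate(n_iterations, k_stat(Y[sample.int(n), , drop = FALSE]))
    })
    p <- (sum(perms >= K_obs) + 1) / (n_iterations + 1)
  }
  structure(list(K = K_obs, p_value = p, n_iterations = n_iterations),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("K_mult = %.5f, p = %.4g (%d permutations)\n",
              x$K, x$p_value, x$n_iterations))
  invisible(x)
}
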