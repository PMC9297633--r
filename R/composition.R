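#' Distance matrix container
#'
#' @param d symmetric non-negative matrix with zero diagonal.
#' @param metric metric name.
#' @return a `distance_matrix` object.
#' @export
distance_matrix <- function(d, metric = "bray_curtis") {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-10))
    mn_stop("distance matrix must be symmetric", "myconet_validation_error")
  if (any(diag(d) != 0))
    mn_stop("distance matrix must have a zero diagonal",
            "myconet_validation_error")
  if (any(d < 0))
    mn_stop("distances must be non-negative", "myconet_validation_error")
  structure(list(d = d, metric = metric), class = "distance_matrix")
}

dist_of <- function(x) {
  if (inherits(x, "distance_matrix")) x$d else as.matrix(x)
}

#' Bray-Curtis dissimilarities between root samples
#'
#' `BC(x, y) = sum|x_k - y_k| / sum(x_k + y_k)`, computed on per-sample
#' relative abundances by default (so heterogeneous sequencing depths
#' do not masquerade as compositional differences), or on raw counts.
#'
#' @param table a [sample_table()] with >= 2 samples.
#' @param use_relative divide each sample by its total first (default
#'   TRUE).
#' @return a `distance_matrix` over the sample ids.
#' @export
bray_curtis <- function(table, use_relative = TRUE) {
  stopifnot(inherits(table, "sample_table"))
  x <- table$counts
  if (nrow(x) < 2)
    mn_stop("need >= 2 samples", "myconet_validation_error")
  tot <- rowSums(x)
  if (any(tot == 0))
    mn_stop(paste("all-zero sample(s):",
                  paste(rownames(x)[tot == 0], collapse = ", ")),
            "myconet_validation_error")
  if (use_relative) x <- x / tot
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  distance_matrix(d, metric = "bray_curtis")
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the
#' Gower-centered squared distances into between- and within-group
#' sums of squares and compares the observed pseudo-F to its
#' distribution under random label permutations.
#'
#' @param dist a `distance_matrix` (or square matrix).
#' @param grouping factor/character vector of group labels, one per
#'   sample, in matrix order.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return a `permanova_result`: `pseudo_F`, `R2`, `p_value`, `n_perm`,
#'   `factor_name`.
#' @export
permanova <- function(dist, grouping, n_perm = 10000, seed = 1) {
  d <- dist_of(dist)
  grouping <- as.factor(grouping)
  if (length(grouping) != nrow(d))
    mn_stop("grouping must cover all samples", "myconet_validation_error")
  if (nlevels(droplevels(grouping)) < 2)
    mn_stop("need >= 2 groups", "myconet_validation_error")
  if (n_perm < 1) mn_stop("n_perm must be >= 1", "myconet_validation_error")
  set.seed(as.integer(seed))
  df <- data.frame(g = grouping)
  fit <- vegan::adonis2(stats::as.dist(d) ~ g, data = df,
                        permutations = n_perm)
  structure(list(pseudo_F = fit$F[1],
                 R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 n_perm = n_perm,
                 factor_name = deparse(substitute(grouping))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns coordinates
#' scaled by the square root of the eigenvalues. Only axes with
#' positive eigenvalues are retained; negative eigenvalues (possible
#' for non-Euclidean dissimilarities such as Bray-Curtis) are reported.
#'
#' @param dist a `distance_matrix` (or square matrix) over >= 3
#'   samples.
#' @param n_axes number of axes to retain (>= 1).
#' @return an `ordination`: `coordinates`, `eigenvalues`,
#'   `prop_variance` (per retained axis, over the positive eigenvalue
#'   mass), `negative_eigenvalues`.
#' @export
pcoa <- function(dist, n_axes = 2) {
  d <- dist_of(dist)
  if (nrow(d) < 3) mn_stop("need >= 3 samples", "myconet_validation_error")
  if (n_axes < 1) mn_stop("n_axes must be >= 1", "myconet_validation_error")
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # positive subset is exactly what we retain
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-10)
  keep <- seq_len(min(n_axes, length(pos)))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("Axis", keep)
  structure(list(coordinates = coords,
                 eigenvalues = eig[pos][keep],
                 prop_variance = eig[pos][keep] / sum(eig[pos]),
                 negative_eigenvalues = eig[eig < -1e-10]),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d axes (%s of positive variance)%s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$prop_variance),
                    collapse = " + "),
              if (length(x$negative_eigenvalues))
                sprintf("; %d negative eigenvalues dropped",
                        length(x$negative_eigenvalues)) else ""))
  invisible(x)
}

#' Neighbor-joining dendrogram of root samples
#'
#' Saitou-Nei neighbor joining on a dissimilarity matrix; the unrooted
#' tree reproduces additive distances exactly. Negative branch lengths
#' (possible for non-additive input) are kept as-is unless
#' `clamp = TRUE`.
#'
#' @param dist a `distance_matrix` (or square matrix) over >= 3
#'   samples.
#' @param clamp set negative branch lengths to zero (default FALSE).
#' @return an `nj_tree`: the `ape::phylo` tree and its Newick string.
#' @export
nj_dendrogram <- function(dist, clamp = FALSE) {
  d <- dist_of(dist)
  if (nrow(d) < 3) mn_stop("need >= 3 samples", "myconet_validation_error")
  tree <- ape::nj(stats::as.dist(d))
  if (clamp) tree$edge.length <- pmax(tree$edge.length, 0)
  structure(list(tree = tree, newick = ape::write.tree(tree)),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("nj_tree:", x$newick, "\n")
  invisible(x)
}
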