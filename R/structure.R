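net_matrix <- function(net) {
  if (inherits(net, "bipartite_network")) net$weights else as.matrix(net)
}

#' Connectance of a bipartite network
#'
#' Fraction of the possible plant-OTU links that are realized.
#'
#' @param net a `bipartite_network` (or plain matrix).
#' @return a number in \[0, 1\].
#' @export
connectance <- function(net) {
  w <- net_matrix(net)
  if (nrow(w) < 1 || ncol(w) < 1)
    mn_stop("empty network", "myconet_degenerate_error")
  sum(w > 0) / (nrow(w) * ncol(w))
}

#' Checkerboard score (C-score)
#'
#' Mean number of checkerboard units over all unordered pairs of plant
#' species, computed on the binarized network:
#' `(r_i - S_ij)(r_j - S_ij)` where `r` are plant degrees and `S` the
#' number of shared fungal partners. High values indicate partner
#' avoidance among plants.
#'
#' @param net a `bipartite_network` (or matrix); weights are binarized.
#' @param axis `"rows"` (plants, default) or `"cols"` (fungi).
#' @return mean checkerboard units.
#' @export
c_score <- function(net, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  a <- binarize(net_matrix(net))
  if (axis == "cols") a <- t(a)
  n <- nrow(a)
  if (n < 2) mn_stop("need >= 2 plant species", "myconet_degenerate_error")
  s <- tcrossprod(a)
  r <- rowSums(a)
  cu <- (matrix(r, n, n) - s) * (matrix(r, n, n, byrow = TRUE) - s)
  mean(cu[upper.tri(cu)])
}

# shared pairwise NODF machinery: contribution matrix for a sorted
# binary (paired-overlap) or weighted matrix; rows only.
nodf_row_terms_binary <- function(a) {
  deg <- rowSums(a)
  s <- tcrossprod(a)
  n <- nrow(a)
  # term for ordered pair (u above, l below): 100 * shared / deg_l,
  # only when deg_u strictly exceeds deg_l
  deg_l <- matrix(deg, n, n, byrow = TRUE)
  terms <- ifelse(outer(deg, deg, ">") & deg_l > 0, 100 * s / deg_l, 0)
  terms[upper.tri(terms)]
}

nodf_row_terms_weighted <- function(w) {
  tot <- rowSums(w)
  n <- nrow(w)
  out <- numeric(0)
  for (u in seq_len(n - 1)) for (l in (u + 1):n) {
    term <- 0
    if (tot[u] > tot[l]) {
      pos <- w[l, ] > 0
      if (any(pos))
        term <- 100 * sum(w[l, pos] < w[u, pos]) / sum(pos)
    }
    out <- c(out, term)
  }
  out
}

#' Binary nestedness (NODF2)
#'
#' NODF computed after sorting rows and columns by decreasing degree
#' (the NODF2 convention): for an ordered pair with strictly decreasing
#' degree, the paired overlap is the percentage of the poorer node's
#' partners shared with the richer node; pairs with equal degrees
#' contribute 0. The index is the mean over all row pairs and column
#' pairs, from 0 (no nesting) to 100 (perfect nesting).
#'
#' @param net a `bipartite_network` (or matrix); weights are binarized.
#' @return NODF2 in \[0, 100\].
#' @export
nodf <- function(net) {
  a <- binarize(net_matrix(net))
  if (nrow(a) < 2 || ncol(a) < 2)
    mn_stop("NODF needs >= 2 rows and >= 2 columns",
            "myconet_degenerate_error")
  a <- a[order_dec(rowSums(a)), order_dec(colSums(a)), drop = FALSE]
  terms <- c(nodf_row_terms_binary(a), nodf_row_terms_binary(t(a)))
  mean(terms)
}

#' Weighted nestedness (weighted NODF)
#'
#' After sorting rows and columns by decreasing marginal totals, an
#' ordered pair with strictly decreasing totals contributes the
#' percentage of the poorer node's positive cells whose weight is
#' strictly smaller than the corresponding cell of the richer node;
#' equal totals contribute 0. Mean over all row and column pairs.
#'
#' @param net a weighted `bipartite_network` (abundance or incidence).
#' @return weighted NODF in \[0, 100\].
#' @export
weighted_nodf <- function(net) {
  w <- net_matrix(net)
  if (nrow(w) < 2 || ncol(w) < 2)
    mn_stop("NODF needs >= 2 rows and >= 2 columns",
            "myconet_degenerate_error")
  w <- w[order_dec(rowSums(w)), order_dec(colSums(w)), drop = FALSE]
  terms <- c(nodf_row_terms_weighted(w), nodf_row_terms_weighted(t(w)))
  mean(terms)
}
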