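#' Normalized degree of each plant species
#'
#' Number of fungal partners divided by the number of available
#' partners; close to 0 for specialists, close to 1 for generalists.
#' Depends only on the support of the network, not on the weights.
#'
#' @param net a `bipartite_network` (or matrix).
#' @return named numeric vector, one value per plant species.
#' @export
normalized_degree <- function(net) {
  a <- binarize(net_matrix(net))
  rowSums(a) / ncol(a)
}

# largest-remainder integer apportionment of n units proportional to q
apportion_units <- function(n, q) {
  q <- q / sum(q)
  exp_u <- n * q
  base <- floor(exp_u)
  left <- n - sum(base)
  if (left > 0) {
    frac <- exp_u - base
    take <- order(-frac, seq_along(frac))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  base
}

kl_nats <- function(p, q) {
  sel <- p > 0
  sum(p[sel] * log(p[sel] / q[sel]))
}

#' Bluthgen d' specialization of each plant species
#'
#' For plant `i` with partner use `p'_ij = a_ij / A_i` and partner
#' availability `q_j = C_j / m`, the raw index is the Kullback-Leibler
#' divergence `d_i = sum_j p'_ij ln(p'_ij / q_j)` (nats). It is
#' standardized to `d'_i = (d_i - d_min) / (d_max - d_min)` with
#' `d_max = ln(m / A_i)` and `d_min` obtained by redistributing the
#' `A_i` interaction units over the fungi as proportionally to `q` as
#' integers allow (largest-remainder apportionment); the result is
#' clipped to \[0, 1\]. A value near 0 means the plant tracks the
#' available fungi; near 1, strict specificity.
#'
#' Real-valued abundance weights (per-thousand) are rounded to integer
#' pseudo-counts before the integer redistribution.
#'
#' @param net a weighted `bipartite_network` (abundance).
#' @return data.frame with one row per plant species: `plant`,
#'   `normalized_degree`, `d_raw`, `d_prime`.
#' @export
d_prime <- function(net) {
  a <- net_matrix(net)
  ai <- round(a)
  # guard: rounding must not empty a row
  if (any(rowSums(ai) == 0))
    ai <- a
  m <- sum(ai)
  if (m <= 0) mn_stop("network has zero total weight",
                      "myconet_degenerate_error")
  q <- colSums(ai) / m
  nd <- normalized_degree(net)
  res <- data.frame(plant = rownames(a), normalized_degree = unname(nd),
                    d_raw = NA_real_, d_prime = NA_real_)
  for (i in seq_len(nrow(ai))) {
    A_i <- sum(ai[i, ])
    if (A_i == 0)
      mn_stop(paste("all-zero plant row:", rownames(a)[i]),
              "myconet_degenerate_error")
    p <- ai[i, ] / A_i
    d <- kl_nats(p, q)
    d_max <- log(m / A_i)
    n_units <- round(A_i)
    lowrow <- apportion_units(n_units, q)
    d_min <- kl_nats(lowrow / n_units, q)
    denom <- d_max - d_min
    dp <- if (denom <= 1e-12) {
      mn_warn(paste("degenerate d' denominator for plant", rownames(a)[i],
                    "- returning 0"))
      0
    } else (d - d_min) / denom
    res$d_raw[i] <- d
    res$d_prime[i] <- min(1, max(0, dp))
  }
  res
}

entropy_nats <- function(x) {
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# maximum-entropy integer table with the given marginals: floor of the
# independence expectation, then repair by assigning the remaining
# units to the cells with the largest remainders that still need them.
h2max_table <- function(r, c) {
  m <- sum(r)
  e <- outer(r, c) / m
  x <- floor(e)
  need_r <- r - rowSums(x)
  need_c <- c - colSums(x)
  rem <- e - x
  while (sum(need_r) > 0) {
    ok <- outer(need_r > 0, need_c > 0, "&")
    if (!any(ok)) break
    cand <- which(ok, arr.ind = TRUE)
    pick <- cand[which.max(rem[cand]), , drop = FALSE]
    i <- pick[1, 1]; j <- pick[1, 2]
    x[i, j] <- x[i, j] + 1
    rem[i, j] <- rem[i, j] - 1
    need_r[i] <- need_r[i] - 1
    need_c[j] <- need_c[j] - 1
  }
  x
}

# minimum-entropy integer table: greedily pack the largest feasible
# value into the cell of the currently largest row and column totals.
h2min_table <- function(r, c) {
  x <- matrix(0, length(r), length(c))
  rr <- r; cc <- c
  while (sum(rr) > 0) {
    i <- which.max(rr); j <- which.max(cc)
    v <- min(rr[i], cc[j])
    x[i, j] <- x[i, j] + v
    rr[i] <- rr[i] - v
    cc[j] <- cc[j] - v
  }
  x
}

#' Network-level specialization H2'
#'
#' Two-dimensional Shannon entropy of the interaction matrix,
#' standardized between heuristic extrema over non-negative integer
#' tables with the observed marginal totals:
#' `H2' = (H2max - H2) / (H2max - H2min)`, clipped to \[0, 1\].
#' Low H2' indicates frequent fungal sharing (low specialization);
#' H2' = 1 indicates perfect specialization. Real-valued abundance
#' weights are rounded to integer pseudo-counts for the extrema.
#'
#' @param net a weighted `bipartite_network` (abundance).
#' @return an `h2_result` list: `H2`, `H2max`, `H2min`, `H2prime`.
#' @export
h2_prime <- function(net) {
  a <- net_matrix(net)
  if (sum(a) <= 0)
    mn_stop("network has zero total weight", "myconet_degenerate_error")
  if (sum(a > 0) == 1) {
    message("single-cell network: H2' defined as 1 by convention")
    return(structure(list(H2 = 0, H2max = 0, H2min = 0, H2prime = 1),
                     class = "h2_result"))
  }
  ai <- round(a)
  if (any(rowSums(ai) == 0) || any(colSums(ai) == 0)) ai <- a
  h2 <- entropy_nats(ai)
  r <- rowSums(ai); c <- colSums(ai)
  h2max <- entropy_nats(h2max_table(r, c))
  h2min <- entropy_nats(h2min_table(r, c))
  denom <- h2max - h2min
  h2p <- if (denom <= 1e-12) 1 else (h2max - h2) / denom
  structure(list(H2 = h2, H2max = h2max, H2min = h2min,
                 H2prime = min(1, max(0, h2p))),
            class = "h2_result")
}

#' @export
print.h2_result <- function(x, ...) {
  cat(sprintf("H2' = %.4f (H2 = %.4f, H2min = %.4f, H2max = %.4f)\n",
              x$H2prime, x$H2, x$H2min, x$H2max))
  invisible(x)
}
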