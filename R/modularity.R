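#' Barber bipartite modularity of a given partition
#'
#' `M = (1/m) * sum over same-module (plant i, OTU j) of
#' (A_ij - k_i d_j / m)` where `A` is the (binary or weighted) weight
#' matrix, `k`/`d` the marginal totals and `m` the grand total.
#'
#' @param net a `bipartite_network` (or matrix).
#' @param partition a `module_partition`, or a named module vector
#'   covering every plant and OTU.
#' @return the modularity M (<= 1).
#' @export
barber_modularity <- function(net, partition) {
  a <- net_matrix(net)
  mod <- partition_vector(partition, a)
  m <- sum(a)
  k <- rowSums(a); d <- colSums(a)
  same <- outer(mod[rownames(a)], mod[colnames(a)], "==")
  sum((a - outer(k, d) / m)[same]) / m
}

#' Ratio of interactions falling within modules
#'
#' `Q` is the proportion of the total interaction weight whose plant
#' and OTU belong to the same module; Q close to 1 means the modules
#' capture most interactions.
#'
#' @inheritParams barber_modularity
#' @return Q in \[0, 1\].
#' @export
within_module_ratio <- function(net, partition) {
  a <- net_matrix(net)
  mod <- partition_vector(partition, a)
  same <- outer(mod[rownames(a)], mod[colnames(a)], "==")
  sum(a[same]) / sum(a)
}

partition_vector <- function(partition, a) {
  mod <- if (inherits(partition, "module_partition")) partition$module_of
  else partition
  nodes <- c(rownames(a), colnames(a))
  missing <- setdiff(nodes, names(mod))
  if (length(missing))
    mn_stop(paste("partition does not cover nodes:",
                  paste(missing, collapse = ", ")),
            "myconet_validation_error")
  mod
}

new_module_partition <- function(module_of, M, Q, meta = list()) {
  structure(list(module_of = module_of, M = M, Q = Q,
                 n_modules = length(unique(module_of)), meta = meta),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, M = %.4f, Q = %.4f\n",
              x$n_modules, x$M, x$Q))
  invisible(x)
}

# one label-propagation + greedy run; a is the weight matrix
lpa_run <- function(a, seed) {
  set.seed(seed)
  r <- nrow(a); cc <- ncol(a)
  m <- sum(a)
  bbar <- a - outer(rowSums(a), colSums(a)) / m
  rl <- sample.int(r)                    # row labels, random start
  cl <- rep(NA_integer_, cc)

  score <- function(rl, cl) sum(bbar[outer(rl, cl, "==")]) / m

  # propagate: columns adopt the best row label, rows the best column label
  best <- -Inf
  repeat {
    g <- rowsum(bbar, rl)                         # |labels| x cc
    labs <- as.integer(rownames(g))
    cl <- labs[max.col(t(g), ties.method = "first")]
    g2 <- rowsum(t(bbar), cl)                     # |labels| x r
    labs2 <- as.integer(rownames(g2))
    rl <- labs2[max.col(t(g2), ties.method = "first")]
    cur <- score(rl, cl)
    if (cur <= best + 1e-12) break
    best <- cur
  }

  # agglomeration: merge module pairs while modularity increases
  repeat {
    labs <- sort(unique(c(rl, cl)))
    if (length(labs) < 2) break
    rind <- outer(rl, labs, "==") * 1             # r x L memberships
    cind <- outer(cl, labs, "==") * 1             # cc x L
    s <- t(rind) %*% bbar %*% cind                # s[a,b]: rows in a, cols in b
    delta <- (s + t(s)) / m                       # gain of merging (a, b)
    diag(delta) <- -Inf
    gain <- max(delta)
    if (gain <= 1e-12) break
    ij <- which(delta == gain, arr.ind = TRUE)[1, ]
    from <- labs[ij[1]]; to <- labs[ij[2]]
    rl[rl == from] <- to
    cl[cl == from] <- to
    best <- best + gain
    # re-propagate after each merge
    repeat {
      g <- rowsum(bbar, rl)
      labsx <- as.integer(rownames(g))
      cl2 <- labsx[max.col(t(g), ties.method = "first")]
      g2 <- rowsum(t(bbar), cl2)
      labs2 <- as.integer(rownames(g2))
      rl2 <- labs2[max.col(t(g2), ties.method = "first")]
      cur <- score(rl2, cl2)
      if (cur > best + 1e-12) {
        rl <- rl2; cl <- cl2; best <- cur
      } else break
    }
  }
  list(rl = rl, cl = cl, M = best)
}

#' Search for the most modular bipartite partition
#'
#' Maximizes Barber bipartite modularity by label propagation between
#' the two sides followed by greedy module merges, restarted from
#' random initial labels. The same optimizer serves binary and
#' weighted networks (the objective only differs through the weights).
#' Deterministic given `(net, restarts, seed)`.
#'
#' @param net a `bipartite_network` (or matrix).
#' @param restarts number of random restarts (default 20).
#' @param seed integer seed.
#' @return a `module_partition` with the best `M` found, its `Q`, the
#'   module assignment of every node and optimizer metadata.
#' @export
optimize_modules <- function(net, restarts = 20, seed = 1) {
  a <- net_matrix(net)
  if (nrow(a) < 2 || ncol(a) < 2)
    mn_stop("modularity needs >= 2 rows and >= 2 columns",
            "myconet_degenerate_error")
  best <- NULL
  for (rep in seq_len(restarts)) {
    run <- lpa_run(a, substream_seed(seed, rep))
    if (is.null(best) || run$M > best$M) best <- run
  }
  labs <- c(best$rl, best$cl)
  mod <- stats::setNames(match(labs, sort(unique(labs))),
                         c(rownames(a), colnames(a)))
  part <- new_module_partition(
    mod, M = best$M, Q = NA_real_,
    meta = list(restarts = restarts, seed = seed,
                objective = if (all(a %in% c(0, 1))) "binary" else "weighted"))
  part$Q <- within_module_ratio(a, part)
  part$M <- barber_modularity(a, part)  # recompute from the partition
  part
}
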