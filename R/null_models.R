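#' Fixed-marginals null draws for a binary matrix (quasiswap-type)
#'
#' Randomizations of a binary matrix preserving its row sums, column
#' sums and therefore its fill/connectance (for a binary matrix the
#' fill equals the marginal total). Draws target the uniform
#' distribution over all binary matrices with the observed marginals -
#' the distribution the quasiswap algorithm samples - and are produced
#' by a burned-in, thinned curveball trade chain, which mixes well
#' even when skewed marginals force rows or columns (the regime where
#' swap-repair samplers stall). Deterministic per seed.
#'
#' @param mat binary matrix (>= 2 rows and columns).
#' @param seed integer seed.
#' @param n number of draws.
#' @param burnin,thin trades before the first draw and between draws;
#'   default 30x and 2x the matrix fill.
#' @return a single matrix when `n = 1`, otherwise a list of matrices.
#' @export
quasiswap_binary <- function(mat, seed = 1, n = 1,
                             burnin = NULL, thin = NULL) {
  mat <- binarize(as.matrix(mat))
  if (nrow(mat) < 2 || ncol(mat) < 2)
    mn_stop("need >= 2 rows and columns", "myconet_degenerate_error")
  fill <- sum(mat)
  burnin <- burnin %||% (30 * fill)
  thin <- thin %||% max(2 * fill, 10)
  nm <- vegan::nullmodel(mat, "curveball")
  sims <- stats::simulate(nm, nsim = n, seed = as.integer(seed),
                          burnin = burnin, thin = thin)
  out <- lapply(seq_len(n), function(i) {
    s <- sims[, , i]
    dimnames(s) <- dimnames(mat)
    s
  })
  if (n == 1) out[[1]] else out
}

#' Quasiswap null draws for a count matrix
#'
#' Count analogue of [quasiswap_binary()]: draws preserve the row
#' sums, column sums, grand total and fill of a non-negative integer
#' matrix (a Patefield table is adjusted by unit 2x2 transfers until
#' the fill matches). Deterministic per seed.
#'
#' @inheritParams quasiswap_binary
#' @param mat non-negative integer matrix.
#' @export
quasiswap_count <- function(mat, seed = 1, n = 1) {
  mat <- as.matrix(mat)
  if (any(mat < 0) || any(abs(mat - round(mat)) > 1e-8))
    mn_stop("quasiswap_count needs a non-negative integer matrix",
            "myconet_validation_error")
  nm <- vegan::nullmodel(mat, "quasiswap_count")
  sims <- stats::simulate(nm, nsim = n, seed = as.integer(seed))
  out <- lapply(seq_len(n), function(i) {
    s <- sims[, , i]
    dimnames(s) <- dimnames(mat)
    s
  })
  if (n == 1) out[[1]] else out
}

#' Patefield random contingency tables
#'
#' Samples integer tables uniformly from the fixed-marginals
#' independence distribution (sequential multivariate hypergeometric
#' draws): marginal sums are preserved but the fill (connectance) is
#' free. This is the "marginal" null model used for the specialization
#' indices.
#'
#' @param row_sums,col_sums non-negative integer marginals with equal
#'   totals.
#' @param seed integer seed.
#' @param n number of tables.
#' @return a single matrix when `n = 1`, otherwise a list of matrices.
#' @export
patefield <- function(row_sums, col_sums, seed = 1, n = 1) {
  if (sum(row_sums) != sum(col_sums))
    mn_stop("row and column totals must agree", "myconet_validation_error")
  set.seed(as.integer(seed))
  out <- stats::r2dtable(n, as.integer(round(row_sums)),
                         as.integer(round(col_sums)))
  if (n == 1) out[[1]] else out
}

#' Shuffle-sample null model
#'
#' Permutes the plant-species assignment of the root samples within a
#' community: each plant species keeps its number of samples and each
#' sample keeps its OTU read vector, so a rebuilt network tests
#' whether species-level patterns exceed what sample identity alone
#' produces. The taxonomic group travels with the species label; the
#' plot stays with the sample.
#'
#' @param table a [sample_table()] restricted to one community.
#' @param seed integer seed.
#' @return a new [sample_table()] with permuted species labels.
#' @export
shuffle_samples <- function(table, seed = 1) {
  stopifnot(inherits(table, "sample_table"))
  comms <- unique(table$sample_meta$community)
  if (length(comms) > 1)
    mn_stop("shuffle-sample operates within one community; subset first",
            "myconet_config_error")
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(table$counts))
  meta <- table$sample_meta
  meta$plant_species <- meta$plant_species[perm]
  meta$taxonomic_group <- meta$taxonomic_group[perm]
  out <- table
  out$sample_meta <- meta
  out
}

#' Default index-null model pairings
#'
#' The pairings used in the analyses: connectance is tested against
#' the shuffle-sample null only; C-score, nestedness and modularity
#' against quasiswap and shuffle-sample; the specialization indices
#' against the Patefield marginal null and shuffle-sample.
#'
#' @return data.frame with columns `index` and `null_model`.
#' @export
default_null_pairings <- function() {
  data.frame(
    index = c("connectance",
              "cscore", "cscore", "nodf", "nodf", "wnodf", "wnodf",
              "modularity", "modularity",
              "nd_mean", "nd_mean", "dprime_mean", "dprime_mean",
              "h2prime", "h2prime"),
    null_model = c("shuffle_sample",
                   "quasiswap", "shuffle_sample", "quasiswap",
                   "shuffle_sample", "quasiswap", "shuffle_sample",
                   "quasiswap", "shuffle_sample",
                   "patefield", "shuffle_sample", "patefield",
                   "shuffle_sample", "patefield", "shuffle_sample"))
}

index_registry <- function(optimizer_args = list()) {
  list(
    connectance = connectance,
    cscore = c_score,
    nodf = nodf,
    wnodf = weighted_nodf,
    modularity = function(net) {
      do.call(optimize_modules,
              c(list(net = net), optimizer_args))$M
    },
    nd_mean = function(net) mean(normalized_degree(net)),
    dprime_mean = function(net) mean(d_prime(net)$d_prime),
    h2prime = function(net) h2_prime(net)$H2prime
  )
}

#' Null-model significance test of a network index
#'
#' Recomputes an index over an ensemble of null replicates and compares
#' it to the observed value. Both one-tailed p-values carry the
#' `(x + 1) / (n + 1)` at-least-as-extreme correction; the significance
#' flags follow the raw two-tailed 2.5\% rule: the network scores
#' significantly high (low) when at most 2.5\% of the null values are
#' greater-or-equal (less-or-equal) than the observed one.
#'
#' Matrix null models (`quasiswap`, `patefield`) operate on the network
#' weight matrix (binarized for `quasiswap` on binary indices;
#' integer-rounded for `patefield`). The `shuffle_sample` null instead
#' permutes species labels in the underlying sample table and rebuilds
#' the network from scratch for every replicate, which requires
#' `table` and the network-construction arguments.
#'
#' @param net a `bipartite_network` (observed network).
#' @param index index name (see [default_null_pairings()]) or a
#'   function `net -> numeric`.
#' @param null_model `"quasiswap"`, `"patefield"` or
#'   `"shuffle_sample"`.
#' @param n_null ensemble size (default 10000).
#' @param seed integer seed; replicates use substreams so results do
#'   not depend on evaluation order.
#' @param table,build_args for `shuffle_sample`: the community
#'   [sample_table()] and a list of arguments for [build_network()].
#' @param optimizer_args arguments forwarded to [optimize_modules()]
#'   when `index = "modularity"` (e.g. fewer restarts for ensembles).
#' @return a `null_test_result` list.
#' @export
null_test <- function(net, index,
                      null_model = c("quasiswap", "patefield",
                                     "shuffle_sample"),
                      n_null = 10000, seed = 1,
                      table = NULL, build_args = list(),
                      optimizer_args = list()) {
  null_model <- match.arg(null_model)
  if (n_null < 1) mn_stop("n_null must be >= 1", "myconet_validation_error")
  if (!inherits(net, "bipartite_network")) {
    m0 <- as.matrix(net)
    net <- as_bipartite_network(
      m0, net_type = if (all(m0 %in% c(0, 1))) "binary" else "abundance",
      prune = FALSE)
  }
  index_name <- if (is.character(index)) index else "custom"
  fn <- if (is.character(index)) {
    reg <- index_registry(optimizer_args)
    if (!index %in% names(reg))
      mn_stop(paste("unknown index:", index), "myconet_config_error")
    reg[[index]]
  } else index

  binary_indices <- c("connectance", "cscore", "nodf", "modularity", "nd_mean")
  w <- net_matrix(net)
  is_binary_net <- all(w %in% c(0, 1))
  if (null_model == "quasiswap" && !is_binary_net &&
      index_name %in% c("cscore", "nodf"))
    w <- binarize(w)
  if (null_model == "quasiswap" && !is_binary_net &&
      index_name %in% c("wnodf", "modularity", "h2prime", "dprime_mean")) {
    if (any(abs(w - round(w)) > 1e-8)) w <- round(w)
  }
  if (null_model == "patefield" &&
      index_name %in% c("connectance", "cscore", "nodf") && is_binary_net) {
    # fine: marginals of the binary matrix
  }
  if (null_model == "quasiswap" && index_name == "wnodf" && is_binary_net)
    mn_stop("wnodf requires a weighted network", "myconet_config_error")

  obs <- fn(net)
  wrap <- function(mat) {
    nn <- net
    dimnames(mat) <- dimnames(w)
    nn$weights <- mat
    nn$links <- sum(mat > 0)
    nn
  }

  nulls <- switch(null_model,
    quasiswap = {
      draws <- if (is_binary_net || index_name %in% c("cscore", "nodf"))
        quasiswap_binary(w, seed = seed, n = n_null)
      else quasiswap_count(round(w), seed = seed, n = n_null)
      if (n_null == 1) draws <- list(draws)
      vapply(draws, function(mm) fn(wrap(mm)), numeric(1))
    },
    patefield = {
      wi <- round(w)
      draws <- patefield(rowSums(wi), colSums(wi), seed = seed, n = n_null)
      if (n_null == 1) draws <- list(draws)
      vapply(draws, function(mm) fn(wrap(mm)), numeric(1))
    },
    shuffle_sample = {
      if (is.null(table))
        mn_stop("shuffle_sample needs the sample table", "myconet_config_error")
      vapply(seq_len(n_null), function(i) {
        shuf <- shuffle_samples(table, seed = substream_seed(seed, i))
        nn <- tryCatch(do.call(build_network, c(list(table = shuf),
                                                build_args)),
                       myconet_degenerate_error = function(e) NULL)
        if (is.null(nn)) return(NA_real_)
        fn(nn)
      }, numeric(1))
    })

  nulls <- nulls[!is.na(nulls)]
  n_eff <- length(nulls)
  ge <- sum(nulls >= obs)
  le <- sum(nulls <= obs)
  structure(list(
    index = index_name,
    observed = obs,
    n_null = n_eff,
    null_values = nulls,
    p_upper = (ge + 1) / (n_eff + 1),
    p_lower = (le + 1) / (n_eff + 1),
    significant_high = (ge / n_eff) <= 0.025,
    significant_low = (le / n_eff) <= 0.025,
    null_model = null_model,
    seed = seed
  ), class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  flag <- if (x$significant_high) " [significantly HIGH]"
  else if (x$significant_low) " [significantly LOW]" else ""
  cat(sprintf(
    "null_test: %s = %.4f vs %s null (n = %d)\n  p_upper = %.4g, p_lower = %.4g%s\n",
    x$index, x$observed, x$null_model, x$n_null,
    x$p_upper, x$p_lower, flag))
  invisible(x)
}
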