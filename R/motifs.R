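# Bipartite motif machinery. A motif is an isomorphism class of a
# connected bipartite graph with distinguishable sides (plants vs
# fungi). The canonical form of a p x f biadjacency matrix is the
# lexicographically smallest row-major bit string over all row
# permutations, with columns sorted ascending (which minimizes the
# string for a fixed row order). Motifs are keyed and ordered by
# (node count, plant count, canonical string).

.motif_cache <- new.env(parent = emptyenv())

# all permutations of 1..n, memoized (n <= 5 in practice)
all_perms <- function(n) {
  key <- paste0("perm", n)
  hit <- .motif_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (n <= 1) list(seq_len(n)) else {
    sub <- all_perms(n - 1)
    res <- vector("list", factorial(n))
    k <- 0
    for (i in seq_len(n)) {
      rest <- setdiff(seq_len(n), i)
      for (s in sub) {
        k <- k + 1
        res[[k]] <- c(i, rest[s])
      }
    }
    res
  }
  .motif_cache[[key]] <- out
  out
}

col_key_order <- function(b) {
  # ascending lexicographic column order (top row most significant)
  keys <- apply(b, 2, paste, collapse = "")
  order(keys, seq_len(ncol(b)))
}

# row orders compatible with ascending row degree (all orders among
# equal-degree rows); closed under isomorphic relabeling, so the
# minimum over them is a valid canonical form.
canonical_row_orders <- function(b) {
  deg <- rowSums(b)
  groups <- split(seq_len(nrow(b)), deg)
  orders <- list(integer(0))
  for (g in groups) {
    pg <- all_perms(length(g))
    orders <- unlist(lapply(orders, function(o)
      lapply(pg, function(s) c(o, g[s]))), recursive = FALSE)
  }
  orders
}

#' Canonical form of a bipartite motif
#'
#' The canonical key is the lexicographically smallest row-major bit
#' string over all degree-sorted row orders, columns sorted ascending
#' (the string-minimizing column order for a fixed row order).
#'
#' @param b binary p x f biadjacency matrix (plants in rows).
#' @return list with `key` (canonical bit string), `mat` (canonical
#'   matrix), `row_map`, `col_map` (original index -> canonical
#'   position for the minimizing permutation).
#' @keywords internal
motif_canonical <- function(b) {
  b <- unname(as.matrix(b)) * 1
  p <- nrow(b)
  best <- NULL
  for (rp in canonical_row_orders(b)) {
    bb <- b[rp, , drop = FALSE]
    co <- col_key_order(bb)
    bb <- bb[, co, drop = FALSE]
    key <- paste(t(bb), collapse = "")
    if (is.null(best) || key < best$key) {
      row_map <- integer(p); row_map[rp] <- seq_len(p)
      col_map <- integer(ncol(b)); col_map[co] <- seq_len(ncol(b))
      best <- list(key = key, mat = bb, row_map = row_map, col_map = col_map)
    }
  }
  best
}

motif_connected <- function(b) {
  p <- nrow(b); f <- ncol(b)
  n <- p + f
  adj <- matrix(FALSE, n, n)
  adj[seq_len(p), p + seq_len(f)] <- b > 0
  adj[p + seq_len(f), seq_len(p)] <- t(b > 0)
  seen <- c(TRUE, rep(FALSE, n - 1))
  frontier <- 1
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

motif_orbits <- function(b) {
  # automorphism orbits of rows and columns (side-preserving). The
  # automorphisms form a group, so each index's orbit is exactly its
  # set of images; the minimum image is an exact orbit representative.
  p <- nrow(b); f <- ncol(b)
  b <- unname(as.matrix(b)) * 1
  row_rep <- seq_len(p); col_rep <- seq_len(f)
  for (rp in all_perms(p)) for (cp in all_perms(f)) {
    if (identical(b[rp, cp, drop = FALSE], b)) {
      row_rep <- pmin(row_rep, rp)
      col_rep <- pmin(col_rep, cp)
    }
  }
  list(row = match(row_rep, sort(unique(row_rep))),
       col = match(col_rep, sort(unique(col_rep))))
}

#' Canonical dictionary of bipartite motifs
#'
#' All connected bipartite graphs (plants vs fungi, sides not
#' interchangeable) with 2 to `max_nodes` nodes, in canonical order
#' (node count, plant count, canonical bi-adjacency). Sizes 2..6 hold
#' 1, 2, 4, 10 and 27 classes (44 in total). The dictionary carries a
#' `published_id` slot as a cross-walk to external numberings, left NA
#' by default.
#'
#' @param max_nodes largest motif size, between 2 and 6.
#' @return data.frame-like list of motifs with ids, sizes, canonical
#'   matrices and automorphism orbits.
#' @export
motif_dictionary <- function(max_nodes = 6) {
  if (max_nodes < 2 || max_nodes > 6)
    mn_stop("max_nodes must be in [2, 6]", "myconet_validation_error")
  cache_key <- paste0("dict", max_nodes)
  if (!is.null(.motif_cache[[cache_key]])) return(.motif_cache[[cache_key]])
  entries <- list()
  for (s in 2:max_nodes) {
    for (p in seq_len(s - 1)) {
      f <- s - p
      seen <- character(0)
      for (code in seq_len(2^(p * f)) - 1L) {
        bits <- as.integer(intToBits(code))[seq_len(p * f)]
        b <- matrix(bits, p, f)
        if (any(rowSums(b) == 0) || any(colSums(b) == 0)) next
        if (!motif_connected(b)) next
        can <- motif_canonical(b)
        if (can$key %in% seen) next
        seen <- c(seen, can$key)
        orb <- motif_orbits(can$mat)
        entries[[length(entries) + 1]] <- list(
          n_nodes = s, n_plants = p, key = can$key, mat = can$mat,
          row_orbits = orb$row, col_orbits = orb$col)
      }
    }
  }
  ord <- order(vapply(entries, `[[`, 1, "n_nodes"),
               vapply(entries, `[[`, 1, "n_plants"),
               vapply(entries, `[[`, "", "key"))
  entries <- entries[ord]
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(entries)) {
    entries[[i]]$id <- i
    entries[[i]]$published_id <- NA_integer_
    assign(paste0(entries[[i]]$n_plants, ":", entries[[i]]$key), i,
           envir = lookup)
  }
  dict <- list(motifs = entries, lookup = lookup, max_nodes = max_nodes)
  class(dict) <- "motif_dictionary"
  .motif_cache[[cache_key]] <- dict
  dict
}

#' @export
print.motif_dictionary <- function(x, ...) {
  sizes <- table(vapply(x$motifs, `[[`, 1, "n_nodes"))
  cat(sprintf("motif_dictionary: %d motifs up to %d nodes (%s)\n",
              length(x$motifs), x$max_nodes,
              paste(names(sizes), sizes, sep = ":", collapse = ", ")))
  invisible(x)
}

# enumerate all connected induced subgraphs of size k (ESU algorithm);
# calls visit(nodes) for each. adj: list of neighbor integer vectors.
esu_enumerate <- function(adj, k, visit) {
  n <- length(adj)
  extend <- function(sub, ext, v) {
    if (length(sub) == k) {
      visit(sub)
      return(invisible(NULL))
    }
    while (length(ext)) {
      w <- ext[1]
      ext <- ext[-1]
      nb <- adj[[w]]
      excl <- unique(unlist(adj[sub]))
      ext2 <- c(ext, setdiff(nb[nb > v & !(nb %in% sub)], excl))
      extend(c(sub, w), unique(ext2), v)
    }
  }
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    extend(v, nb[nb > v], v)
  }
  invisible(NULL)
}

net_adjlist <- function(a) {
  p <- nrow(a); f <- ncol(a)
  adj <- vector("list", p + f)
  for (i in seq_len(p)) adj[[i]] <- p + which(a[i, ] > 0)
  for (j in seq_len(f)) adj[[p + j]] <- which(a[, j] > 0)
  adj
}

#' Bipartite motif census
#'
#' Counts, over every connected induced subnetwork of 2 to `max_nodes`
#' species, the occurrences of each motif class of
#' [motif_dictionary()]. Counting respects the bipartition (a
#' two-plants-one-fungus path is distinct from one-plant-two-fungi).
#'
#' @param net a `bipartite_network` (or matrix); binarized support.
#' @param max_nodes motif sizes counted, in \[2, 6\].
#' @param normalization `"raw"`, `"sum_all"` (frequencies summing to 1)
#'   or `"sum_within_size"` (frequencies per size class).
#' @return a `motif_census` with the count vector over motif ids.
#' @export
motif_census <- function(net, max_nodes = 6,
                         normalization = c("raw", "sum_all",
                                           "sum_within_size")) {
  normalization <- match.arg(normalization)
  dict <- motif_dictionary(max_nodes)
  a <- binarize(net_matrix(net))
  p <- nrow(a)
  adj <- net_adjlist(a)
  counts <- numeric(length(dict$motifs))
  for (k in 2:max_nodes) {
    esu_enumerate(adj, k, function(sub) {
      rows <- sub[sub <= p]
      cols <- sub[sub > p] - p
      if (length(rows) == 0 || length(cols) == 0) return(invisible(NULL))
      b <- a[rows, cols, drop = FALSE]
      can <- motif_canonical(b)
      id <- get0(paste0(length(rows), ":", can$key), envir = dict$lookup)
      if (!is.null(id)) counts[id] <<- counts[id] + 1
    })
  }
  counts <- normalize_census(counts, dict, normalization)
  structure(list(counts = counts,
                 motif_ids = vapply(dict$motifs, `[[`, 1, "id"),
                 n_nodes = vapply(dict$motifs, `[[`, 1, "n_nodes"),
                 n_plants = vapply(dict$motifs, `[[`, 1, "n_plants"),
                 max_nodes = max_nodes,
                 normalization = normalization,
                 network = list(lineage = if (inherits(net,
                   "bipartite_network")) net$lineage else NA,
                   community = if (inherits(net, "bipartite_network"))
                     net$community else NA)),
            class = "motif_census")
}

normalize_census <- function(counts, dict, normalization) {
  if (normalization == "raw") return(counts)
  if (normalization == "sum_all") {
    tot <- sum(counts)
    return(if (tot > 0) counts / tot else counts)
  }
  sizes <- vapply(dict$motifs, `[[`, 1, "n_nodes")
  for (s in unique(sizes)) {
    sel <- sizes == s
    tot <- sum(counts[sel])
    if (tot > 0) counts[sel] <- counts[sel] / tot
  }
  counts
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("motif_census: %d motif classes (up to %d nodes), %s counts\n",
              length(x$counts), x$max_nodes, x$normalization))
  invisible(x)
}

#' Node-position census within motifs
#'
#' For every motif occurrence containing a focal species, increments
#' the count of the automorphism orbit (position) the species occupies
#' in that motif. Positions are numbered per motif: plant orbits first,
#' then fungus orbits.
#'
#' @param net a `bipartite_network` (or matrix).
#' @param species focal species label (plant or OTU), or `NULL` for a
#'   census of every node.
#' @param max_nodes motif sizes counted, in \[2, 6\].
#' @return a `node_position_census`: counts over
#'   (motif id, position) per focal node.
#' @export
node_position_census <- function(net, species = NULL, max_nodes = 6) {
  dict <- motif_dictionary(max_nodes)
  a <- binarize(net_matrix(net))
  p <- nrow(a)
  nodes <- c(rownames(a), colnames(a))
  if (!is.null(species) && !species %in% nodes)
    mn_stop(paste("unknown species:", species), "myconet_validation_error")
  # position table: one row per (motif, orbit, side)
  pos <- do.call(rbind, lapply(dict$motifs, function(mo) {
    rbind(
      data.frame(motif_id = mo$id, side = "plant",
                 orbit = sort(unique(mo$row_orbits))),
      data.frame(motif_id = mo$id, side = "fungus",
                 orbit = sort(unique(mo$col_orbits))))
  }))
  pos$position_id <- seq_len(nrow(pos))
  counts <- matrix(0, length(nodes), nrow(pos),
                   dimnames = list(nodes, NULL))
  adj <- net_adjlist(a)
  for (k in 2:max_nodes) {
    esu_enumerate(adj, k, function(sub) {
      rows <- sub[sub <= p]
      cols <- sub[sub > p] - p
      if (length(rows) == 0 || length(cols) == 0) return(invisible(NULL))
      b <- a[rows, cols, drop = FALSE]
      can <- motif_canonical(b)
      id <- get0(paste0(length(rows), ":", can$key), envir = dict$lookup)
      if (is.null(id)) return(invisible(NULL))
      mo <- dict$motifs[[id]]
      for (ri in seq_along(rows)) {
        orbit <- mo$row_orbits[can$row_map[ri]]
        pid <- pos$position_id[pos$motif_id == id & pos$side == "plant" &
                                 pos$orbit == orbit]
        counts[rows[ri], pid] <<- counts[rows[ri], pid] + 1
      }
      for (ci in seq_along(cols)) {
        orbit <- mo$col_orbits[can$col_map[ci]]
        pid <- pos$position_id[pos$motif_id == id & pos$side == "fungus" &
                                 pos$orbit == orbit]
        counts[p + cols[ci], pid] <<- counts[p + cols[ci], pid] + 1
      }
    })
  }
  if (!is.null(species)) counts <- counts[species, , drop = FALSE]
  structure(list(counts = counts, positions = pos, max_nodes = max_nodes),
            class = "node_position_census")
}

#' Ordination of motif-frequency profiles
#'
#' Normalizes a list of motif censuses, computes pairwise distances
#' between their profiles and ordinates them by principal coordinate
#' analysis, as used to compare networks by their building blocks.
#'
#' @param censuses list of `motif_census` objects sharing `max_nodes`.
#' @param normalization `"sum_all"` (default) or `"sum_within_size"`.
#' @param distance `"bray_curtis"` or `"euclidean"`.
#' @param n_axes axes to retain.
#' @return an `ordination` (see [pcoa()]); degenerate configurations
#'   (all profiles identical) are flagged with `degenerate = TRUE`.
#' @export
motif_profile_ordination <- function(censuses,
                                     normalization = c("sum_all",
                                                       "sum_within_size"),
                                     distance = c("bray_curtis",
                                                  "euclidean"),
                                     n_axes = 2) {
  normalization <- match.arg(normalization)
  distance <- match.arg(distance)
  if (length(censuses) < 3)
    mn_stop("need >= 3 censuses", "myconet_validation_error")
  mx <- unique(vapply(censuses, `[[`, 1, "max_nodes"))
  if (length(mx) > 1)
    mn_stop("censuses use different motif dictionaries",
            "myconet_validation_error")
  dict <- motif_dictionary(mx)
  prof <- t(vapply(censuses, function(cs) {
    raw <- cs$counts
    if (cs$normalization != "raw" && cs$normalization != normalization)
      mn_stop("censuses carry mixed normalizations; use raw censuses",
              "myconet_validation_error")
    if (cs$normalization == "raw")
      raw <- normalize_census(raw, dict, normalization)
    raw
  }, numeric(length(censuses[[1]]$counts))))
  rownames(prof) <- names(censuses) %||% paste0("net", seq_len(nrow(prof)))
  d <- if (distance == "bray_curtis")
    as.matrix(vegan::vegdist(prof, method = "bray"))
  else as.matrix(stats::dist(prof))
  dm <- distance_matrix(d, metric = distance)
  if (all(d < 1e-12)) {
    message("all motif profiles identical: degenerate ordination")
    ord <- structure(list(coordinates = matrix(0, nrow(prof), 1,
                                               dimnames = list(rownames(prof),
                                                               "Axis1")),
                          eigenvalues = 0, prop_variance = NaN,
                          negative_eigenvalues = numeric(0),
                          degenerate = TRUE),
                     class = "ordination")
    return(ord)
  }
  out <- pcoa(dm, n_axes = n_axes)
  out$degenerate <- FALSE
  out
}
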