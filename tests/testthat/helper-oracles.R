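# Independent brute-force oracles used to validate the fast
# implementations, plus small fixture builders. Oracles deliberately
# use naive loops / exhaustive enumeration, never the package's own
# code paths.

# ---- structure oracles -------------------------------------------------

oracle_nodf <- function(a) {
  a <- (a > 0) * 1
  a <- a[order(-rowSums(a), seq_len(nrow(a))),
         order(-colSums(a), seq_len(ncol(a))), drop = FALSE]
  pair_terms <- function(m) {
    deg <- rowSums(m)
    out <- c()
    for (u in seq_len(nrow(m) - 1)) for (l in (u + 1):nrow(m)) {
      t <- 0
      if (deg[u] > deg[l] && deg[l] > 0) {
        shared <- sum(m[u, ] == 1 & m[l, ] == 1)
        t <- 100 * shared / deg[l]
      }
      out <- c(out, t)
    }
    out
  }
  mean(c(pair_terms(a), pair_terms(t(a))))
}

oracle_wnodf <- function(w) {
  w <- w[order(-rowSums(w), seq_len(nrow(w))),
         order(-colSums(w), seq_len(ncol(w))), drop = FALSE]
  pair_terms <- function(m) {
    tot <- rowSums(m)
    out <- c()
    for (u in seq_len(nrow(m) - 1)) for (l in (u + 1):nrow(m)) {
      t <- 0
      if (tot[u] > tot[l]) {
        np <- 0; nless <- 0
        for (j in seq_len(ncol(m))) {
          if (m[l, j] > 0) {
            np <- np + 1
            if (m[l, j] < m[u, j]) nless <- nless + 1
          }
        }
        if (np > 0) t <- 100 * nless / np
      }
      out <- c(out, t)
    }
    out
  }
  mean(c(pair_terms(w), pair_terms(t(w))))
}

oracle_cscore <- function(a) {
  a <- (a > 0) * 1
  n <- nrow(a)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sum(a[i, ] == 1 & a[j, ] == 1)
    vals <- c(vals, (sum(a[i, ]) - s) * (sum(a[j, ]) - s))
  }
  mean(vals)
}

oracle_modularity <- function(a, mod) {
  m <- sum(a)
  k <- rowSums(a); d <- colSums(a)
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (mod[rownames(a)[i]] == mod[colnames(a)[j]])
      acc <- acc + a[i, j] - k[i] * d[j] / m
  }
  unname(acc / m)
}

# ---- motif oracles -----------------------------------------------------

# permutation-search bipartite isomorphism (sides fixed)
oracle_iso <- function(b1, b2) {
  b1 <- unname((b1 > 0) * 1); b2 <- unname((b2 > 0) * 1)
  if (!all(dim(b1) == dim(b2))) return(FALSE)
  rp_all <- oracle_perms(nrow(b1))
  cp_all <- oracle_perms(ncol(b1))
  for (rp in rp_all) for (cp in cp_all) {
    if (identical(b1[rp, cp, drop = FALSE], b2)) return(TRUE)
  }
  FALSE
}

oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- oracle_perms(n - 1)
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in sub) out[[length(out) + 1]] <- c(i, rest[s])
  }
  out
}

oracle_connected <- function(b) {
  p <- nrow(b); f <- ncol(b); n <- p + f
  edge <- function(x, y) {
    if (x <= p && y > p) b[x, y - p] > 0
    else if (y <= p && x > p) b[y, x - p] > 0
    else FALSE
  }
  seen <- rep(FALSE, n); seen[1] <- TRUE
  repeat {
    grew <- FALSE
    for (x in which(seen)) for (y in which(!seen)) {
      if (edge(x, y)) { seen[y] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  all(seen)
}

# exhaustive census: all node subsets of sizes 2..max_nodes, keep
# connected induced subgraphs, classify against reference motifs by
# permutation-search isomorphism. Returns counts aligned to the given
# dictionary (by brute iso match of canonical matrices).
oracle_motif_census <- function(a, dict, max_nodes = 6) {
  a <- (a > 0) * 1
  p <- nrow(a); n <- p + ncol(a)
  counts <- numeric(length(dict$motifs))
  for (k in 2:max_nodes) {
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      rows <- sub[sub <= p]; cols <- sub[sub > p] - p
      if (length(rows) == 0 || length(cols) == 0) next
      b <- a[rows, cols, drop = FALSE]
      if (any(rowSums(b) == 0) || any(colSums(b) == 0)) next
      if (!oracle_connected(b)) next
      for (mi in seq_along(dict$motifs)) {
        mo <- dict$motifs[[mi]]
        if (mo$n_nodes != k || mo$n_plants != length(rows)) next
        if (oracle_iso(b, mo$mat)) {
          counts[mi] <- counts[mi] + 1
          break
        }
      }
    }
  }
  counts
}

# ---- fixtures ----------------------------------------------------------

random_binary_matrix <- function(nr, nc, p = 0.45) {
  repeat {
    a <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) break
  }
  dimnames(a) <- list(paste0("P", seq_len(nr)), paste0("F", seq_len(nc)))
  a
}

random_count_matrix <- function(nr, nc, p = 0.55, lambda = 4) {
  a <- random_binary_matrix(nr, nc, p)
  a * (matrix(rpois(nr * nc, lambda), nr, nc) + 1)
}

toy_sample_table <- function() {
  counts <- rbind(
    S1 = c(OTU1 = 120L, OTU2 = 40L, OTU3 = 0L, OTU4 = 3L),
    S2 = c(OTU1 = 0L, OTU2 = 300L, OTU3 = 55L, OTU4 = 0L),
    S3 = c(OTU1 = 80L, OTU2 = 0L, OTU3 = 25L, OTU4 = 9L))
  sample_meta <- data.frame(
    sample_id = c("S1", "S2", "S3"),
    plant_species = c("plantA", "plantA", "plantB"),
    taxonomic_group = c("ferns", "ferns", "monocots"),
    plot = c("p1", "p2", "p1"),
    community = "c1",
    marker = "18S")
  otu_meta <- data.frame(
    otu_id = paste0("OTU", 1:4),
    lineage = c("Fungi/Glomeromycotina/Glomerales",
                "Fungi/Glomeromycotina/Archaeosporales",
                "Fungi/Mucoromycotina/Endogonales",
                "Fungi/Ascomycota/Helotiales"),
    guild = c("mycorrhizal", "mycorrhizal", "mycorrhizal", "endophyte"))
  sample_table(counts, sample_meta, otu_meta)
}

write_toy_tsvs <- function(dir, drop_sample = NULL, extra_meta = NULL,
                           counts_edit = NULL) {
  tab <- toy_sample_table()
  counts <- t(tab$counts)
  if (!is.null(drop_sample))
    counts <- counts[, setdiff(colnames(counts), drop_sample), drop = FALSE]
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  if (!is.null(counts_edit)) df[counts_edit$i, counts_edit$j] <- counts_edit$v
  meta <- tab$sample_meta
  if (!is.null(extra_meta)) meta <- rbind(meta, extra_meta)
  write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tab$otu_meta, file.path(dir, "tax.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(counts = file.path(dir, "counts.tsv"),
       meta = file.path(dir, "meta.tsv"),
       tax = file.path(dir, "tax.tsv"))
}

# adjusted Rand index between two labelings (contingency-table form)
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}
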