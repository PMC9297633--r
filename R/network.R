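#' Detect plant-fungus interactions in root samples
#'
#' An OTU is considered to interact with the plant of a root sample when
#' its reads are both at least `min_reads` (contamination floor) and at
#' least `rel_threshold` of the sample's total reads. Both conditions
#' are required: the relative rule corrects for heterogeneous
#' sequencing depth, the absolute floor removes low-level cross-sample
#' contamination.
#'
#' @param table a guild-filtered [sample_table()].
#' @param rel_threshold minimum fraction of the sample's reads
#'   (default 0.01, i.e. 1\%).
#' @param min_reads minimum read count (default 5).
#' @param sample_totals optional named vector of per-sample totals to
#'   use as the denominator of the relative rule. Defaults to the
#'   totals of `table` itself; pass the totals of the full
#'   guild-filtered table when `table` is a lineage subset, so that the
#'   1\% rule refers to the whole root sample.
#' @return logical samples x OTUs presence matrix.
#' @export
detect_interactions <- function(table, rel_threshold = 0.01, min_reads = 5,
                                sample_totals = NULL) {
  stopifnot(inherits(table, "sample_table"))
  if (rel_threshold <= 0 || rel_threshold > 1)
    mn_stop("rel_threshold must be in (0, 1]", "myconet_validation_error")
  if (min_reads < 0)
    mn_stop("min_reads must be >= 0", "myconet_validation_error")
  counts <- table$counts
  if (is.null(sample_totals)) {
    sample_totals <- rowSums(counts)
  } else {
    if (is.null(names(sample_totals)) ||
        !all(rownames(counts) %in% names(sample_totals)))
      mn_stop("sample_totals must be named and cover all samples",
              "myconet_validation_error")
    sample_totals <- sample_totals[rownames(counts)]
  }
  zero <- sample_totals == 0
  if (any(zero))
    mn_warn(paste("skipping samples with zero reads:",
                  paste(rownames(counts)[zero], collapse = ", ")))
  denom <- ifelse(zero, Inf, sample_totals)
  (counts >= min_reads) & (counts / denom >= rel_threshold)
}

#' Species-level bipartite plant-fungus network
#'
#' Aggregates the per-sample interactions of one fungal lineage in one
#' community into a plant-species x fungal-OTU weight matrix. Plots are
#' merged within the community (samples are grouped by plant species).
#' Three weighting schemes are available:
#' \describe{
#'   \item{binary}{1 when the interaction was detected in at least one
#'     root sample of the species.}
#'   \item{abundance}{reads of the OTU in the detected cells of the
#'     species, per thousand reads over all detected cells of that
#'     species (each row sums to 1000).}
#'   \item{incidence}{number of root samples of the species in which
#'     the interaction was detected.}
#' }
#' All-zero plant rows and OTU columns are pruned. Reads of cells that
#' fail the detection rule contribute nothing, even when positive.
#'
#' @param table a guild-filtered [sample_table()] restricted to one
#'   community (and typically one lineage).
#' @param net_type `"binary"`, `"abundance"` or `"incidence"`.
#' @param rel_threshold,min_reads,sample_totals passed to
#'   [detect_interactions()].
#' @param lineage,community labels stored on the network; defaulted
#'   from the table when unambiguous.
#' @return a `bipartite_network` object: list with the weight matrix,
#'   `net_type`, labels, `n_samples_per_species`, `total_reads` (reads
#'   in detected cells) and `links`.
#' @export
build_network <- function(table,
                          net_type = c("binary", "abundance", "incidence"),
                          rel_threshold = 0.01, min_reads = 5,
                          sample_totals = NULL,
                          lineage = NA_character_, community = NULL) {
  stopifnot(inherits(table, "sample_table"))
  net_type <- match.arg(net_type)
  comms <- unique(table$sample_meta$community)
  if (is.null(community)) {
    if (length(comms) > 1)
      mn_stop(paste("table spans several communities; subset first:",
                    paste(comms, collapse = ", ")), "myconet_config_error")
    community <- comms
  }
  pres <- detect_interactions(table, rel_threshold, min_reads, sample_totals)
  species <- table$sample_meta$plant_species
  det_reads <- table$counts * pres              # reads in detected cells only

  inc <- rowsum(pres * 1, species)              # samples with the interaction
  reads <- rowsum(det_reads, species)
  n_samples <- base::table(species)

  w <- switch(net_type,
    binary = (inc > 0) * 1,
    incidence = inc,
    abundance = {
      tot <- rowSums(reads)
      a <- 1000 * reads / ifelse(tot > 0, tot, 1)
      a[inc == 0] <- 0
      a
    })

  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  w <- w[keep_r, keep_c, drop = FALSE]
  if (nrow(w) < 2 || ncol(w) < 2)
    mn_stop(sprintf(
      "degenerate network after pruning (%d plant species x %d OTUs); structural metrics are undefined",
      nrow(w), ncol(w)), "myconet_degenerate_error")

  structure(list(
    weights = w,
    net_type = net_type,
    lineage = lineage,
    community = community,
    marker = unique(table$sample_meta$marker)[1],
    n_samples_per_species =
      stats::setNames(as.integer(n_samples[rownames(w)]), rownames(w)),
    total_reads = sum(det_reads),
    links = sum(w > 0)
  ), class = "bipartite_network")
}

#' Construct a bipartite network directly from a weight matrix
#'
#' Mostly used in tests and simulations; applies the same pruning and
#' degeneracy rules as [build_network()].
#'
#' @param weights plants x OTUs non-negative matrix.
#' @param net_type network type label.
#' @param lineage,community,marker metadata labels.
#' @param prune drop all-zero rows/columns (default TRUE).
#' @return a `bipartite_network`.
#' @export
as_bipartite_network <- function(weights, net_type = "binary",
                                 lineage = NA_character_,
                                 community = NA_character_,
                                 marker = NA_character_, prune = TRUE) {
  w <- as.matrix(weights)
  if (any(w < 0)) mn_stop("negative weights", "myconet_validation_error")
  if (is.null(rownames(w))) rownames(w) <- paste0("P", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- paste0("F", seq_len(ncol(w)))
  if (net_type == "binary") w <- binarize(w)
  if (prune) w <- w[rowSums(w) > 0, colSums(w) > 0, drop = FALSE]
  structure(list(
    weights = w, net_type = net_type, lineage = lineage,
    community = community, marker = marker,
    n_samples_per_species = NULL,
    total_reads = sum(w), links = sum(w > 0)
  ), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "bipartite_network (%s): %d plant species x %d OTUs, %d links%s%s\n",
    x$net_type, nrow(x$weights), ncol(x$weights), x$links,
    if (!is.na(x$lineage)) paste0(", lineage ", x$lineage) else "",
    if (!is.null(x$community) && !is.na(x$community))
      paste0(", community ", x$community) else ""))
  invisible(x)
}

#' Linear relationship between abundance and incidence weights
#'
#' Ordinary least squares of the abundance weight on the incidence
#' weight over the shared nonzero cells, used to check that the two
#' weighted network types quantify interaction strength consistently.
#'
#' @param net_ab abundance network.
#' @param net_inc incidence network with identical support.
#' @return list with `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
abundance_incidence_fit <- function(net_ab, net_inc) {
  stopifnot(inherits(net_ab, "bipartite_network"),
            inherits(net_inc, "bipartite_network"))
  a <- net_ab$weights
  b <- net_inc$weights
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b)) ||
      !identical(unname(a > 0), unname(b > 0)))
    mn_stop("abundance and incidence networks must share the same support",
            "myconet_validation_error")
  sel <- a > 0
  x <- b[sel]; y <- a[sel]
  if (length(x) < 3)
    mn_stop("need at least 3 nonzero cells for a fit",
            "myconet_validation_error")
  if (stats::var(x) == 0)
    mn_stop("incidence weights are constant; slope undefined",
            "myconet_degenerate_error")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly proportional (perfect) fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_points = length(x))
}

#' Write / read a bipartite network
#'
#' Networks are serialized as an edge-list TSV (`plant`, `otu`,
#' `weight`, `net_type`, `lineage`, `community`) or as a dense weighted
#' adjacency TSV. Round-trips are lossless for integer-valued types.
#'
#' @param net a `bipartite_network`.
#' @param path output file.
#' @param format `"edgelist"` or `"dense"`.
#' @export
write_network <- function(net, path, format = c("edgelist", "dense")) {
  format <- match.arg(format)
  w <- net$weights
  if (format == "edgelist") {
    nz <- which(w > 0, arr.ind = TRUE)
    df <- data.frame(plant = rownames(w)[nz[, 1]],
                     otu = colnames(w)[nz[, 2]],
                     weight = w[nz],
                     net_type = net$net_type,
                     lineage = net$lineage,
                     community = net$community)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(plant = rownames(w), w, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @param path path to an edge-list TSV written by [write_network()].
#' @return `read_network()` returns the reconstructed
#'   `bipartite_network` (rows/columns in first-appearance order).
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  plants <- unique(df$plant); otus <- unique(df$otu)
  w <- matrix(0, length(plants), length(otus),
              dimnames = list(plants, otus))
  w[cbind(match(df$plant, plants), match(df$otu, otus))] <- df$weight
  as_bipartite_network(w, net_type = df$net_type[1],
                       lineage = df$lineage[1], community = df$community[1],
                       prune = FALSE)
}
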