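#' Fungal sharing summary across plant species and taxonomic groups
#'
#' Quantifies how much of the mycobiome is shared: for each OTU, the
#' number of plant species and of plant taxonomic groups hosting it,
#' and the table-wide fractions of OTUs (and of reads) that are shared
#' by at least two species or groups, plus the fraction of reads in
#' OTUs found in exactly one sample.
#'
#' Presence can be judged from raw reads (`any_read`) or from the
#' thresholded interaction rule used for network reconstruction
#' (`network_link`, see [detect_interactions()]).
#'
#' @param table a [sample_table()].
#' @param presence_rule `"any_read"` or `"network_link"`.
#' @param presence optional logical samples x OTUs presence matrix; when
#'   missing and `presence_rule = "network_link"` it is computed with
#'   [detect_interactions()] defaults.
#' @return a `sharing_summary` list with per-OTU occupancy and the four
#'   sharing fractions.
#' @export
sharing_summary <- function(table,
                            presence_rule = c("network_link", "any_read"),
                            presence = NULL) {
  stopifnot(inherits(table, "sample_table"))
  presence_rule <- match.arg(presence_rule)
  if (ncol(table$counts) == 0)
    mn_stop("sample table has no OTU", "myconet_empty_error")
  if (is.null(presence)) {
    presence <- if (presence_rule == "any_read") table$counts > 0
    else detect_interactions(table)
  }
  species <- table$sample_meta$plant_species
  groups <- table$sample_meta$taxonomic_group
  # species-level presence: any sample of the species holds the OTU
  sp_pres <- rowsum((presence) * 1, species) > 0
  occ_species <- colSums(sp_pres)
  grp_of_sp <- groups[match(rownames(sp_pres), species)]
  grp_pres <- rowsum(sp_pres * 1, grp_of_sp) > 0
  occ_groups <- colSums(grp_pres)

  shared_sp <- occ_species >= 2
  reads_per_otu <- colSums(table$counts)
  total <- sum(reads_per_otu)
  samples_per_otu <- colSums(table$counts > 0)

  structure(list(
    occupancy = data.frame(otu_id = colnames(table$counts),
                           n_species = as.integer(occ_species),
                           n_groups = as.integer(occ_groups),
                           row.names = NULL),
    fraction_otus_shared_species = mean(shared_sp),
    fraction_otus_shared_groups = mean(occ_groups >= 2),
    fraction_reads_shared =
      if (total > 0) sum(reads_per_otu[shared_sp]) / total else 0,
    fraction_reads_sample_specific =
      if (total > 0) sum(reads_per_otu[samples_per_otu == 1]) / total else 0,
    presence_rule = presence_rule
  ), class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf(
    paste0("sharing_summary (%s): %.1f%% OTUs in >=2 plant species, ",
           "%.1f%% in >=2 groups;\n  %.1f%% of reads in shared OTUs, ",
           "%.1f%% in sample-specific OTUs\n"),
    x$presence_rule,
    100 * x$fraction_otus_shared_species,
    100 * x$fraction_otus_shared_groups,
    100 * x$fraction_reads_shared,
    100 * x$fraction_reads_sample_specific))
  invisible(x)
}

#' Sample-based rarefaction curve for one plant species
#'
#' Mean cumulative OTU richness when the species' root samples are
#' accumulated in random order, averaged over `n_perm` orderings. The
#' final point always equals the species' total richness.
#'
#' @param table a [sample_table()].
#' @param species plant species label.
#' @param n_perm number of random orderings (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `k` (samples drawn) and
#'   `mean_richness`.
#' @export
rarefaction_curve <- function(table, species, n_perm = 100, seed = 1) {
  stopifnot(inherits(table, "sample_table"), n_perm >= 1)
  idx <- which(table$sample_meta$plant_species == species)
  if (length(idx) == 0)
    mn_stop(paste("unknown plant species:", species),
            "myconet_validation_error")
  pres <- table$counts[idx, , drop = FALSE] > 0
  n <- nrow(pres)
  acc <- matrix(0, n_perm, n)
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, ncol(pres))
    for (k in seq_len(n)) {
      seen <- seen | pres[ord[k], ]
      acc[p, k] <- sum(seen)
    }
  }
  data.frame(k = seq_len(n), mean_richness = colMeans(acc))
}
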