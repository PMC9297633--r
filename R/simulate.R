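#' Scenario with planted plant-fungus interaction structure
#'
#' Builds the ground truth of a synthetic study: a sampling design
#' (communities x plots x plant species x samples per species), a
#' fungal OTU pool for one lineage, and a plant-species x OTU
#' interaction propensity matrix with planted structure:
#' \describe{
#'   \item{nested}{propensities `exp(-alpha * (rank_i + rank_j))` on
#'     the triangular region `rank_i + rank_j <= 1` (normalized ranks),
#'     so the binarized support is exactly triangular and NODF of the
#'     truth is 100; `alpha` skews the weights.}
#'   \item{modular}{species and OTUs split into `n_modules` blocks;
#'     links drawn with probability `p_in` within and `p_out` between
#'     blocks, gamma-distributed weights.}
#'   \item{random}{i.i.d. Bernoulli(`p`) links with gamma weights.}
#' }
#'
#' @param structure `"nested"`, `"modular"` or `"random"`.
#' @param params list of overrides: `n_species` (12), `n_otus` (40),
#'   `n_communities` (1), `n_plots` (3), `samples_per_species` (6),
#'   `alpha` (2), `nest_span` (0.7), `nest_noise` (0.15),
#'   `n_modules` (3), `p_in` (0.9), `p_out` (0.05),
#'   `p` (0.3), `lineage` ("Glomeromycotina"), `marker` ("18S"),
#'   `concentration` (50), `depth_log_mean` (9), `depth_log_sd` (0.5),
#'   `contam_cells_per_sample` (3), `contam_mean_reads` (2),
#'   `sample_specific_rate` (0.05).
#' @param seed integer seed.
#' @return a `scenario_truth` object.
#' @export
make_scenario <- function(structure = c("nested", "modular", "random"),
                          params = list(), seed = 1) {
  structure_tag <- match.arg(structure)
  p <- utils::modifyList(list(
    n_species = 12, n_otus = 40, n_communities = 1, n_plots = 3,
    samples_per_species = 6, alpha = 2, nest_span = 0.7, nest_noise = 0.15,
    n_modules = 3, p_in = 0.9, p_out = 0.05, p = 0.3,
    lineage = "Glomeromycotina", marker = "18S",
    concentration = 50, depth_log_mean = 9, depth_log_sd = 0.5,
    contam_cells_per_sample = 3, contam_mean_reads = 2,
    sample_specific_rate = 0.05), params)
  if (structure_tag == "modular" && p$p_out >= p$p_in)
    mn_stop("modular scenarios need p_out < p_in", "myconet_validation_error")
  set.seed(as.integer(seed))
  ns <- p$n_species; no <- p$n_otus
  module_map <- NULL
  if (structure_tag == "nested") {
    # nested core with noise: the core support is the staircase
    # rank_i + rank_j <= nest_span (plus the top-ranked OTU for every
    # species), and each cell is flipped with probability nest_noise,
    # planting holes inside the core and sporadic links outside it.
    # At nest_noise = 0 the support is exactly triangular (perfectly
    # nested truth, unique realization of its marginals); the default
    # noise leaves a detectably nested but imperfect network, the
    # regime real root mycobiomes occupy. alpha skews the weights
    # toward the generalist corner; nest_span sets the core
    # connectance (~nest_span^2 / 2).
    ri <- (seq_len(ns) - 1) / (ns - 1)
    rj <- (seq_len(no) - 1) / (no - 1)
    prop <- outer(ri, rj, function(a, b) exp(-p$alpha * (a + b)))
    supp <- outer(ri, rj, "+") <= p$nest_span + 1e-12
    supp[, 1] <- TRUE
    if (p$nest_noise > 0) {
      flip <- matrix(stats::runif(ns * no) < p$nest_noise, ns, no)
      supp <- xor(supp, flip)
    }
    prop[!supp] <- 0
  } else if (structure_tag == "modular") {
    sp_mod <- rep_len(seq_len(p$n_modules), ns)
    ot_mod <- rep_len(seq_len(p$n_modules), no)
    same <- outer(sp_mod, ot_mod, "==")
    link <- matrix(stats::rbinom(ns * no, 1,
                                 ifelse(same, p$p_in, p$p_out)), ns, no)
    prop <- link * matrix(stats::rgamma(ns * no, shape = 2, rate = 1), ns, no)
    module_map <- list(species = sp_mod, otus = ot_mod)
  } else {
    link <- matrix(stats::rbinom(ns * no, 1, p$p), ns, no)
    prop <- link * matrix(stats::rgamma(ns * no, shape = 2, rate = 1), ns, no)
  }
  # every species must have at least one partner
  for (i in which(rowSums(prop) == 0)) {
    cand <- if (!is.null(module_map))
      which(module_map$otus == module_map$species[i]) else seq_len(no)
    j <- cand[sample.int(length(cand), 1)]
    prop[i, j] <- stats::rgamma(1, shape = 2, rate = 1)
  }
  groups <- c("bryophytes", "lycopods", "ferns", "monocots", "eudicots",
              "Orchidaceae", "Ericaceae")
  # per-community availability multiplier per OTU (mild lognormal)
  avail <- matrix(stats::rlnorm(p$n_communities * no, 0, 0.25),
                  p$n_communities, no)
  structure(list(
    structure = structure_tag,
    params = p,
    species = paste0("sp", sprintf("%02d", seq_len(ns))),
    otus = paste0("OTU", sprintf("%03d", seq_len(no))),
    taxonomic_group = rep_len(groups, ns),
    communities = paste0("community", seq_len(p$n_communities)),
    plots = paste0("plot", seq_len(p$n_plots)),
    propensity = prop,
    availability = avail,
    module_map = module_map,
    seed = seed
  ), class = "scenario_truth")
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf(
    "scenario_truth (%s): %d plant species x %d OTUs, %d community(ies), seed %d\n",
    x$structure, length(x$species), length(x$otus),
    length(x$communities), x$seed))
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate sample-level read tables from a scenario
#'
#' For each root sample, the expected fungal composition is the
#' species' propensity row scaled by the community availability,
#' perturbed by a Dirichlet draw (`concentration` x composition);
#' sequencing depth is log-normal and reads are multinomial.
#' Contamination adds a few foreign-OTU cells per sample with
#' Poisson-distributed read counts (designed to fall below the 5-read
#' floor at default rates), and rare sample-specific OTUs are injected
#' at a configured rate. Deterministic per seed; every random draw
#' uses a substream indexed by sample so results do not depend on
#' evaluation order.
#'
#' @param truth a `scenario_truth` from [make_scenario()].
#' @param seed integer seed.
#' @return a [sample_table()]; the injected contamination cells are
#'   attached as `attr(, "contam_cells")` (sample, otu, reads) and the
#'   injected sample-specific OTUs as `attr(, "sample_specific")`.
#' @export
simulate_reads <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "scenario_truth"))
  p <- truth$params
  ns <- length(truth$species); no <- length(truth$otus)
  design <- expand.grid(species_i = seq_len(ns),
                        rep = seq_len(p$samples_per_species),
                        community_i = seq_along(truth$communities),
                        KEEP.OUT.ATTRS = FALSE)
  n_samples <- nrow(design)
  counts <- matrix(0L, n_samples, no)
  contam <- list()
  sso <- list()
  sso_counts <- list()
  for (s in seq_len(n_samples)) {
    set.seed(substream_seed(seed, s))
    i <- design$species_i[s]
    ci <- design$community_i[s]
    base <- truth$propensity[i, ] * truth$availability[ci, ]
    comp <- base / sum(base)
    comp <- rdirichlet1(p$concentration * comp + 1e-9)
    depth <- round(stats::rlnorm(1, p$depth_log_mean, p$depth_log_sd))
    reads <- stats::rmultinom(1, size = max(depth, 1), prob = comp)[, 1]
    # cross-sample contamination on foreign OTUs
    foreign <- which(truth$propensity[i, ] == 0)
    n_cells <- stats::rpois(1, p$contam_cells_per_sample)
    if (n_cells > 0 && length(foreign) > 0) {
      cells <- foreign[sample.int(length(foreign),
                                  min(n_cells, length(foreign)))]
      creads <- stats::rpois(length(cells), p$contam_mean_reads)
      reads[cells] <- reads[cells] + creads
      contam[[length(contam) + 1]] <-
        data.frame(sample = s, otu = cells, reads = creads)
    }
    # sample-specific rare OTU
    if (stats::runif(1) < p$sample_specific_rate) {
      sso[[length(sso) + 1]] <- s
      sso_counts[[length(sso_counts) + 1]] <- 1 + stats::rpois(1, 30)
    }
    counts[s, ] <- reads
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  otu_ids <- truth$otus
  # append the sample-specific OTUs as new columns
  if (length(sso)) {
    extra <- matrix(0L, n_samples, length(sso))
    for (k in seq_along(sso)) extra[sso[[k]], k] <- sso_counts[[k]]
    counts <- cbind(counts, extra)
    otu_ids <- c(otu_ids, sprintf("OTUss%02d", seq_along(sso)))
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  plot_of <- rep_len(truth$plots, n_samples)
  sample_meta <- data.frame(
    sample_id = sample_ids,
    plant_species = truth$species[design$species_i],
    taxonomic_group = truth$taxonomic_group[design$species_i],
    plot = plot_of,
    community = truth$communities[design$community_i],
    marker = p$marker)
  otu_meta <- data.frame(
    otu_id = otu_ids,
    lineage = paste0("Fungi/", p$lineage),
    guild = "mycorrhizal")
  tab <- sample_table(counts, sample_meta, otu_meta)
  attr(tab, "contam_cells") <- if (length(contam)) {
    cc <- do.call(rbind, contam)
    cc$sample <- sample_ids[cc$sample]
    cc$otu <- truth$otus[cc$otu]
    cc
  } else data.frame(sample = character(0), otu = character(0),
                    reads = integer(0))
  attr(tab, "sample_specific") <- if (length(sso))
    data.frame(sample = sample_ids[unlist(sso)],
               otu = sprintf("OTUss%02d", seq_along(sso)))
  else data.frame(sample = character(0), otu = character(0))
  tab
}

#' Write a simulated scenario to disk
#'
#' Writes the counts, sample metadata and taxonomy TSVs (readable by
#' [load_sample_table()]) plus a JSON description of the truth.
#'
#' @param truth a `scenario_truth`.
#' @param table the matching [sample_table()] from [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scenario <- function(truth, table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- data.frame(otu_id = colnames(table$counts), t(table$counts),
                       check.names = FALSE)
  utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(table$sample_meta, file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$otu_meta, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth_json <- list(structure = truth$structure, params = truth$params,
                       seed = truth$seed,
                       module_map = truth$module_map)
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
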