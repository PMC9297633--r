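#' Sample-level OTU table with plant-host metadata
#'
#' A `sample_table` bundles a samples x OTUs read-count matrix with the
#' per-sample plant metadata (plant species, taxonomic group, plot,
#' community, marker) and the per-OTU taxonomy (lineage path, guild).
#' It is the sole empirical input of the pipeline: every network and
#' every compositional analysis starts here.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns,
#'   with row and column names.
#' @param sample_meta data.frame with columns `sample_id`,
#'   `plant_species`, `taxonomic_group`, `plot`, `community`, `marker`.
#' @param otu_meta data.frame with columns `otu_id`, `lineage` (a
#'   `/`-separated lineage path) and `guild`.
#' @return an object of class `sample_table`.
#' @export
sample_table <- function(counts, sample_meta, otu_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    mn_stop("counts must have sample row names and OTU column names",
            "myconet_validation_error")
  validate_sample_table(counts, sample_meta, otu_meta)
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  otu_meta <- otu_meta[match(colnames(counts), otu_meta$otu_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  rownames(otu_meta) <- NULL
  structure(
    list(counts = counts, sample_meta = sample_meta, otu_meta = otu_meta),
    class = "sample_table"
  )
}

validate_sample_table <- function(counts, sample_meta, otu_meta) {
  req_s <- c("sample_id", "plant_species", "taxonomic_group", "plot",
             "community", "marker")
  req_o <- c("otu_id", "lineage", "guild")
  if (!all(req_s %in% names(sample_meta)))
    mn_stop(paste("sample metadata must contain columns:",
                  paste(req_s, collapse = ", ")), "myconet_validation_error")
  if (!all(req_o %in% names(otu_meta)))
    mn_stop(paste("OTU taxonomy must contain columns:",
                  paste(req_o, collapse = ", ")), "myconet_validation_error")
  if (anyDuplicated(rownames(counts)))
    mn_stop("duplicated sample ids in counts", "myconet_validation_error")
  if (anyDuplicated(colnames(counts)))
    mn_stop("duplicated OTU ids in counts", "myconet_validation_error")
  if (anyDuplicated(sample_meta$sample_id))
    mn_stop("duplicated sample ids in metadata", "myconet_validation_error")
  if (anyDuplicated(otu_meta$otu_id))
    mn_stop("duplicated OTU ids in taxonomy", "myconet_validation_error")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    mn_stop("counts must be non-negative integers",
            "myconet_validation_error")
  missing_s <- setdiff(rownames(counts), sample_meta$sample_id)
  if (length(missing_s))
    mn_stop(paste("samples in counts without metadata:",
                  paste(missing_s, collapse = ", ")),
            "myconet_validation_error")
  missing_o <- setdiff(colnames(counts), otu_meta$otu_id)
  if (length(missing_o))
    mn_stop(paste("OTUs in counts without taxonomy:",
                  paste(missing_o, collapse = ", ")),
            "myconet_validation_error")
  markers <- unique(sample_meta$marker[sample_meta$sample_id %in%
                                         rownames(counts)])
  if (length(markers) > 1)
    mn_stop(paste("a sample table must hold a single marker, found:",
                  paste(markers, collapse = ", ")),
            "myconet_validation_error")
  invisible(TRUE)
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf(
    "sample_table: %d samples x %d OTUs (%s), %d plant species, %s reads\n",
    nrow(x$counts), ncol(x$counts),
    unique(x$sample_meta$marker)[1],
    length(unique(x$sample_meta$plant_species)),
    format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$counts)

#' Read a sample table from delimited files
#'
#' Reads a read-count matrix together with its sample metadata and OTU
#' taxonomy. The count file is either a TSV with OTUs as rows and
#' samples as columns (the common metabarcoding layout; the transposed
#' orientation is auto-detected by matching ids against the metadata)
#' or a Matrix-Market sparse triplet file accompanied by row- and
#' column-label files.
#'
#' @param counts_path path to the count TSV (first column = ids) or
#'   `.mtx` file.
#' @param sample_meta_path path to the sample metadata TSV.
#' @param taxonomy_path path to the OTU taxonomy TSV.
#' @param mtx_row_labels,mtx_col_labels for `.mtx` input, paths to one-
#'   id-per-line label files for the matrix rows and columns.
#' @return a [sample_table()]. Metadata rows describing samples absent
#'   from the count matrix are dropped with a warning.
#' @export
load_sample_table <- function(counts_path, sample_meta_path, taxonomy_path,
                              mtx_row_labels = NULL, mtx_col_labels = NULL) {
  for (p in c(counts_path, sample_meta_path, taxonomy_path))
    if (!file.exists(p))
      mn_stop(paste("file not found:", p), "myconet_validation_error")
  sample_meta <- utils::read.delim(sample_meta_path, stringsAsFactors = FALSE,
                                   check.names = FALSE)
  otu_meta <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE,
                                check.names = FALSE)

  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    if (is.null(mtx_row_labels) || is.null(mtx_col_labels))
      mn_stop("mtx input requires row and column label files",
              "myconet_validation_error")
    rownames(m) <- readLines(mtx_row_labels)
    colnames(m) <- readLines(mtx_col_labels)
  } else {
    df <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (!is.numeric(m))
      mn_stop("non-numeric values in count matrix",
              "myconet_validation_error")
  }

  # orientation: we want samples in rows; the file usually has OTUs as rows
  row_is_sample <- mean(rownames(m) %in% sample_meta$sample_id)
  col_is_sample <- mean(colnames(m) %in% sample_meta$sample_id)
  if (col_is_sample > row_is_sample) m <- t(m)

  unknown <- setdiff(rownames(m), sample_meta$sample_id)
  if (length(unknown))
    mn_stop(paste("samples in counts without metadata:",
                  paste(unknown, collapse = ", ")),
            "myconet_validation_error")
  extra <- setdiff(sample_meta$sample_id, rownames(m))
  if (length(extra)) {
    mn_warn(paste("dropping metadata rows with no counts:",
                  paste(extra, collapse = ", ")))
    sample_meta <- sample_meta[sample_meta$sample_id %in% rownames(m), ,
                               drop = FALSE]
  }
  extra_o <- setdiff(otu_meta$otu_id, colnames(m))
  if (length(extra_o)) {
    mn_warn(paste("dropping taxonomy rows with no counts:",
                  paste(extra_o, collapse = ", ")))
    otu_meta <- otu_meta[otu_meta$otu_id %in% colnames(m), , drop = FALSE]
  }
  sample_table(m, sample_meta, otu_meta)
}

#' Guild filter configuration
#'
#' The guild filter keeps the putatively mycorrhizal part of the table:
#' OTUs whose lineage path contains one of the whitelisted labels are
#' retained, and samples left with fewer than `min_sample_reads` reads
#' of the retained OTUs are discarded.
#'
#' @param lineage_whitelist non-empty character vector of lineage
#'   labels (matched against any level of the `/`-separated path).
#' @param min_sample_reads minimum retained-read total per sample
#'   (default 20).
#' @return a `guild_config` object.
#' @export
guild_config <- function(lineage_whitelist, min_sample_reads = 20) {
  if (length(lineage_whitelist) == 0)
    mn_stop("lineage whitelist must be non-empty", "myconet_validation_error")
  if (min_sample_reads < 0)
    mn_stop("min_sample_reads must be >= 0", "myconet_validation_error")
  structure(list(lineage_whitelist = as.character(lineage_whitelist),
                 min_sample_reads = as.integer(min_sample_reads)),
            class = "guild_config")
}

lineage_levels <- function(lineage) strsplit(lineage, "/", fixed = TRUE)

#' Retain putatively mycorrhizal OTUs and sufficiently covered samples
#'
#' @param table a [sample_table()].
#' @param config a [guild_config()].
#' @return the filtered [sample_table()]; row/column order preserved.
#' @export
filter_guild <- function(table, config) {
  stopifnot(inherits(table, "sample_table"), inherits(config, "guild_config"))
  levs <- lineage_levels(table$otu_meta$lineage)
  keep_otu <- vapply(levs, function(l) any(l %in% config$lineage_whitelist),
                     logical(1))
  if (!any(keep_otu))
    mn_stop(paste("guild whitelist matched no OTU lineage:",
                  paste(config$lineage_whitelist, collapse = ", ")),
            "myconet_empty_error")
  counts <- table$counts[, keep_otu, drop = FALSE]
  keep_sample <- rowSums(counts) >= config$min_sample_reads
  counts <- counts[keep_sample, , drop = FALSE]
  if (nrow(counts) == 0)
    mn_stop("no sample passes the minimum-read filter",
            "myconet_empty_error")
  sample_table(counts,
               table$sample_meta[keep_sample, , drop = FALSE],
               table$otu_meta[keep_otu, , drop = FALSE])
}

#' Default lineage-to-marker mapping
#'
#' Glomeromycotina and Mucoromycotina are detected by the 18S rRNA
#' marker; Sebacinales, Helotiales and Cantharellales by ITS2.
#'
#' @return named character vector mapping lineage to marker.
#' @export
default_lineage_markers <- function() {
  c(Glomeromycotina = "18S", Mucoromycotina = "18S",
    Sebacinales = "ITS2", Helotiales = "ITS2", Cantharellales = "ITS2")
}

#' Subset a sample table to one fungal lineage
#'
#' Samples with zero reads of the lineage are retained as all-zero rows:
#' they still count in incidence denominators downstream.
#'
#' @param table a [sample_table()].
#' @param lineage lineage label (matched against any level of the path).
#' @param marker expected marker for the lineage; defaults to the value
#'   in [default_lineage_markers()] when the lineage is listed there.
#' @return the lineage sub-table.
#' @export
subset_lineage <- function(table, lineage, marker = NULL) {
  stopifnot(inherits(table, "sample_table"))
  mapping <- default_lineage_markers()
  if (is.null(marker) && lineage %in% names(mapping))
    marker <- mapping[[lineage]]
  table_marker <- unique(table$sample_meta$marker)[1]
  if (!is.null(marker) && !identical(table_marker, marker))
    mn_stop(sprintf(
      paste0("lineage %s is expected on the %s marker but the table is %s ",
             "(default mapping: %s)"),
      lineage, marker, table_marker,
      paste(names(mapping), mapping, sep = "->", collapse = ", ")),
      "myconet_config_error")
  levs <- lineage_levels(table$otu_meta$lineage)
  keep <- vapply(levs, function(l) lineage %in% l, logical(1))
  if (!any(keep))
    message("lineage ", lineage, " matches no OTU; returning empty sub-table")
  sub <- table
  sub$counts <- table$counts[, keep, drop = FALSE]
  sub$otu_meta <- table$otu_meta[keep, , drop = FALSE]
  sub
}

#' Subset a sample table to one community
#'
#' @param table a [sample_table()].
#' @param community community label.
#' @return the community sub-table.
#' @export
subset_community <- function(table, community) {
  stopifnot(inherits(table, "sample_table"))
  keep <- table$sample_meta$community == community
  if (!any(keep))
    mn_stop(paste("unknown community:", community), "myconet_validation_error")
  sub <- table
  sub$counts <- table$counts[keep, , drop = FALSE]
  sub$sample_meta <- table$sample_meta[keep, , drop = FALSE]
  sub
}
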