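test_that("loading preserves read totals and validates orientation", {
  dir <- withr::local_tempdir()
  paths <- write_toy_tsvs(dir)
  tab <- load_sample_table(paths$counts, paths$meta, paths$tax)
  expect_s3_class(tab, "sample_table")
  expect_identical(dim(tab$counts), c(3L, 4L))
  expect_equal(sum(tab$counts), sum(toy_sample_table()$counts))
  # samples end up in rows whatever the file orientation
  expect_true(all(rownames(tab$counts) %in% tab$sample_meta$sample_id))
})

test_that("invalid counts and inconsistent metadata are rejected", {
  dir <- withr::local_tempdir()
  paths <- write_toy_tsvs(dir, counts_edit = list(i = 2, j = 2, v = -2L))
  expect_error(load_sample_table(paths$counts, paths$meta, paths$tax),
               class = "myconet_validation_error")

  tab <- toy_sample_table()
  expect_error(
    sample_table(tab$counts, tab$sample_meta[-1, ], tab$otu_meta),
    class = "myconet_validation_error")
  dup <- tab$counts
  rownames(dup) <- c("S1", "S1", "S3")
  expect_error(sample_table(dup, tab$sample_meta, tab$otu_meta),
               class = "myconet_validation_error")
  mixed <- tab$sample_meta
  mixed$marker[2] <- "ITS2"
  expect_error(sample_table(tab$counts, mixed, tab$otu_meta),
               class = "myconet_validation_error")
})

test_that("metadata rows without counts are dropped with a warning", {
  dir <- withr::local_tempdir()
  extra <- data.frame(sample_id = "S9", plant_species = "plantC",
                      taxonomic_group = "eudicots", plot = "p1",
                      community = "c1", marker = "18S")
  paths <- write_toy_tsvs(dir, extra_meta = extra)
  expect_warning(tab <- load_sample_table(paths$counts, paths$meta,
                                          paths$tax),
                 "S9")
  expect_identical(nrow(tab$counts), 3L)
  expect_false("S9" %in% tab$sample_meta$sample_id)
})

test_that("guild filter keeps whitelisted lineages and covered samples", {
  tab <- toy_sample_table()
  ft <- filter_guild(tab, guild_config(c("Glomeromycotina", "Helotiales"),
                                       min_sample_reads = 20))
  expect_identical(colnames(ft$counts), c("OTU1", "OTU2", "OTU4"))
  # sample below the 20-read floor of retained OTUs is dropped:
  # S3 keeps 80 + 0 + 9 = 89 reads, retained; shrink the floor case
  ft2 <- filter_guild(tab, guild_config("Helotiales", min_sample_reads = 4))
  expect_identical(rownames(ft2$counts), "S3")  # S1 has 3 < 4, S2 has 0

  # exactly at the threshold is kept, one below is dropped
  counts <- rbind(A = c(x = 20L, y = 0L), B = c(x = 19L, y = 500L))
  meta <- data.frame(sample_id = c("A", "B"), plant_species = "p",
                     taxonomic_group = "ferns", plot = "p1",
                     community = "c1", marker = "18S")
  otus <- data.frame(otu_id = c("x", "y"),
                     lineage = c("Fungi/Glomeromycotina", "Fungi/Ascomycota"),
                     guild = "g")
  st <- sample_table(counts, meta, otus)
  kept <- filter_guild(st, guild_config("Glomeromycotina", 20))
  expect_identical(rownames(kept$counts), "A")

  expect_error(filter_guild(tab, guild_config("Zygomycota")),
               class = "myconet_empty_error")
})

test_that("lineage subsetting respects the marker mapping", {
  tab <- toy_sample_table()  # an 18S table
  sub <- subset_lineage(tab, "Glomeromycotina")
  expect_identical(colnames(sub$counts), c("OTU1", "OTU2"))
  expect_identical(nrow(sub$counts), 3L)  # zero-read samples retained
  expect_error(subset_lineage(tab, "Helotiales"),
               class = "myconet_config_error")
  expect_message(empty <- subset_lineage(tab, "Cantharellales",
                                         marker = "18S"))
  expect_identical(ncol(empty$counts), 0L)
})

test_that("guild filtering commutes with lineage subsetting and never adds reads", {
  tr <- make_scenario("random", seed = 42)
  tab <- simulate_reads(tr, seed = 43)
  cfg <- guild_config("Glomeromycotina", 20)
  a <- subset_lineage(filter_guild(tab, cfg), "Glomeromycotina")
  b <- filter_guild(subset_lineage(tab, "Glomeromycotina"), cfg)
  expect_identical(a$counts[rownames(b$counts), colnames(b$counts)],
                   b$counts)
  expect_lte(sum(filter_guild(tab, cfg)$counts), sum(tab$counts))
})

test_that("sharing fractions match direct occupancy tallies", {
  tab <- toy_sample_table()
  # any_read: OTU1 in plantA+plantB, OTU2 in plantA, OTU3 in both,
  # OTU4 in both -> 3/4 shared across species and groups
  sh <- sharing_summary(tab, presence_rule = "any_read")
  expect_equal(sh$fraction_otus_shared_species, 3 / 4)
  expect_equal(sh$fraction_otus_shared_groups, 3 / 4)
  reads <- colSums(tab$counts)
  expect_equal(sh$fraction_reads_shared,
               sum(reads[c(1, 3, 4)]) / sum(reads))
  # OTUs confined to one species share nothing
  conf <- tab
  conf$counts[c("S3"), ] <- 0L
  conf$counts["S3", "OTU3"] <- 50L
  conf$counts["S1", "OTU3"] <- 0L
  conf$counts["S2", "OTU3"] <- 0L
  sh2 <- sharing_summary(conf, presence_rule = "any_read")
  expect_equal(sh2$fraction_otus_shared_species, 0)

  # brute-force tally on a randomized table
  tr <- make_scenario("random", seed = 7)
  big <- simulate_reads(tr, seed = 8)
  sh3 <- sharing_summary(big, presence_rule = "any_read")
  pres <- big$counts > 0
  spp <- big$sample_meta$plant_species
  occ <- vapply(seq_len(ncol(pres)), function(j)
    length(unique(spp[pres[, j]])), integer(1))
  expect_equal(sh3$occupancy$n_species, occ)
  expect_equal(sh3$fraction_otus_shared_species, mean(occ >= 2))
  # invariance to sample order
  perm <- sample(nrow(big$counts))
  shuf <- sample_table(big$counts[perm, ], big$sample_meta[perm, ],
                       big$otu_meta)
  sh4 <- sharing_summary(shuf, presence_rule = "any_read")
  expect_equal(sh4$fraction_otus_shared_species,
               sh3$fraction_otus_shared_species)
  expect_equal(sh4$fraction_reads_shared, sh3$fraction_reads_shared)
  expect_gte(sh3$fraction_otus_shared_species,
             sh3$fraction_otus_shared_groups)
})

test_that("rarefaction curves accumulate to the exact total richness", {
  tab <- toy_sample_table()
  cur <- rarefaction_curve(tab, "plantB", n_perm = 5, seed = 1)
  expect_identical(nrow(cur), 1L)
  expect_equal(cur$mean_richness, sum(tab$counts["S3", ] > 0))

  tr <- make_scenario("random", seed = 3)
  big <- simulate_reads(tr, seed = 4)
  sp <- big$sample_meta$plant_species[1]
  c1 <- rarefaction_curve(big, sp, n_perm = 10, seed = 1)
  c2 <- rarefaction_curve(big, sp, n_perm = 10, seed = 99)
  idx <- big$sample_meta$plant_species == sp
  union_rich <- sum(colSums(big$counts[idx, , drop = FALSE]) > 0)
  expect_equal(c1$mean_richness[nrow(c1)], union_rich)
  expect_equal(c2$mean_richness[nrow(c2)], union_rich)
  # k = 1 converges to the mean per-sample richness
  c3 <- rarefaction_curve(big, sp, n_perm = 400, seed = 5)
  per_sample <- rowSums(big$counts[idx, , drop = FALSE] > 0)
  expect_lt(abs(c3$mean_richness[1] - mean(per_sample)),
            3 * sd(per_sample) / sqrt(400) + 1e-9)
  expect_error(rarefaction_curve(big, "no-such-species"),
               class = "myconet_validation_error")
})
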