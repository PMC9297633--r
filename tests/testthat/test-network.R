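test_that("interaction detection is the conjunction of both thresholds", {
  counts <- rbind(
    S1 = c(a = 10L, b = 4L, c = 986L),
    S2 = c(a = 50L, b = 9950L, c = 0L))
  meta <- data.frame(sample_id = c("S1", "S2"),
                     plant_species = c("p1", "p2"),
                     taxonomic_group = "ferns", plot = "p1",
                     community = "c1", marker = "18S")
  otus <- data.frame(otu_id = c("a", "b", "c"),
                     lineage = "Fungi/Glomeromycotina", guild = "g")
  tab <- sample_table(counts, meta, otus)
  pres <- detect_interactions(tab)
  # S1 total 1000: 10 reads = 1% and >= 5 -> in; 4 reads fail the floor
  expect_true(pres["S1", "a"])
  expect_false(pres["S1", "b"])
  # S2 total 10000: 50 reads = 0.5% < 1% -> out despite the floor
  expect_false(pres["S2", "a"])
  # raising either threshold never adds a link
  stricter1 <- detect_interactions(tab, rel_threshold = 0.05)
  stricter2 <- detect_interactions(tab, min_reads = 20)
  expect_true(all(pres | !stricter1))
  expect_true(all(pres | !stricter2))
})

test_that("zero-read samples are skipped with a warning", {
  counts <- rbind(S1 = c(a = 100L, b = 20L), S2 = c(a = 0L, b = 0L))
  meta <- data.frame(sample_id = c("S1", "S2"), plant_species = "p",
                     taxonomic_group = "ferns", plot = "p1",
                     community = "c1", marker = "18S")
  otus <- data.frame(otu_id = c("a", "b"),
                     lineage = "Fungi/Glomeromycotina", guild = "g")
  tab <- sample_table(counts, meta, otus)
  expect_warning(pres <- detect_interactions(tab), "S2")
  expect_false(any(pres["S2", ]))
})

test_that("network weights follow the per-type aggregation rules", {
  # plant species 'p' with two samples: A: OTU1 100/100; B: OTU1 300,
  # OTU2 100 of 400. second species keeps the network non-degenerate.
  counts <- rbind(
    A = c(OTU1 = 100L, OTU2 = 0L, OTU3 = 0L),
    B = c(OTU1 = 300L, OTU2 = 100L, OTU3 = 0L),
    C = c(OTU1 = 0L, OTU2 = 60L, OTU3 = 140L))
  meta <- data.frame(sample_id = c("A", "B", "C"),
                     plant_species = c("p", "p", "q"),
                     taxonomic_group = "ferns", plot = "p1",
                     community = "c1", marker = "18S")
  otus <- data.frame(otu_id = paste0("OTU", 1:3),
                     lineage = "Fungi/Glomeromycotina", guild = "g")
  tab <- sample_table(counts, meta, otus)
  ab <- build_network(tab, "abundance")
  expect_equal(unname(ab$weights["p", c("OTU1", "OTU2")]), c(800, 200))
  expect_equal(unname(rowSums(ab$weights)), c(1000, 1000))
  inc <- build_network(tab, "incidence")
  expect_equal(unname(inc$weights["p", c("OTU1", "OTU2")]), c(2, 1))
  expect_true(all(inc$weights <= inc$n_samples_per_species[rownames(inc$weights)]))
  bin <- build_network(tab, "binary")
  expect_true(all(bin$weights %in% c(0, 1)))
  expect_identical(unname(bin$weights > 0), unname(inc$weights > 0))
  expect_identical(unname(bin$weights > 0), unname(ab$weights > 0))
})

test_that("undetected reads contribute nothing and degeneracy errors", {
  counts <- rbind(A = c(x = 1000L, y = 4L), B = c(x = 0L, y = 900L))
  meta <- data.frame(sample_id = c("A", "B"),
                     plant_species = c("p", "q"),
                     taxonomic_group = "ferns", plot = "p1",
                     community = "c1", marker = "18S")
  otus <- data.frame(otu_id = c("x", "y"),
                     lineage = "Fungi/Glomeromycotina", guild = "g")
  tab <- sample_table(counts, meta, otus)
  # y in sample A fails the floor: cell (p, y) stays 0 even though raw
  # reads exist
  ab <- build_network(tab, "abundance")
  expect_equal(unname(ab$weights["p", "y"]), 0)
  expect_equal(unname(ab$weights["p", "x"]), 1000)
  # a single detectable species leaves a degenerate network
  solo <- sample_table(counts[1, , drop = FALSE], meta[1, ], otus)
  expect_error(build_network(solo, "binary"),
               class = "myconet_degenerate_error")
})

test_that("abundance-incidence fits recover the closed-form OLS solution", {
  w_inc <- matrix(c(3, 1, 0, 2, 0, 4), 2, 3,
                  dimnames = list(c("p", "q"), c("a", "b", "c")))
  # abundance proportional to incidence -> perfect fit
  ab <- as_bipartite_network(w_inc * 250, "abundance", prune = FALSE)
  inc <- as_bipartite_network(w_inc, "incidence", prune = FALSE)
  fit <- abundance_incidence_fit(ab, inc)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 250)
  expect_equal(fit$intercept, 0)

  # general 6-cell case vs normal equations
  set.seed(1)
  y <- w_inc
  y[y > 0] <- c(700, 300, 420, 580)
  ab2 <- as_bipartite_network(y, "abundance", prune = FALSE)
  fit2 <- abundance_incidence_fit(ab2, inc)
  x <- w_inc[w_inc > 0]; yy <- y[w_inc > 0]
  xm <- cbind(1, x)
  beta <- solve(t(xm) %*% xm, t(xm) %*% yy)
  expect_equal(fit2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit2$slope, beta[2], tolerance = 1e-10)

  const <- w_inc
  const[const > 0] <- 2
  expect_error(abundance_incidence_fit(
    as_bipartite_network(const * 100, "abundance", prune = FALSE),
    as_bipartite_network(const, "incidence", prune = FALSE)),
    class = "myconet_degenerate_error")
  # support mismatch
  other <- w_inc; other[1, 3] <- 5
  expect_error(abundance_incidence_fit(
    as_bipartite_network(other, "abundance", prune = FALSE), inc),
    class = "myconet_validation_error")
})

test_that("network serialization round-trips integer types losslessly", {
  set.seed(5)
  w <- random_count_matrix(4, 6)
  net <- as_bipartite_network(w, "incidence", lineage = "Glomeromycotina",
                              community = "c1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back$weights[rownames(net$weights), colnames(net$weights)],
               net$weights)
  expect_identical(back$net_type, "incidence")
  expect_identical(back$lineage, "Glomeromycotina")
})
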