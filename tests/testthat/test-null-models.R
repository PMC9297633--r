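test_that("binary fixed-marginal draws conserve marginals and fill", {
  set.seed(91)
  a <- random_binary_matrix(6, 8)
  draws <- quasiswap_binary(a, seed = 1, n = 300)
  ok <- vapply(draws, function(x)
    all(rowSums(x) == rowSums(a)) && all(colSums(x) == colSums(a)) &&
      sum(x) == sum(a) && all(x %in% c(0, 1)), logical(1))
  expect_true(all(ok))
  # at least some draws differ from the input (the sampler moves)
  expect_true(any(vapply(draws, function(x) any(x != a), logical(1))))
})

test_that("the 2x2 checkerboard has exactly two equally likely states", {
  m <- diag(2)
  draws <- quasiswap_binary(m, seed = 5, n = 4000)
  states <- vapply(draws, function(x) x[1, 1] == 1, logical(1))
  expect_true(all(vapply(draws, function(x)
    all(rowSums(x) == 1) && all(colSums(x) == 1), logical(1))))
  # each orientation with frequency 1/2 within 3 sigma
  expect_lt(abs(mean(states) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("count quasiswap draws conserve marginals, total and fill", {
  set.seed(101)
  cm <- random_count_matrix(5, 7)
  draws <- quasiswap_count(cm, seed = 2, n = 300)
  ok <- vapply(draws, function(x)
    all(rowSums(x) == rowSums(cm)) && all(colSums(x) == colSums(cm)) &&
      sum(x) == sum(cm) && sum(x > 0) == sum(cm > 0), logical(1))
  expect_true(all(ok))
})

test_that("Patefield tables have exact marginals and free fill", {
  # forced table
  expect_equal(patefield(c(2, 0), c(1, 1), seed = 1),
               matrix(c(1, 0, 1, 0), 2, 2))
  expect_error(patefield(c(2, 1), c(1, 1)),
               class = "myconet_validation_error")
  # marginals always conserved; cell means near r_i c_j / m
  r <- c(8, 5, 3); cc <- c(6, 6, 4)
  draws <- patefield(r, cc, seed = 3, n = 2000)
  expect_true(all(vapply(draws, function(x)
    all(rowSums(x) == r) && all(colSums(x) == cc), logical(1))))
  means <- Reduce(`+`, draws) / length(draws)
  expected <- outer(r, cc) / sum(r)
  # hypergeometric cell sd <= binomial sd; allow 4 sigma of the mean
  sds <- sqrt(expected * (1 - outer(r, rep(1, 3)) / sum(r)) /
                length(draws)) + 1e-6
  expect_true(all(abs(means - expected) < 4 * pmax(sds, 0.02)))
})

test_that("sample shuffling permutes species labels and nothing else", {
  tr <- make_scenario("random", seed = 5)
  tab <- simulate_reads(tr, seed = 6)
  sh <- shuffle_samples(tab, seed = 9)
  expect_identical(sh$counts, tab$counts)
  expect_identical(sort(sh$sample_meta$plant_species),
                   sort(tab$sample_meta$plant_species))
  expect_identical(sh$sample_meta$plot, tab$sample_meta$plot)
  # species -> group mapping is preserved
  map1 <- unique(tab$sample_meta[, c("plant_species", "taxonomic_group")])
  map2 <- unique(sh$sample_meta[, c("plant_species", "taxonomic_group")])
  expect_identical(map1[order(map1$plant_species), ]$taxonomic_group,
                   map2[order(map2$plant_species), ]$taxonomic_group)
  # multiple communities refuse to shuffle
  tr2 <- make_scenario("random", params = list(n_communities = 2), seed = 7)
  tab2 <- simulate_reads(tr2, seed = 8)
  expect_error(shuffle_samples(tab2), class = "myconet_config_error")
})

test_that("p-values and flags implement the two-tailed 2.5% rule", {
  set.seed(111)
  a <- random_binary_matrix(5, 6)
  net <- as_bipartite_network(a, "binary")

  # constant index: observed ties every null, both p-values are 1
  res <- null_test(net, function(n) 42, "quasiswap", n_null = 99, seed = 1)
  expect_equal(res$p_upper, 1)
  expect_equal(res$p_lower, 1)
  expect_false(res$significant_high)
  expect_false(res$significant_low)

  # stateful index: observed 100, nulls 2..1000 -> classic counting rule
  idx <- local({
    i <- 0
    function(n) {
      i <<- i + 1
      if (i == 1) 100000 else i
    }
  })
  res2 <- null_test(net, idx, "quasiswap", n_null = 999, seed = 1)
  expect_equal(res2$p_upper, 1 / 1000)
  expect_equal(res2$p_lower, 1)
  expect_true(res2$significant_high)
  expect_false(res2$significant_low)

  # boundary of the raw 2.5% rule: exactly 2.5% of nulls >= observed
  idx3 <- local({
    i <- 0
    function(n) {
      i <<- i + 1
      if (i == 1) 100 else if (i <= 11) 200 else 0  # 10 of 400 >= obs
    }
  })
  res3 <- null_test(net, idx3, "quasiswap", n_null = 400, seed = 1)
  expect_equal(sum(res3$null_values >= res3$observed), 10)
  expect_true(res3$significant_high)  # 10/400 = 2.5% passes "at most"
  expect_error(null_test(net, "nodf", "quasiswap", n_null = 0),
               class = "myconet_validation_error")
})

test_that("rebuilt networks under shuffle-sample preserve sample profiles", {
  tr <- make_scenario("modular", seed = 13)
  tab <- simulate_reads(tr, seed = 14)
  ft <- filter_guild(tab, guild_config("Glomeromycotina"))
  net <- build_network(ft, "binary")
  res <- null_test(net, "connectance", "shuffle_sample", n_null = 30,
                   seed = 4, table = ft,
                   build_args = list(net_type = "binary"))
  expect_identical(res$n_null, 30L)
  expect_true(all(is.finite(res$null_values)))
  # identity shuffle reproduces the observed network
  ids <- shuffle_samples(ft, seed = 1)
  o <- order(ids$sample_meta$plant_species)
  expect_identical(sort(unique(ids$sample_meta$plant_species)),
                   sort(unique(ft$sample_meta$plant_species)))
})

test_that("nestedness of a strongly nested weighted network is detected", {
  tr <- make_scenario("nested", seed = 17)
  tab <- simulate_reads(tr, seed = 18)
  net <- build_network(filter_guild(tab, guild_config("Glomeromycotina")),
                       "abundance")
  res <- null_test(net, "wnodf", "quasiswap", n_null = 199, seed = 2)
  expect_true(res$significant_high)
  expect_lt(res$p_upper, 0.025)
})
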