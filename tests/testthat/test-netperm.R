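test_that("graph construction collapses duplicates and drops self-loops", {
  edges <- data.frame(
    protein_a = c("A", "B", "A", "C"),
    protein_b = c("B", "A", "A", "D"),
    score = c(0.4, 0.9, 1.0, 0.7), stringsAsFactors = FALSE)
  g <- interactome_graph(edges)
  expect_equal(nrow(g$edges), 2L)                    # A-B collapsed, A-A gone
  ab <- g$edges[g$edges$protein_a == "A" & g$edges$protein_b == "B", ]
  expect_equal(ab$score, 0.9)                        # max score kept
  expect_error(interactome_graph(data.frame(protein_a = "A", protein_b = "B",
                                            score = 1.2)),
               "scores must lie")
})

test_that("seed-network definitions: first degree, internodes, connectivity", {
  # empty edge set
  g0 <- interactome_graph(data.frame(protein_a = character(0),
                                     protein_b = character(0),
                                     score = numeric(0)),
                          nodes = c("S1", "M1"))
  n0 <- build_seed_network(g0, "S1", "M1")
  expect_length(n0$connected_mendelian, 0)

  # direct seed-mendelian edge: first degree, no internode
  g1 <- interactome_graph(data.frame(protein_a = "S1", protein_b = "M1",
                                     score = 1))
  n1 <- build_seed_network(g1, "S1", "M1")
  expect_equal(n1$connected_mendelian, "M1")
  expect_length(n1$internodes, 0)

  # seed - X - mendelian path: connected via internode X
  g2 <- interactome_graph(data.frame(protein_a = c("S1", "X"),
                                     protein_b = c("X", "M1"), score = 1))
  n2 <- build_seed_network(g2, "S1", "M1")
  expect_equal(n2$connected_mendelian, "M1")
  expect_equal(n2$internodes, "X")

  # three hops is out of reach at the default depth
  g3 <- interactome_graph(data.frame(protein_a = c("S1", "X", "Y"),
                                     protein_b = c("X", "Y", "M1"), score = 1))
  expect_length(build_seed_network(g3, "S1", "M1")$connected_mendelian, 0)
  # and the 2-hop path vanishes at depth 1
  expect_length(build_seed_network(g2, "S1", "M1",
                                   max_hops = 1L)$connected_mendelian, 0)

  # duplicate paths to one mendelian protein count once
  g4 <- interactome_graph(data.frame(
    protein_a = c("S1", "X", "S1", "Y", "S1"),
    protein_b = c("X", "M1", "Y", "M1", "M1"), score = 1))
  expect_equal(count_mendelian_connections(
    build_seed_network(g4, "S1", "M1")), 1L)

  # edges below score_min are ignored
  g5 <- interactome_graph(data.frame(protein_a = "S1", protein_b = "M1",
                                     score = 0.3))
  expect_length(build_seed_network(g5, "S1", "M1",
                                   score_min = 0.5)$connected_mendelian, 0)

  expect_error(build_seed_network(g1, "S1", c("S1", "M1")), "overlap")
  expect_warning(build_seed_network(g1, c("S1", "GHOST"), "M1"), "absent")
})

test_that("connectivity counting is invariant to node relabeling", {
  set.seed(91)
  it <- simulate_interactome(60, 0.03, paste0("S", 1:5), paste0("M", 1:10),
                             n_bridges = 4, pool_size = 30, seed = 6)
  base <- count_mendelian_connections(
    build_seed_network(it$graph, paste0("S", 1:5), paste0("M", 1:10)))
  # relabel every node with a random permutation of new names
  nodes <- it$graph$nodes
  relabel <- setNames(paste0("N", sample(seq_along(nodes))), nodes)
  e2 <- data.frame(protein_a = relabel[it$graph$edges$protein_a],
                   protein_b = relabel[it$graph$edges$protein_b],
                   score = it$graph$edges$score, stringsAsFactors = FALSE)
  g2 <- interactome_graph(e2, nodes = unname(relabel))
  got <- count_mendelian_connections(
    build_seed_network(g2, unname(relabel[paste0("S", 1:5)]),
                       unname(relabel[paste0("M", 1:10)])))
  expect_equal(got, base)
})

test_that("the permutation fast path matches per-set network construction", {
  it <- simulate_interactome(80, 0.02, paste0("S", 1:6), paste0("M", 1:12),
                             n_bridges = 5, pool_size = 40, seed = 14)
  pr <- permutation_test(it$graph, paste0("S", 1:6), paste0("M", 1:12),
                         it$null_pool, B = 25, rng_seed = 3)
  # replay the same control draws through build_seed_network
  replay <- locusweave:::with_seed(3, {
    vapply(1:25, function(b) {
      ctrl <- it$null_pool[sample.int(length(it$null_pool), 6)]
      count_mendelian_connections(
        build_seed_network(it$graph, ctrl, paste0("M", 1:12)))
    }, 0L)
  })
  expect_identical(pr$null_counts, replay)
})

test_that("empirical p follows the add-one rule and its boundary cases", {
  seeds <- paste0("S", 1:9); mend <- paste0("M", 1:20)
  it <- simulate_interactome(200, 0.003, seeds, mend, n_bridges = 9,
                             pool_size = 118, seed = 8)
  pr <- permutation_test(it$graph, seeds, mend, it$null_pool,
                         B = 1000, rng_seed = 4)
  expect_equal(pr$observed_count, 9L)
  # planted bridges exceed every control network
  expect_true(all(pr$null_counts < 9))
  expect_equal(pr$p_emp, 1 / 1001)
  expect_lt(pr$p_emp, 1e-3)
  expect_gt(pr$p_emp, 0)

  # determinism
  pr2 <- permutation_test(it$graph, seeds, mend, it$null_pool,
                          B = 1000, rng_seed = 4)
  expect_identical(pr$null_counts, pr2$null_counts)

  # observed count 0: p = 1 (every null count >= 0)
  it0 <- simulate_interactome(50, 0, seeds, mend, n_bridges = 0,
                              pool_size = 30, seed = 9)
  pr0 <- suppressWarnings(
    permutation_test(it0$graph, seeds, mend, it0$null_pool, B = 100,
                     rng_seed = 5))
  expect_equal(pr0$p_emp, 1)

  # widening B tightens the smallest attainable p as 1/(B+1)
  prB <- permutation_test(it$graph, seeds, mend, it$null_pool,
                          B = 200, rng_seed = 4)
  expect_equal(prB$p_emp, 1 / 201)

  expect_error(permutation_test(it$graph, seeds, mend, it$null_pool[1:5]),
               "smaller than")
  expect_error(permutation_test(it$graph, c(seeds, "POOL001"), mend,
                                it$null_pool),
               "overlaps")
})

test_that("permutation results round-trip through the JSON writer", {
  it <- simulate_interactome(30, 0.02, paste0("S", 1:3), paste0("M", 1:5),
                             n_bridges = 2, pool_size = 20, seed = 10)
  pr <- permutation_test(it$graph, paste0("S", 1:3), paste0("M", 1:5),
                         it$null_pool, B = 50, rng_seed = 6)
  path <- tempfile(fileext = ".json")
  write_permutation_json(pr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$observed_count, pr$observed_count)
  expect_equal(back$p_emp, pr$p_emp)
  expect_equal(back$null_counts, pr$null_counts)
})
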