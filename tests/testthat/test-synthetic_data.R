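# Generators with planted ground truth.

test_that("gen_network plants cliques at p_in=1, p_out=0 and shares subunits", {
  sim <- gen_network(n_background = 10L, complex_sizes = c(4L, 5L),
                     p_in = 1, p_out = 0, seed = 2L)
  g <- as_igraph(sim$network)
  comp <- igraph::components(g)
  for (members in sim$truth$planted) {
    expect_equal(subgraph_density(sim$network, members), 1.0)
    expect_length(unique(comp$membership[members]), 1L)
  }
  # background nodes are isolated singletons here
  expect_equal(sum(comp$csize == 1), 10L)

  expect_error(gen_network(10, c(2, 5)), ">= 3")

  sim2 <- gen_network(n_background = 5L, complex_sizes = rep(4L, 4L),
                      p_in = 1, p_out = 0, n_shared = 2L, seed = 3L)
  shared <- table(unlist(sim2$truth$planted))
  expect_equal(sum(shared == 2L), 2L)
  expect_length(sim2$truth$shared_subunits, 2L)
})

test_that("generated intra-complex density is within 3 SE of p_in", {
  p_in <- 0.9
  sizes <- rep(6L, 10L)
  sim <- gen_network(n_background = 100L, complex_sizes = sizes,
                     p_in = p_in, p_out = 0.02, seed = 7L)
  n_pairs <- sum(choose(sizes, 2))
  observed <- sum(vapply(sim$truth$planted, function(m) {
    subgraph_density(sim$network, m) * choose(length(m), 2)
  }, numeric(1)))
  se <- sqrt(n_pairs * p_in * (1 - p_in))
  expect_lt(abs(observed - n_pairs * p_in), 3 * se)
})

test_that("gen_go drives the consistency index as configured", {
  sim <- gen_network(n_background = 20L, complex_sizes = rep(4L, 3L),
                     p_in = 1, p_out = 0, seed = 4L)
  go1 <- gen_go(sim$truth, f_consistent = 1, noise_terms_per_protein = 0,
                seed = 5L)
  norm <- normalize_to_depth(go1$annotations, go1$graph, 5)
  for (members in sim$truth$planted) {
    expect_equal(consistency_index(members, norm)$index, 1.0)
  }
  # dedicated terms are depth 5; deep attachment terms are depth 6
  d <- term_depths(go1$graph)
  expect_true(all(d[go1$truth$go_terms] == 5L))

  go0 <- gen_go(sim$truth, f_consistent = 0, noise_terms_per_protein = 0,
                seed = 5L)
  expect_true(all(lengths(go0$annotations) == 0L))
})

test_that("gen_expression controls coherence and tissue specificity", {
  sim <- gen_network(n_background = 10L, complex_sizes = rep(4L, 3L),
                     p_in = 1, p_out = 0, seed = 6L)
  ex <- gen_expression(sim$truth, coherence = 1, noise_sd = 0, seed = 7L,
                       tags_per_locus = 3L)
  prof <- collapse_tags(ex$expr)
  expect_equal(sum(ex$expr$locus_id == sim$truth$planted[[1]][1]), 3L)
  for (members in sim$truth$planted) {
    expect_equal(complex_coherence(members, prof)$avg_cosine, 1.0,
                 tolerance = 1e-9)
  }
  ts <- gen_expression(sim$truth, coherence = 1, tissue_specific = TRUE,
                       noise_sd = 0, seed = 8L)
  pr <- collapse_tags(ts$expr)
  ents <- apply(pr, 1, profile_entropy)
  expect_true(all(ents < log2(10)))
})

test_that("gen_homology separates core and peripheral family members", {
  sim <- gen_network(n_background = 0L, complex_sizes = c(5L),
                     p_in = 1, p_out = 0, seed = 9L)
  fam <- list(list(genes = sim$truth$planted[[1]],
                   core = sim$truth$planted[[1]][1:3]))
  ho <- gen_homology(sim$truth, family_assignments = fam, seed = 10L)
  s_strict <- paralog_summary(sim$truth$planted, ho$table, threshold = 1e-5)
  s_loose <- paralog_summary(sim$truth$planted, ho$table, threshold = 1e-3)
  expect_equal(s_strict$n_duplicated_genes, 3L)
  expect_equal(s_loose$n_duplicated_genes, 5L)

  ho0 <- gen_homology(sim$truth, family_assignments = list(), seed = 1L)
  expect_equal(nrow(ho0$table), 0L)

  # two families produce no cross-family pairs
  sim2 <- gen_network(n_background = 0L, complex_sizes = c(4L, 4L),
                      p_in = 1, p_out = 0, seed = 11L)
  ho2 <- gen_homology(sim2$truth, seed = 12L)
  f1 <- sim2$truth$planted[[1]]
  cross <- ho2$table$a %in% f1 != ho2$table$b %in% f1
  expect_false(any(cross))
})

test_that("gen_reference perturbations shape recall and precision", {
  sim <- gen_network(n_background = 20L, complex_sizes = rep(5L, 4L),
                     p_in = 1, p_out = 0, seed = 13L)
  ref0 <- gen_reference(sim$truth)
  m0 <- match_complexes(sim$truth$planted, ref0)
  self <- m0[m0$known_id == m0$predicted_id, ]
  expect_true(all(self$recall == 1 & self$precision == 1))

  # dropping one member per 5-mer: predicted original has precision 4/5
  ref1 <- gen_reference(sim$truth, n_drop = 1L, seed = 14L)
  m1 <- match_complexes(sim$truth$planted, ref1)
  self1 <- m1[m1$known_id == m1$predicted_id, ]
  expect_true(all(self1$overlap == 4L))
  expect_true(all(self1$precision == 4 / 5))
  expect_true(all(self1$recall == 1))   # reference shrank to 4 members

  # adding one foreign member: the planted prediction misses it
  ref2 <- gen_reference(sim$truth, n_add = 1L, seed = 15L)
  m2 <- match_complexes(sim$truth$planted, ref2)
  self2 <- m2[m2$known_id == m2$predicted_id, ]
  expect_true(all(self2$recall == 5 / 6))
  expect_true(all(self2$precision == 1))
})

test_that("truth files and preset outputs round-trip", {
  sim <- gen_network(n_background = 5L, complex_sizes = c(3L, 4L),
                     p_in = 1, p_out = 0, n_shared = 1L, seed = 16L)
  f <- tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_identical(back$planted, sim$truth$planted)
  expect_identical(back$all_nodes, sim$truth$all_nodes)

  dir <- tempfile()
  paths <- suppressWarnings(simulate_preset("clean", seed = 21L, out_dir = dir))
  expect_true(all(file.exists(paths)))
  net <- read_network(paths[["network"]])
  expect_gt(nrow(net$edges), 0L)
  ref <- read_reference(paths[["reference"]])
  expect_length(ref$complexes, 10L)
  g <- read_term_graph_tsv(paths[["term_graph"]])
  expect_true("GO:ROOT" %in% g$roots)
  ann <- read_annotations(paths[["annotations"]])
  expect_gt(length(ann), 0L)
  expr <- read_expression(paths[["expression"]])
  expect_equal(ncol(expr), 12L)
  tab <- read_homology(paths[["homology"]])
  expect_gt(nrow(tab), 0L)
})

test_that("power-law size sampler stays in range and is reproducible", {
  s <- sample_complex_sizes(500, exponent = 2, seed = 17L)
  expect_true(all(s >= 3L & s <= 25L))
  expect_gt(mean(s == 3L), mean(s == 10L))  # heavier head than tail
  expect_identical(s, sample_complex_sizes(500, exponent = 2, seed = 17L))
})
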