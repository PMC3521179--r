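# Ontology depth normalization, enrichment, consistency index and controls.

diamond_graph <- function() {
  # two paths to T: length 3 (via a1, a2) and length 5 (via b1..b4)
  term_graph(
    child = c("a1", "a2", "T", "b1", "b2", "b3", "b4", "T"),
    parent = c("root", "a1", "a2", "root", "b1", "b2", "b3", "b4"))
}

test_that("term_depths is shortest-path-from-root and rejects cycles", {
  g <- term_graph(child = c("t1", "t2"), parent = c("root", "t1"))
  d <- term_depths(g)
  expect_equal(unname(d["root"]), 0L)
  expect_equal(unname(d["t2"]), 2L)

  expect_equal(unname(term_depths(diamond_graph())["T"]), 3L)

  cyc <- term_graph(child = c("x", "y", "z"), parent = c("y", "z", "x"))
  expect_error(term_depths(cyc), "cycle")
})

test_that("normalize_to_depth drops shallow terms and lifts deep ones", {
  # chain root -> d1 -> ... -> d7, with a second depth-5 parent for d6
  chain <- paste0("d", 1:7)
  g <- term_graph(child = c(chain, "e5", "d6"),
                  parent = c("root", paste0("d", 1:6), "e4", "e5"))
  # give e4/e5 a path from root at depths 4/5
  g <- term_graph(child = c(chain, "d6", "e2", "e3", "e4", "e5", "e5"),
                  parent = c("root", paste0("d", 1:6), "e5", "root", "e2",
                             "e3", "e4", "d4"))
  d <- term_depths(g)
  expect_equal(unname(d["d5"]), 5L)
  expect_equal(unname(d["e5"]), 4L)

  ann <- list(p1 = "d5",          # depth 5: kept
              p2 = "d3",          # depth 3: dropped
              p3 = "d7")          # depth 7: lifted to all depth-5 ancestors
  norm <- normalize_to_depth(ann, g, 5)
  expect_equal(norm$p1, "d5")
  expect_equal(norm$p2, character(0))
  expect_setequal(norm$p3, c("d5", "d6"))  # both depth-5 ancestors of d7

  # a deep term with two depth-5 ancestors keeps both (oracle: manual
  # ancestor enumeration of this fixture)
  g2 <- term_graph(child = c(paste0("u", 1:5), paste0("v", 1:5), "X", "X"),
                   parent = c("root", paste0("u", 1:4), "root",
                              paste0("v", 1:4), "u5", "v5"))
  norm2 <- normalize_to_depth(list(p = "X"), g2, 5)
  expect_setequal(norm2$p, c("u5", "v5"))

  # idempotence
  expect_identical(normalize_to_depth(norm, g, 5), norm)

  # unknown terms dropped with a warning
  expect_warning(n3 <- normalize_to_depth(list(p = c("d5", "zz")), g, 5),
                 "unknown")
  expect_equal(n3$p, "d5")
})

test_that("enrichment p-value equals the hypergeometric upper tail", {
  # complex of 4, all carrying a term held by 10 of 1000 proteome proteins
  proteome <- sprintf("g%04d", 1:1000)
  ann <- stats::setNames(vector("list", 1000), proteome)
  for (i in 1:10) ann[[i]] <- "T1"
  members <- proteome[1:4]
  for (m in members) ann[[m]] <- union(ann[[m]], "T1")  # ensure all 4 carry T1
  res <- enrichment_test(members, ann, proteome)
  row <- res[res$term == "T1", ]
  # a = 4 of 4 subunits; background c counts proteins with T1
  K <- sum(vapply(ann, function(t) !is.null(t) && "T1" %in% t, logical(1)))
  expect_equal(row$a, 4L)
  expect_equal(row$c, K)
  expect_equal(row$p_value, oracle_hyper_tail(4, K, 1000, 4), tolerance = 1e-12)

  # a term held by the whole proteome is never enriched
  ann2 <- lapply(ann, function(t) union(t, "ALL"))
  res2 <- enrichment_test(members, ann2, proteome)
  expect_equal(res2$p_value[res2$term == "ALL"], 1.0)

  expect_error(enrichment_test(members, ann, character(0)), "empty proteome")
  # only terms hitting >= 1 subunit are tested
  expect_false("T2" %in% res$term)
})

test_that("consistency index counts term-sharing pairs", {
  ann <- list(p1 = "T", p2 = "T", p3 = "T")
  expect_equal(consistency_index(c("p1", "p2", "p3"), ann)$index, 1.0)

  ann2 <- list(p1 = c("T", "A"), p2 = "T", p3 = "B")
  ci <- consistency_index(c("p1", "p2", "p3"), ann2)
  expect_equal(ci$n_cons, 1L)
  expect_equal(ci$n_all, 3)
  expect_equal(ci$index, 1 / 3)

  expect_error(consistency_index("p1", ann), ">= 2")

  # random 6-member fixtures vs the pairwise oracle
  set.seed(9)
  for (rep in 1:10) {
    univ <- paste0("q", 1:12)
    ann3 <- stats::setNames(lapply(univ, function(p) {
      sample(paste0("T", 1:5), sample(0:3, 1))
    }), univ)
    mem <- sample(univ, 6)
    expect_equal(consistency_index(mem, ann3)$index,
                 oracle_consistency(mem, ann3))
  }

  # removing annotations never increases the index
  ann4 <- list(p1 = c("T", "A"), p2 = c("T", "A"), p3 = "A", p4 = "B")
  full <- consistency_index(paste0("p", 1:4), ann4)$index
  ann5 <- lapply(ann4, setdiff, "A")
  expect_lte(consistency_index(paste0("p", 1:4), ann5)$index, full)
})

test_that("random controls hit the degenerate extremes and are reproducible", {
  univ <- stats::setNames(lapply(1:20, function(i) paste0("T", i)), paste0("p", 1:20))
  r0 <- random_control_indexes(univ, c(3, 4), n_sets = 5, seed = 1)
  expect_true(all(unlist(r0) == 0))  # no shared terms anywhere

  univ1 <- stats::setNames(rep(list("T"), 20), paste0("p", 1:20))
  r1 <- random_control_indexes(univ1, c(3, 4), n_sets = 5, seed = 1)
  expect_true(all(unlist(r1) == 1))

  expect_identical(random_control_indexes(univ, c(3, 3), 3, seed = 42),
                   random_control_indexes(univ, c(3, 3), 3, seed = 42))
  expect_error(random_control_indexes(univ, 25, 2, seed = 1), "universe")
})

test_that("compare_distributions behaves at the extremes", {
  same <- c(0.2, 0.4, 0.6, 0.8)
  r <- compare_distributions(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- compare_distributions(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(r2$mean_a - r2$mean_b, -1)
  expect_lt(r2$p_value, 0.01)

  # agrees with stats::t.test (pooled) on non-degenerate data
  set.seed(4)
  a <- runif(30); b <- runif(25) + 0.2
  r3 <- compare_distributions(a, b, n_comparisons = 3)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r3$p_value, tt$p.value)
  expect_equal(r3$p_adjusted, min(1, tt$p.value * 3))
  expect_equal(sum(r3$hist_a), 30L)
})

test_that("simulated null pairs give roughly uniform t-test p-values", {
  set.seed(8)
  ps <- replicate(200, {
    compare_distributions(rnorm(15), rnorm(15))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("OBO is_a stanzas parse into the same graph as the TSV reader", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "",
    "[Term]", "id: GO:0000002", "name: child",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: grandchild",
    "is_a: GO:0000002 ! child",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), obo)
  g <- read_obo(obo)
  expect_setequal(g$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(g$roots, "GO:0000001")
  expect_setequal(g$parents[["GO:0000003"]], c("GO:0000001", "GO:0000002"))
  d <- term_depths(g)
  expect_equal(unname(d["GO:0000003"]), 1L)  # shortest path via direct is_a
})
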