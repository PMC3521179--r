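# PPI loading, merging, and cross-source overlap statistics.

write_edge_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("load_interactions removes self-loops, collapses duplicates, maps IDs", {
  f <- write_edge_file(c("A\tB", "B\tC", "A\tA"))
  r <- load_interactions(f, "X")
  expect_equal(nrow(r), 2L)
  expect_setequal(paste(r$protein_a, r$protein_b), c("A B", "B C"))
  expect_true(all(r$source == "X"))

  # unordered-pair identity
  f2 <- write_edge_file(c("A\tB", "B\tA"))
  expect_equal(nrow(load_interactions(f2, "X")), 1L)

  # ID mapping
  f3 <- write_edge_file("P1\tP2")
  r3 <- load_interactions(f3, "X", id_map = c(P1 = "H1", P2 = "H2"))
  expect_equal(r3$protein_a, "H1")
  expect_equal(r3$protein_b, "H2")

  # unmapped IDs dropped with a message
  f4 <- write_edge_file(c("P1\tP2", "P1\tP9"))
  expect_message(r4 <- load_interactions(f4, "X", id_map = c(P1 = "H1", P2 = "H2")),
                 "dropped 1")
  expect_equal(nrow(r4), 1L)
})

test_that("load_interactions errors and edge cases", {
  f <- write_edge_file(c("A\tB", "C"))
  expect_error(load_interactions(f, "X"), "line 2")
  f2 <- write_edge_file(character(0))
  expect_warning(r <- load_interactions(f2, "X"), "empty")
  expect_equal(nrow(r), 0L)
})

test_that("PSI-MI TAB columns 1-2 are used and prefixes stripped", {
  f <- write_edge_file(c("uniprotkb:P1\tuniprotkb:P2\tignored\tignored",
                         "uniprotkb:P2\tuniprotkb:P1\tother\tcols"))
  r <- load_interactions(f, "INTDB", psimi_tab = TRUE)
  expect_equal(nrow(r), 1L)
  expect_setequal(c(r$protein_a, r$protein_b), c("P1", "P2"))
})

test_that("merge_networks unions source tags and is idempotent", {
  recs <- data.frame(protein_a = c("A", "A", "B"), protein_b = c("B", "B", "C"),
                     source = c("X", "Y", "Y"), stringsAsFactors = FALSE)
  net <- merge_networks(recs)
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  i <- which(net$edges$a == "A" & net$edges$b == "B")
  expect_equal(net$sources[[i]], c("X", "Y"))

  # idempotence: re-merging the expanded records reproduces the network
  re <- do.call(rbind, lapply(seq_len(nrow(net$edges)), function(k) {
    data.frame(protein_a = net$edges$a[k], protein_b = net$edges$b[k],
               source = net$sources[[k]], stringsAsFactors = FALSE)
  }))
  expect_identical(merge_networks(re)$edges, net$edges)
  expect_identical(merge_networks(re)$sources, net$sources)

  # empty input
  empty <- merge_networks(recs[0, ])
  expect_equal(length(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("merged edge count equals brute-force set union over 6 sources", {
  set.seed(42)
  nodes <- sprintf("N%02d", 1:20)
  all_pairs <- utils::combn(nodes, 2L)
  shared_idx <- sample(ncol(all_pairs), 3L)       # 3 edges in every source
  per_source <- lapply(1:6, function(s) {
    unique(c(shared_idx, sample(ncol(all_pairs), 7L)))
  })
  recs <- do.call(rbind, lapply(1:6, function(s) {
    data.frame(protein_a = all_pairs[1L, per_source[[s]]],
               protein_b = all_pairs[2L, per_source[[s]]],
               source = paste0("S", s), stringsAsFactors = FALSE)
  }))
  net <- merge_networks(recs)
  expect_equal(nrow(net$edges), length(Reduce(union, per_source)))
})

test_that("overlap_matrix matches a set-intersection oracle and its invariants", {
  net <- make_net(c("A", "B"), c("B", "C"))
  net$sources <- list(c("X", "Y"), "Y")
  m <- overlap_matrix(net)
  expect_equal(m["X", "Y"], 1L)
  expect_equal(m["X", "X"], 1L)
  expect_equal(m["Y", "Y"], 2L)

  # random 5-source fixture vs brute-force intersections
  set.seed(7)
  nodes <- sprintf("P%02d", 1:15)
  recs <- do.call(rbind, lapply(1:5, function(s) {
    e <- random_edges(nodes, 0.2, seed = 100 + s)
    data.frame(protein_a = e$a, protein_b = e$b, source = paste0("S", s),
               stringsAsFactors = FALSE)
  }))
  net2 <- merge_networks(recs)
  m2 <- overlap_matrix(net2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_sets <- lapply(paste0("S", 1:5), function(s) {
    sub <- recs[recs$source == s, ]
    unique(key(sub$protein_a, sub$protein_b))
  })
  names(edge_sets) <- paste0("S", 1:5)
  for (i in paste0("S", 1:5)) for (j in paste0("S", 1:5)) {
    expect_equal(m2[i, j], length(intersect(edge_sets[[i]], edge_sets[[j]])),
                 info = paste(i, j))
  }
  expect_true(isSymmetric(m2))
  for (i in rownames(m2)) for (j in colnames(m2)) {
    expect_lte(m2[i, j], min(m2[i, i], m2[j, j]))
  }
})

test_that("shared_in_k_sources counts and conserves totals", {
  net <- make_net(c("A", "B"), c("B", "C"))
  net$sources <- list(c("X", "Y"), "Y")
  h <- shared_in_k_sources(net)
  expect_equal(unname(h), c(1L, 1L))

  empty <- make_net(character(0), character(0))
  expect_length(shared_in_k_sources(empty), 0L)

  # generated multiplicities recovered exactly; conservation invariants
  set.seed(11)
  n_edges <- 40L
  ks <- sample(1:4, n_edges, replace = TRUE)
  nodes <- sprintf("Q%02d", 1:40)
  pairs <- utils::combn(nodes, 2L)[, sample(choose(40, 2), n_edges)]
  net3 <- make_net(pairs[1L, ], pairs[2L, ])
  net3$sources <- lapply(ks, function(k) paste0("S", sort(sample(1:4, k))))
  # ensure all 4 tags appear so nbins is right
  net3$sources[[1L]] <- paste0("S", 1:4)
  h3 <- shared_in_k_sources(net3)
  kk <- vapply(net3$sources, length, integer(1))
  expect_equal(unname(h3), as.integer(tabulate(kk, 4)))
  expect_equal(sum(h3), nrow(net3$edges))
  expect_equal(sum(as.integer(names(h3)) * h3), sum(diag(overlap_matrix(net3))))
})

test_that("network TSV and GraphML round-trips preserve structure", {
  net <- make_net(c("A", "B", "C"), c("B", "C", "D"), source = "X",
                  isolated = "Z")
  f <- tempfile(fileext = ".tsv")
  write_network(net, f, header = "test")
  back <- read_network(f)
  expect_identical(back$edges, net$edges)
  expect_identical(back$sources, net$sources)
  expect_identical(back$nodes, net$nodes)

  g <- tempfile(fileext = ".graphml")
  write_network_graphml(net, g)
  ig <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gorder(ig), length(net$nodes))
  expect_equal(igraph::gsize(ig), nrow(net$edges))
})
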