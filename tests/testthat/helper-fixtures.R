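# Shared fixtures and independent oracles for the test suite.

# Build a ppi_network from parallel edge endpoint vectors.
make_net <- function(a, b, source = "X", isolated = character(0)) {
  if (length(a) == 0L) {
    recs <- data.frame(protein_a = character(0), protein_b = character(0),
                       source = character(0), stringsAsFactors = FALSE)
  } else {
    recs <- data.frame(protein_a = a, protein_b = b,
                       source = rep_len(source, length(a)),
                       stringsAsFactors = FALSE)
  }
  class(recs) <- c("ppi_records", "data.frame")
  merge_networks(recs, isolated = isolated)
}

# Clique edge list over the given node names.
clique_edges <- function(nodes) {
  p <- utils::combn(nodes, 2L)
  list(a = p[1L, ], b = p[2L, ])
}

# Erdos-Renyi edge list (independent oracle for generators is NOT this; it
# is only a fixture source).
random_edges <- function(nodes, p, seed) {
  set.seed(seed)
  pr <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pr)) < p
  list(a = pr[1L, keep], b = pr[2L, keep])
}

# --- independent oracles -----------------------------------------------------

# Brute-force induced-subgraph density from a raw edge table.
oracle_density <- function(edges_a, edges_b, members) {
  members <- unique(members)
  cnt <- sum((edges_a %in% members) & (edges_b %in% members))
  n <- length(members)
  2 * cnt / (n * (n - 1))
}

# Exhaustive enumeration of all maximal subsets (size >= min_size) with
# density >= d_in, for graphs with few nodes.
oracle_dense_subsets <- function(net, d_in, min_size = 3L) {
  nodes <- net$nodes
  n <- length(nodes)
  stopifnot(n <= 14L)
  dense <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < min_size) next
    mem <- nodes[idx]
    if (oracle_density(net$edges$a, net$edges$b, mem) >= d_in) {
      dense[[length(dense) + 1L]] <- mem
    }
  }
  # keep maximal sets only
  keep <- rep(TRUE, length(dense))
  for (i in seq_along(dense)) {
    for (j in seq_along(dense)) {
      if (i != j && all(dense[[i]] %in% dense[[j]])) { keep[i] <- FALSE; break }
    }
  }
  dense[keep]
}

# Hypergeometric upper tail by explicit binomial-coefficient summation.
oracle_hyper_tail <- function(a, K, N, n) {
  i <- a:min(K, n)
  if (length(i) == 0L || a > min(K, n)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Pairwise term-sharing scan.
oracle_consistency <- function(members, annotations) {
  members <- unique(members)
  n <- length(members)
  cons <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- annotations[[members[i]]]; b <- annotations[[members[j]]]
    if (!is.null(a) && !is.null(b) && length(intersect(a, b)) > 0L) cons <- cons + 1L
  }
  cons / (n * (n - 1L) / 2L)
}

# Benjamini-Hochberg step-up from first principles.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Mean pairwise cosine by direct pair enumeration.
oracle_avg_cosine <- function(mat) {
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- mat[i, ]; v <- mat[j, ]
    vals <- c(vals, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  mean(vals)
}

# Exhaustive within-complex paralog summary.
oracle_paralog_summary <- function(complexes, tab, threshold, strict = TRUE) {
  pass <- if (strict) tab$e_value < threshold else tab$e_value <= threshold
  tab <- tab[pass, , drop = FALSE]
  dup <- character(0)
  with_pair <- 0L; majority <- 0L
  for (members in complexes) {
    members <- unique(members)
    genes <- character(0); pairs <- 0L
    for (i in seq_along(members)) for (j in seq_along(members)) {
      if (i < j) {
        lo <- min(members[i], members[j]); hi <- max(members[i], members[j])
        hit <- any(tab$a == lo & tab$b == hi)
        if (hit) { pairs <- pairs + 1L; genes <- union(genes, c(lo, hi)) }
      }
    }
    dup <- union(dup, genes)
    if (pairs > 0L) with_pair <- with_pair + 1L
    if (length(genes) > length(members) / 2) majority <- majority + 1L
  }
  list(n_duplicated_genes = length(dup), n_complexes_with_pair = with_pair,
       n_complexes_majority_paralog = majority)
}
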