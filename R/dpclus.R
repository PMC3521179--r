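# Density/cluster-property graph clustering (DPClus-style), overlapping mode.
#
# The expansion rule is fully deterministic:
#   seed   = unclustered node of highest degree (ties: smallest ID, C locale);
#   start  = {seed, w} where w is the seed neighbour sharing the most common
#            neighbours (ties: higher degree, then smallest ID);
#   grow   = among nodes adjacent to the cluster, ordered by edges-into-cluster
#            desc, degree desc, ID asc, admit the first v with
#            cluster_property(v) >= cp_in AND density(cluster + v) >= d_in;
#   stop   = no candidate qualifies; emit if |cluster| >= min_size.

#' Clustering parameters
#'
#' @param d_in Minimum network density of an emitted cluster, in [0, 1].
#' @param cp_in Minimum cluster property a candidate must reach to be
#'   admitted during growth (>= 0; the grid search clamps it to [0, 1]).
#' @param min_size Minimum cluster size (default 3).
#' @param overlapping Allow a protein to appear in several clusters
#'   (default TRUE).  Non-overlapping mode removes emitted members from the
#'   graph instead.
#' @return A \code{cluster_params} list.
#' @export
cluster_params <- function(d_in = 0.6, cp_in = 0.5, min_size = 3L,
                           overlapping = TRUE) {
  stopifnot(is.numeric(d_in), length(d_in) == 1L, d_in >= 0, d_in <= 1,
            is.numeric(cp_in), length(cp_in) == 1L, cp_in >= 0,
            min_size >= 2L, is.logical(overlapping))
  structure(list(d_in = d_in, cp_in = cp_in, min_size = as.integer(min_size),
                 overlapping = overlapping),
            class = "cluster_params")
}

# Integer adjacency representation; node index order = C-locale sorted names,
# so index ties double as lexicographic ID ties.
build_adjacency <- function(net) {
  nodes <- sort(net$nodes, method = "radix")
  n <- length(nodes)
  ai <- match(net$edges$a, nodes)
  bi <- match(net$edges$b, nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (length(ai) > 0) {
    by_a <- split(bi, ai)
    by_b <- split(ai, bi)
    for (k in names(by_a)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], by_a[[k]])
    for (k in names(by_b)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], by_b[[k]])
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  list(nodes = nodes, adj = adj, deg = vapply(adj, length, integer(1)))
}

#' Network density of a node subset
#'
#' Density of the induced subgraph: \eqn{2E / (n (n - 1))} where E is the
#' number of edges among the \code{members}.
#'
#' @param net A \code{ppi_network}.
#' @param members Character vector of at least two node IDs.
#' @return Density in [0, 1].
#' @export
subgraph_density <- function(net, members) {
  members <- unique(members)
  if (length(members) < 2L) stop("density needs at least 2 members")
  if (!all(members %in% net$nodes)) stop("members must all be graph nodes")
  g <- build_adjacency(net)
  idx <- match(members, g$nodes)
  density_core(g$adj, idx)
}

density_core <- function(adj, idx) {
  inset <- idx
  e <- sum(vapply(idx, function(v) sum(adj[[v]] %in% inset), numeric(1))) / 2
  n <- length(idx)
  2 * e / (n * (n - 1))
}

#' Cluster property of a candidate node
#'
#' The admission statistic of the growth phase:
#' \eqn{E_c / (d \cdot n)} where \eqn{E_c} is the number of edges from the
#' candidate into the cluster, \eqn{d} the cluster density and \eqn{n} the
#' cluster size.  A dense candidate well connected to the periphery scores
#' high even across sparse regions.
#'
#' @param net A \code{ppi_network}.
#' @param members Current cluster member IDs.
#' @param candidate A node ID not in \code{members}.
#' @return Nonnegative real (can exceed 1).
#' @export
cluster_property <- function(net, members, candidate) {
  if (candidate %in% members) stop("candidate must not be a cluster member")
  d <- subgraph_density(net, members)
  if (d == 0) stop("cluster density is zero; cluster property undefined")
  g <- build_adjacency(net)
  idx <- match(members, g$nodes)
  ci <- match(candidate, g$nodes)
  e_c <- sum(g$adj[[ci]] %in% idx)
  e_c / (d * length(members))
}

# Core growth on the integer adjacency; blocked nodes are invisible.
# Returns integer member indices or NULL.
grow_core <- function(g, params, seed_i, blocked = logical(length(g$adj))) {
  adj <- g$adj
  if (blocked[seed_i]) return(NULL)
  nbrs <- adj[[seed_i]]
  nbrs <- nbrs[!blocked[nbrs]]
  if (length(nbrs) == 0L) return(NULL)
  # initial partner: most shared neighbours, then degree, then smallest index
  seed_nb <- adj[[seed_i]]
  shared <- vapply(nbrs, function(w) sum(adj[[w]] %in% seed_nb), integer(1))
  ord <- order(-shared, -g$deg[nbrs], nbrs)
  w <- nbrs[ord[1L]]
  members <- c(seed_i, w)
  in_cl <- logical(length(adj))
  in_cl[members] <- TRUE
  e_in <- 1L
  repeat {
    cand <- unique(unlist(adj[members], use.names = FALSE))
    cand <- cand[!in_cl[cand] & !blocked[cand]]
    if (length(cand) == 0L) break
    e_into <- vapply(cand, function(v) sum(in_cl[adj[[v]]]), integer(1))
    ord <- order(-e_into, -g$deg[cand], cand)
    n_m <- length(members)
    d <- 2 * e_in / (n_m * (n_m - 1))
    added <- FALSE
    for (j in ord) {
      v <- cand[j]
      cp <- e_into[j] / (d * n_m)
      d_new <- 2 * (e_in + e_into[j]) / ((n_m + 1) * n_m)
      if (cp >= params$cp_in && d_new >= params$d_in) {
        members <- c(members, v)
        in_cl[v] <- TRUE
        e_in <- e_in + e_into[j]
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  if (length(members) < params$min_size) return(NULL)
  n_m <- length(members)
  dens <- 2 * e_in / (n_m * (n_m - 1))
  stopifnot(dens >= params$d_in)  # emission contract
  list(members = sort(members), density = dens, seed = seed_i)
}

#' Grow a single cluster from a seed node
#'
#' @param net A \code{ppi_network}.
#' @param params A \code{\link{cluster_params}} object.
#' @param seed Seed node ID (must be a graph node).
#' @param blocked Node IDs excluded from the cluster (used by
#'   non-overlapping mode).
#' @return A list \code{(members, density, seed)} or \code{NULL} when the
#'   grown set has fewer than \code{min_size} members.
#' @export
grow_cluster <- function(net, params, seed, blocked = character(0)) {
  g <- build_adjacency(net)
  seed_i <- match(seed, g$nodes)
  if (is.na(seed_i)) stop("seed is not a graph node: ", seed)
  bl <- logical(length(g$adj))
  bl[match(blocked, g$nodes)] <- TRUE
  bl[seed_i] <- FALSE
  cl <- grow_core(g, params, seed_i, bl)
  if (is.null(cl)) return(NULL)
  list(members = g$nodes[cl$members], density = cl$density, seed = seed)
}

#' Predict protein complexes by density clustering
#'
#' Repeatedly seeds at the unclustered node of highest degree and grows a
#' cluster under the density / cluster-property admission rule.  In
#' overlapping mode, members of emitted clusters no longer seed new clusters
#' but remain available as expansion candidates, so a protein can be a
#' subunit of several predicted complexes.  Output is deterministic and
#' independent of input row order.
#'
#' @param net A \code{ppi_network}.
#' @param params A \code{\link{cluster_params}} object.
#' @return List of clusters, each \code{(members, density, seed)}, sorted by
#'   size (descending) then seed ID; duplicate member sets removed.
#' @export
cluster_graph <- function(net, params = cluster_params()) {
  g <- build_adjacency(net)
  n <- length(g$nodes)
  if (n == 0L) return(list())
  clustered <- logical(n)
  removed <- logical(n)   # only used in non-overlapping mode
  out <- list()
  seen <- character(0)
  repeat {
    avail <- which(!clustered & !removed)
    if (length(avail) == 0L) break
    if (params$overlapping) {
      eff_deg <- g$deg[avail]
    } else {
      eff_deg <- vapply(avail, function(v) sum(!removed[g$adj[[v]]]), integer(1))
    }
    seed_i <- avail[order(-eff_deg, avail)][1L]
    cl <- grow_core(g, params, seed_i, blocked = removed)
    if (is.null(cl)) {
      clustered[seed_i] <- TRUE
      next
    }
    clustered[cl$members] <- TRUE
    if (!params$overlapping) removed[cl$members] <- TRUE
    key <- paste(cl$members, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(members = g$nodes[cl$members],
                                      density = cl$density,
                                      seed = g$nodes[cl$seed])
    }
  }
  if (length(out) == 0L) return(out)
  sizes <- vapply(out, function(x) length(x$members), integer(1))
  seeds <- vapply(out, function(x) x$seed, character(1))
  out[order(-sizes, seeds, method = "radix")]
}
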