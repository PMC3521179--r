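# Ontology-based validation of complex sets: depth-5 term normalization,
# per-complex term enrichment (one-sided Fisher / hypergeometric upper tail),
# the GO consistency index, random controls and distribution comparison.

#' Build a term graph from child -> parent links
#'
#' @param child,parent Character vectors of equal length: each position is a
#'   \code{child is_a parent} link.
#' @param extra_terms Terms with no links (isolated roots).
#' @return A \code{term_graph}: \code{terms}, \code{parents} (named list),
#'   \code{children} (named list), \code{roots}.
#' @export
term_graph <- function(child, parent, extra_terms = character(0)) {
  stopifnot(length(child) == length(parent))
  terms <- sort(unique(c(child, parent, extra_terms)), method = "radix")
  parents <- lapply(stats::setNames(terms, terms), function(t) {
    sort(unique(parent[child == t]))
  })
  children <- lapply(stats::setNames(terms, terms), function(t) {
    sort(unique(child[parent == t]))
  })
  roots <- terms[vapply(parents, length, integer(1)) == 0L]
  structure(list(terms = terms, parents = parents, children = children,
                 roots = roots),
            class = "term_graph")
}

#' Read a term graph from a 2-column child TAB parent TSV
#' @param path File path.
#' @return A \code{term_graph}.
#' @export
read_term_graph_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  term_graph(vapply(parts, `[[`, character(1), 1L),
             vapply(parts, `[[`, character(1), 2L))
}

#' Read a minimal OBO file (id / is_a only)
#'
#' Parses \code{[Term]} stanzas, keeping \code{id:} and \code{is_a:} lines;
#' obsolete terms and all other relationship types are ignored.
#'
#' @param path Path to an OBO file.
#' @return A \code{term_graph}.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  child <- character(0); parent <- character(0); solo <- character(0)
  cur <- NULL; in_term <- FALSE; obsolete <- FALSE; had_parent <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete && !had_parent) solo <<- c(solo, cur)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; in_term <- TRUE
                          obsolete <- FALSE; had_parent <- FALSE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term) next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    if (grepl("^is_obsolete: *true", ln)) obsolete <- TRUE
    if (grepl("^is_a:", ln) && !is.null(cur)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      child <- c(child, cur); parent <- c(parent, p); had_parent <- TRUE
    }
  }
  flush()
  term_graph(child, parent, extra_terms = solo)
}

#' Term depths (shortest path from a root)
#'
#' Depth of a term is the length of the shortest is_a path to its namespace
#' root; roots have depth 0.  In a DAG with multiple paths the minimum is
#' taken (a declared choice; see the methods vignette).
#'
#' @param graph A \code{term_graph}.
#' @return Named integer vector over all terms.  Terms unreachable from any
#'   root (impossible in a well-formed acyclic graph) get \code{NA} with a
#'   warning; a cycle raises an error.
#' @export
term_depths <- function(graph) {
  check_acyclic(graph)
  depth <- stats::setNames(rep(NA_integer_, length(graph$terms)), graph$terms)
  frontier <- graph$roots
  depth[frontier] <- 0L
  d <- 0L
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(graph$children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depth[nxt])]
    d <- d + 1L
    depth[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(depth)) warning("terms unreachable from any root: ",
                            paste(names(depth)[is.na(depth)], collapse = ", "))
  depth
}

check_acyclic <- function(graph) {
  # Kahn peeling on child -> parent edges; leftovers imply a cycle.
  n_parents <- vapply(graph$parents, length, integer(1))
  remaining <- stats::setNames(n_parents, graph$terms)
  queue <- graph$terms[n_parents == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in graph$children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(graph$terms)) stop("term graph contains a cycle")
  invisible(TRUE)
}

ancestors_at_depth <- function(graph, depths, term, target) {
  # all ancestors of `term` with depth exactly `target` (upward BFS)
  seen <- character(0)
  frontier <- term
  hits <- character(0)
  while (length(frontier) > 0L) {
    up <- unique(unlist(graph$parents[frontier], use.names = FALSE))
    up <- setdiff(up, seen)
    seen <- c(seen, up)
    hits <- c(hits, up[!is.na(depths[up]) & depths[up] == target])
    frontier <- up
  }
  sort(unique(hits))
}

#' Normalize annotations to a fixed ontology depth
#'
#' Terms at exactly the target depth are kept; shallower terms are dropped
#' (too generic to witness functional consistency); deeper terms are replaced
#' by all of their ancestors at exactly the target depth.  Duplicates are
#' removed.  Annotation to a term absent from the graph is dropped with a
#' warning.
#'
#' @param annotations Named list: protein ID -> character vector of term IDs.
#' @param graph A \code{term_graph}.
#' @param target_depth Normalization depth (default 5).
#' @return Named list of depth-normalized term sets (proteins whose set
#'   becomes empty are kept with \code{character(0)}).
#' @export
normalize_to_depth <- function(annotations, graph, target_depth = 5L) {
  depths <- term_depths(graph)
  cache <- new.env(parent = emptyenv())
  unknown <- character(0)
  norm_term <- function(t) {
    if (!is.null(cache[[t]])) return(cache[[t]])
    res <- if (!(t %in% graph$terms) || is.na(depths[t])) {
      unknown <<- c(unknown, t)
      character(0)
    } else if (depths[t] < target_depth) {
      character(0)
    } else if (depths[t] == target_depth) {
      t
    } else {
      ancestors_at_depth(graph, depths, t, target_depth)
    }
    cache[[t]] <- res
    res
  }
  out <- lapply(annotations, function(terms) {
    res <- unlist(lapply(unique(terms), norm_term), use.names = FALSE)
    if (is.null(res)) character(0) else sort(unique(res))
  })
  if (length(unknown) > 0L) {
    warning("dropped annotations to unknown terms: ",
            paste(sort(unique(unknown)), collapse = ", "))
  }
  out
}

#' Per-complex term enrichment (one-sided Fisher exact test)
#'
#' For each term annotated to at least one subunit, tests enrichment of the
#' term among the complex's annotatable subunits against the proteome
#' background with a one-sided Fisher exact test on the 2x2 table
#' (a = subunits with the term, b = subunits without, c/d = proteome
#' counterparts); the p-value equals the hypergeometric upper tail.
#'
#' @param members Character vector of complex member IDs.
#' @param annotations Named list protein -> normalized term set (covering at
#'   least the proteome).
#' @param proteome Character vector: the background protein universe
#'   (includes the complex members; proteins without annotations count as
#'   term-free).
#' @return data.frame: \code{term}, \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{p_value}, sorted by p then term.
#' @export
enrichment_test <- function(members, annotations, proteome) {
  if (length(proteome) == 0L) stop("empty proteome background")
  members <- unique(members)
  ann_of <- function(p) {
    t <- annotations[[p]]
    if (is.null(t)) character(0) else t
  }
  member_terms <- lapply(members, ann_of)
  annotatable <- members[vapply(member_terms, length, integer(1)) > 0L]
  n_complex <- length(annotatable)
  if (n_complex == 0L) {
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  terms <- sort(unique(unlist(member_terms, use.names = FALSE)))
  n_prot <- length(unique(proteome))
  prot_terms <- unlist(lapply(unique(proteome), ann_of), use.names = FALSE)
  prot_count <- table(prot_terms)
  rows <- lapply(terms, function(t) {
    a <- sum(vapply(annotatable, function(p) t %in% ann_of(p), logical(1)))
    b <- n_complex - a
    cc <- as.integer(prot_count[t])
    if (is.na(cc)) cc <- 0L
    d <- n_prot - cc
    # upper tail P(X >= a) drawing (a+b) from cc successes among n_prot
    p <- stats::phyper(a - 1L, cc, d, a + b, lower.tail = FALSE)
    data.frame(term = t, a = a, b = b, c = cc, d = d, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$term, method = "radix"), , drop = FALSE]
}

#' GO consistency index of a complex
#'
#' The fraction of unordered subunit pairs sharing at least one
#' (depth-normalized) term: \code{index = n_cons / n_all} with
#' \code{n_all = n(n-1)/2}.
#'
#' @param members Character vector (>= 2) of member IDs.
#' @param annotations Named list protein -> normalized term set.
#' @return List \code{(n_cons, n_all, index)}.
#' @export
consistency_index <- function(members, annotations) {
  members <- unique(members)
  n <- length(members)
  if (n < 2L) stop("consistency index needs >= 2 members")
  sets <- lapply(members, function(p) {
    t <- annotations[[p]]
    if (is.null(t)) character(0) else t
  })
  n_cons <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (any(sets[[i]] %in% sets[[j]])) n_cons <- n_cons + 1L
    }
  }
  n_all <- n * (n - 1L) / 2L
  list(n_cons = n_cons, n_all = n_all, index = n_cons / n_all)
}

#' Consistency indexes of size-matched random control sets
#'
#' Draws \code{n_sets} control collections; each mirrors the complex-size
#' profile of the annotated set by sampling genes uniformly without
#' replacement from the annotated universe.
#'
#' @param annotations Named list protein -> term set: the universe.
#' @param complex_sizes Integer vector of complex sizes (each >= 2).
#' @param n_sets Number of control collections (default 100).
#' @param seed RNG seed.
#' @return List of length \code{n_sets}; each element a numeric vector of
#'   consistency indexes, one per size.
#' @export
random_control_indexes <- function(annotations, complex_sizes, n_sets = 100L,
                                   seed = 1L) {
  stopifnot(all(complex_sizes >= 2L))
  universe <- names(annotations)
  if (max(complex_sizes) > length(universe)) {
    stop("complex size exceeds annotated universe")
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    vapply(complex_sizes, function(k) {
      members <- sample(universe, k)
      consistency_index(members, annotations)$index
    }, numeric(1))
  })
}

#' Compare two consistency-index distributions
#'
#' Two-sample Student t test (pooled variance) on the index lists, with
#' optional Bonferroni adjustment over a family of comparisons, plus fixed
#' [0,1] histogram bins for plotting.  Degenerate zero-variance inputs are
#' handled deterministically: equal constants give statistic 0 / p 1,
#' separated constants give p 0.
#'
#' @param set_a,set_b Numeric vectors (n >= 2 each).
#' @param n_comparisons Bonferroni family size (default 1 = no adjustment).
#' @param bins Histogram break points (default \code{seq(0, 1, 0.1)}).
#' @return List \code{(statistic, df, p_value, p_adjusted, mean_a, mean_b,
#'   hist_a, hist_b)}.
#' @export
compare_distributions <- function(set_a, set_b, n_comparisons = 1L,
                                  bins = seq(0, 1, by = 0.1)) {
  stopifnot(length(set_a) >= 2L, length(set_b) >= 2L)
  n1 <- length(set_a); n2 <- length(set_b)
  m1 <- mean(set_a); m2 <- mean(set_b)
  sp2 <- ((n1 - 1) * stats::var(set_a) + (n2 - 1) * stats::var(set_b)) /
    (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(stat), df)
  }
  hist_of <- function(x) {
    h <- graphics::hist(pmin(pmax(x, min(bins)), max(bins)),
                        breaks = bins, plot = FALSE)
    stats::setNames(h$counts, paste0("[", utils::head(bins, -1L), ",",
                                     bins[-1L], ")"))
  }
  list(statistic = stat, df = df, p_value = p,
       p_adjusted = min(1, p * n_comparisons),
       mean_a = m1, mean_b = m2,
       hist_a = hist_of(set_a), hist_b = hist_of(set_b))
}

#' Fraction of complexes with at least one enriched term
#'
#' @param complexes List of member-ID vectors.
#' @param annotations Normalized annotation list.
#' @param proteome Background universe.
#' @param p_threshold Enrichment cut-off (default 0.01, unadjusted).
#' @return List \code{(n_enriched, n_total, fraction)}.
#' @export
enriched_complex_fraction <- function(complexes, annotations, proteome,
                                      p_threshold = 0.01) {
  complexes <- normalize_predicted(complexes)
  hit <- vapply(complexes, function(members) {
    e <- enrichment_test(members, annotations, proteome)
    nrow(e) > 0L && min(e$p_value) <= p_threshold
  }, logical(1))
  list(n_enriched = sum(hit), n_total = length(complexes),
       fraction = if (length(hit) > 0) mean(hit) else NA_real_)
}
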