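# Synthetic-data generators with planted ground truth: networks with planted
# complexes, matched ontology annotations, expression profiles, homology
# tables and reference sets.  Every generator is reproducible under a seed.

#' Generate a PPI network with planted complexes
#'
#' Planted complexes receive intra-member edges with probability \code{p_in};
#' every other node pair (background-background, background-complex and
#' cross-complex) is an Erdos-Renyi edge with probability \code{p_out}.
#' Optionally \code{n_shared} proteins belong to two planted complexes, and
#' complex sizes can be drawn from a truncated power law with
#' \code{\link{sample_complex_sizes}}.
#'
#' @param n_background Number of background proteins.
#' @param complex_sizes Integer vector of planted complex sizes (each >= 3).
#' @param p_in Within-complex edge probability.
#' @param p_out Background edge probability (\code{p_out < p_in}).
#' @param n_shared Number of proteins shared between consecutive complex
#'   pairs (complex 2i inherits one member from complex 2i-1).
#' @param seed RNG seed.
#' @return List \code{(network, truth)}: a \code{ppi_network} (source tag
#'   \code{"SIM"}) and a \code{synthetic_truth} object.
#' @export
gen_network <- function(n_background = 100L, complex_sizes = rep(6L, 10L),
                        p_in = 0.9, p_out = 0.02, n_shared = 0L, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  if (any(complex_sizes < 3L)) stop("planted complex sizes must be >= 3")
  if (n_shared > 0L && length(complex_sizes) < 2L * n_shared) {
    stop("n_shared requires at least 2 * n_shared planted complexes")
  }
  set.seed(seed)
  planted <- list()
  for (i in seq_along(complex_sizes)) {
    planted[[paste0("K", i)]] <-
      sprintf("K%d_%02d", i, seq_len(complex_sizes[i]))
  }
  shared_subunits <- list()
  if (n_shared > 0L) {
    for (s in seq_len(n_shared)) {
      i <- 2L * s - 1L; j <- 2L * s
      donor <- planted[[i]][1L]
      planted[[j]][1L] <- donor
      shared_subunits[[s]] <- c(names(planted)[i], names(planted)[j], donor)
    }
  }
  background <- sprintf("B%03d", seq_len(n_background))
  nodes <- sort(unique(c(unlist(planted, use.names = FALSE), background)))
  intra <- unique(do.call(rbind, lapply(planted, function(m) {
    if (length(m) < 2L) return(NULL)
    t(utils::combn(sort(m), 2L))
  })))
  all_pairs <- t(utils::combn(nodes, 2L))
  intra_key <- paste(intra[, 1L], intra[, 2L], sep = "\r")
  pair_key <- paste(all_pairs[, 1L], all_pairs[, 2L], sep = "\r")
  is_intra <- pair_key %in% intra_key
  keep_in <- is_intra & stats::runif(length(pair_key)) < p_in
  keep_out <- !is_intra & stats::runif(length(pair_key)) < p_out
  keep <- keep_in | keep_out
  recs <- data.frame(protein_a = all_pairs[keep, 1L],
                     protein_b = all_pairs[keep, 2L],
                     source = "SIM", stringsAsFactors = FALSE)
  class(recs) <- c("ppi_records", "data.frame")
  truth <- structure(list(planted = planted,
                          shared_subunits = shared_subunits,
                          all_nodes = nodes, background = background,
                          go_terms = NULL, latent_profiles = NULL,
                          paralog_families = NULL),
                     class = "synthetic_truth")
  list(network = merge_networks(recs, isolated = nodes), truth = truth)
}

#' Sample complex sizes from a truncated inverse power law
#'
#' Complex-size distributions in curated resources follow an inverse power
#' law; sizes are drawn with \code{P(s) proportional to s^-exponent} on the
#' range [min_size, max_size].
#'
#' @param n Number of sizes.
#' @param exponent Power-law exponent (default 2).
#' @param min_size,max_size Truncation range (defaults 3 and 25).
#' @param seed RNG seed.
#' @return Integer vector of length \code{n}.
#' @export
sample_complex_sizes <- function(n, exponent = 2, min_size = 3L,
                                 max_size = 25L, seed = 1L) {
  set.seed(seed)
  sizes <- seq.int(min_size, max_size)
  probs <- sizes^(-exponent)
  sample(sizes, n, replace = TRUE, prob = probs / sum(probs))
}

#' Generate a term graph and annotations matched to planted complexes
#'
#' Builds a rooted term tree (a spine to depth \code{target_depth - 1} whose
#' leaves sit at the target depth) and annotates a fraction
#' \code{f_consistent} of each planted complex's members with a dedicated
#' target-depth term.  Half of those consistent annotations are attached via
#' a depth \code{target_depth + 1} child term to exercise depth
#' normalization.  Every node additionally receives random noise terms.
#'
#' @param truth A \code{synthetic_truth} from \code{\link{gen_network}}.
#' @param n_noise_terms Number of extra target-depth noise terms.
#' @param target_depth Depth of the informative terms (default 5).
#' @param f_consistent Fraction of each planted complex annotated with its
#'   dedicated term.
#' @param noise_terms_per_protein Random noise terms per protein (default 1).
#' @param seed RNG seed.
#' @return List \code{(graph, annotations, truth)}; \code{truth$go_terms}
#'   records each complex's dedicated term.
#' @export
gen_go <- function(truth, n_noise_terms = 20L, target_depth = 5L,
                   f_consistent = 0.9, noise_terms_per_protein = 1L,
                   seed = 1L) {
  stopifnot(f_consistent >= 0, f_consistent <= 1, target_depth >= 1L)
  set.seed(seed)
  spine <- c("GO:ROOT", sprintf("GO:SPINE%d", seq_len(target_depth - 1L)))
  child <- spine[-1L]
  parent <- spine[-length(spine)]
  dedicated <- sprintf("GO:CPLX%03d", seq_along(truth$planted))
  noise_terms <- sprintf("GO:NOISE%03d", seq_len(n_noise_terms))
  deep <- sprintf("GO:DEEP%03d", seq_along(truth$planted))
  leaf_parent <- spine[length(spine)]
  child <- c(child, dedicated, noise_terms, deep)
  parent <- c(parent, rep(leaf_parent, length(dedicated) + length(noise_terms)),
              dedicated)
  graph <- term_graph(child, parent)
  ann <- stats::setNames(vector("list", length(truth$all_nodes)),
                         truth$all_nodes)
  for (i in seq_along(truth$planted)) {
    members <- truth$planted[[i]]
    n_cons <- round(f_consistent * length(members))
    if (n_cons > 0L) {
      chosen <- sample(members, n_cons)
      for (m in chosen) {
        use_deep <- stats::runif(1) < 0.5
        t <- if (use_deep) deep[i] else dedicated[i]
        ann[[m]] <- c(ann[[m]], t)
      }
    }
  }
  if (noise_terms_per_protein > 0L && n_noise_terms > 0L) {
    for (p in truth$all_nodes) {
      ann[[p]] <- c(ann[[p]], sample(noise_terms, noise_terms_per_protein))
    }
  }
  ann <- lapply(ann, function(x) sort(unique(x)))
  truth$go_terms <- stats::setNames(dedicated, names(truth$planted))
  list(graph = graph, annotations = ann, truth = truth)
}

#' Generate an expression matrix matched to planted complexes
#'
#' Each planted complex draws a latent tissue profile (concentrated on one
#' tissue when \code{tissue_specific}); each member's profile is the convex
#' mixture \code{coherence * latent + (1 - coherence) * independent draw}
#' plus Gaussian noise (truncated at 0).  Background proteins get
#' independent profiles.  Each locus is emitted as \code{tags_per_locus}
#' tag rows with small tag-level noise, so tag collapsing is exercised.
#'
#' @param truth A \code{synthetic_truth}.
#' @param n_tissues Number of tissue categories (default 10).
#' @param coherence Mixing weight in [0, 1].
#' @param tissue_specific Concentrate latent profiles on a single tissue.
#' @param noise_sd Gaussian noise SD (default 0.05).
#' @param tags_per_locus Tag rows per locus (default 1).
#' @param seed RNG seed.
#' @return List \code{(expr, truth)}: a tag-level data.frame in the
#'   \code{\link{read_expression}} layout (locus_id = protein ID) and the
#'   truth with \code{latent_profiles} recorded.
#' @export
gen_expression <- function(truth, n_tissues = 10L, coherence = 0.8,
                           tissue_specific = FALSE, noise_sd = 0.05,
                           tags_per_locus = 1L, seed = 1L) {
  stopifnot(coherence >= 0, coherence <= 1)
  set.seed(seed)
  draw_profile <- function() {
    if (tissue_specific) {
      v <- rep(0.2 / (n_tissues - 1L), n_tissues)
      v[sample.int(n_tissues, 1L)] <- 0.8
      v
    } else {
      g <- stats::rgamma(n_tissues, shape = 1)
      g / sum(g)
    }
  }
  latents <- lapply(truth$planted, function(m) draw_profile())
  prof <- list()
  for (i in seq_along(truth$planted)) {
    for (m in truth$planted[[i]]) {
      if (!is.null(prof[[m]])) next  # shared subunit: first complex wins
      indep <- draw_profile()
      v <- coherence * latents[[i]] + (1 - coherence) * indep
      v <- pmax(v + stats::rnorm(n_tissues, 0, noise_sd), 0)
      if (sum(v) == 0) v <- latents[[i]]
      prof[[m]] <- v
    }
  }
  for (b in truth$background) prof[[b]] <- draw_profile()
  loci <- names(prof)
  tag_ids <- character(0); locus_ids <- character(0); vals <- list()
  for (l in loci) {
    for (t in seq_len(tags_per_locus)) {
      v <- pmax(prof[[l]] + stats::rnorm(n_tissues, 0, noise_sd / 2), 0)
      if (sum(v) == 0) v <- prof[[l]]
      tag_ids <- c(tag_ids, sprintf("%s_tag%d", l, t))
      locus_ids <- c(locus_ids, l)
      vals[[length(vals) + 1L]] <- v
    }
  }
  expr <- data.frame(tag_id = tag_ids, locus_id = locus_ids,
                     do.call(rbind, vals), stringsAsFactors = FALSE)
  names(expr) <- c("tag_id", "locus_id", paste0("T", seq_len(n_tissues)))
  truth$latent_profiles <- latents
  list(expr = expr, truth = truth)
}

#' Generate a homology table with planted paralog families
#'
#' Families default to one per planted complex with roughly half the members
#' designated "core".  Core-core pairs receive E-values below
#' \code{e_value_strong}; pairs involving a peripheral member receive
#' E-values between \code{e_value_strong} and \code{e_value_weak}, so a
#' strict threshold at \code{e_value_strong} detects only the core family
#' while a looser one at \code{e_value_weak} detects all of it.
#'
#' @param truth A \code{synthetic_truth}.
#' @param family_assignments Optional list of \code{list(genes, core)}
#'   specifying families explicitly; default derives one family per planted
#'   complex (\code{ceiling(size / 2)} core members).
#' @param e_value_strong Strong-similarity threshold (default 1e-5).
#' @param e_value_weak Weak-similarity threshold (default 1e-3).
#' @param seed RNG seed.
#' @return List \code{(table, truth)}: a \code{\link{homology_table}} and
#'   the truth with \code{paralog_families} recorded.
#' @export
gen_homology <- function(truth, family_assignments = NULL,
                         e_value_strong = 1e-5, e_value_weak = 1e-3,
                         seed = 1L) {
  stopifnot(e_value_strong < e_value_weak)
  set.seed(seed)
  if (is.null(family_assignments)) {
    family_assignments <- lapply(truth$planted, function(m) {
      list(genes = m, core = m[seq_len(ceiling(length(m) / 2))])
    })
  }
  a <- character(0); b <- character(0); ev <- numeric(0)
  loguni <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  for (fam in family_assignments) {
    genes <- sort(unique(fam$genes))
    if (length(genes) < 2L) next
    pairs <- utils::combn(genes, 2L)
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      core_pair <- g1 %in% fam$core && g2 %in% fam$core
      e <- if (core_pair) loguni(e_value_strong * 1e-10, e_value_strong * 0.99)
           else loguni(e_value_strong * 1.01, e_value_weak * 0.99)
      a <- c(a, g1); b <- c(b, g2); ev <- c(ev, e)
    }
  }
  truth$paralog_families <- family_assignments
  list(table = homology_table(a, b, ev), truth = truth)
}

#' Generate a reference set from planted truth
#'
#' Optionally perturbs each planted complex by dropping members and/or
#' adding foreign background proteins, to exercise recall/precision below 1.
#'
#' @param truth A \code{synthetic_truth}.
#' @param n_drop Members dropped per complex (never below 2 remaining).
#' @param n_add Foreign background proteins added per complex.
#' @param seed RNG seed.
#' @return A \code{\link{reference_set}}.
#' @export
gen_reference <- function(truth, n_drop = 0L, n_add = 0L, seed = 1L) {
  set.seed(seed)
  complexes <- lapply(truth$planted, function(m) {
    keep <- m
    if (n_drop > 0L && length(keep) - n_drop >= 2L) {
      keep <- sample(keep, length(keep) - n_drop)
    }
    if (n_add > 0L) {
      pool <- setdiff(truth$background, keep)
      keep <- c(keep, sample(pool, min(n_add, length(pool))))
    }
    keep
  })
  reference_set(complexes)
}

#' Write / read a synthetic truth object (JSON round-trip)
#' @param truth A \code{synthetic_truth}.
#' @param path JSON file path.
#' @return \code{write_truth}: \code{path}, invisibly; \code{read_truth}: a
#'   \code{synthetic_truth}.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$planted <- lapply(raw$planted, as.character)
  raw$shared_subunits <- lapply(raw$shared_subunits, as.character)
  structure(raw, class = "synthetic_truth")
}

#' Write all simulator outputs for a preset scenario
#'
#' Presets: \code{"clean"} (strong planted signal), \code{"noisy"}
#' (weaker signal), \code{"null"} (no coherent structure beyond the planted
#' topology).  Writes the network TSV, reference TSV, term-graph TSV,
#' annotation TSV, expression TSV, homology TSV and truth JSON into
#' \code{out_dir}, in the formats the corresponding readers consume.
#'
#' @param preset One of \code{"clean"}, \code{"noisy"}, \code{"null"}.
#' @param seed RNG seed.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
simulate_preset <- function(preset = c("clean", "noisy", "null"), seed = 1L,
                            out_dir = ".") {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    clean = list(p_in = 0.9, p_out = 0.02, f_cons = 0.9, coh = 0.8),
    noisy = list(p_in = 0.7, p_out = 0.05, f_cons = 0.5, coh = 0.4),
    null  = list(p_in = 0.9, p_out = 0.02, f_cons = 0.0, coh = 0.0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- gen_network(n_background = 100L, complex_sizes = rep(6L, 10L),
                     p_in = cfg$p_in, p_out = cfg$p_out, seed = seed)
  go <- gen_go(net$truth, f_consistent = cfg$f_cons, seed = seed + 1L)
  ex <- gen_expression(go$truth, coherence = cfg$coh, seed = seed + 2L)
  ho <- gen_homology(ex$truth, seed = seed + 3L)
  ref <- gen_reference(ho$truth, seed = seed + 4L)
  truth <- ho$truth
  paths <- c(
    network = file.path(out_dir, "network.tsv"),
    reference = file.path(out_dir, "reference.tsv"),
    term_graph = file.path(out_dir, "term_graph.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    homology = file.path(out_dir, "homology.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_network(net$network, paths[["network"]],
                header = sprintf("simulate preset=%s seed=%d", preset, seed))
  write_reference(ref, paths[["reference"]])
  eg <- term_graph_edges(go$graph)
  writeLines(paste(eg$child, eg$parent, sep = "\t"), paths[["term_graph"]])
  ann_rows <- unlist(lapply(names(go$annotations), function(p) {
    if (length(go$annotations[[p]]) == 0L) return(character(0))
    paste(p, go$annotations[[p]], sep = "\t")
  }), use.names = FALSE)
  writeLines(ann_rows, paths[["annotations"]])
  utils::write.table(ex$expr, paths[["expression"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(paste(ho$table$a, ho$table$b,
                   format(ho$table$e_value, scientific = TRUE), sep = "\t"),
             paths[["homology"]])
  write_truth(truth, paths[["truth"]])
  invisible(paths)
}

term_graph_edges <- function(graph) {
  child <- character(0); parent <- character(0)
  for (t in graph$terms) {
    for (p in graph$parents[[t]]) {
      child <- c(child, t); parent <- c(parent, p)
    }
  }
  list(child = child, parent = parent)
}

#' Read a protein TAB term annotation TSV
#' @param path File path.
#' @return Named list protein -> character vector of terms.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  prot <- vapply(parts, `[[`, character(1), 1L)
  term <- vapply(parts, `[[`, character(1), 2L)
  lapply(split(term, prot), function(x) sort(unique(x)))
}
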