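# Expression-coherence validation: average pairwise cosine over 10 tissue
# categories, a Monte-Carlo size-matched null, BH FDR, tissue-specificity
# entropy and the size-vs-similarity trend.

#' Read an expression matrix (tag_id, locus_id, 10 tissue values)
#'
#' @param path TSV path; a header line is detected when the value columns of
#'   the first line are non-numeric.
#' @param n_tissues Number of tissue-category columns (default 10).
#' @return data.frame with columns \code{tag_id}, \code{locus_id} and
#'   \code{T1..Tn}.
#' @export
read_expression <- function(path, n_tissues = 10L) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             colClasses = "character", comment.char = "#")
  has_header <- any(is.na(suppressWarnings(as.numeric(first[1L, -(1:2)]))))
  df <- utils::read.delim(path, header = has_header, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != n_tissues + 2L) {
    stop(sprintf("expected %d columns (tag, locus, %d tissues), found %d",
                 n_tissues + 2L, n_tissues, ncol(df)))
  }
  names(df) <- c("tag_id", "locus_id", paste0("T", seq_len(n_tissues)))
  for (j in 3:ncol(df)) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Collapse iAFLP tags to per-locus expression profiles
#'
#' Multiple tags mapping to one locus are averaged element-wise; loci whose
#' averaged profile is all-zero are dropped with a warning.
#'
#' @param expr data.frame from \code{\link{read_expression}} (or with the
#'   same columns).
#' @return Numeric matrix, one row per locus (rownames = locus IDs), one
#'   column per tissue category.
#' @export
collapse_tags <- function(expr) {
  vals <- as.matrix(expr[, -(1:2), drop = FALSE])
  loci <- as.character(expr$locus_id)
  prof <- rowsum(vals, loci) / as.vector(table(loci)[sort(unique(loci))])
  zero <- rowSums(prof) == 0
  if (any(zero)) {
    warning("dropped all-zero loci: ", paste(rownames(prof)[zero], collapse = ", "))
    prof <- prof[!zero, , drop = FALSE]
  }
  prof
}

#' Cosine similarity of two expression profiles
#'
#' @param u,v Nonnegative, non-zero numeric vectors of equal length.
#' @return \code{dot(u, v) / (|u| |v|)}; in [0, 1] for nonnegative input.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Average pairwise cosine of a complex's subunits
#'
#' @param members Character vector of protein IDs.
#' @param profiles Numeric matrix of locus profiles (rownames = locus IDs).
#' @param protein_to_locus Optional named character vector mapping protein
#'   IDs to locus IDs (identity by default).
#' @return List \code{(avg_cosine, k)} with \code{k} the number of members
#'   that have profiles, or \code{NULL} when fewer than two do.
#' @export
complex_coherence <- function(members, profiles, protein_to_locus = NULL) {
  loci <- map_to_loci(members, protein_to_locus)
  loci <- unique(loci[loci %in% rownames(profiles)])
  k <- length(loci)
  if (k < 2L) return(NULL)
  m <- profiles[loci, , drop = FALSE]
  u <- m / sqrt(rowSums(m^2))
  s <- colSums(u)
  avg <- (sum(s^2) - k) / (k * (k - 1))
  list(avg_cosine = avg, k = k)
}

map_to_loci <- function(members, protein_to_locus) {
  if (is.null(protein_to_locus)) return(members)
  out <- unname(protein_to_locus[members])
  out[!is.na(out)]
}

# Null distribution of the average pairwise cosine for size k, sampled
# uniformly without replacement from the profile universe.
coherence_null <- function(k, profiles, n_reps, seed) {
  n <- nrow(profiles)
  stopifnot(k >= 2L, n >= k)
  u <- profiles / sqrt(rowSums(profiles^2))
  set.seed(seed)
  vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(n, k)
    s <- colSums(u[idx, , drop = FALSE])
    (sum(s^2) - k) / (k * (k - 1))
  }, numeric(1))
}

#' Monte-Carlo p-value for a complex's expression coherence
#'
#' The null draws k loci uniformly without replacement from the profile
#' universe and records their average pairwise cosine;
#' \code{p = (1 + #\{null >= observed\}) / (1 + n_reps)} (pseudocount keeps
#' the permutation p valid, never exactly 0).
#'
#' @param avg_cosine Observed average pairwise cosine.
#' @param k Complex size (profiled subunits).
#' @param profiles Profile matrix: the sampling universe.
#' @param n_reps Replicates (default 100000).
#' @param seed RNG seed; identical seed + k reproduce the p-value exactly.
#' @return The permutation p-value in (0, 1].
#' @export
coherence_p_value <- function(avg_cosine, k, profiles, n_reps = 100000L,
                              seed = 1L) {
  null <- coherence_null(k, profiles, n_reps, seed)
  (1 + sum(null >= avg_cosine)) / (1 + n_reps)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Step-up q-values, order-preserving, capped at 1.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Tissue-specificity entropy of an expression profile
#'
#' Shannon entropy of the normalized tissue fractions; 0 for a single-tissue
#' profile, \code{log2(n_tissues)} for a uniform one.
#'
#' @param v Nonnegative, non-zero numeric vector.
#' @param base Logarithm base (default 2).
#' @return Entropy >= 0.
#' @export
profile_entropy <- function(v, base = 2) {
  s <- sum(v)
  if (s == 0) stop("entropy undefined for a zero vector")
  p <- v / s
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Coherence testing over a complex set
#'
#' Computes, for every complex with at least two profiled subunits, the
#' average pairwise cosine, its permutation p-value against the size-matched
#' null (null draws cached per size k, seeded as \code{seed + k}), the BH
#' q-value over the tested complexes, and the mean subunit profile entropy.
#' Complexes with fewer than two profiled subunits are skipped and listed in
#' the \code{"skipped"} attribute.
#'
#' @param complexes Named list of member-ID vectors (or cluster lists).
#' @param profiles Locus-profile matrix from \code{\link{collapse_tags}}.
#' @param protein_to_locus Optional protein -> locus map.
#' @param n_reps Null replicates per size (default 100000; tests use less).
#' @param seed Base RNG seed.
#' @param entropy_base Log base for \code{\link{profile_entropy}}.
#' @return data.frame: \code{complex_id}, \code{k}, \code{avg_cosine},
#'   \code{p_value}, \code{fdr}, \code{entropy}.
#' @export
coherence_test <- function(complexes, profiles, protein_to_locus = NULL,
                           n_reps = 100000L, seed = 1L, entropy_base = 2) {
  complexes <- normalize_predicted(complexes)
  null_cache <- new.env(parent = emptyenv())
  rows <- list()
  skipped <- character(0)
  for (id in names(complexes)) {
    cc <- complex_coherence(complexes[[id]], profiles, protein_to_locus)
    if (is.null(cc)) { skipped <- c(skipped, id); next }
    key <- as.character(cc$k)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- coherence_null(cc$k, profiles, n_reps,
                                          seed = seed + cc$k)
    }
    null <- null_cache[[key]]
    p <- (1 + sum(null >= cc$avg_cosine)) / (1 + length(null))
    loci <- map_to_loci(complexes[[id]], protein_to_locus)
    loci <- unique(loci[loci %in% rownames(profiles)])
    ent <- mean(vapply(loci, function(l) {
      profile_entropy(profiles[l, ], base = entropy_base)
    }, numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      complex_id = id, k = cc$k, avg_cosine = cc$avg_cosine, p_value = p,
      entropy = ent, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(complex_id = character(0), k = integer(0),
                      avg_cosine = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), entropy = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- fdr_adjust(out$p_value)
  out <- out[, c("complex_id", "k", "avg_cosine", "p_value", "fdr", "entropy")]
  attr(out, "skipped") <- skipped
  out
}

#' Size-vs-similarity summary (box-plot table and trend test)
#'
#' Bins \code{-log10(p)} by complex size k and reports per-k quartiles plus
#' a Spearman rank correlation of the per-k median against k — the
#' "coherence increases with complex size" trend.
#'
#' @param results data.frame from \code{\link{coherence_test}}.
#' @return List \code{(table, spearman_rho, spearman_p)}; the table has one
#'   row per k with columns \code{k}, \code{n}, \code{q1}, \code{median},
#'   \code{q3}.
#' @export
size_similarity_summary <- function(results) {
  if (nrow(results) == 0L) {
    return(list(table = data.frame(k = integer(0), n = integer(0),
                                   q1 = numeric(0), median = numeric(0),
                                   q3 = numeric(0)),
                spearman_rho = NA_real_, spearman_p = NA_real_))
  }
  neglog <- -log10(results$p_value)
  ks <- sort(unique(results$k))
  tab <- do.call(rbind, lapply(ks, function(k) {
    x <- neglog[results$k == k]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(k = k, n = length(x), q1 = q[1L], median = q[2L], q3 = q[3L])
  }))
  if (nrow(tab) >= 3L) {
    ct <- suppressWarnings(stats::cor.test(tab$k, tab$median,
                                           method = "spearman"))
    rho <- unname(ct$estimate); sp <- ct$p.value
  } else {
    rho <- NA_real_; sp <- NA_real_
  }
  list(table = tab, spearman_rho = rho, spearman_p = sp)
}
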