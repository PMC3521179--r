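# Within-complex gene-duplication statistics from a precomputed pairwise
# homology table (e.g. BLASTP all-vs-all output reduced to best E-values).

#' Build a homology table
#'
#' Unordered pair identity; when both orientations of a pair are present the
#' smaller E-value is kept.
#'
#' @param gene_a,gene_b Character vectors of gene IDs.
#' @param e_value Nonnegative numeric E-values.
#' @return A \code{homology_table} data.frame with columns \code{a},
#'   \code{b} (\code{a < b}) and \code{e_value}.
#' @export
homology_table <- function(gene_a, gene_b, e_value) {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(e_value), all(e_value >= 0))
  if (length(gene_a) == 0L) {
    out <- data.frame(a = character(0), b = character(0),
                      e_value = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("homology_table", "data.frame")
    return(out)
  }
  keep <- gene_a != gene_b
  lo <- pmin(gene_a[keep], gene_b[keep])
  hi <- pmax(gene_a[keep], gene_b[keep])
  ev <- e_value[keep]
  key <- paste(lo, hi, sep = "\r")
  best <- tapply(ev, key, min)
  pairs <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(pairs, `[[`, character(1), 1L),
                    b = vapply(pairs, `[[`, character(1), 2L),
                    e_value = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homology_table", "data.frame")
  out
}

#' Read a homology TSV (gene_a, gene_b, e_value)
#' @param path File path; lines starting with # skipped.
#' @return A \code{homology_table}.
#' @export
read_homology <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(homology_table(character(0), character(0), numeric(0)))
  homology_table(as.character(df[[1L]]), as.character(df[[2L]]),
                 as.numeric(df[[3L]]))
}

#' Paralogous pairs within a complex
#'
#' All unordered member pairs whose homology E-value passes the threshold.
#' The default comparison is strict \code{<} (a pair at exactly the
#' threshold is excluded); set \code{strict = FALSE} for \code{<=}.
#'
#' @param members Character vector of member gene IDs.
#' @param table A \code{\link{homology_table}}.
#' @param threshold E-value threshold (default 1e-5).
#' @param strict Use strict \code{<} (default TRUE).
#' @return data.frame with columns \code{a}, \code{b}, \code{e_value}.
#' @export
complex_paralog_pairs <- function(members, table, threshold = 1e-5,
                                  strict = TRUE) {
  members <- unique(members)
  hit <- table$a %in% members & table$b %in% members
  hit <- hit & if (strict) table$e_value < threshold else table$e_value <= threshold
  out <- table[hit, c("a", "b", "e_value"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-complex paralogy summary over a complex set
#'
#' @param complexes Named list of member-ID vectors (or cluster lists).
#' @param table A \code{\link{homology_table}}.
#' @param threshold E-value threshold (default 1e-5).
#' @param strict Strict \code{<} comparison (default TRUE).
#' @return A \code{paralog_summary} list: \code{n_duplicated_genes} (genes in
#'   at least one within-complex paralog pair, counted once globally),
#'   \code{n_total_genes} (union of complex memberships),
#'   \code{n_complexes_with_pair}, \code{n_complexes_majority_paralog}
#'   (strictly more than half of members paired within the complex),
#'   \code{frac_with_pair}, \code{frac_majority}, and \code{per_complex}
#'   (data.frame: \code{complex_id}, \code{n_members}, \code{n_pairs},
#'   \code{n_paralog_genes}, \code{majority}).
#' @export
paralog_summary <- function(complexes, table, threshold = 1e-5, strict = TRUE) {
  complexes <- normalize_predicted(complexes)
  dup_global <- character(0)
  rows <- list()
  for (id in names(complexes)) {
    members <- unique(complexes[[id]])
    pairs <- complex_paralog_pairs(members, table, threshold, strict)
    genes <- unique(c(pairs$a, pairs$b))
    dup_global <- union(dup_global, genes)
    rows[[length(rows) + 1L]] <- data.frame(
      complex_id = id, n_members = length(members), n_pairs = nrow(pairs),
      n_paralog_genes = length(genes),
      majority = length(genes) > length(members) / 2,
      stringsAsFactors = FALSE)
  }
  per_complex <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(complex_id = character(0), n_members = integer(0),
               n_pairs = integer(0), n_paralog_genes = integer(0),
               majority = logical(0), stringsAsFactors = FALSE)
  total_genes <- unique(unlist(complexes, use.names = FALSE))
  n_cx <- length(complexes)
  structure(list(
    n_duplicated_genes = length(dup_global),
    n_total_genes = length(total_genes),
    n_complexes_with_pair = sum(per_complex$n_pairs > 0L),
    n_complexes_majority_paralog = sum(per_complex$majority),
    frac_with_pair = if (n_cx > 0) sum(per_complex$n_pairs > 0L) / n_cx else NA_real_,
    frac_majority = if (n_cx > 0) sum(per_complex$majority) / n_cx else NA_real_,
    per_complex = per_complex), class = "paralog_summary")
}

#' @export
print.paralog_summary <- function(x, ...) {
  cat(sprintf(paste0("paralogy: %d/%d genes duplicated; %d complex(es) with ",
                     ">=1 pair (%.1f%%); %d majority-paralog (%.1f%%)\n"),
              x$n_duplicated_genes, x$n_total_genes, x$n_complexes_with_pair,
              100 * x$frac_with_pair, x$n_complexes_majority_paralog,
              100 * x$frac_majority))
  invisible(x)
}
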