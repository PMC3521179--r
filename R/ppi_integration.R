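# PPI data integration: tagged edge lists -> one nonredundant undirected network.

#' Load protein-protein interactions from a tagged edge list
#'
#' Reads a TSV edge list (two or more columns; only the first two are used,
#' which also covers PSI-MI TAB 2.5 columns 1-2) and returns one interaction
#' record per unordered protein pair found in the file.  Self-loops are
#' removed, duplicate pairs within the file are collapsed, and identifiers can
#' optionally be translated through a mapping and/or stripped of database
#' prefixes such as \code{"uniprotkb:"}.
#'
#' @param path Path to a TSV file with at least two columns (interactor A,
#'   interactor B).  Lines starting with \code{#} are skipped.
#' @param source_tag Tag naming the source database (e.g. \code{"BIND"}).
#' @param id_map Optional named character vector mapping raw IDs to canonical
#'   protein IDs.  Records whose IDs are absent from the map are dropped and
#'   the number of dropped records is reported via a message.
#' @param strip_prefix Optional regular expression removed from the start of
#'   each raw identifier before mapping (default \code{"^[A-Za-z0-9_.-]+:"}
#'   when \code{psimi_tab = TRUE}, none otherwise).
#' @param psimi_tab Treat the file as PSI-MI TAB 2.5: use columns 1-2 and
#'   strip ID prefixes.
#' @return A data.frame of class \code{ppi_records} with columns
#'   \code{protein_a}, \code{protein_b} (canonicalised so that
#'   \code{protein_a < protein_b}) and \code{source}.
#' @export
load_interactions <- function(path, source_tag, id_map = NULL,
                              strip_prefix = NULL, psimi_tab = FALSE) {
  stopifnot(is.character(source_tag), length(source_tag) == 1L)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("empty interaction file: %s", path))
    return(empty_records())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1L]])
  if (ncols < 2L) {
    stop(sprintf("parse error at line 1 of %s: expected >= 2 tab-separated columns", path))
  }
  bad <- which(vapply(fields, length, integer(1)) != ncols)
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d of %s: expected %d columns",
                 bad[1L], path, ncols))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  if (psimi_tab && is.null(strip_prefix)) strip_prefix <- "^[A-Za-z0-9_.-]+:"
  if (!is.null(strip_prefix)) {
    a <- sub(strip_prefix, "", a)
    b <- sub(strip_prefix, "", b)
  }
  if (!is.null(id_map)) {
    mapped_a <- unname(id_map[a])
    mapped_b <- unname(id_map[b])
    keep <- !is.na(mapped_a) & !is.na(mapped_b)
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      message(sprintf("load_interactions: dropped %d record(s) with unmapped IDs", n_dropped))
    }
    a <- mapped_a[keep]
    b <- mapped_b[keep]
  }
  keep <- a != b  # self-loops
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(protein_a = lo[!dup], protein_b = hi[!dup],
                    source = rep(source_tag, sum(!dup)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ppi_records", "data.frame")
  out
}

empty_records <- function() {
  out <- data.frame(protein_a = character(0), protein_b = character(0),
                    source = character(0), stringsAsFactors = FALSE)
  class(out) <- c("ppi_records", "data.frame")
  out
}

#' Merge interaction records into a nonredundant integrated network
#'
#' Collapses records from any number of sources into a simple undirected
#' graph: one edge per unordered protein pair, carrying the union of the
#' source tags under which the pair was observed.
#'
#' @param records A \code{ppi_records} data.frame (rows from one or several
#'   \code{\link{load_interactions}} calls, concatenated with \code{rbind}).
#' @param isolated Optional character vector of protein IDs to declare as
#'   isolated nodes (present in the network without any edge).
#' @return An object of class \code{ppi_network}: a list with \code{nodes}
#'   (sorted character vector), \code{edges} (data.frame \code{a}, \code{b}
#'   with \code{a < b}, sorted) and \code{sources} (list of character vectors
#'   parallel to \code{edges}).
#' @export
merge_networks <- function(records, isolated = character(0)) {
  stopifnot(is.data.frame(records),
            all(c("protein_a", "protein_b", "source") %in% names(records)))
  if (nrow(records) > 0 && any(records$protein_a == records$protein_b)) {
    stop("records contain self-loops; filter them with load_interactions()")
  }
  lo <- pmin(records$protein_a, records$protein_b)
  hi <- pmax(records$protein_a, records$protein_b)
  key <- paste(lo, hi, sep = "\r")
  idx <- split(seq_along(key), key)
  keys <- names(idx)
  ord <- order(keys)
  idx <- idx[ord]
  srcs <- lapply(idx, function(i) sort(unique(records$source[i])))
  first <- vapply(idx, `[[`, integer(1), 1L)
  edges <- data.frame(a = lo[first], b = hi[first], stringsAsFactors = FALSE)
  o <- order(edges$a, edges$b)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  srcs <- unname(srcs[o])
  net <- list(nodes = sort(unique(c(edges$a, edges$b, isolated))),
              edges = edges, sources = srcs)
  class(net) <- "ppi_network"
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d interactions, %d source(s)\n",
              length(x$nodes), nrow(x$edges), length(network_sources(x))))
  invisible(x)
}

#' Source tags present in an integrated network
#' @param net A \code{ppi_network}.
#' @return Sorted character vector of source tags.
#' @export
network_sources <- function(net) sort(unique(unlist(net$sources)))

#' Pairwise source-overlap matrix
#'
#' Cell (i, j) counts the edges tagged with both source i and source j; the
#' diagonal holds each source's nonredundant edge count.
#'
#' @param net A \code{ppi_network} with at least one source tag.
#' @return A symmetric integer matrix with source tags as dimnames.
#' @export
overlap_matrix <- function(net) {
  srcs <- network_sources(net)
  if (length(srcs) == 0L) stop("network has no source tags")
  m <- matrix(0L, length(srcs), length(srcs), dimnames = list(srcs, srcs))
  for (tags in net$sources) {
    i <- match(tags, srcs)
    m[i, i] <- m[i, i] + 1L
  }
  m
}

#' Histogram of edges shared by exactly k sources
#'
#' @param net A \code{ppi_network}.
#' @return Named integer vector indexed "1".."n_sources"; entry k counts the
#'   edges carrying exactly k source tags.  Values sum to the edge count.
#' @export
shared_in_k_sources <- function(net) {
  n_src <- length(network_sources(net))
  if (n_src == 0L) return(stats::setNames(integer(0), character(0)))
  k <- vapply(net$sources, length, integer(1))
  counts <- tabulate(k, nbins = n_src)
  stats::setNames(as.integer(counts), as.character(seq_len(n_src)))
}

#' Convert an integrated network to an igraph object
#'
#' Edge attribute \code{sources} holds the comma-joined tag list.
#' @param net A \code{ppi_network}.
#' @return An undirected \code{igraph} graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$sources <- vapply(net$sources, paste, character(1), collapse = ",")
  g
}

#' Write / read an integrated network as TSV
#'
#' Three tab-separated columns: protein A, protein B, comma-joined source
#' tags.  Lines starting with \code{#} are treated as comments.
#'
#' @param net A \code{ppi_network}.
#' @param path Output (input) file path.
#' @param header Provenance comment lines to prepend (each prefixed
#'   \code{#}).
#' @return \code{write_network}: \code{path}, invisibly.
#'   \code{read_network}: a \code{ppi_network}.
#' @export
write_network <- function(net, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  tags <- vapply(net$sources, paste, character(1), collapse = ",")
  writeLines(paste(net$edges$a, net$edges$b, tags, sep = "\t"), con)
  iso <- setdiff(net$nodes, c(net$edges$a, net$edges$b))
  if (length(iso) > 0) writeLines(paste0("#ISOLATED\t", paste(iso, collapse = ",")), con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  iso <- character(0)
  iso_lines <- grep("^#ISOLATED\t", lines, value = TRUE)
  if (length(iso_lines) > 0) {
    iso <- unlist(strsplit(sub("^#ISOLATED\t", "", iso_lines), ",", fixed = TRUE))
  }
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(merge_networks(empty_records(), isolated = iso))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  recs <- do.call(rbind, lapply(parts, function(p) {
    if (length(p) < 3L) stop("malformed network line: ", paste(p, collapse = "\t"))
    tags <- unlist(strsplit(p[[3L]], ",", fixed = TRUE))
    data.frame(protein_a = p[[1L]], protein_b = p[[2L]], source = tags,
               stringsAsFactors = FALSE)
  }))
  class(recs) <- c("ppi_records", "data.frame")
  merge_networks(recs, isolated = iso)
}

#' Write an integrated network as GraphML
#' @inheritParams write_network
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
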