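# Benchmarking predicted complexes against a reference set and grid-searching
# the two clustering parameters.

#' Build a reference complex set
#'
#' @param complexes Named list: complex_id -> character vector of member
#'   protein IDs (>= 2 each).  Proteins may recur across complexes.
#' @param provenance Optional named character vector of free-text provenance.
#' @return A \code{reference_set} object.
#' @export
reference_set <- function(complexes, provenance = NULL) {
  stopifnot(is.list(complexes), !is.null(names(complexes)),
            all(nzchar(names(complexes))))
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  if (any(vapply(complexes, length, integer(1)) < 2L)) {
    stop("every reference complex needs >= 2 members")
  }
  structure(list(complexes = complexes, provenance = provenance),
            class = "reference_set")
}

#' Read a reference set from TSV (complex_id TAB comma-joined members)
#' @param path File path.
#' @return A \code{reference_set}.
#' @export
read_reference <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  members <- lapply(parts, function(p) strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  reference_set(stats::setNames(members, ids))
}

#' @export
write_reference <- function(ref, path) {
  writeLines(paste(names(ref$complexes),
                   vapply(ref$complexes, paste, character(1), collapse = ","),
                   sep = "\t"), path)
  invisible(path)
}

#' Match predicted complexes to a reference set
#'
#' A predicted complex matches a known complex when the two share at least
#' two proteins; pairs sharing fewer are omitted (their recall and precision
#' are zero by construction).  Recall normalises the overlap by the known
#' complex size, precision by the predicted complex size.
#'
#' @param predicted List of member-ID vectors; names are used as predicted
#'   IDs (defaults to \code{"P1"..}).  Cluster lists from
#'   \code{\link{cluster_graph}} are accepted directly.
#' @param reference A \code{reference_set}.
#' @return data.frame with columns \code{known_id}, \code{predicted_id},
#'   \code{overlap}, \code{recall}, \code{precision}.
#' @export
match_complexes <- function(predicted, reference) {
  predicted <- normalize_predicted(predicted)
  rows <- list()
  for (kid in names(reference$complexes)) {
    known <- reference$complexes[[kid]]
    for (pid in names(predicted)) {
      ov <- sum(predicted[[pid]] %in% known)
      if (ov >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          known_id = kid, predicted_id = pid, overlap = ov,
          recall = ov / length(known),
          precision = ov / length(predicted[[pid]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(known_id = character(0), predicted_id = character(0),
                      overlap = integer(0), recall = numeric(0),
                      precision = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

normalize_predicted <- function(predicted) {
  if (length(predicted) == 0L) return(stats::setNames(list(), character(0)))
  if (is.list(predicted[[1L]]) && !is.null(predicted[[1L]]$members)) {
    predicted <- lapply(predicted, `[[`, "members")
  }
  predicted <- lapply(predicted, function(m) unique(as.character(m)))
  if (is.null(names(predicted)) || any(!nzchar(names(predicted)))) {
    names(predicted) <- paste0("P", seq_along(predicted))
  }
  predicted
}

#' Frequency-adjusted recall and precision sums
#'
#' For each known complex, the best-matching predicted complex's recall and
#' precision (best recall; ties broken by higher precision, then smaller
#' predicted ID) are divided by the number of predicted complexes matching
#' that known complex — damping credit for over-predicted duplicates — and
#' summed over known complexes.
#'
#' @param matches Output of \code{\link{match_complexes}}.
#' @return List \code{(adjusted_recall_sum, adjusted_precision_sum,
#'   n_matched_known)}.
#' @export
frequency_adjusted_scores <- function(matches) {
  if (nrow(matches) == 0L) {
    return(list(adjusted_recall_sum = 0, adjusted_precision_sum = 0,
                n_matched_known = 0L))
  }
  r_sum <- 0
  p_sum <- 0
  for (kid in unique(matches$known_id)) {
    sub <- matches[matches$known_id == kid, , drop = FALSE]
    ord <- order(-sub$recall, -sub$precision, sub$predicted_id, method = "radix")
    best <- sub[ord[1L], ]
    freq <- nrow(sub)
    r_sum <- r_sum + best$recall / freq
    p_sum <- p_sum + best$precision / freq
  }
  list(adjusted_recall_sum = r_sum, adjusted_precision_sum = p_sum,
       n_matched_known = length(unique(matches$known_id)))
}

#' Grid search over the two clustering parameters
#'
#' Runs \code{\link{cluster_graph}} at every (density, cluster property)
#' grid point on [0, 1] x [0, 1] and scores each predicted set against the
#' reference with frequency-adjusted recall/precision sums.  The selected
#' point maximises the sum of the two scores (ties: larger density, then
#' larger cluster property).
#'
#' @param net A \code{ppi_network}.
#' @param reference A \code{reference_set}.
#' @param grid_step Grid increment; must divide 1 (default 0.1, the
#'   11 x 11 grid).
#' @param min_size Minimum cluster size passed to the clusterer.
#' @param overlapping Clustering mode.
#' @return List with \code{grid} (data.frame of one row per grid point:
#'   \code{d_in}, \code{cp_in}, \code{adjusted_recall_sum},
#'   \code{adjusted_precision_sum}, \code{score}, \code{n_matched_known},
#'   \code{n_predicted}) and \code{best} = \code{(d_in, cp_in)}.
#' @export
grid_search <- function(net, reference, grid_step = 0.1, min_size = 3L,
                        overlapping = TRUE) {
  stopifnot(grid_step > 0, grid_step <= 1)
  n_steps <- 1 / grid_step
  if (abs(n_steps - round(n_steps)) > 1e-9) stop("grid_step must divide 1.0")
  pts <- seq(0, 1, by = grid_step)
  rows <- list()
  for (d in pts) {
    for (cp in pts) {
      params <- cluster_params(d_in = d, cp_in = cp, min_size = min_size,
                               overlapping = overlapping)
      clusters <- cluster_graph(net, params)
      m <- match_complexes(clusters, reference)
      sc <- frequency_adjusted_scores(m)
      rows[[length(rows) + 1L]] <- data.frame(
        d_in = d, cp_in = cp,
        adjusted_recall_sum = sc$adjusted_recall_sum,
        adjusted_precision_sum = sc$adjusted_precision_sum,
        score = sc$adjusted_recall_sum + sc$adjusted_precision_sum,
        n_matched_known = sc$n_matched_known,
        n_predicted = length(clusters),
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  ord <- order(-grid$score, -grid$d_in, -grid$cp_in)
  best <- grid[ord[1L], ]
  list(grid = grid, best = list(d_in = best$d_in, cp_in = best$cp_in))
}

#' Reporting summary of a matched prediction
#'
#' Average recall/precision over matched known complexes (best match per
#' known complex) and the mean number of complexes sharing a protein.
#'
#' @param predicted List of member-ID vectors or clusters.
#' @param reference A \code{reference_set}.
#' @return List \code{(n_matched_known, avg_recall, avg_precision,
#'   complexes_per_protein)}.
#' @export
benchmark_summary <- function(predicted, reference) {
  predicted <- normalize_predicted(predicted)
  m <- match_complexes(predicted, reference)
  if (nrow(m) == 0L) {
    avg_r <- NA_real_; avg_p <- NA_real_; nk <- 0L
  } else {
    best <- lapply(split(m, m$known_id), function(sub) {
      sub[order(-sub$recall, -sub$precision, sub$predicted_id,
                method = "radix")[1L], ]
    })
    best <- do.call(rbind, best)
    avg_r <- mean(best$recall); avg_p <- mean(best$precision)
    nk <- nrow(best)
  }
  membership <- table(unlist(reference$complexes))
  list(n_matched_known = nk, avg_recall = avg_r, avg_precision = avg_p,
       complexes_per_protein = mean(as.numeric(membership)))
}
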