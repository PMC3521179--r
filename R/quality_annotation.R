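# Evidence categories, the Complex Quality Index (CQI), complex typing,
# curation edits, and the hypothetical-protein report.
#
# Category I  : subunit confirmed for this complex in literature / structure.
# Category II : function-related evidence only.
# Category III: predicted subunit with neither.
# CQI string  : "n1.n2.n3/total".

#' Build an evidence table
#'
#' @param category_I data.frame with columns \code{protein}, \code{complex_id}:
#'   literature/structure-confirmed subunit-of-complex pairs.
#' @param category_II Same schema: function-related evidence pairs.
#' @return An \code{evidence_table}.  A (protein, complex) pair present in
#'   both categories is a conflict and raises an error naming the pair.
#' @export
evidence_table <- function(category_I = NULL, category_II = NULL) {
  empty <- data.frame(protein = character(0), complex_id = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(category_I)) category_I <- empty
  if (is.null(category_II)) category_II <- empty
  stopifnot(all(c("protein", "complex_id") %in% names(category_I)),
            all(c("protein", "complex_id") %in% names(category_II)))
  k1 <- paste(category_I$protein, category_I$complex_id, sep = "\r")
  k2 <- paste(category_II$protein, category_II$complex_id, sep = "\r")
  clash <- intersect(k1, k2)
  if (length(clash) > 0L) {
    pair <- strsplit(clash[[1L]], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("conflicting evidence for pair (%s, %s): listed in both category I and II",
                 pair[1L], pair[2L]))
  }
  structure(list(category_I = unique(category_I[c("protein", "complex_id")]),
                 category_II = unique(category_II[c("protein", "complex_id")])),
            class = "evidence_table")
}

#' Read an evidence TSV (protein TAB complex_id)
#' @param path File path; lines starting with # skipped.
#' @return data.frame with columns \code{protein}, \code{complex_id}.
#' @export
read_evidence_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(protein = character(0), complex_id = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(protein = vapply(parts, `[[`, character(1), 1L),
             complex_id = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Assign evidence categories to complex members
#'
#' A member is category I if a category-I pair exists for this complex,
#' otherwise II if a category-II pair exists, otherwise III.  The same
#' protein may receive different categories in different complexes.
#'
#' @param members Character vector of member protein IDs.
#' @param complex_id The complex the members belong to.
#' @param evidence An \code{\link{evidence_table}}.
#' @return Named character vector, values in \code{c("I", "II", "III")}.
#' @export
assign_categories <- function(members, complex_id, evidence) {
  e1 <- evidence$category_I
  e2 <- evidence$category_II
  in1 <- members %in% e1$protein[e1$complex_id == complex_id]
  in2 <- members %in% e2$protein[e2$complex_id == complex_id]
  cat <- ifelse(in1, "I", ifelse(in2, "II", "III"))
  stats::setNames(cat, members)
}

#' Complex Quality Index
#'
#' \code{compute_cqi} counts category I/II/III members; \code{format_cqi}
#' renders the "n1.n2.n3/total" string (e.g. a complex of eight subunits
#' with five, two and one in categories I, II, III formats as
#' \code{"5.2.1/8"}); \code{parse_cqi} is its inverse.
#'
#' @param category_of Named character vector of categories (from
#'   \code{\link{assign_categories}}).
#' @return A \code{cqi} list \code{(n1, n2, n3, total)}.
#' @export
compute_cqi <- function(category_of) {
  if (length(category_of) == 0L) stop("category map is empty")
  stopifnot(all(category_of %in% c("I", "II", "III")))
  structure(list(n1 = sum(category_of == "I"),
                 n2 = sum(category_of == "II"),
                 n3 = sum(category_of == "III"),
                 total = length(category_of)),
            class = "cqi")
}

#' @rdname compute_cqi
#' @param cqi A \code{cqi} object.
#' @export
format_cqi <- function(cqi) {
  sprintf("%d.%d.%d/%d", cqi$n1, cqi$n2, cqi$n3, cqi$total)
}

#' @rdname compute_cqi
#' @param x A CQI string such as \code{"5.2.1/8"}.
#' @export
parse_cqi <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)\\.([0-9]+)\\.([0-9]+)/([0-9]+)$", x))[[1L]]
  if (length(m) != 5L) stop("malformed CQI string: ", x)
  v <- as.integer(m[-1L])
  if (v[1L] + v[2L] + v[3L] != v[4L]) {
    stop(sprintf("inconsistent CQI string %s: %d + %d + %d != %d",
                 x, v[1L], v[2L], v[3L], v[4L]))
  }
  structure(list(n1 = v[1L], n2 = v[2L], n3 = v[3L], total = v[4L]),
            class = "cqi")
}

#' @export
print.cqi <- function(x, ...) {
  cat("CQI:", format_cqi(x), "\n")
  invisible(x)
}

#' Classify a complex from its member categories
#'
#' Perfectly matched: all members category I.  Partially matched: at least
#' two members category I (but not all).  Hypothetical: all members category
#' III.  Everything else (e.g. a single category-I member, or all-II) is
#' reported as \code{"other"} so the three printed definitions stay
#' literally true.
#'
#' @param category_of Named character vector of categories.
#' @return One of \code{"perfectly_matched"}, \code{"partially_matched"},
#'   \code{"hypothetical"}, \code{"other"}.
#' @export
classify_complex <- function(category_of) {
  if (length(category_of) == 0L) stop("category map is empty")
  n1 <- sum(category_of == "I")
  if (n1 == length(category_of)) return("perfectly_matched")
  if (all(category_of == "III")) return("hypothetical")
  if (n1 >= 2L) return("partially_matched")
  "other"
}

#' Annotate predicted complexes with categories, CQI and type
#'
#' @param complexes List of complexes: each either a member-ID vector or a
#'   list with a \code{members} field (as emitted by
#'   \code{\link{cluster_graph}}); names become complex IDs (default
#'   \code{"C1"..}).
#' @param evidence An \code{\link{evidence_table}}.
#' @return List of \code{annotated_complex} objects: \code{complex_id},
#'   \code{members}, \code{category_of}, \code{cqi}, \code{complex_type},
#'   plus free-text \code{name}, \code{description}, \code{localization}.
#' @export
annotate_complexes <- function(complexes, evidence = evidence_table()) {
  complexes <- normalize_predicted(complexes)
  if (is.null(names(complexes)) || any(!nzchar(names(complexes)))) {
    names(complexes) <- paste0("C", seq_along(complexes))
  }
  out <- lapply(names(complexes), function(id) {
    members <- sort(unique(complexes[[id]]))
    cat <- assign_categories(members, id, evidence)
    structure(list(complex_id = id, members = members, category_of = cat,
                   cqi = compute_cqi(cat), complex_type = classify_complex(cat),
                   name = paste(members, collapse = "-"),
                   description = "", localization = ""),
              class = "annotated_complex")
  })
  stats::setNames(out, names(complexes))
}

#' @export
print.annotated_complex <- function(x, ...) {
  cat(sprintf("%s [%s] %s: %s\n", x$complex_id, format_cqi(x$cqi),
              x$complex_type, paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Apply curation directives to annotated complexes
#'
#' The curation file is a TSV of directives, applied in file order:
#' \preformatted{
#' add    complex_id  protein  category
#' merge  complex_id_a  complex_id_b  new_id
#' }
#' Adding an existing member is a no-op with a warning; a directive naming an
#' unknown complex is an error.  CQI and complex type are recomputed after
#' every edit.  Merging keeps, for proteins present in both complexes, the
#' stronger evidence category (I < II < III).
#'
#' @param complexes Output of \code{\link{annotate_complexes}}.
#' @param curation_file Path to the directive TSV.
#' @return The edited complex list, with an \code{"audit"} attribute listing
#'   the applied edits.
#' @export
apply_curation <- function(complexes, curation_file) {
  lines <- readLines(curation_file, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  audit <- character(0)
  for (i in seq_along(lines)) {
    p <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    op <- p[[1L]]
    if (op == "add") {
      if (length(p) != 4L) stop("malformed add directive at line ", i)
      id <- p[[2L]]; protein <- p[[3L]]; category <- p[[4L]]
      if (!(id %in% names(complexes))) stop("add: unknown complex ", id)
      if (!(category %in% c("I", "II", "III"))) stop("add: bad category ", category)
      cx <- complexes[[id]]
      if (protein %in% cx$members) {
        warning(sprintf("add: %s already a member of %s; no-op", protein, id))
        next
      }
      cx$members <- sort(c(cx$members, protein))
      cx$category_of <- c(cx$category_of, stats::setNames(category, protein))
      cx$category_of <- cx$category_of[cx$members]
      cx <- recompute_annotation(cx)
      complexes[[id]] <- cx
      audit <- c(audit, sprintf("add %s to %s as category %s", protein, id, category))
    } else if (op == "merge") {
      if (length(p) != 4L) stop("malformed merge directive at line ", i)
      ida <- p[[2L]]; idb <- p[[3L]]; new_id <- p[[4L]]
      for (id in c(ida, idb)) {
        if (!(id %in% names(complexes))) stop("merge: unknown complex ", id)
      }
      a <- complexes[[ida]]; b <- complexes[[idb]]
      members <- sort(unique(c(a$members, b$members)))
      rank <- c(I = 1L, II = 2L, III = 3L)
      cat <- vapply(members, function(m) {
        cands <- c(a$category_of[m], b$category_of[m])
        cands <- cands[!is.na(cands)]
        names(rank)[min(rank[cands])]
      }, character(1))
      cx <- structure(list(complex_id = new_id, members = members,
                           category_of = stats::setNames(cat, members),
                           cqi = NULL, complex_type = NULL,
                           name = paste(members, collapse = "-"),
                           description = "", localization = ""),
                      class = "annotated_complex")
      cx <- recompute_annotation(cx)
      complexes[[ida]] <- NULL
      complexes[[idb]] <- NULL
      complexes[[new_id]] <- cx
      audit <- c(audit, sprintf("merge %s + %s -> %s", ida, idb, new_id))
    } else {
      stop("unknown curation directive at line ", i, ": ", op)
    }
  }
  attr(complexes, "audit") <- audit
  complexes
}

recompute_annotation <- function(cx) {
  cx$cqi <- compute_cqi(cx$category_of)
  cx$complex_type <- classify_complex(cx$category_of)
  cx
}

#' Report hypothetical proteins and the complexes they join
#'
#' One row per (hypothetical protein, complex) pair.  A complex is flagged
#' function-inferable when at least half of its subunits are category I —
#' the complex's function then transfers plausibly to the hypothetical
#' member.
#'
#' @param complexes Output of \code{\link{annotate_complexes}}.
#' @param hypothetical_ids Character vector of hypothetical protein IDs.
#' @return data.frame with columns \code{protein}, \code{complex_id},
#'   \code{cqi}, \code{complex_type}, \code{function_inferable}.
#' @export
hypothetical_protein_report <- function(complexes, hypothetical_ids) {
  rows <- list()
  for (cx in complexes) {
    hits <- intersect(cx$members, hypothetical_ids)
    if (length(hits) == 0L) next
    frac_I <- sum(cx$category_of == "I") / length(cx$members)
    for (h in sort(hits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein = h, complex_id = cx$complex_id, cqi = format_cqi(cx$cqi),
        complex_type = cx$complex_type,
        function_inferable = frac_I >= 0.5,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein = character(0), complex_id = character(0),
                      cqi = character(0), complex_type = character(0),
                      function_inferable = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Tabulate annotation statistics over a complex set
#'
#' @param complexes Output of \code{\link{annotate_complexes}}.
#' @return List with \code{n_complexes}, \code{type_counts},
#'   \code{category_counts} (per-complex sharing counted, i.e. a protein in
#'   two complexes contributes to both), and \code{size_distribution}.
#' @export
annotation_summary <- function(complexes) {
  types <- vapply(complexes, `[[`, character(1), "complex_type")
  cats <- unlist(lapply(complexes, `[[`, "category_of"), use.names = FALSE)
  sizes <- vapply(complexes, function(x) length(x$members), integer(1))
  list(n_complexes = length(complexes),
       type_counts = table(factor(types, levels = c("perfectly_matched",
                                                    "partially_matched",
                                                    "hypothetical", "other"))),
       category_counts = table(factor(cats, levels = c("I", "II", "III"))),
       size_distribution = table(sizes))
}
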