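#' Six membrane protein type names
#'
#' The label vocabulary of the human membrane protein classification problem:
#' GPI-anchor, lipid-anchor, multipass, peripheral, single-pass type I and
#' single-pass type II. One protein can carry one to three of these types.
#'
#' @return Character vector of length 6.
#' @export
membrane_types <- function() {
  c("GPI-anchor", "lipid-anchor", "multipass", "peripheral",
    "single-pass-I", "single-pass-II")
}

#' Construct an annotation table
#'
#' An annotation table maps each protein identifier to a non-empty list of
#' functional domain term tokens (for real data, InterPro IPR accessions such
#' as `"IPR001806"`; tokens are opaque strings so GO terms or pathway
#' identifiers work identically).
#'
#' @param terms Named list; names are unique protein identifiers, each element
#'   a character vector of distinct domain terms (length >= 1).
#' @return An object of class `annotation_table` with elements `protein_ids`
#'   and `terms`.
#' @export
annotation_table <- function(terms) {
  if (!is.list(terms) || length(terms) == 0L || is.null(names(terms)))
    stop("'terms' must be a non-empty named list of character vectors")
  ids <- names(terms)
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (i in seq_along(terms)) {
    tk <- terms[[i]]
    if (!is.character(tk) || length(tk) == 0L)
      stop("protein '", ids[i], "' has no domain terms")
    if (anyDuplicated(tk))
      stop("protein '", ids[i], "' has duplicate terms")
  }
  structure(list(protein_ids = ids, terms = terms), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  nt <- lengths(x$terms)
  cat("Annotation table:", length(x$protein_ids), "proteins,",
      length(unique(unlist(x$terms, use.names = FALSE))), "distinct terms\n")
  cat("Terms per protein: min", min(nt), "/ median", stats::median(nt),
      "/ max", max(nt), "\n")
  invisible(x)
}

#' Read a protein-domain annotation table
#'
#' Two tab-separated dialects are supported. `"pairs"` is the
#' protein2ipr-like layout with one `protein_id<TAB>term_id` pair per line;
#' `"lists"` has one line per protein: `protein_id<TAB>term1,term2,...`.
#' Lines starting with `#` are ignored. Duplicate (protein, term) pairs are
#' collapsed; term order within a protein is first occurrence in the file.
#'
#' @param path Path to a TSV file.
#' @param dialect `"pairs"` (default) or `"lists"`.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, dialect = c("pairs", "lists")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no annotation records in ", path)
  idx <- which(keep)
  terms <- new.env(parent = emptyenv())
  order_ids <- character(0)
  for (ln in idx) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L || !nzchar(fields[1]) || !nzchar(fields[2]))
      stop("malformed annotation line ", ln, " in ", path, ": ", lines[ln])
    pid <- fields[1]
    toks <- if (dialect == "pairs") fields[2] else
      strsplit(fields[2], ",", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L)
      stop("malformed annotation line ", ln, " in ", path, ": no terms")
    if (!exists(pid, envir = terms, inherits = FALSE)) {
      order_ids <- c(order_ids, pid)
      assign(pid, character(0), envir = terms)
    }
    cur <- get(pid, envir = terms, inherits = FALSE)
    assign(pid, c(cur, setdiff(toks, cur)), envir = terms)
  }
  annotation_table(stats::setNames(
    lapply(order_ids, get, envir = terms), order_ids))
}

#' Write an annotation table
#'
#' @param annotations An [annotation_table()].
#' @param path Output file.
#' @param dialect `"pairs"` or `"lists"` (see [read_annotations()]).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, dialect = c("pairs", "lists")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(annotations, "annotation_table"))
  lines <- if (dialect == "pairs") {
    unlist(lapply(annotations$protein_ids, function(p)
      paste(p, annotations$terms[[p]], sep = "\t")), use.names = FALSE)
  } else {
    vapply(annotations$protein_ids, function(p)
      paste(p, paste(annotations$terms[[p]], collapse = ","), sep = "\t"),
      character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a label matrix
#'
#' A binary protein-by-type indicator matrix. Every protein (row) must carry
#' at least one type, matching the study design in which every membrane
#' protein belongs to one to three of the six types.
#'
#' @param indicators Numeric/integer matrix of 0/1 with one row per protein.
#' @param protein_ids Row identifiers (defaults to existing rownames).
#' @param label_names Column names (defaults to existing colnames).
#' @return Integer matrix of class `label_matrix` with dimnames set.
#' @export
label_matrix <- function(indicators, protein_ids = rownames(indicators),
                         label_names = colnames(indicators)) {
  m <- as.matrix(indicators)
  if (is.null(protein_ids) || is.null(label_names))
    stop("protein_ids and label_names are required")
  if (length(protein_ids) != nrow(m) || length(label_names) != ncol(m))
    stop("dimnames lengths do not match the indicator matrix")
  if (anyDuplicated(protein_ids)) stop("duplicate protein ids")
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
    stop("indicators must be binary")
  if (any(rowSums(m) == 0L))
    stop("every protein must carry at least one label; offending: ",
         paste(utils::head(protein_ids[rowSums(m) == 0L], 5), collapse = ", "))
  dimnames(m) <- list(protein_ids, label_names)
  class(m) <- c("label_matrix", class(m))
  m
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("Label matrix:", nrow(x), "proteins x", ncol(x), "types\n")
  print(colSums(unclass(x)))
  invisible(x)
}

# subsetting a label_matrix keeps its class (rows always retain >= 1 label
# only if the caller subsets rows, which is the only supported use)
#' @export
`[.label_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("label_matrix", "matrix", "array")
  out
}

#' Read a protein-type label table
#'
#' Expects one line per record: `protein_id<TAB>type1[;type2[;type3]]`.
#' `#`-prefixed lines are ignored. A protein appearing on several lines gets
#' the union of the listed types (proteins are unique entities; the union is
#' the only lossless merge).
#'
#' @param path Path to the label TSV.
#' @param label_names Ordered label vocabulary; every type name in the file
#'   must be one of these. Defaults to [membrane_types()]; `NULL` infers the
#'   vocabulary as the sorted distinct type names found in the file.
#' @return A [label_matrix()] with columns ordered as `label_names`.
#' @export
read_labels <- function(path, label_names = membrane_types()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no label records in ", path)
  if (is.null(label_names)) {
    seen <- unlist(lapply(strsplit(lines[keep], "\t", fixed = TRUE),
                          function(f) if (length(f) >= 2)
                            strsplit(f[2], ";", fixed = TRUE)[[1]]),
                   use.names = FALSE)
    label_names <- sort(unique(seen[nzchar(seen)]), method = "radix")
  }
  sets <- new.env(parent = emptyenv())
  order_ids <- character(0)
  for (ln in keep) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L || !nzchar(fields[1]))
      stop("malformed label line ", ln, " in ", path, ": ", lines[ln])
    pid <- fields[1]
    types <- strsplit(fields[2], ";", fixed = TRUE)[[1]]
    types <- types[nzchar(types)]
    if (length(types) == 0L)
      stop("protein '", pid, "' (line ", ln, ") has no types")
    bad <- setdiff(types, label_names)
    if (length(bad))
      stop("unknown type name(s) on line ", ln, ": ", paste(bad, collapse = ", "))
    if (!exists(pid, envir = sets, inherits = FALSE)) {
      order_ids <- c(order_ids, pid)
      assign(pid, character(0), envir = sets)
    }
    assign(pid, union(get(pid, envir = sets, inherits = FALSE), types), envir = sets)
  }
  ind <- t(vapply(order_ids, function(p)
    as.integer(label_names %in% get(p, envir = sets, inherits = FALSE)),
    integer(length(label_names))))
  label_matrix(ind, protein_ids = order_ids, label_names = label_names)
}

#' Write a protein-type label table
#'
#' @param labels A [label_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_matrix"))
  lines <- vapply(seq_len(nrow(labels)), function(i)
    paste(rownames(labels)[i],
          paste(colnames(labels)[labels[i, ] == 1L], collapse = ";"),
          sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict labels and annotations to proteins with domain information
#'
#' Proteins lacking domain annotations cannot be encoded and are excluded
#' from the study; this applies the exclusion in both directions, keeping
#' only proteins present in both tables (every annotated protein has >= 1
#' term by construction). Relative order follows the label matrix.
#'
#' @param labels A [label_matrix()].
#' @param annotations An [annotation_table()].
#' @return List with `labels`, `annotations` (both restricted, rows/entries
#'   in the label matrix's order) and `n_dropped`, the number of labelled
#'   proteins removed.
#' @export
filter_annotated <- function(labels, annotations) {
  stopifnot(inherits(labels, "label_matrix"),
            inherits(annotations, "annotation_table"))
  keep <- rownames(labels)[rownames(labels) %in% annotations$protein_ids]
  if (length(keep) == 0L)
    stop("no protein is present in both the label and annotation tables")
  n_dropped <- nrow(labels) - length(keep)
  list(
    labels = labels[keep, , drop = FALSE],
    annotations = annotation_table(annotations$terms[keep]),
    n_dropped = n_dropped
  )
}

#' Summarize label structure
#'
#' Computes per-type protein counts, the total number of (protein, type)
#' assignments, and the label multiplicity distribution (how many proteins
#' carry exactly 1, 2, ... types). For the real study these are the Table-1
#' style counts: 2810 assignments over 2729 proteins, of which 2652 carry one
#' type, 73 two and 4 three.
#'
#' @param labels A [label_matrix()].
#' @return An object of class `label_summary`: list with `per_type_counts`,
#'   `total_assignments`, `multiplicity_counts`, `n_proteins`.
#' @export
summarize_labels <- function(labels) {
  stopifnot(inherits(labels, "label_matrix"))
  per_type <- colSums(unclass(labels))
  mult <- rowSums(unclass(labels))
  mult_tab <- table(factor(mult, levels = sort(unique(mult))))
  mult_counts <- stats::setNames(as.integer(mult_tab), names(mult_tab))
  total <- sum(per_type)
  # conservation: every assignment counted once per type and once per protein
  stopifnot(total == sum(as.integer(names(mult_counts)) * mult_counts),
            sum(mult_counts) == nrow(labels))
  structure(list(per_type_counts = per_type,
                 total_assignments = as.integer(total),
                 multiplicity_counts = mult_counts,
                 n_proteins = nrow(labels)),
            class = "label_summary")
}

#' @export
print.label_summary <- function(x, ...) {
  cat("Label summary over", x$n_proteins, "proteins,",
      x$total_assignments, "assignments\n")
  cat("Per type:\n"); print(x$per_type_counts)
  cat("Multiplicity (types per protein -> proteins):\n")
  print(x$multiplicity_counts)
  invisible(x)
}
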