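# Readers and writers: PHYLIP / CSV distance matrices, STR CSV tables,
# GraphML / DOT / TSV network export. GraphML and DOT go through igraph;
# the TSV edge list is written directly so its byte layout is deterministic
# (golden-file friendly).

#' Read a labeled dissimilarity matrix
#'
#' Supports two dialects: \code{"csv"} (header row of labels, first column
#' of labels) and \code{"phylip"} (square PHYLIP distance matrix: first line
#' the vertex count, then one line per vertex with its label followed by the
#' full row of distances; labels are taken up to whitespace rather than
#' fixed-width). The result is validated and symmetrized by
#' [as_dissimilarity()]: asymmetries within 1e-9 relative are averaged away,
#' anything larger is a format error naming the offending pair.
#'
#' @param path file to read.
#' @param format \code{"csv"} or \code{"phylip"}.
#' @return a labeled dissimilarity matrix.
#' @export
read_distance_matrix <- function(path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("cannot read distance matrix: ", path)
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop_format("malformed CSV in ", path, ": ",
        conditionMessage(e)))
    if (ncol(df) < 3L)
      stop_format("CSV distance matrix needs a label column plus >= 2 ",
        "value columns: ", path)
    labels <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop_format("non-numeric entries in ", path)
    if (!identical(colnames(m), labels))
      stop_format("row labels and column header disagree in ", path)
    rownames(m) <- labels
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop_format("truncated PHYLIP matrix: ", path)
    n <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]][1L]))
    if (is.na(n) || n < 2L)
      stop_format("bad vertex count on PHYLIP header line: ", path)
    if (length(lines) != n + 1L)
      stop_format("expected ", n, " matrix rows in ", path, ", found ",
        length(lines) - 1L)
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    bad <- which(lengths(rows) != n + 1L)
    if (length(bad))
      stop_format("PHYLIP row ", bad[1L], " has ", lengths(rows)[bad[1L]] - 1L,
        " values, expected ", n)
    labels <- vapply(rows, `[[`, "", 1L)
    vals <- suppressWarnings(
      vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
    if (anyNA(vals)) stop_format("non-numeric distance in ", path)
    m <- t(vals)
    dimnames(m) <- list(labels, labels)
  }
  as_dissimilarity(m, labels = rownames(m))
}

#' Write a subdominant ultrametric (or any labeled symmetric matrix)
#'
#' Values are printed with 17 significant digits, so a round-trip through
#' [read_distance_matrix()] reproduces them exactly.
#'
#' @param x an \code{"ultranet"} fit (its W* is written) or a labeled
#'   symmetric matrix with at least 2 rows.
#' @param path destination file.
#' @param format \code{"csv"} or \code{"phylip"}.
#' @export
write_ultrametric <- function(x, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  m <- if (inherits(x, "ultranet")) x$Wstar else x
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2L)
    stop_validation("need a square matrix with at least 2 labels")
  labels <- rownames(m)
  if (is.null(labels)) stop_validation("matrix must carry labels")
  fmtrow <- function(i) paste(sprintf("%.17g", m[i, ]), collapse =
    if (format == "csv") "," else " ")
  lines <- if (format == "csv") {
    c(paste(c("", labels), collapse = ","),
      vapply(seq_len(nrow(m)), function(i)
        paste(labels[i], fmtrow(i), sep = ","), ""))
  } else {
    c(as.character(nrow(m)),
      vapply(seq_len(nrow(m)), function(i)
        paste(labels[i], fmtrow(i)), ""))
  }
  write_lines_checked(lines, path)
}

#' Read an STR haplotype table from CSV
#'
#' Expects a header row of locus names, a first column of individual
#' identifiers, optionally a second column named \code{population}, and
#' nonnegative integer repeat counts everywhere else. Missing cells,
#' non-integer counts and duplicate identifiers are rejected.
#'
#' @param path CSV file.
#' @return an \code{"str_table"} (locus weights default to 1; see
#'   [str_weights()] to derive weights from mutation rates).
#' @export
read_str_table <- function(path) {
  if (!file.exists(path)) stop_io("cannot read STR table: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
      colClasses = "character"),
    error = function(e) stop_format("malformed CSV in ", path, ": ",
      conditionMessage(e)))
  if (ncol(df) < 2L) stop_format("STR table has no locus columns: ", path)
  ids <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  populations <- NULL
  if (tolower(names(df)[1L]) == "population") {
    populations <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  if (ncol(df) < 1L) stop_format("STR table has no locus columns: ", path)
  cells <- as.matrix(df)
  if (anyNA(cells) || any(!nzchar(trimws(cells))))
    stop_validation("missing repeat counts in ", path)
  if (any(!grepl("^\\s*[0-9]+\\s*$", cells)))
    stop_validation("non-integer repeat count in ", path)
  counts <- matrix(as.integer(cells), nrow(df), ncol(df),
    dimnames = list(ids, colnames(df)))
  str_table(counts, populations = populations)
}

#' Write a network to GraphML, DOT or a TSV edge list
#'
#' Every edge carries its dissimilarity as a numeric \code{weight}
#' attribute; edges of the (un-augmented) ultrametric network additionally
#' carry their subdominant ultrametric value as \code{wstar} and an
#' \code{exact} flag (FALSE for delta-relaxed extras). Vertices carry a
#' boolean \code{artificial} attribute, TRUE for inserted median vertices
#' (labeled "N1", "N2", ...).
#'
#' The \code{"edge-tsv"} dialect is one line per edge,
#' \code{label1 TAB label2 TAB weight}, labels sorted within a line and lines
#' sorted lexicographically -- byte-identical across runs, so suitable for
#' golden-file comparison.
#'
#' @param x an \code{"ultranet"} fit (its final graph -- after relaxation
#'   and augmentation -- is written), or an edge data.frame with columns
#'   \code{u}, \code{v}, \code{weight}.
#' @param path destination file.
#' @param format \code{"graphml"}, \code{"dot"} or \code{"edge-tsv"}.
#' @export
write_network <- function(x, path, format = c("graphml", "dot", "edge-tsv")) {
  format <- match.arg(format)
  g <- as_igraph_network(x)
  if (igraph::ecount(g) == 0L) stop_validation("refusing to write an empty network")
  if (format == "edge-tsv") {
    ed <- igraph::as_data_frame(g, what = "edges")
    ef <- edge_frame(ed$from, ed$to, ed$weight)
    write_lines_checked(
      sprintf("%s\t%s\t%.15g", ef$u, ef$v, ef$weight), path)
  } else {
    if (format == "dot") {
      # the DOT writer has no boolean type; convert explicitly
      igraph::V(g)$artificial <- as.integer(igraph::V(g)$artificial)
      if ("exact" %in% igraph::edge_attr_names(g))
        igraph::E(g)$exact <- as.integer(igraph::E(g)$exact)
    }
    ok <- tryCatch({
      igraph::write_graph(g, path, format = format)
      TRUE
    }, error = function(e) FALSE)
    if (!ok || !file.exists(path)) stop_io("cannot write network to ", path)
  }
  invisible(path)
}

#' Convert a fit (or edge table) to an igraph object
#'
#' @param x an \code{"ultranet"} fit or an edge data.frame.
#' @return an undirected \code{igraph} graph with \code{weight} (and for
#'   fits \code{wstar}, \code{exact}, \code{artificial}) attributes.
#' @export
as_igraph_network <- function(x) {
  if (inherits(x, "ultranet")) {
    ed <- x$graph
    wl <- edge_weight_lookup_num(x$edges)
    verts <- data.frame(
      name = sort(unique(c(ed$u, ed$v, x$labels)), method = "radix"),
      stringsAsFactors = FALSE)
    verts$artificial <- verts$name %in% x$artificial
    key <- ekey(ed$u, ed$v)
    ed$wstar <- unname(wl$wstar[key])
    ed$exact <- unname(wl$exact[key])
    ed$exact[is.na(ed$exact)] <- FALSE  # star edges of artificial vertices
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
      vertices = verts)
  } else {
    ed <- net_edges(x)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
    igraph::V(g)$artificial <- grepl("^N[0-9]+$", igraph::V(g)$name)
  }
  g
}

edge_weight_lookup_num <- function(edges) {
  key <- ekey(edges$u, edges$v)
  list(wstar = structure(edges$wstar, names = key),
       exact = structure(edges$exact, names = key))
}

write_lines_checked <- function(lines, path) {
  ok <- tryCatch({
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(lines, con)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write to ", path)
  invisible(path)
}
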