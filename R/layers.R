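## Layer matrices: weighted bipartite plant x ant count matrices, one per
## resource type, plus the pooled multilayer matrix.

#' Construct a layer matrix object
#'
#' A `layer_matrix` is an integer matrix with plant species as rows and ant
#' species as columns, cell `[i, j]` holding the number of interaction events
#' between plant `i` and ant `j`. Every row and column has a positive margin;
#' species absent from the layer are not represented.
#'
#' @param A Non-negative integer matrix with row/column names.
#' @param resource One of [resource_types()] or `"multilayer"`.
#' @param sites Character vector of the site ids pooled into this matrix.
#' @return A `layer_matrix`.
#' @export
layer_matrix <- function(A, resource = "multilayer", sites = character()) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  if (any(A < 0)) stop_validation("layer matrix cells must be non-negative")
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop_validation("layer matrix needs plant row names and ant column names")
  }
  if (any(rowSums(A) == 0L) || any(colSums(A) == 0L)) {
    stop_validation("layer matrix may not contain all-zero rows or columns")
  }
  structure(A, class = c("layer_matrix", class(A)),
            resource = resource, sites = sites)
}

#' @export
print.layer_matrix <- function(x, ...) {
  cat(sprintf("<layer_matrix> resource=%s  %d plants x %d ants  F=%d events\n",
              attr(x, "resource"), nrow(x), ncol(x), sum(x)))
  print(unclass_layer(x), ...)
  invisible(x)
}

unclass_layer <- function(A) {
  attr(A, "resource") <- NULL
  attr(A, "sites") <- NULL
  class(A) <- setdiff(class(A), "layer_matrix")
  A
}

as_count_matrix <- function(A) {
  A <- unclass(as.matrix(A))
  attr(A, "resource") <- NULL
  attr(A, "sites") <- NULL
  storage.mode(A) <- "double"
  A
}

#' Build one resource layer from an event table
#'
#' Counts events per plant-ant pair for one resource type, optionally
#' restricted to a subset of sites. Species with no event in the layer are
#' absent from the matrix; species order is lexicographic so construction is
#' deterministic regardless of event order.
#'
#' @param events Validated event data.frame.
#' @param resource One of [resource_types()], or `NULL` to pool all
#'   resource types (the multilayer matrix).
#' @param sites Optional character vector of site ids to keep.
#' @return A [layer_matrix()].
#' @seealso [build_multilayer()]
#' @export
build_layer <- function(events, resource = NULL, sites = NULL) {
  events <- validate_events(events)
  keep <- rep(TRUE, nrow(events))
  if (!is.null(resource)) {
    stopifnot(resource %in% resource_types())
    keep <- keep & events$resource == resource
  }
  if (!is.null(sites)) keep <- keep & events$site_id %in% sites
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop_empty_layer(paste0("no events for resource '",
                            if (is.null(resource)) "multilayer" else resource,
                            "' under the given filter"))
  }
  plants <- sort_species(ev$plant_sp)
  ants <- sort_species(ev$ant_sp)
  A <- matrix(0L, length(plants), length(ants),
              dimnames = list(plants, ants))
  idx <- cbind(match(ev$plant_sp, plants), match(ev$ant_sp, ants))
  for (k in seq_len(nrow(idx))) A[idx[k, 1L], idx[k, 2L]] <- A[idx[k, 1L], idx[k, 2L]] + 1L
  layer_matrix(A,
               resource = if (is.null(resource)) "multilayer" else resource,
               sites = sort_species(ev$site_id))
}

#' Build the full multilayer network
#'
#' Builds one layer per resource type plus the pooled matrix (element-wise
#' sum over all five layers on the union of species, equal to building a
#' single matrix from all events). Resource types with no events yield a
#' `NULL` layer entry.
#'
#' @param events Validated event data.frame (non-empty).
#' @return A `multilayer_network`: list with `layers` (named list over
#'   [resource_types()]) and `pooled` (a [layer_matrix()]).
#' @export
build_multilayer <- function(events) {
  events <- validate_events(events)
  if (nrow(events) == 0L) stop_empty_layer("no events")
  layers <- setNames(vector("list", length(resource_types())), resource_types())
  for (res in resource_types()) {
    layers[[res]] <- tryCatch(build_layer(events, res),
                              antnets_empty_layer = function(e) NULL)
  }
  structure(list(layers = layers, pooled = build_layer(events, NULL)),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("<multilayer_network>\n")
  for (res in names(x$layers)) {
    L <- x$layers[[res]]
    if (is.null(L)) {
      cat(sprintf("  %-12s (empty)\n", res))
    } else {
      cat(sprintf("  %-12s %3d plants x %2d ants  F=%d\n",
                  res, nrow(L), ncol(L), sum(L)))
    }
  }
  cat(sprintf("  %-12s %3d plants x %2d ants  F=%d\n", "pooled",
              nrow(x$pooled), ncol(x$pooled), sum(x$pooled)))
  invisible(x)
}

## ---------------------------------------------------------------- I/O ----

#' Write a layer matrix as TSV
#'
#' First column holds plant labels (`species`), remaining columns are ant
#' labels.
#'
#' @param A A [layer_matrix()] or plain named matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layer_tsv <- function(A, path) {
  M <- as_count_matrix(A)
  df <- data.frame(species = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a layer matrix from TSV
#'
#' @param path Path written by [write_layer_tsv()].
#' @param resource Resource label to attach.
#' @return A [layer_matrix()].
#' @export
read_layer_tsv <- function(path, resource = "multilayer") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1L]]
  layer_matrix(M, resource = resource)
}

#' Export a layer matrix as a bipartite Pajek network
#'
#' Writes a `.net` file with the plant partition first (`*Vertices N NP`
#' header), followed by weighted `*Edges` lines.
#'
#' @param A A [layer_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(A, path) {
  M <- as_count_matrix(A)
  n <- nrow(M); m <- ncol(M)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d %d", n + m, n), con)
  writeLines(sprintf('%d "%s"', seq_len(n), rownames(M)), con)
  writeLines(sprintf('%d "%s"', n + seq_len(m), colnames(M)), con)
  writeLines("*Edges", con)
  pos <- which(M > 0, arr.ind = TRUE)
  pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
  writeLines(sprintf("%d %d %d", pos[, 1L], n + pos[, 2L],
                     M[pos]), con)
  invisible(path)
}

#' Read a bipartite Pajek network back into a layer matrix
#'
#' Inverse of [export_pajek()] for files written by this package.
#'
#' @param path Path to a `.net` file.
#' @param resource Resource label to attach.
#' @return A [layer_matrix()].
#' @export
read_pajek <- function(path, resource = "multilayer") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (tolower(hdr[1L]) != "*vertices" || length(hdr) < 3L) {
    stop_schema("not a bipartite Pajek file written by export_pajek()")
  }
  total <- as.integer(hdr[2L]); n <- as.integer(hdr[3L])
  vl <- lines[2L:(1L + total)]
  labels <- sub('^\\s*\\d+\\s+"(.*)"\\s*$', "\\1", vl)
  edge_start <- which(tolower(trimws(lines)) == "*edges")[1L]
  M <- matrix(0L, n, total - n,
              dimnames = list(labels[seq_len(n)], labels[(n + 1L):total]))
  if (!is.na(edge_start) && edge_start < length(lines)) {
    el <- lines[(edge_start + 1L):length(lines)]
    el <- el[nzchar(trimws(el))]
    for (ln in el) {
      f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
      M[f[1L], f[2L] - n] <- as.integer(f[3L])
    }
  }
  layer_matrix(M, resource = resource)
}
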