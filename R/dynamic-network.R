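#' Construct a dynamic network from per-time snapshot graphs
#'
#' A dynamic network is an ordered series of two or more network snapshots
#' over a shared node universe. Each snapshot is an undirected, weighted
#' igraph graph over the subset of nodes present at that time; a node may be
#' present yet isolated. Presence is derived from snapshot vertex membership.
#'
#' @param snapshots named or unnamed list of undirected \pkg{igraph} graphs,
#'   in time order. Vertices must carry a \code{name} attribute; edges may
#'   carry a \code{weight} attribute (default 1).
#' @param times optional vector of distinct time keys, one per snapshot.
#'   Defaults to \code{seq_along(snapshots)}. The order of \code{snapshots}
#'   is the analysis order: community stitching depends on it.
#' @return An object of class \code{dynamic_network} with components
#'   \code{nodes} (sorted node universe), \code{times}, \code{snapshots}
#'   (list of igraph graphs) and \code{presence} (nodes x times logical
#'   matrix).
#' @export
dynamic_network <- function(snapshots, times = NULL) {
  if (!is.list(snapshots) || length(snapshots) < 2L)
    stop("a dynamic network needs at least 2 snapshots (T >= 2)")
  if (is.null(times)) times <- seq_along(snapshots)
  if (length(times) != length(snapshots))
    stop("'times' must have one entry per snapshot")
  if (anyDuplicated(times))
    stop("time keys must be distinct")
  snapshots <- lapply(seq_along(snapshots), function(i) {
    g <- snapshots[[i]]
    if (!igraph::is_igraph(g))
      stop("snapshot ", i, " is not an igraph graph")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    if (igraph::ecount(g) > 0) {
      if (any(igraph::which_loop(g)))
        stop("self-loops are not allowed (snapshot ", i, ")")
      w <- igraph::E(g)$weight
      if (is.null(w)) {
        igraph::E(g)$weight <- 1
      } else if (any(!is.finite(w)) || any(w <= 0)) {
        stop("edge weights must be finite and > 0 (snapshot ", i, ")")
      }
      g <- igraph::simplify(g, remove.loops = FALSE,
                            edge.attr.comb = list(weight = "sum"))
    }
    g
  })
  nodes <- sort(unique(unlist(lapply(snapshots, function(g) igraph::V(g)$name))))
  if (length(nodes) == 0L) stop("network has no nodes")
  presence <- vapply(snapshots,
                     function(g) nodes %in% igraph::V(g)$name,
                     logical(length(nodes)))
  presence <- matrix(presence, nrow = length(nodes),
                     dimnames = list(nodes, as.character(times)))
  structure(
    list(nodes = nodes, times = times, snapshots = snapshots,
         presence = presence),
    class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("Dynamic network: ", length(x$nodes), " nodes, ",
      length(x$times), " snapshots\n", sep = "")
  ne <- vapply(x$snapshots, igraph::ecount, numeric(1))
  nv <- vapply(x$snapshots, igraph::vcount, numeric(1))
  cat("  times: ", paste(x$times, collapse = ", "), "\n", sep = "")
  cat("  nodes per snapshot:", paste(nv, collapse = ", "), "\n")
  cat("  edges per snapshot:", paste(ne, collapse = ", "), "\n")
  invisible(x)
}

#' Number of time points of a dynamic network
#' @param network a \code{dynamic_network}
#' @return integer, the number of snapshots T
#' @export
n_times <- function(network) length(network$times)

#' Read a dynamic network from per-snapshot edge-list files
#'
#' Each file holds one snapshot as whitespace-separated lines
#' \code{"u v [w]"}; the order of \code{paths} defines the time order and
#' the weight defaults to 1 when omitted. Lines that are empty or start with
#' \code{#} are ignored.
#'
#' @param paths ordered character vector of at least two file paths.
#' @param times optional time keys (default \code{seq_along(paths)}).
#' @return a \code{\link{dynamic_network}}
#' @export
read_edge_lists <- function(paths, times = NULL) {
  if (length(paths) < 2L)
    stop("at least two edge-list files are required (T >= 2)")
  snaps <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    idx <- which(keep)
    if (length(idx) == 0L)
      return(igraph::make_empty_graph(0, directed = FALSE))
    rows <- lapply(idx, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 2L || length(f) > 3L)
        stop("malformed line ", i, " in ", p, ": expected 'u v [w]'")
      w <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3])) else 1
      if (is.na(w))
        stop("non-numeric weight on line ", i, " in ", p)
      if (f[1] == f[2])
        stop("self-loop '", f[1], "' on line ", i, " in ", p)
      data.frame(from = f[1], to = f[2], weight = w,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    igraph::graph_from_data_frame(df, directed = FALSE)
  })
  dynamic_network(snaps, times = times)
}

#' Write a dynamic network as per-snapshot edge-list files
#'
#' Inverse of \code{\link{read_edge_lists}}: one whitespace-separated file
#' per snapshot under \code{dir}, named \code{snapshot_<i>.txt}. Isolated
#' nodes are recorded in a companion \code{nodes_<i>.txt} only when present
#' (so the round trip through edge lists preserves edges, not isolated
#' vertices; use the returned paths with \code{read_edge_lists}).
#'
#' @param network a \code{dynamic_network}
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of written edge-list paths
#' @export
write_edge_lists <- function(network, dir) {
  stopifnot(inherits(network, "dynamic_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(network$snapshots))
  for (i in seq_along(network$snapshots)) {
    g <- network$snapshots[[i]]
    p <- file.path(dir, sprintf("snapshot_%02d.txt", i))
    if (igraph::ecount(g) > 0) {
      el <- igraph::as_data_frame(g, what = "edges")
      txt <- sprintf("%s %s %s", el$from, el$to,
                     format(el$weight, trim = TRUE, scientific = FALSE))
    } else txt <- character(0)
    writeLines(txt, p)
    paths[i] <- p
  }
  invisible(paths)
}
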