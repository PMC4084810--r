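# Dynamic GEXF reader.
#
# Discretisation rule: the observation times are the sorted distinct start
# values of all node/edge spells and timestamps. An element is alive at
# observation time t when one of its spells covers t under the closed-open
# convention [start, end); a timestamp covers exactly its own instant; an
# element with no lifetime information in a dynamic file is alive at every
# observation time. Endpoints of an alive edge are always placed in the
# snapshot, so snapshots never contain dangling edges.

# lifetimes: data.frame(start, end) with -Inf/+Inf for open sides,
# or NULL when the element declares no dynamics
.gexf_lifetime <- function(node) {
  spells <- xml2::xml_find_all(node, "./spells/spell")
  num <- function(x, default) {
    if (is.na(x) || !nzchar(x)) return(default)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("non-numeric time value '", x, "' in GEXF")
    v
  }
  if (length(spells) > 0) {
    st <- vapply(xml2::xml_attr(spells, "start"), num, numeric(1), -Inf)
    en <- vapply(xml2::xml_attr(spells, "end"), num, numeric(1), Inf)
    return(data.frame(start = unname(st), end = unname(en)))
  }
  ts <- xml2::xml_attr(node, "timestamp")
  if (!is.na(ts)) {
    v <- num(ts, NA_real_)
    return(data.frame(start = v, end = v, point = TRUE))
  }
  st <- xml2::xml_attr(node, "start")
  en <- xml2::xml_attr(node, "end")
  if (is.na(st) && is.na(en)) return(NULL)
  data.frame(start = num(st, -Inf), end = num(en, Inf))
}

.gexf_alive <- function(lifetime, t) {
  if (is.null(lifetime)) return(TRUE)  # static element in a dynamic file
  if (!is.null(lifetime$point))
    return(any(lifetime$start == t))
  any(lifetime$start <= t & t < lifetime$end |
        (is.infinite(lifetime$start) & is.infinite(lifetime$end)))
}

#' Read a dynamic network from a dynamic GEXF file
#'
#' Supports GEXF 1.2/1.3 with element lifetimes given as
#' \code{<spells>/<spell start end>} children, \code{start}/\code{end}
#' attributes, or \code{timestamp} attributes. One snapshot is built per
#' distinct observation time, where the observation times are the sorted
#' distinct start values (and timestamps) found in the file. Spells are
#' interpreted closed-open: a spell \code{[start, end)} covers \code{start}
#' but not \code{end}, so single-instant membership is unambiguous.
#'
#' @param path path to a GEXF file
#' @return a \code{\link{dynamic_network}} whose time keys are the
#'   observation times sorted ascending
#' @export
read_dynamic_gexf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)  # malformed XML errors here, with line info
  xml2::xml_ns_strip(doc)
  node_els <- xml2::xml_find_all(doc, ".//graph/nodes/node")
  edge_els <- xml2::xml_find_all(doc, ".//graph/edges/edge")
  if (length(node_els) == 0L) stop("GEXF file contains no nodes: ", path)

  node_ids <- xml2::xml_attr(node_els, "id")
  node_life <- lapply(node_els, .gexf_lifetime)
  edge_src <- xml2::xml_attr(edge_els, "source")
  edge_tgt <- xml2::xml_attr(edge_els, "target")
  edge_w <- suppressWarnings(as.numeric(xml2::xml_attr(edge_els, "weight")))
  edge_w[is.na(edge_w)] <- 1
  edge_life <- lapply(edge_els, .gexf_lifetime)

  starts <- unlist(lapply(c(node_life, edge_life), function(lt) {
    if (is.null(lt)) return(numeric(0))
    lt$start[is.finite(lt$start)]
  }))
  if (length(starts) == 0L)
    stop("GEXF file has no dynamics (no spells, timestamps or start/end ",
         "attributes); for static snapshots use read_edge_lists() with one ",
         "file per time point")
  times <- sort(unique(starts))
  if (length(times) < 2L)
    stop("only ", length(times), " observation time found; a dynamic ",
         "network needs T >= 2")

  snaps <- lapply(times, function(t) {
    e_alive <- vapply(edge_life, .gexf_alive, logical(1), t = t)
    n_alive <- vapply(node_life, .gexf_alive, logical(1), t = t)
    verts <- unique(c(node_ids[n_alive],
                      edge_src[e_alive], edge_tgt[e_alive]))
    if (any(e_alive)) {
      df <- data.frame(from = edge_src[e_alive], to = edge_tgt[e_alive],
                       weight = edge_w[e_alive], stringsAsFactors = FALSE)
      if (any(df$from == df$to))
        stop("self-loop in GEXF edge list at time ", t)
      igraph::graph_from_data_frame(
        df, directed = FALSE,
        vertices = data.frame(name = verts, stringsAsFactors = FALSE))
    } else {
      igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(verts)
    }
  })
  dynamic_network(snaps, times = times)
}
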