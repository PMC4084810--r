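# small graph builders used across tests

g_from_edges <- function(..., weights = NULL) {
  el <- do.call(rbind, lapply(list(...), function(e) e))
  df <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  if (!is.null(weights)) df$weight <- weights
  igraph::graph_from_data_frame(df, directed = FALSE)
}

# two disjoint triangles a1-a2-a3, b1-b2-b3
two_triangles <- function() {
  g_from_edges(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
               c("b1", "b2"), c("b2", "b3"), c("b1", "b3"))
}

# two k-cliques joined by a single bridge edge
two_cliques <- function(k = 4) {
  a <- paste0("a", seq_len(k)); b <- paste0("b", seq_len(k))
  edges <- list()
  for (nodes in list(a, b))
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      edges <- c(edges, list(c(nodes[i], nodes[j])))
  edges <- c(edges, list(c(a[1], b[1])))
  do.call(g_from_edges, edges)
}

write_snapshot_files <- function(lines_per_file, dir = tempfile("net_")) {
  dir.create(dir)
  vapply(seq_along(lines_per_file), function(i) {
    p <- file.path(dir, sprintf("s%02d.txt", i))
    writeLines(lines_per_file[[i]], p)
    p
  }, character(1))
}

# partitions built by hand from group node-set lists, for matcher tests
partitions_from_groups <- function(groups_per_time) {
  lapply(seq_along(groups_per_time), function(t) {
    gs <- groups_per_time[[t]]
    ntg <- integer(0)
    for (i in seq_along(gs))
      ntg[gs[[i]]] <- i
    structure(list(time = t, groups = gs,
                   node_to_group = setNames(as.integer(ntg), names(ntg)),
                   modularity = NA_real_),
              class = "group_partition")
  })
}
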