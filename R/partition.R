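# Stage 1: independent per-snapshot partitioning by Louvain modularity
# optimisation. The optimiser is implemented here (rather than delegated)
# so that the node-visit order is controlled by an explicit seed and the
# downstream matching stage is fully deterministic; tie moves keep the
# current community. igraph's implementation is used only as an independent
# cross-check in the test suite.

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over communities c of w_in(c)/W - (d(c)/(2W))^2, where W is the
#' total edge weight, w_in(c) the weight of edges inside c and d(c) the sum
#' of weighted degrees of its members. Invariant to community relabelling.
#'
#' @param snapshot an undirected weighted igraph graph with >= 1 edge
#' @param partition named vector mapping every vertex name to a group label
#' @return Q, a real number in [-0.5, 1]
#' @export
modularity_q <- function(snapshot, partition) {
  stopifnot(igraph::is_igraph(snapshot))
  nodes <- igraph::V(snapshot)$name
  if (!all(nodes %in% names(partition)))
    stop("partition must cover all vertices of the snapshot")
  w <- igraph::E(snapshot)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(snapshot))
  W <- sum(w)
  if (igraph::ecount(snapshot) == 0L || W <= 0)
    stop("modularity is undefined on a graph with zero total edge weight")
  memb <- partition[nodes]
  el <- igraph::as_edgelist(snapshot, names = TRUE)
  same <- memb[el[, 1]] == memb[el[, 2]]
  deg <- igraph::strength(snapshot, weights = w)
  d_c <- tapply(deg, memb[nodes], sum)
  sum(w[same]) / W - sum((d_c / (2 * W))^2)
}

# run body with a private RNG stream; caller's .Random.seed untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# one Louvain level: local moves on an adjacency structure.
# adj: list per node of data.frame(nb, w); k: weighted degrees incl. 2*self;
# self: self-loop weights (aggregated graphs); W: total weight.
# order: node visit order. Returns community assignment (integer).
.louvain_level <- function(adj, k, self, W, order) {
  n <- length(adj)
  comm <- seq_len(n)
  tot <- k  # sum of degrees per community
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in order) {
      ci <- comm[i]
      nb <- adj[[i]]
      if (nrow(nb) == 0L) next
      # weight from i to each neighbouring community
      wcom <- tapply(nb$w, comm[nb$nb], sum)
      cands <- as.integer(names(wcom))
      tot[ci] <- tot[ci] - k[i]
      w_self <- if (ci %in% cands) wcom[[as.character(ci)]] else 0
      gain_stay <- w_self / W - tot[ci] * k[i] / (2 * W^2)
      gains <- wcom / W - tot[cands] * k[i] / (2 * W^2)
      best <- max(gains)
      if (best > gain_stay + 1e-12) {
        # ties among candidate communities: lowest community id
        cb <- min(cands[gains >= best - 1e-12])
        comm[i] <- cb
        tot[cb] <- tot[cb] + k[i]
        improved <- TRUE
      } else {
        tot[ci] <- tot[ci] + k[i]
      }
    }
  }
  comm
}

# aggregate: collapse communities to super-nodes; returns list(adj, k, self,
# map) where map[i] = super-node of original node i
.louvain_aggregate <- function(edges, comm) {
  labs <- sort(unique(comm))
  map <- match(comm, labs)
  if (nrow(edges) > 0) {
    a <- pmin(map[edges$i], map[edges$j])
    b <- pmax(map[edges$i], map[edges$j])
    agg <- stats::aggregate(w ~ a + b, data.frame(a = a, b = b, w = edges$w),
                            sum)
  } else {
    agg <- data.frame(a = integer(0), b = integer(0), w = numeric(0))
  }
  list(edges = data.frame(i = agg$a, j = agg$b, w = agg$w), map = map,
       n = length(labs))
}

.adj_from_edges <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- data.frame(nb = integer(0), w = numeric(0))
  self <- numeric(n)
  if (nrow(edges) > 0) {
    loops <- edges$i == edges$j
    self[edges$i[loops]] <- self[edges$i[loops]] + edges$w[loops]
    e <- edges[!loops, , drop = FALSE]
    both <- data.frame(a = c(e$i, e$j), b = c(e$j, e$i), w = c(e$w, e$w))
    sp <- split(both[c("b", "w")], both$a)
    for (nm in names(sp))
      adj[[as.integer(nm)]] <- data.frame(nb = sp[[nm]]$b, w = sp[[nm]]$w)
  }
  k <- vapply(adj, function(d) sum(d$w), numeric(1)) + 2 * self
  list(adj = adj, k = k, self = self)
}

#' Partition one snapshot into groups by Louvain modularity optimisation
#'
#' Greedy local moves followed by community aggregation, repeated until no
#' move improves Q. The node visit order at each level is drawn from a
#' private RNG stream seeded by \code{seed} over the lexicographically
#' sorted vertex names, so the result is deterministic for a fixed seed and
#' independent of the input vertex order. A move is only made when it
#' strictly improves Q (ties keep the current community). Isolated nodes
#' form singleton groups.
#'
#' @param snapshot an undirected weighted igraph graph (>= 1 node), or an
#'   empty graph (yielding an empty partition with 0 groups)
#' @param seed integer controlling the node-visit order
#' @return an object of class \code{group_partition}: list with \code{time}
#'   (filled by \code{\link{partition_all}}), \code{groups} (list of node-id
#'   character vectors, group ids 1..G), \code{node_to_group} (named integer
#'   vector), and \code{modularity} (NA for graphs with no edges)
#' @export
louvain_partition <- function(snapshot, seed = 1L) {
  stopifnot(igraph::is_igraph(snapshot))
  nodes <- sort(igraph::V(snapshot)$name)
  n <- length(nodes)
  if (n == 0L) {
    return(structure(list(time = NA, groups = list(),
                          node_to_group = integer(0), modularity = NA_real_),
                     class = "group_partition"))
  }
  el <- igraph::as_edgelist(snapshot, names = TRUE)
  w <- igraph::E(snapshot)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  edges <- data.frame(i = match(el[, 1], nodes), j = match(el[, 2], nodes),
                      w = w)
  if (nrow(edges) == 0L) {
    # modularity cannot distinguish partitions without edges: singletons
    ntg <- stats::setNames(seq_len(n), nodes)
    return(structure(list(time = NA, groups = as.list(nodes),
                          node_to_group = ntg, modularity = NA_real_),
                     class = "group_partition"))
  }
  W <- sum(edges$w)
  assign_final <- seq_len(n)  # original node -> current super-node
  level_edges <- edges
  level_n <- n
  .with_seed(seed, {
    repeat {
      a <- .adj_from_edges(level_edges, level_n)
      ord <- sample.int(level_n)
      comm <- .louvain_level(a$adj, a$k, a$self, W, ord)
      if (length(unique(comm)) == level_n) break  # no merge at this level
      agg <- .louvain_aggregate(level_edges, comm)
      assign_final <- agg$map[comm[assign_final]]
      level_edges <- agg$edges
      level_n <- agg$n
      if (level_n == 1L) break
    }
  })
  # canonical group ids: order of first appearance over sorted node names
  first <- match(unique(assign_final), assign_final)
  relabel <- stats::setNames(rank(first), unique(assign_final))
  gid <- as.integer(relabel[as.character(assign_final)])
  ntg <- stats::setNames(gid, nodes)
  groups <- split(nodes, gid)
  names(groups) <- NULL
  part <- structure(list(time = NA, groups = groups, node_to_group = ntg,
                         modularity = NA_real_),
                    class = "group_partition")
  part$modularity <- modularity_q(snapshot, ntg)
  part
}

#' @export
print.group_partition <- function(x, ...) {
  cat("Snapshot partition",
      if (!is.na(x$time)) paste0(" (time ", x$time, ")"), ": ",
      length(x$groups), " groups over ", length(x$node_to_group),
      " nodes; Q = ", format(x$modularity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Partition every snapshot of a dynamic network
#'
#' Each snapshot is partitioned independently with the same seed, so the
#' partition at time t depends only on snapshot t and the seed.
#'
#' @param network a \code{\link{dynamic_network}}
#' @param seed integer passed to \code{\link{louvain_partition}}
#' @return list of \code{group_partition}, ordered by time
#' @export
partition_all <- function(network, seed = 1L) {
  stopifnot(inherits(network, "dynamic_network"))
  lapply(seq_along(network$times), function(i) {
    p <- louvain_partition(network$snapshots[[i]], seed = seed)
    p$time <- network$times[i]
    p
  })
}
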