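# Planted-partition (SBM-style) generator for dynamic networks. Each node
# has a base community; a cohort is a disjoint subset of nodes that moves
# synchronously through a prescribed sequence of target communities, i.e. a
# planted sub-community. Edges are drawn independently per snapshot with
# probability p_in inside the effective blocks and p_out between; dropout
# removes a node (vertex and incident edges) from a snapshot entirely.

#' Generate a dynamic network with planted communities and cohorts
#'
#' @param n_communities integer >= 2, number of planted communities
#' @param nodes_per_community integer >= 3
#' @param n_times integer >= 2, number of snapshots
#' @param p_in within-block edge probability
#' @param p_out between-block edge probability; must be < p_in
#' @param cohorts list of cohorts, each a list with \code{nodes} (integer
#'   indices into the node universe, disjoint across cohorts) and
#'   \code{targets} (integer vector of length \code{n_times} of community
#'   ids in 1..n_communities, the block the cohort occupies at each time)
#' @param p_absent per (node, time) dropout probability in [0, 1)
#' @param seed integer; the generator is deterministic for a fixed seed
#' @return list with \code{network} (a \code{\link{dynamic_network}}),
#'   \code{membership} (planted nodes x times community matrix, NA where
#'   dropped out) and \code{cohort} (named integer vector, NA for
#'   non-cohort nodes)
#' @export
synthetic_dynamic_network <- function(n_communities = 2L,
                                      nodes_per_community = 10L,
                                      n_times = 2L,
                                      p_in = 0.9, p_out = 0.05,
                                      cohorts = list(),
                                      p_absent = 0, seed = 1L) {
  stopifnot(n_communities >= 2L, nodes_per_community >= 3L, n_times >= 2L)
  if (!(p_out < p_in)) stop("p_out must be < p_in")
  if (p_absent < 0 || p_absent >= 1) stop("p_absent must lie in [0, 1)")
  n <- n_communities * nodes_per_community
  nodes <- sprintf("n%03d", seq_len(n))
  base <- rep(seq_len(n_communities), each = nodes_per_community)
  cohort_of <- stats::setNames(rep(NA_integer_, n), nodes)
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    if (any(!is.na(cohort_of[co$nodes])))
      stop("cohort node subsets must be disjoint")
    if (length(co$targets) != n_times)
      stop("cohort ", ci, ": 'targets' must have length n_times")
    if (any(co$targets < 1 | co$targets > n_communities))
      stop("cohort ", ci, ": target community ids must lie in 1..",
           n_communities)
    cohort_of[co$nodes] <- ci
  }
  membership <- matrix(base, nrow = n, ncol = n_times,
                       dimnames = list(nodes, as.character(seq_len(n_times))))
  for (ci in seq_along(cohorts))
    membership[cohorts[[ci]]$nodes, ] <-
      matrix(cohorts[[ci]]$targets, nrow = length(cohorts[[ci]]$nodes),
             ncol = n_times, byrow = TRUE)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  snaps <- vector("list", n_times)
  .with_seed(seed, {
    for (t in seq_len(n_times)) {
      present <- if (p_absent > 0) stats::runif(n) >= p_absent
                 else rep(TRUE, n)
      if (!any(present))
        stop("dropout produced an empty snapshot at time ", t)
      blk <- membership[, t]
      membership[!present, t] <- NA_integer_
      same <- blk[pairs[, 1]] == blk[pairs[, 2]]
      p <- ifelse(same, p_in, p_out)
      keep <- stats::runif(nrow(pairs)) < p &
        present[pairs[, 1]] & present[pairs[, 2]]
      df <- data.frame(from = nodes[pairs[keep, 1]],
                       to = nodes[pairs[keep, 2]],
                       stringsAsFactors = FALSE)
      snaps[[t]] <- igraph::graph_from_data_frame(
        df, directed = FALSE,
        vertices = data.frame(name = nodes[present],
                              stringsAsFactors = FALSE))
    }
  })
  list(network = dynamic_network(snaps),
       membership = membership, cohort = cohort_of)
}

#' Agreement between inferred and planted memberships (mean adjusted Rand)
#'
#' Computes the adjusted Rand index between the inferred and planted
#' partitions at each time point (over the nodes present at that time) and
#' averages over time. 1 means the partitions are identical (up to
#' relabelling) at every time point; 0 is the chance level.
#'
#' @param inferred,planted nodes x times integer membership matrices with
#'   identical dimensions, row names and NA (absence) support
#' @return real in [-1, 1]
#' @export
evaluate_recovery <- function(inferred, planted) {
  if (!is.matrix(inferred) || !is.matrix(planted) ||
      !identical(dim(inferred), dim(planted)))
    stop("'inferred' and 'planted' must be membership matrices of ",
         "identical dimensions")
  if (!is.null(rownames(inferred)) && !is.null(rownames(planted))) {
    planted <- planted[rownames(inferred), , drop = FALSE]
  }
  if (!identical(is.na(inferred), is.na(planted)))
    stop("presence/absence support of the two matrices differs")
  ari_t <- vapply(seq_len(ncol(inferred)), function(t) {
    a <- inferred[, t]; b <- planted[, t]
    ok <- !is.na(a)
    a <- a[ok]; b <- b[ok]
    if (length(a) == 0L) return(NA_real_)
    if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
    mclust::adjustedRandIndex(a, b)
  }, numeric(1))
  mean(ari_t, na.rm = TRUE)
}
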