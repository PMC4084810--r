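# Stage 1, stitching: groups from independent snapshot partitions are
# assigned persistent community identifiers by Jaccard similarity to groups
# at earlier time points, searched one time point at a time (most recent
# first) up to a configurable look-back depth.

#' Jaccard index of two node sets
#'
#' |a intersect b| / |a union b|; 1 means the two groups are identical.
#'
#' @param a,b character vectors of node ids, not both empty
#' @return real in [0, 1]
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard index is undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Match per-snapshot groups into persistent communities
#'
#' The groups of the first snapshot seed communities 1..G1. For each later
#' time t, candidate matches for the still-unmatched groups are evaluated
#' one earlier time point at a time, starting at t-1 and stepping back, but
#' never more than \code{search_depth} steps. Within an earlier time point,
#' pairs with Jaccard index >= \code{jaccard_threshold} (and > 0: a
#' zero-overlap pair is never a match) are assigned greedily in descending
#' Jaccard order, one-to-one in that time point's groups; ties are broken by
#' the lower group id at t, then the lower earlier group id. Groups still
#' unmatched continue the backward search; groups unmatched after the whole
#' search receive fresh community ids in (time, group id) order.
#'
#' @param partitions list of \code{group_partition} ordered by time (as from
#'   \code{\link{partition_all}})
#' @param jaccard_threshold real in [0, 1]; default 0.4
#' @param search_depth positive integer or \code{Inf} (default: search all
#'   the way back to the first snapshot); depth 1 means only t-1 is searched
#' @return an object of class \code{community_timeline}: list with
#'   \code{times}, \code{community_of_group} (per time, integer vector over
#'   group ids), \code{n_communities}, \code{membership} (nodes x times
#'   integer matrix, NA where a node is absent) and \code{nodes}
#' @export
match_groups <- function(partitions, jaccard_threshold = 0.4,
                         search_depth = Inf) {
  if (length(partitions) < 2L)
    stop("at least two partitions are required")
  if (!all(vapply(partitions, inherits, logical(1), "group_partition")))
    stop("'partitions' must be a list of group_partition objects")
  times <- lapply(partitions, `[[`, "time")
  if (any(vapply(times, function(t) length(t) != 1L || is.na(t), logical(1))))
    stop("every partition must carry a time key")
  times <- unlist(times)
  if (anyDuplicated(times))
    stop("partitions must carry distinct time keys")
  if (is.numeric(times) && any(diff(times) <= 0))
    stop("partitions must be ordered by ascending time")
  if (!is.numeric(jaccard_threshold) || jaccard_threshold < 0 ||
      jaccard_threshold > 1)
    stop("'jaccard_threshold' must lie in [0, 1]")
  if (!(is.infinite(search_depth) ||
        (search_depth == round(search_depth) && search_depth >= 1)))
    stop("'search_depth' must be a positive integer or Inf")

  TT <- length(partitions)
  cog <- vector("list", TT)  # community of group, per time
  g1 <- length(partitions[[1]]$groups)
  cog[[1]] <- seq_len(g1)
  n_comm <- g1
  for (t in seq(2L, TT)) {
    gt <- partitions[[t]]$groups
    cog[[t]] <- rep(NA_integer_, length(gt))
    unmatched <- seq_along(gt)
    max_depth <- min(t - 1L, search_depth)
    d <- 1L
    while (length(unmatched) > 0L && d <= max_depth) {
      tp <- t - d
      gp <- partitions[[tp]]$groups
      if (length(gp) > 0L) {
        # all admissible (current group, earlier group) pairs at this depth
        pairs <- expand.grid(cur = unmatched, prev = seq_along(gp))
        pairs$j <- mapply(function(ci, pj) jaccard_index(gt[[ci]], gp[[pj]]),
                          pairs$cur, pairs$prev)
        pairs <- pairs[pairs$j >= jaccard_threshold & pairs$j > 0, ,
                       drop = FALSE]
        # greedy descending Jaccard; ties: lower current id, lower earlier id
        pairs <- pairs[order(-pairs$j, pairs$cur, pairs$prev), , drop = FALSE]
        used_prev <- logical(length(gp))
        for (r in seq_len(nrow(pairs))) {
          ci <- pairs$cur[r]; pj <- pairs$prev[r]
          if (is.na(cog[[t]][ci]) && !used_prev[pj]) {
            cog[[t]][ci] <- cog[[tp]][pj]
            used_prev[pj] <- TRUE
          }
        }
        unmatched <- which(is.na(cog[[t]]))
      }
      d <- d + 1L
    }
    for (ci in unmatched) {  # fresh communities, in (time, group id) order
      n_comm <- n_comm + 1L
      cog[[t]][ci] <- n_comm
    }
  }

  nodes <- sort(unique(unlist(lapply(partitions,
                                     function(p) names(p$node_to_group)))))
  membership <- matrix(NA_integer_, nrow = length(nodes), ncol = TT,
                       dimnames = list(nodes, as.character(times)))
  for (t in seq_len(TT)) {
    ntg <- partitions[[t]]$node_to_group
    if (length(ntg) > 0)
      membership[names(ntg), t] <- cog[[t]][ntg]
  }
  structure(list(times = times, community_of_group = cog,
                 n_communities = n_comm, membership = membership,
                 nodes = nodes, jaccard_threshold = jaccard_threshold,
                 search_depth = search_depth),
            class = "community_timeline")
}

#' @export
print.community_timeline <- function(x, ...) {
  cat("Community timeline: ", x$n_communities, " communities over ",
      length(x$times), " time points, ", length(x$nodes), " nodes\n",
      sep = "")
  cat("  Jaccard threshold ", x$jaccard_threshold,
      ", search depth ",
      if (is.infinite(x$search_depth)) "unlimited" else x$search_depth,
      "\n", sep = "")
  invisible(x)
}

#' Build a community timeline directly from a membership matrix
#'
#' Constructs the \code{community_timeline} that stage 1 would have produced
#' had each community formed exactly one group per time point: useful for
#' specifying stage-2 scenarios (and benchmarks) directly as node x time
#' community matrices.
#'
#' @param membership integer matrix, nodes x times; entries are community
#'   ids (positive integers) or NA where the node is absent
#' @param times optional time keys (default: column names or 1..T)
#' @return a \code{community_timeline}
#' @export
timeline_from_membership <- function(membership, times = NULL) {
  stopifnot(is.matrix(membership), ncol(membership) >= 2L)
  if (is.null(rownames(membership)))
    rownames(membership) <- sprintf("n%03d", seq_len(nrow(membership)))
  if (is.null(times)) {
    times <- if (!is.null(colnames(membership)))
      colnames(membership) else seq_len(ncol(membership))
  }
  ids <- sort(unique(as.integer(membership[!is.na(membership)])))
  if (length(ids) == 0L || any(ids < 1))
    stop("membership must contain positive integer community ids")
  cog <- lapply(seq_len(ncol(membership)), function(t) {
    present <- sort(unique(membership[!is.na(membership[, t]), t]))
    as.integer(present)
  })
  structure(list(times = times, community_of_group = cog,
                 n_communities = max(ids),
                 membership = membership,
                 nodes = rownames(membership),
                 jaccard_threshold = NA_real_, search_depth = NA),
            class = "community_timeline")
}

#' Is a community present at a time point?
#'
#' A community is present at time t when at least one group at t carries its
#' identifier. Used by the cost model's absence exemption: a node absent
#' while its home community is also absent incurs no cost.
#'
#' @param timeline a \code{community_timeline}
#' @param community a community id in 1..n_communities
#' @param t index of the time point (1..T) or a time key
#' @return logical
#' @export
community_present <- function(timeline, community, t) {
  stopifnot(inherits(timeline, "community_timeline"))
  if (!(community %in% seq_len(timeline$n_communities)))
    stop("unknown community id: ", community)
  ti <- if (is.numeric(t) && length(t) == 1L && t == round(t) &&
            t >= 1 && t <= length(timeline$times)) as.integer(t)
        else match(t, timeline$times)
  if (is.na(ti)) stop("unknown time: ", t)
  community %in% timeline$community_of_group[[ti]]
}

# community x time logical presence matrix (internal)
.community_presence <- function(timeline) {
  TT <- length(timeline$times)
  m <- matrix(FALSE, nrow = timeline$n_communities, ncol = TT)
  for (t in seq_len(TT))
    m[timeline$community_of_group[[t]], t] <- TRUE
  m
}
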