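# Stage 2, option B: the sub-community model. Every node takes the
# community of its group at each time point (no cost accounting); nodes
# whose full membership trajectories -- including absences -- are identical
# form sub-communities. A node with a constant trajectory keeps its
# original community as its label; a node with a unique non-constant
# trajectory stays unassigned.

#' Per-node community membership trajectories
#'
#' @param timeline a \code{community_timeline}
#' @return integer matrix, nodes x times; entry is the community of the
#'   node's group at that time, NA where the node is absent
#' @export
membership_patterns <- function(timeline) {
  stopifnot(inherits(timeline, "community_timeline"))
  timeline$membership
}

#' Node promiscuity: the frequency of community changes
#'
#' Counts the consecutive time-point pairs at which the node is present at
#' both times with a different community, normalised by T - 1. Transitions
#' into or out of absence do not count as changes.
#'
#' @param pattern integer vector of length T >= 2 (NA = absent), or a
#'   pattern matrix as returned by \code{\link{membership_patterns}}
#' @return real in [0, 1] (vector when a matrix is given)
#' @export
node_promiscuity <- function(pattern) {
  if (is.matrix(pattern))
    return(apply(pattern, 1, node_promiscuity))
  TT <- length(pattern)
  if (TT < 2L) stop("promiscuity needs a trajectory of length T >= 2")
  a <- pattern[-TT]; b <- pattern[-1]
  both <- !is.na(a) & !is.na(b)
  sum(a[both] != b[both]) / (TT - 1)
}

#' Group nodes with identical membership patterns into sub-communities
#'
#' Two nodes share a sub-community iff their full trajectories are
#' identical, absences included. A node whose trajectory never changes over
#' the times it is present keeps its original (first observed) community as
#' its label; a non-constant trajectory shared with at least one other node
#' founds a new sub-community (ids continue above the community range,
#' issued in order of the first member's node id); a unique non-constant
#' trajectory is left unassigned (NA label).
#'
#' @param patterns a pattern matrix from \code{\link{membership_patterns}},
#'   or a \code{community_timeline}
#' @param n_communities number of stage-1 communities (taken from the
#'   timeline when one is supplied); new sub-community ids start above it
#' @return an object of class \code{subcommunity_assignment}: list with
#'   \code{pattern}, \code{label} (named integer, NA = unassigned),
#'   \code{is_subcommunity} (TRUE where the label is a new sub-community id),
#'   \code{original} (first observed community per node), \code{sizes}
#'   (member count per label, plus an \code{"unassigned"} count),
#'   \code{promiscuity}, \code{n_communities} and \code{n_subcommunities}
#' @export
derive_subcommunities <- function(patterns, n_communities = NULL) {
  if (inherits(patterns, "community_timeline")) {
    n_communities <- patterns$n_communities
    patterns <- membership_patterns(patterns)
  }
  stopifnot(is.matrix(patterns))
  if (is.null(n_communities))
    n_communities <- max(patterns, na.rm = TRUE)
  nodes <- rownames(patterns)
  key <- apply(patterns, 1, function(r) paste(ifelse(is.na(r), "-", r),
                                              collapse = "|"))
  observed <- apply(patterns, 1, function(r) r[!is.na(r)][1])
  constant <- apply(patterns, 1, function(r) {
    v <- r[!is.na(r)]
    length(unique(v)) <= 1L
  })
  label <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  is_sub <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  label[constant] <- as.integer(observed[constant])
  nonconst <- which(!constant)
  if (length(nonconst)) {
    counts <- table(key[nonconst])
    shared <- names(counts)[counts >= 2L]
    # new ids in order of the first member's node id (row order is the
    # sorted node universe, so the first row of each pattern decides)
    firsts <- vapply(shared, function(k) min(nonconst[key[nonconst] == k]),
                     integer(1))
    shared <- shared[order(firsts)]
    next_id <- n_communities
    for (k in shared) {
      next_id <- next_id + 1L
      idx <- nonconst[key[nonconst] == k]
      label[idx] <- next_id
      is_sub[idx] <- TRUE
    }
  }
  assigned <- !is.na(label)
  sizes <- table(label[assigned])
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  sizes <- c(sizes, unassigned = sum(!assigned))
  structure(list(pattern = patterns, label = label,
                 is_subcommunity = is_sub,
                 original = stats::setNames(as.integer(observed), nodes),
                 sizes = sizes,
                 promiscuity = node_promiscuity(patterns),
                 n_communities = n_communities,
                 n_subcommunities = sum(is_sub & !duplicated(label))),
            class = "subcommunity_assignment")
}

#' @export
print.subcommunity_assignment <- function(x, ...) {
  n <- length(x$label)
  cat("Sub-community assignment: ", n, " nodes x ", ncol(x$pattern),
      " time points\n", sep = "")
  cat("  ", x$n_subcommunities, " sub-communities above ",
      x$n_communities, " communities; ",
      sum(!is.na(x$label) & !x$is_subcommunity),
      " nodes keep their original community; ",
      sum(is.na(x$label)), " unassigned (unique pattern)\n", sep = "")
  cat("  mean node promiscuity: ",
      format(mean(x$promiscuity), digits = 4), "\n", sep = "")
  invisible(x)
}
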