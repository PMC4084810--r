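#' Sweep the Jaccard matching threshold
#'
#' Stage-1 partitioning does not depend on the matching threshold, so the
#' snapshots are partitioned once and the group matching plus sub-community
#' model are re-run for each threshold. Mirrors the usual diagnostic sweep:
#' as the threshold rises, groups match less often, communities multiply
#' and shrink, and node promiscuity rises.
#'
#' @param network a \code{\link{dynamic_network}}
#' @param thresholds ascending vector of Jaccard thresholds in [0, 1]
#' @param search_depth look-back bound passed to \code{\link{match_groups}}
#' @param seed Louvain seed
#' @param partitions optional precomputed stage-1 partitions (from
#'   \code{\link{partition_all}}); when supplied, \code{network}/\code{seed}
#'   are not used for partitioning
#' @return data.frame with one row per threshold: \code{threshold},
#'   \code{n_communities}, \code{mean_community_size} (distinct member
#'   nodes per community, averaged), \code{n_subcommunities},
#'   \code{mean_subcommunity_size}, \code{mean_promiscuity}
#' @export
sweep_thresholds <- function(network = NULL, thresholds,
                             search_depth = Inf, seed = 1L,
                             partitions = NULL) {
  if (length(thresholds) == 0L) stop("'thresholds' must be non-empty")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending")
  if (is.null(partitions)) {
    stopifnot(inherits(network, "dynamic_network"))
    partitions <- partition_all(network, seed = seed)
  }
  rows <- lapply(thresholds, function(th) {
    tl <- match_groups(partitions, jaccard_threshold = th,
                       search_depth = search_depth)
    sub <- derive_subcommunities(tl)
    memb <- tl$membership
    csize <- vapply(seq_len(tl$n_communities), function(cid)
      sum(apply(memb == cid, 1, any, na.rm = TRUE)), integer(1))
    ssize <- sub$sizes[names(sub$sizes) != "unassigned"]
    ssize <- ssize[as.integer(names(ssize)) > tl$n_communities]
    data.frame(threshold = th,
               n_communities = tl$n_communities,
               mean_community_size = mean(csize),
               n_subcommunities = sub$n_subcommunities,
               mean_subcommunity_size =
                 if (length(ssize)) mean(ssize) else NA_real_,
               mean_promiscuity = mean(sub$promiscuity))
  })
  do.call(rbind, rows)
}
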