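#' Fit the two-stage dynamic community model to a dynamic network
#'
#' The front-end of the package. Stage 1 partitions every snapshot
#' independently by Louvain modularity optimisation
#' (\code{\link{partition_all}}) and stitches the per-snapshot groups into
#' persistent communities by Jaccard matching with a bounded look-back
#' (\code{\link{match_groups}}). Stage 2 assigns node trajectories either
#' by the cost model (\code{\link{assign_home}}: switch/visit/absence costs
#' minimised per node by dynamic programming; appropriate when communities
#' can be assumed stable) or by the sub-community model
#' (\code{\link{derive_subcommunities}}: nodes sharing an identical
#' membership pattern form sub-communities; appropriate when stability
#' cannot be assumed).
#'
#' @param network a \code{\link{dynamic_network}}
#' @param model \code{"cost"} or \code{"subcommunity"}
#' @param jaccard_threshold Jaccard index above which two groups match
#'   (default 0.4)
#' @param search_depth how many time points the matcher may look back
#'   (default unlimited)
#' @param switch_cost,visit_cost,absence_cost cost-model parameters
#'   (default 1 each; ignored by the sub-community model)
#' @param seed integer controlling the Louvain node-visit order
#' @return an object of class \code{tempcomm_fit}: list with the
#'   \code{network}, the stage-1 \code{partitions} and \code{timeline}, the
#'   chosen \code{model} and its \code{assignment}, and the parameters
#' @seealso \code{\link{summary.tempcomm_fit}},
#'   \code{\link{plot.tempcomm_fit}}, \code{\link{sweep_thresholds}}
#' @examples
#' sim <- synthetic_dynamic_network(n_communities = 2,
#'                                  nodes_per_community = 6,
#'                                  n_times = 3, p_in = 0.95, p_out = 0.02,
#'                                  seed = 7)
#' fit <- track_communities(sim$network, model = "subcommunity", seed = 7)
#' fit
#' @export
track_communities <- function(network,
                              model = c("cost", "subcommunity"),
                              jaccard_threshold = 0.4,
                              search_depth = Inf,
                              switch_cost = 1, visit_cost = 1,
                              absence_cost = 1,
                              seed = 1L) {
  stopifnot(inherits(network, "dynamic_network"))
  model <- match.arg(model)
  partitions <- partition_all(network, seed = seed)
  timeline <- match_groups(partitions, jaccard_threshold = jaccard_threshold,
                           search_depth = search_depth)
  assignment <- switch(model,
    cost = assign_home(timeline, switch_cost = switch_cost,
                       visit_cost = visit_cost, absence_cost = absence_cost),
    subcommunity = derive_subcommunities(timeline))
  structure(list(network = network, partitions = partitions,
                 timeline = timeline, model = model,
                 assignment = assignment,
                 params = list(jaccard_threshold = jaccard_threshold,
                               search_depth = search_depth,
                               switch_cost = switch_cost,
                               visit_cost = visit_cost,
                               absence_cost = absence_cost, seed = seed),
                 call = match.call()),
            class = "tempcomm_fit")
}

#' @export
print.tempcomm_fit <- function(x, ...) {
  cat("Two-stage dynamic community fit (", x$model, " model)\n", sep = "")
  cat("  ", length(x$network$nodes), " nodes, ", length(x$network$times),
      " snapshots; ", x$timeline$n_communities, " communities ",
      "(Jaccard threshold ", x$params$jaccard_threshold, ")\n", sep = "")
  if (x$model == "cost") {
    cat("  total cost C = ", format(x$assignment$total_cost),
        "; average cost C/(N*T) = ",
        format(average_cost(x$assignment), digits = 4), "\n", sep = "")
  } else {
    cat("  ", x$assignment$n_subcommunities, " sub-communities; ",
        sum(is.na(x$assignment$label)), " nodes unassigned; mean ",
        "promiscuity ", format(mean(x$assignment$promiscuity), digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' Summarise a dynamic community fit
#'
#' @param object a \code{tempcomm_fit}
#' @param ... unused
#' @return a \code{summary.tempcomm_fit} list with per-snapshot modularity
#'   and group counts, community count and sizes, and the stage-2 summary
#'   (total/average cost, or sub-community counts and promiscuity)
#' @export
summary.tempcomm_fit <- function(object, ...) {
  memb <- object$timeline$membership
  comm_sizes <- vapply(seq_len(object$timeline$n_communities), function(cid)
    sum(apply(memb == cid, 1, any, na.rm = TRUE)), integer(1))
  out <- list(
    model = object$model,
    n_nodes = length(object$network$nodes),
    n_times = length(object$network$times),
    n_groups = vapply(object$partitions, function(p) length(p$groups),
                      integer(1)),
    modularity = vapply(object$partitions, `[[`, numeric(1), "modularity"),
    n_communities = object$timeline$n_communities,
    community_sizes = comm_sizes,
    params = object$params)
  if (object$model == "cost") {
    out$total_cost <- object$assignment$total_cost
    out$average_cost <- average_cost(object$assignment)
    out$node_cost <- object$assignment$node_cost
  } else {
    out$n_subcommunities <- object$assignment$n_subcommunities
    out$n_unassigned <- sum(is.na(object$assignment$label))
    out$mean_promiscuity <- mean(object$assignment$promiscuity)
    out$subcommunity_sizes <-
      object$assignment$sizes[names(object$assignment$sizes) != "unassigned"]
  }
  class(out) <- "summary.tempcomm_fit"
  out
}

#' @export
print.summary.tempcomm_fit <- function(x, ...) {
  cat("Two-stage dynamic community fit (", x$model, " model)\n", sep = "")
  cat("  nodes: ", x$n_nodes, ", time points: ", x$n_times, "\n", sep = "")
  cat("  groups per snapshot: ", paste(x$n_groups, collapse = ", "), "\n",
      sep = "")
  cat("  modularity per snapshot: ",
      paste(format(x$modularity, digits = 3), collapse = ", "), "\n",
      sep = "")
  cat("  communities: ", x$n_communities, " (sizes ",
      paste(x$community_sizes, collapse = ", "), ")\n", sep = "")
  if (x$model == "cost") {
    cat("  total cost C = ", format(x$total_cost), "; average C/(N*T) = ",
        format(x$average_cost, digits = 4), "\n", sep = "")
  } else {
    cat("  sub-communities: ", x$n_subcommunities, "; unassigned nodes: ",
        x$n_unassigned, "\n", sep = "")
    cat("  mean node promiscuity: ", format(x$mean_promiscuity, digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' Plot the membership matrix of a fit
#'
#' Time on the x axis, nodes on the y axis; cells coloured by community
#' (white where the node is absent).
#'
#' @param x a \code{tempcomm_fit}
#' @param ... passed to \code{\link[graphics]{image}}
#' @export
plot.tempcomm_fit <- function(x, ...) {
  memb <- x$timeline$membership
  ids <- sort(unique(memb[!is.na(memb)]))
  z <- matrix(match(memb, ids), nrow = nrow(memb))
  cols <- vapply(ids, community_colour, character(1))
  graphics::image(x = seq_len(ncol(memb)), y = seq_len(nrow(memb)),
                  z = t(z), col = cols, xlab = "time point", ylab = "node",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(memb)), labels = colnames(memb))
  graphics::axis(2, at = seq_len(nrow(memb)), labels = rownames(memb),
                 las = 2, cex.axis = 0.6)
  invisible(x)
}
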