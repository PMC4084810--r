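# Stage 2, option A: the social cost model. Each node is assigned a "home"
# community at every time point so that the total of switch, visit and
# absence costs is minimal. The per-node optimisation is an independent
# dynamic programme over (time, candidate home); candidate homes are the
# communities the node is ever observed in (a home never visited is weakly
# dominated, since it can only add visit and absence costs).
#
# Event accounting at (node n, time t), home trajectory h:
#   switch   h_t != h_{t-1}                     (t >= 2)         cost switch
#   visit    n present, membership(n,t) != h_t                   cost visit
#   absence  n absent,  home community present at t              cost absence
#   exempt   n absent,  home community also absent               no cost
# A switch and a visit can co-occur at the same time step.

#' Assign home-community trajectories by cost minimisation
#'
#' For each node independently, finds the trajectory h_1..h_T over its
#' candidate home communities minimising
#' \deqn{\sum_{t\ge2} s\,[h_t \ne h_{t-1}] + \sum_t v\,[present \wedge
#'   m(n,t) \ne h_t] + \sum_t a\,[absent \wedge h_t\ present]}
#' with switch cost s, visit cost v and absence cost a. Absence while the
#' home community is itself absent costs nothing. Ties between equal-cost
#' trajectories are resolved towards fewer switches, then towards the
#' community the node was observed in earliest (then the lower community
#' id), so the output is canonical.
#'
#' @param timeline a \code{community_timeline}
#' @param switch_cost,visit_cost,absence_cost nonnegative reals, default 1
#' @return an object of class \code{home_assignment}: list with \code{home}
#'   (nodes x times integer matrix; homes persist through absence),
#'   \code{node_cost}, \code{total_cost}, \code{n_nodes}, \code{n_times},
#'   \code{events} (nodes x times character matrix with tags among
#'   \code{none}, \code{switch}, \code{visit}, \code{absence},
#'   \code{exempt-absence}, joined by \code{+} when they co-occur),
#'   per-node event counts, the membership matrix and the costs used
#' @export
assign_home <- function(timeline, switch_cost = 1, visit_cost = 1,
                        absence_cost = 1) {
  stopifnot(inherits(timeline, "community_timeline"))
  costs <- c(switch = switch_cost, visit = visit_cost, absence = absence_cost)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("switch, visit and absence costs must be nonnegative finite reals")
  memb <- timeline$membership
  TT <- ncol(memb)
  nodes <- rownames(memb)
  cpres <- .community_presence(timeline)
  home <- matrix(NA_integer_, nrow = length(nodes), ncol = TT,
                 dimnames = dimnames(memb))
  node_cost <- stats::setNames(numeric(length(nodes)), nodes)
  events <- matrix("none", nrow = length(nodes), ncol = TT,
                   dimnames = dimnames(memb))

  for (ni in seq_along(nodes)) {
    mrow <- memb[ni, ]
    obs_t <- which(!is.na(mrow))
    if (length(obs_t) == 0L)
      stop("node '", nodes[ni], "' is never a member of any group; ",
           "it has no candidate home community")
    # candidates ordered by first observation time, then community id
    first_seen <- tapply(obs_t, mrow[obs_t], min)
    cand <- as.integer(names(first_seen))[order(first_seen,
                                                as.integer(names(first_seen)))]
    K <- length(cand)
    # stage costs S[k, t]
    S <- matrix(0, nrow = K, ncol = TT)
    for (t in seq_len(TT)) {
      if (is.na(mrow[t])) {
        S[, t] <- absence_cost * cpres[cand, t]
      } else {
        S[, t] <- visit_cost * (cand != mrow[t])
      }
    }
    # DP over (t, candidate) on lexicographic value (cost, n_switches);
    # back-pointers take the earliest candidate in 'cand' order on ties
    C <- S[, 1]; SW <- rep(0L, K)
    back <- matrix(NA_integer_, nrow = K, ncol = TT)
    if (TT > 1) for (t in 2:TT) {
      Cn <- numeric(K); SWn <- integer(K)
      for (k in seq_len(K)) {
        tc <- C + switch_cost * (seq_len(K) != k)
        tw <- SW + as.integer(seq_len(K) != k)
        bk <- which(tc < min(tc) + 1e-12)
        bk <- bk[tw[bk] == min(tw[bk])][1L]
        Cn[k] <- tc[bk] + S[k, t]
        SWn[k] <- tw[bk]
        back[k, t] <- bk
      }
      C <- Cn; SW <- SWn
    }
    kk <- which(C < min(C) + 1e-12)
    kk <- kk[SW[kk] == min(SW[kk])][1L]
    traj <- integer(TT)
    traj[TT] <- kk
    if (TT > 1) for (t in TT:2) traj[t - 1L] <- back[traj[t], t]
    h <- cand[traj]
    home[ni, ] <- h
    # itemised accounting
    cst <- 0
    for (t in seq_len(TT)) {
      tags <- character(0)
      if (t > 1 && h[t] != h[t - 1]) { tags <- c(tags, "switch")
        cst <- cst + switch_cost }
      if (!is.na(mrow[t])) {
        if (mrow[t] != h[t]) { tags <- c(tags, "visit")
          cst <- cst + visit_cost }
      } else if (cpres[h[t], t]) { tags <- c(tags, "absence")
        cst <- cst + absence_cost
      } else tags <- c(tags, "exempt-absence")
      events[ni, t] <- if (length(tags)) paste(tags, collapse = "+") else "none"
    }
    node_cost[ni] <- cst
  }
  structure(list(home = home, node_cost = node_cost,
                 total_cost = sum(node_cost),
                 n_nodes = length(nodes), n_times = TT,
                 events = events, membership = memb,
                 costs = costs),
            class = "home_assignment")
}

#' @export
print.home_assignment <- function(x, ...) {
  cat("Home-community assignment: ", x$n_nodes, " nodes x ", x$n_times,
      " time points\n", sep = "")
  cat("  total cost C = ", format(x$total_cost),
      "; average cost C/(N*T) = ",
      format(average_cost(x), digits = 4), "\n", sep = "")
  ev <- table(unlist(strsplit(as.vector(x$events), "+", fixed = TRUE)))
  ev <- ev[setdiff(names(ev), "none")]
  if (length(ev))
    cat("  events:", paste(names(ev), ev, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Average cost per node per time step
#'
#' C / (N * T), where C is the total cost, N the number of nodes and T the
#' number of time steps. A small average indicates stable community
#' membership; large values indicate frequent switching/visiting, for which
#' the sub-community model is the better description.
#'
#' @param assignment a \code{home_assignment}, or NULL when the three
#'   summary quantities are given directly
#' @param total_cost,n_nodes,n_times used when \code{assignment} is NULL
#' @return real >= 0
#' @export
average_cost <- function(assignment = NULL, total_cost = NULL,
                         n_nodes = NULL, n_times = NULL) {
  if (!is.null(assignment)) {
    stopifnot(inherits(assignment, "home_assignment"))
    total_cost <- assignment$total_cost
    n_nodes <- assignment$n_nodes
    n_times <- assignment$n_times
  }
  if (is.null(total_cost) || is.null(n_nodes) || is.null(n_times))
    stop("provide an assignment or all of total_cost, n_nodes, n_times")
  total_cost / (n_nodes * n_times)
}
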