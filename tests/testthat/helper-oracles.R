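# Independent oracles. These deliberately avoid the package's algorithmic
# shortcuts: exhaustive enumeration instead of greedy matching, full
# trajectory enumeration instead of dynamic programming, all set partitions
# instead of Louvain.

# --- all set partitions of n elements (restricted growth strings) ---------
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    k <- length(rgs)
    if (k == n) { out[[length(out) + 1L]] <<- rgs; return(invisible()) }
    for (v in seq_len(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive modularity maximisation; returns best Q and one argmax
best_partition_exhaustive <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  stopifnot(length(nodes) <= 8)
  best_q <- -Inf; best <- NULL
  for (p in all_set_partitions(length(nodes))) {
    q <- modularity_q(g, setNames(p, nodes))
    if (q > best_q + 1e-12) { best_q <- q; best <- setNames(p, nodes) }
  }
  list(q = best_q, partition = best)
}

# --- exhaustive cost-model trajectory enumeration -------------------------
# membership: node row (vector over T, NA = absent); cpres: community x T
# presence matrix; returns the minimal total cost over all trajectories
# with homes drawn from the candidate set.
enumerate_node_cost <- function(mrow, cpres, switch_cost = 1,
                                visit_cost = 1, absence_cost = 1,
                                candidates = NULL) {
  TT <- length(mrow)
  if (is.null(candidates)) candidates <- sort(unique(mrow[!is.na(mrow)]))
  K <- length(candidates)
  trajs <- as.matrix(expand.grid(rep(list(seq_len(K)), TT)))
  H <- matrix(candidates[trajs], nrow = nrow(trajs))
  cost <- numeric(nrow(H))
  if (TT > 1)
    cost <- cost + switch_cost *
      rowSums(H[, -1, drop = FALSE] != H[, -TT, drop = FALSE])
  for (t in seq_len(TT)) {
    if (!is.na(mrow[t])) {
      cost <- cost + visit_cost * (H[, t] != mrow[t])
    } else {
      cost <- cost + absence_cost * cpres[H[, t], t]
    }
  }
  min(cost)
}

# --- brute-force group matcher --------------------------------------------
# Enumerates, at each time point and look-back depth, every maximal
# one-to-one pairing between still-unmatched current groups and the earlier
# groups whose Jaccard clears the threshold, and selects the pairing whose
# selection sequence (ordered by descending Jaccard, then lower current
# group id, then lower earlier group id) is lexicographically best. This is
# the declarative counterpart of the implementation's greedy pass.
brute_force_match <- function(partitions, jaccard_threshold = 0.4,
                              search_depth = Inf) {
  TT <- length(partitions)
  cog <- vector("list", TT)
  cog[[1]] <- seq_along(partitions[[1]]$groups)
  n_comm <- length(cog[[1]])
  key_rank <- function(pairs) order(-pairs$j, pairs$cur, pairs$prev)
  for (t in seq(2L, TT)) {
    gt <- partitions[[t]]$groups
    cog[[t]] <- rep(NA_integer_, length(gt))
    unmatched <- seq_along(gt)
    d <- 1L
    while (length(unmatched) > 0L && d <= min(t - 1L, search_depth)) {
      tp <- t - d
      gp <- partitions[[tp]]$groups
      pairs <- expand.grid(cur = unmatched, prev = seq_along(gp))
      if (nrow(pairs) > 0) {
        pairs$j <- mapply(function(ci, pj)
          jaccard_index(gt[[ci]], gp[[pj]]), pairs$cur, pairs$prev)
        pairs <- pairs[pairs$j >= jaccard_threshold & pairs$j > 0, ,
                       drop = FALSE]
      }
      if (nrow(pairs) > 0) {
        pairs <- pairs[key_rank(pairs), , drop = FALSE]
        # enumerate all maximal one-to-one selections (by row index sets)
        best_sel <- NULL
        n <- nrow(pairs)
        rec <- function(i, used_cur, used_prev, sel) {
          feasible <- any(vapply(seq(i, length.out = max(0, n - i + 1)),
                                 function(r) !(pairs$cur[r] %in% used_cur) &&
                                   !(pairs$prev[r] %in% used_prev),
                                 logical(1)))
          if (!feasible) {
            if (is.null(best_sel)) best_sel <<- sel
            else {
              # lexicographic comparison of selection row sequences
              l <- min(length(sel), length(best_sel))
              cmp <- 0L
              for (x in seq_len(l)) {
                if (sel[x] < best_sel[x]) { cmp <- -1L; break }
                if (sel[x] > best_sel[x]) { cmp <- 1L; break }
              }
              if (cmp == -1L || (cmp == 0L && length(sel) > length(best_sel)))
                best_sel <<- sel
            }
            return(invisible())
          }
          for (r in seq(i, n)) {
            if (!(pairs$cur[r] %in% used_cur) &&
                !(pairs$prev[r] %in% used_prev))
              rec(r + 1L, c(used_cur, pairs$cur[r]),
                  c(used_prev, pairs$prev[r]), c(sel, r))
          }
        }
        rec(1L, integer(0), integer(0), integer(0))
        for (r in best_sel)
          cog[[t]][pairs$cur[r]] <- cog[[tp]][pairs$prev[r]]
        unmatched <- which(is.na(cog[[t]]))
      }
      d <- d + 1L
    }
    for (ci in unmatched) {
      n_comm <- n_comm + 1L
      cog[[t]][ci] <- n_comm
    }
  }
  list(community_of_group = cog, n_communities = n_comm)
}

# --- brute-force sub-community grouping -----------------------------------
# pairwise full-vector equality, no hashing/keying
brute_force_subcommunities <- function(patterns) {
  n <- nrow(patterns)
  same <- function(i, j) {
    a <- patterns[i, ]; b <- patterns[j, ]
    all((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b))
  }
  groups <- list()
  assigned <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    members <- i
    for (j in seq_len(n)) if (j != i && same(i, j)) members <- c(members, j)
    gid <- length(groups) + 1L
    groups[[gid]] <- sort(unique(members))
    assigned[groups[[gid]]] <- gid
  }
  groups
}
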