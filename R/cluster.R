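# Ancestry-group assignment: density-based core-cluster selection on top-2
# principal-component coordinates (DBSCAN), and community detection on an
# identity-by-descent sharing graph (a Leiden-style modularity optimiser:
# local moving, refinement, aggregation, iterated to convergence).

#' Density-based clustering of 2-D principal-component points
#'
#' Classic DBSCAN with Euclidean distance.  A point is a core point when
#' its eps-neighbourhood (including itself) holds at least `min_pts`
#' points; clusters are maximal density-connected sets; non-core points
#' within eps of a cluster's core join it as border points; all other
#' points are labelled noise (0).  Border points reachable from several
#' clusters join the cluster reached first in index order, so the
#' labelling is deterministic.
#'
#' @param points data frame with columns `pc1`, `pc2` (an `id` column is
#'   used to name the result), or a two-column matrix.
#' @param eps neighbourhood radius (> 0).
#' @param min_pts core-point threshold (>= 1), counting the point itself.
#' @return integer cluster labels (0 = noise), named by id when available.
#' @export
dbscan_points <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  if (is.data.frame(points)) {
    xy <- cbind(points$pc1, points$pc2)
    ids <- if ("id" %in% names(points)) points$id else NULL
  } else {
    xy <- as.matrix(points)
    ids <- rownames(points)
  }
  stopifnot(ncol(xy) == 2, all(is.finite(xy)))
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nbrs) >= min_pts
  labels <- integer(n)
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in nbrs[[v]]) {
        if (labels[u] == 0L) {
          labels[u] <- cluster_id
          if (core[u]) queue <- c(queue, u)
        }
      }
    }
  }
  if (!is.null(ids)) names(labels) <- ids
  labels
}

#' Select the core genetic cluster for a population group
#'
#' Retains the DBSCAN cluster that contains the largest number of the
#' group's seed members (e.g. individuals born in the target country).
#'
#' @param labels integer labels from [dbscan_points()], named by id.
#' @param seed_ids ids of the seed group.
#' @return ids of all members of the selected cluster.
#' @export
select_core_cluster <- function(labels, seed_ids) {
  stopifnot(!is.null(names(labels)), length(seed_ids) >= 1)
  seed_labels <- labels[intersect(seed_ids, names(labels))]
  seed_labels <- seed_labels[seed_labels != 0L]
  if (length(seed_labels) == 0) {
    stop("all seed members are noise: no cluster to select", call. = FALSE)
  }
  tab <- table(seed_labels)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1) {
    message("tie between clusters ", paste(best, collapse = ", "),
            "; keeping the smallest label")
    best <- as.character(min(as.integer(best)))
  }
  names(labels)[labels == as.integer(best)]
}

#' Build an identity-by-descent sharing graph
#'
#' Retains segments with `min_cm < length < max_cm` (strict bounds: very
#' short segments are unreliable, very long ones reflect recent
#' relatedness rather than population structure) and sums retained lengths
#' per pair of individuals into an undirected edge weight.
#'
#' @param segments data frame with columns `id_a`, `id_b`, `length_cm`.
#' @param min_cm,max_cm open-interval bounds in centimorgans (3 and 30).
#' @return an `ibd_graph`: list with `nodes` (every id appearing in
#'   `segments`) and `edges` (data frame `from`, `to`, `weight`).
#' @export
build_ibd_graph <- function(segments, min_cm = 3, max_cm = 30) {
  stopifnot(is.data.frame(segments),
            all(c("id_a", "id_b", "length_cm") %in% names(segments)),
            all(segments$length_cm > 0), min_cm < max_cm)
  nodes <- sort(unique(c(segments$id_a, segments$id_b)))
  keep <- segments$length_cm > min_cm & segments$length_cm < max_cm &
    segments$id_a != segments$id_b
  seg <- segments[keep, , drop = FALSE]
  if (nrow(seg)) {
    from <- pmin(seg$id_a, seg$id_b)
    to <- pmax(seg$id_a, seg$id_b)
    key <- paste(from, to, sep = "\r")
    w <- tapply(seg$length_cm, key, sum)
    pairs <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                        weight = as.numeric(w), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "ibd_graph")
}

#' @export
print.ibd_graph <- function(x, ...) {
  cat(sprintf("<ibd_graph> %d nodes, %d edges, total weight %.1f cM\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

# internal adjacency-list representation of a weighted undirected graph
# with self-loops (self-loops arise during aggregation)
as_adjlist <- function(n, from, to, weight) {
  selfw <- numeric(n)
  is_self <- from == to
  if (any(is_self)) {
    selfw <- selfw + as.vector(tapply(weight[is_self], factor(from[is_self],
                                      levels = seq_len(n)), sum))
    selfw[is.na(selfw)] <- 0
  }
  f <- from[!is_self]; t <- to[!is_self]; w <- weight[!is_self]
  nbr <- vector("list", n)
  nw <- vector("list", n)
  all_from <- c(f, t); all_to <- c(t, f); all_w <- c(w, w)
  ord <- order(all_from)
  all_from <- all_from[ord]; all_to <- all_to[ord]; all_w <- all_w[ord]
  idx <- split(seq_along(all_from), factor(all_from, levels = seq_len(n)))
  for (i in seq_len(n)) {
    j <- idx[[i]]
    nbr[[i]] <- all_to[j]
    nw[[i]] <- all_w[j]
  }
  k <- vapply(seq_len(n), function(i) sum(nw[[i]]), numeric(1)) + 2 * selfw
  list(n = n, nbr = nbr, nw = nw, selfw = selfw, k = k, m2 = sum(k))
}

# weighted modularity at resolution gamma of membership on adjacency g
adj_modularity <- function(g, memb, gamma) {
  if (g$n == 0 || g$m2 == 0) return(0)
  comms <- unique(memb)
  q <- 0
  for (c in comms) {
    members <- which(memb == c)
    inw <- 2 * sum(g$selfw[members])
    for (v in members) {
      inside <- memb[g$nbr[[v]]] == c
      inw <- inw + sum(g$nw[[v]][inside])
    }
    tot <- sum(g$k[members])
    q <- q + inw / g$m2 - gamma * (tot / g$m2)^2
  }
  q
}

# one pass of fast local moving; returns updated membership
local_move <- function(g, memb, gamma) {
  if (g$n <= 1 || g$m2 == 0) return(memb)
  comm_tot <- numeric(max(memb))
  for (v in seq_len(g$n)) comm_tot[memb[v]] <- comm_tot[memb[v]] + g$k[v]
  queue <- sample.int(g$n)
  in_queue <- rep(TRUE, g$n)
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    in_queue[v] <- FALSE
    if (length(g$nbr[[v]]) == 0) next  # isolated node stays put
    cv <- memb[v]
    nbr_comms <- memb[g$nbr[[v]]]
    w_vc <- tapply(g$nw[[v]], nbr_comms, sum)
    cand <- as.integer(names(w_vc))
    if (!cv %in% cand) {
      cand <- c(cand, cv)
      w_vc <- c(w_vc, 0)
    }
    comm_tot[cv] <- comm_tot[cv] - g$k[v]
    gain <- as.numeric(w_vc) - gamma * g$k[v] * comm_tot[cand] / g$m2
    # deterministic tie-break: stay put if the current community ties
    best <- cand[which.max(gain)]
    if (gain[cand == cv] >= max(gain) - 1e-12) best <- cv
    memb[v] <- best
    comm_tot[best] <- comm_tot[best] + g$k[v]
    if (best != cv) {
      push <- g$nbr[[v]][memb[g$nbr[[v]]] != best & !in_queue[g$nbr[[v]]]]
      if (length(push)) {
        queue <- c(queue, push)
        in_queue[push] <- TRUE
      }
    }
  }
  memb
}

# refinement phase: split each community into well-merged sub-communities,
# starting from singletons and greedily merging within the community
refine_partition <- function(g, memb, gamma) {
  refined <- seq_len(g$n)
  ref_tot <- g$k
  for (c in unique(memb)) {
    members <- which(memb == c)
    if (length(members) < 2) next
    for (v in sample(members)) {
      if (sum(refined == refined[v]) > 1) next  # already merged
      inside <- memb[g$nbr[[v]]] == c
      if (!any(inside)) next
      nbr_ref <- refined[g$nbr[[v]][inside]]
      w_vr <- tapply(g$nw[[v]][inside], nbr_ref, sum)
      cand <- as.integer(names(w_vr))
      cand_w <- as.numeric(w_vr)
      keep <- cand != refined[v]
      cand <- cand[keep]; cand_w <- cand_w[keep]
      if (!length(cand)) next
      gain <- cand_w - gamma * g$k[v] * ref_tot[cand] / g$m2
      if (max(gain) > 1e-12) {
        best <- cand[which.max(gain)]
        ref_tot[best] <- ref_tot[best] + g$k[v]
        ref_tot[refined[v]] <- ref_tot[refined[v]] - g$k[v]
        refined[v] <- best
      }
    }
  }
  refined
}

# aggregate g by the refined partition; returns the aggregate adjacency
# plus the refined-community index of each original node
aggregate_graph <- function(g, refined) {
  comm_ids <- sort(unique(refined))
  remap <- match(refined, comm_ids)
  n2 <- length(comm_ids)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (v in seq_len(g$n)) {
    nb <- g$nbr[[v]]
    keep <- nb > v  # each undirected edge once
    if (any(keep)) {
      from <- c(from, rep.int(remap[v], sum(keep)))
      to <- c(to, remap[nb[keep]])
      w <- c(w, g$nw[[v]][keep])
    }
  }
  if (any(g$selfw > 0)) {
    from <- c(from, remap)
    to <- c(to, remap)
    w <- c(w, g$selfw)
    zero <- w == 0
    from <- from[!zero]; to <- to[!zero]; w <- w[!zero]
  }
  list(adj = as_adjlist(n2, from, to, w), remap = remap)
}

#' Leiden-style community detection on an IBD graph
#'
#' Optimises weighted modularity at the given resolution by iterated local
#' moving, refinement and aggregation, finishing with a stabilising local
#' pass on the original graph so that no single-node move can improve the
#' returned partition.  All randomness (node processing order) flows from
#' `seed`, so results are reproducible.
#'
#' @param graph an [build_ibd_graph()] result.
#' @param resolution modularity resolution parameter (default 1).
#' @param seed integer seed.
#' @param max_iter maximum local-move/aggregate rounds (default 20).
#' @return an `ibd_partition`: list with `membership` (named integer,
#'   communities numbered 1..k by decreasing size), `modularity`, and
#'   `resolution`.
#' @export
detect_communities <- function(graph, resolution = 1, seed = 1L,
                               max_iter = 20L) {
  stopifnot(inherits(graph, "ibd_graph"), resolution > 0)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) {
    return(structure(list(membership = setNames(integer(0), character(0)),
                          modularity = 0, resolution = resolution),
                     class = "ibd_partition"))
  }
  g0 <- as_adjlist(n, match(graph$edges$from, nodes),
                   match(graph$edges$to, nodes), graph$edges$weight)
  memb <- with_seed(seed, {
    g <- g0
    node_of <- seq_len(n)  # original node -> current aggregate node
    memb_cur <- seq_len(g$n)
    for (iter in seq_len(max_iter)) {
      memb_cur <- local_move(g, memb_cur, resolution)
      n_comms <- length(unique(memb_cur))
      if (n_comms == g$n) break  # nothing merged: converged
      refined <- refine_partition(g, memb_cur, resolution)
      agg <- aggregate_graph(g, refined)
      # aggregate nodes inherit the community of their (refined) members
      memb_agg <- integer(agg$adj$n)
      memb_agg[agg$remap] <- memb_cur
      node_of <- agg$remap[node_of]
      g <- agg$adj
      memb_cur <- memb_agg
      if (g$n == n_comms) {
        # refinement did not split anything beyond the communities:
        # one more local move on the aggregate then stop if stable
        memb_next <- local_move(g, memb_cur, resolution)
        if (identical(memb_next, memb_cur)) break
        memb_cur <- memb_next
      }
    }
    final <- memb_cur[node_of]
    # stabilising pass at the original level
    local_move(g0, final, resolution)
  })
  # renumber communities 1..k by decreasing size (ties: first appearance)
  tab <- sort(table(memb), decreasing = TRUE)
  memb <- match(as.character(memb), names(tab))
  structure(
    list(membership = setNames(as.integer(memb), nodes),
         modularity = adj_modularity(g0, memb, resolution),
         resolution = resolution),
    class = "ibd_partition"
  )
}

#' @export
print.ibd_partition <- function(x, ...) {
  cat(sprintf(
    "<ibd_partition> %d nodes in %d communities, modularity %.4f (resolution %.2f)\n",
    length(x$membership), length(unique(x$membership)), x$modularity,
    x$resolution))
  invisible(x)
}

#' Weighted modularity of a partition of an IBD graph
#'
#' Independent recomputation of the objective optimised by
#' [detect_communities()].
#'
#' @param graph an `ibd_graph`.
#' @param membership named integer vector (id -> community).
#' @param resolution resolution parameter.
#' @return the modularity value.
#' @export
graph_modularity <- function(graph, membership, resolution = 1) {
  stopifnot(inherits(graph, "ibd_graph"),
            all(graph$nodes %in% names(membership)))
  nodes <- graph$nodes
  g <- as_adjlist(length(nodes), match(graph$edges$from, nodes),
                  match(graph$edges$to, nodes), graph$edges$weight)
  adj_modularity(g, as.integer(factor(membership[nodes])), resolution)
}

#' Annotate communities with reference ancestry labels
#'
#' Names each detected community by majority vote of the reference labels
#' (e.g. grandparental birthplaces) of its members; communities without any
#' labelled reference are `"unlabelled"`; ties produce a joint label.
#'
#' @param partition an `ibd_partition`.
#' @param reference_labels named character vector (id -> region/province)
#'   for the reference subset.
#' @return named character vector (community -> name).
#' @export
annotate_communities <- function(partition, reference_labels) {
  stopifnot(inherits(partition, "ibd_partition"))
  memb <- partition$membership
  comms <- sort(unique(memb))
  out <- vapply(comms, function(c) {
    members <- names(memb)[memb == c]
    refs <- reference_labels[intersect(members, names(reference_labels))]
    if (length(refs) == 0) return("unlabelled")
    tab <- table(refs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1) {
      message("community ", c, ": tied labels ",
              paste(sort(winners), collapse = "/"))
      return(paste(sort(winners), collapse = "/"))
    }
    winners
  }, character(1))
  setNames(out, comms)
}
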