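#' Leiden community detection
#'
#' Community detection under weighted modularity with a resolution
#' parameter, via the three Leiden phases: queue-based fast local moving,
#' community refinement (singletons merged within their community, only
#' into refined communities they share an edge with), and aggregation of
#' the refined partition with the unrefined partition as the initial
#' assignment of the aggregate graph. Levels repeat until no further
#' merging is possible. All randomness (node processing order) comes from
#' one generator seeded with `seed`, so identical inputs give identical
#' partitions; the caller's RNG state is untouched.
#'
#' Guarantees: quality never decreases across phases; every returned
#' community induces a connected subgraph (communities that end up
#' disconnected are split into their components, which cannot lower
#' modularity); `Q(returned) >= Q(singleton partition)`.
#'
#' Community labels are 0-based and relabelled by decreasing community
#' size (ties by smallest member id) for stable reporting.
#'
#' @param graph an igraph graph with optional `weight` edge attribute.
#' @param resolution gamma > 0; default 0.6.
#' @param seed integer RNG seed; default 42.
#' @param max_passes cap on aggregation levels.
#' @param n_restarts number of independent seeded runs; the first starts
#'   from singletons, the rest from random initial partitions, and the
#'   best-quality result is kept. Restarts are the standard way to escape
#'   the local optima a single greedy pass can settle into, and are cheap
#'   at the network sizes this package targets.
#' @return An object of class `substance_partition`: list with
#'   `membership` (named, 0-based), `resolution`, `quality` (the
#'   gamma-scaled objective that was maximized), `modularity` (the same
#'   partition scored at standard gamma = 1, the scale of the usual
#'   "Q >= 0.3" convention) and `n_communities`.
#' @export
leiden <- function(graph, resolution = 0.6, seed = 42L, max_passes = 50L,
                   n_restarts = 25L) {
  abort_if(resolution <= 0, "resolution must be positive")
  abort_if(n_restarts < 1, "n_restarts must be >= 1")
  g <- graph_arrays(graph)
  if (g$n == 0) {
    return(new_partition(stats::setNames(integer(0), character(0)),
                         resolution, 0))
  }
  if (g$m == 0) {
    mem <- stats::setNames(seq_len(g$n) - 1L, g$names)
    return(new_partition(mem, resolution, 0))
  }
  mem0 <- with_seed(seed, {
    best <- NULL
    best_q <- -Inf
    for (i in seq_len(n_restarts)) {
      # restart 1 from the singleton partition (the canonical start);
      # later restarts from random initial partitions, which escape the
      # rare configurations where a pair of strongly tied nodes must end
      # up on opposite sides of the optimal cut. Each run then iterates
      # the whole procedure from its result until quality stops improving.
      init <- if (i == 1) NULL else
        sample.int(sample.int(g$n, 1), g$n, replace = TRUE)
      cand <- leiden_core(g, resolution, max_passes, init = init)
      q <- modularity_from_arrays(cand + 1L, g$el, g$w, g$k, g$m, resolution)
      repeat {
        cand2 <- leiden_core(g, resolution, max_passes, init = cand + 1L)
        q2 <- modularity_from_arrays(cand2 + 1L, g$el, g$w, g$k, g$m,
                                     resolution)
        if (q2 <= q + 1e-12) break
        cand <- cand2
        q <- q2
      }
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- cand
      }
    }
    best
  })
  mem <- stats::setNames(mem0, g$names)
  mem <- split_disconnected(graph, mem)
  mem <- relabel_partition(mem)
  q <- modularity_q(graph, mem, resolution)
  # `quality` is the gamma-scaled objective the algorithm maximized;
  # `modularity` is the standard (gamma = 1) value, the scale on which
  # the Q >= 0.3 meaningfulness convention is defined
  new_partition(mem, resolution, q, modularity_q(graph, mem, 1))
}

new_partition <- function(membership, resolution, quality,
                          modularity = quality) {
  structure(list(membership = membership, resolution = resolution,
                 quality = quality, modularity = modularity,
                 n_communities = length(unique(unname(membership)))),
            class = "substance_partition")
}

#' @export
print.substance_partition <- function(x, ...) {
  cat(sprintf("<substance_partition> %d nodes, %d communities, Q = %.4f (objective %.4f at gamma = %g)\n",
              length(x$membership), x$n_communities, x$modularity,
              x$quality, x$resolution))
  invisible(x)
}

# ---- internal machinery (1-based integer labels over level nodes) --------

# adjacency lists from an edge list
make_adj <- function(n, el, w) {
  nbr <- vector("list", n)
  wt <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    if (a == b) next
    nbr[[a]] <- c(nbr[[a]], b); wt[[a]] <- c(wt[[a]], w[r])
    nbr[[b]] <- c(nbr[[b]], a); wt[[b]] <- c(wt[[b]], w[r])
  }
  list(nbr = nbr, wt = wt)
}

# queue-based local moving; returns improved membership (integer labels)
local_move <- function(n, adj, k, m, gamma, mem) {
  next_label <- max(mem) + 1L
  comm_k <- numeric(next_label + n)
  for (v in seq_len(n)) comm_k[mem[v]] <- comm_k[mem[v]] + k[v]
  queue <- sample.int(n)
  in_q <- rep(TRUE, n)
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L; in_q[v] <- FALSE
    cv <- mem[v]
    comm_k[cv] <- comm_k[cv] - k[v]
    nbr <- adj$nbr[[v]]
    target <- cv
    if (length(nbr) > 0) {
      # gain of inserting v into community c, relative to standing alone:
      # k_{v,c}/m - gamma * k_v * d_c / (2 m^2)
      cw <- tapply(adj$wt[[v]], mem[nbr], sum)
      cand <- as.integer(names(cw))
      gains <- unname(cw) / m - gamma * k[v] * comm_k[cand] / (2 * m^2)
      gain_cv <- if (cv %in% cand) gains[match(cv, cand)] else
        -gamma * k[v] * comm_k[cv] / (2 * m^2)  # 0 when v was alone
      gmax <- max(gains, 0)
      if (gmax <= gain_cv + 1e-12) {
        target <- cv  # staying put is as good as any move
      } else if (gmax > 1e-12) {
        target <- min(cand[gains >= gmax - 1e-12])
      } else {
        # strictly better off alone in a fresh community
        target <- next_label
        next_label <- next_label + 1L
        if (target > length(comm_k)) comm_k <- c(comm_k, numeric(n))
      }
    }
    comm_k[target] <- comm_k[target] + k[v]
    if (target != cv) {
      mem[v] <- target
      moved_nbr <- nbr[mem[nbr] != target & !in_q[nbr]]
      if (length(moved_nbr) > 0) {
        queue <- c(queue, moved_nbr)
        in_q[moved_nbr] <- TRUE
      }
    }
  }
  mem
}

# refinement: singleton start, lone nodes merge into neighbouring refined
# communities within the same unrefined community. The receiving community
# is drawn uniformly among the non-negative-gain candidates (randomized
# constrained merging), which keeps refined communities connected while
# letting repeated runs explore different aggregations.
refine_partition <- function(n, adj, k, m, gamma, mem) {
  rmem <- seq_len(n)
  rsize <- rep(1L, n)
  rk <- k
  for (v in sample.int(n)) {
    if (rsize[rmem[v]] > 1L) next
    nbr <- adj$nbr[[v]]
    if (length(nbr) == 0) next
    ok <- mem[nbr] == mem[v] & rmem[nbr] != rmem[v]
    if (!any(ok)) next
    cw <- tapply(adj$wt[[v]][ok], rmem[nbr[ok]], sum)
    cand <- as.integer(names(cw))
    gains <- unname(cw) / m - gamma * k[v] * rk[cand] / (2 * m^2)
    pos <- which(gains > 1e-12)
    if (length(pos) > 0) {
      b <- if (length(pos) == 1) pos else pos[sample.int(length(pos), 1)]
      old <- rmem[v]
      rk[old] <- rk[old] - k[v]; rsize[old] <- rsize[old] - 1L
      rmem[v] <- cand[b]
      rk[cand[b]] <- rk[cand[b]] + k[v]; rsize[cand[b]] <- rsize[cand[b]] + 1L
    }
  }
  rmem
}

# full multi-level run over graph arrays; returns 0-based membership over
# the original nodes. `init` (1-based labels) seeds the first local-moving
# phase; the default is the singleton partition.
leiden_core <- function(g, gamma, max_passes, init = NULL) {
  n <- g$n; el <- g$el; w <- g$w
  self <- numeric(n)
  node_map <- seq_len(n)      # original node -> level node
  m <- g$m
  mem_init <- if (is.null(init)) seq_len(n) else as.integer(init)
  for (pass in seq_len(max_passes)) {
    # strengths at this level (self loops count twice)
    k <- 2 * self
    for (r in seq_len(nrow(el))) {
      k[el[r, 1]] <- k[el[r, 1]] + w[r]
      k[el[r, 2]] <- k[el[r, 2]] + w[r]
    }
    adj <- make_adj(n, el, w)
    mem <- local_move(n, adj, k, m, gamma, mem_init)
    mem <- match(mem, sort(unique(mem)))
    nc <- max(mem)
    if (nc == n) break
    rmem <- refine_partition(n, adj, k, m, gamma, mem)
    rmem <- match(rmem, sort(unique(rmem)))
    R <- max(rmem)
    if (R == n) rmem <- mem  # refinement idle: aggregate the partition itself
    R <- max(rmem)
    if (R == n) break
    # aggregate by rmem
    new_self <- as.numeric(tapply(self, rmem, sum))
    intra <- rmem[el[, 1]] == rmem[el[, 2]]
    if (any(intra)) {
      add <- tapply(w[intra], rmem[el[intra, 1]], sum)
      idx <- as.integer(names(add))
      new_self[idx] <- new_self[idx] + as.numeric(add)
    }
    if (any(!intra)) {
      a <- pmin(rmem[el[!intra, 1]], rmem[el[!intra, 2]])
      b <- pmax(rmem[el[!intra, 1]], rmem[el[!intra, 2]])
      keyw <- rowsum(w[!intra], group = paste(a, b))
      ab <- do.call(rbind, strsplit(rownames(keyw), " "))
      el <- cbind(as.integer(ab[, 1]), as.integer(ab[, 2]))
      w <- as.numeric(keyw)
    } else {
      el <- matrix(integer(0), ncol = 2)
      w <- numeric(0)
    }
    # initial assignment of aggregate nodes = their unrefined community
    mem_init <- as.integer(tapply(mem, rmem, function(v) v[1]))
    self <- new_self
    node_map <- rmem[node_map]
    n <- R
  }
  mem[node_map] - 1L
}

# split communities that do not induce connected subgraphs into their
# components (never decreases modularity for gamma > 0)
split_disconnected <- function(graph, mem) {
  out <- mem
  next_label <- max(mem) + 1L
  for (cm in unique(unname(mem))) {
    nodes <- names(mem)[mem == cm]
    sub <- igraph::induced_subgraph(graph, nodes)
    comp <- igraph::components(sub)
    if (comp$no > 1) {
      for (ci in 2:comp$no) {
        out[names(comp$membership)[comp$membership == ci]] <- next_label
        next_label <- next_label + 1L
      }
    }
  }
  out
}

# 0-based labels by decreasing community size, ties by smallest member id
relabel_partition <- function(mem) {
  sizes <- table(unname(mem))
  first <- tapply(names(mem), unname(mem), min)
  labs <- names(sizes)[order(-as.integer(sizes), first[names(sizes)])]
  stats::setNames(match(as.character(unname(mem)), labs) - 1L, names(mem))
}

#' Exhaustive best-modularity partition (test oracle)
#'
#' Enumerates every set partition of the nodes (Bell-number many; allowed
#' up to 10 nodes) and returns one maximising modularity at the given
#' resolution. Independent of [leiden()]; intended as a brute-force
#' oracle on small graphs.
#'
#' @param graph an igraph graph (<= 10 nodes).
#' @param resolution gamma > 0.
#' @return A `substance_partition`.
#' @export
brute_force_best_partition <- function(graph, resolution = 1) {
  abort_if(resolution <= 0, "resolution must be positive")
  g <- graph_arrays(graph)
  abort_if(g$n > 10, "brute force limited to 10 nodes (got %d)", g$n)
  if (g$n == 0) {
    return(new_partition(stats::setNames(integer(0), character(0)),
                         resolution, 0))
  }
  n <- g$n
  assign <- integer(n)
  best_q <- -Inf
  best <- NULL
  rec <- function(i, maxlab) {
    if (i > n) {
      q <- modularity_from_arrays(assign, g$el, g$w, g$k, g$m, resolution)
      if (q > best_q + 1e-15) {
        best_q <<- q
        best <<- assign
      }
      return(invisible(NULL))
    }
    for (lab in seq_len(maxlab + 1L)) {
      assign[i] <<- lab
      rec(i + 1L, max(maxlab, lab))
    }
  }
  if (g$m == 0) {
    best <- seq_len(n)
    best_q <- 0
  } else {
    rec(1L, 0L)
  }
  mem <- relabel_partition(stats::setNames(best, g$names))
  new_partition(mem, resolution, best_q,
                if (g$m == 0) 0 else
                  modularity_from_arrays(best, g$el, g$w, g$k, g$m, 1))
}
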