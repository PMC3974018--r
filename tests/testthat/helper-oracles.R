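# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms from the implementation:
# single-pair recursion instead of maximal-helix recursion, exhaustive
# path enumeration instead of Dijkstra, threshold flooding instead of
# best-first sweeps.

TOY_PARAMS <- energy_parameters()

# all pseudoknot-free structures (lonely pairs allowed) by naive recursion
# over "first position unpaired / first position paired to k"
oracle_all_structures <- function(sq) {
  chars <- sq$chars
  n <- sq$n
  ok <- outer(chars, chars, FUN = function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  })
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(list(integer(0)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- rec(i + 1L, j)
    for (k in seq.int(i + 4L, j)) {
      if (!ok[i, k]) next
      for (inner in rec(i + 1L, k - 1L)) {
        for (outer in rec(k + 1L, j)) {
          res[[length(res) + 1L]] <- c(i, k, inner, outer)
        }
      }
    }
    memo[[key]] <- res
    res
  }
  rec(1L, n)
}

# dot-bracket set of the noLP folding space by filtering the naive space
oracle_nolp_space <- function(sq) {
  pts <- lapply(oracle_all_structures(sq),
                function(p) hishapes:::pt_from_pairs(p, sq$n))
  keep <- vapply(pts, hishapes:::pt_is_nolp, logical(1))
  sort(vapply(pts[keep], hishapes:::db_from_pt, character(1)))
}

# minimax path cost by exhaustive enumeration of all simple paths
oracle_minimax <- function(weights, source, target) {
  nv <- nrow(weights)
  best <- Inf
  walk <- function(u, seen, mx) {
    if (u == target) {
      best <<- min(best, mx)
      return(invisible())
    }
    for (v in seq_len(nv)) {
      w <- weights[u, v]
      if (v == u || seen[v] || is.na(w) || !is.finite(w)) next
      seen2 <- seen
      seen2[v] <- TRUE
      walk(v, seen2, max(mx, w))
    }
  }
  seen <- logical(nv)
  seen[source] <- TRUE
  walk(source, seen, -Inf)
  best
}

# exact barrier by threshold flooding: smallest energy cutoff under which
# start and target are connected in the level subgraph
oracle_barrier_flood <- function(graph, sdb, tdb) {
  src <- match(sdb, graph$db)
  dst <- match(tdb, graph$db)
  stopifnot(!is.na(src), !is.na(dst))
  cuts <- sort(unique(graph$energy[graph$energy >=
                                     max(graph$energy[c(src, dst)])]))
  for (cut in cuts) {
    inside <- graph$energy <= cut + 1e-12
    if (!inside[src] || !inside[dst]) next
    # BFS in the subgraph
    seen <- logical(length(graph$db))
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in graph$adj[[u]]) {
        if (inside[v] && !seen[v]) {
          seen[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
    if (seen[dst]) return(cut - graph$energy[src])
  }
  Inf
}

# random symmetric weighted graph for minimax tests
random_weight_matrix <- function(nv, p_edge = 0.6) {
  w <- matrix(NA_real_, nv, nv)
  for (a in seq_len(nv - 1)) {
    for (b in seq.int(a + 1, nv)) {
      if (stats::runif(1) < p_edge) {
        w[a, b] <- w[b, a] <- round(stats::runif(1, 0, 10), 2)
      }
    }
  }
  w
}
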