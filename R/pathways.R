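#' Auto-adjusted anchor count
#'
#' Empirical rule for the number of fuzzy related hishapes kept as pathway
#' anchors, derived from the `a * b^n * n^(-3/2)` growth asymptotics of
#' abstract-shape spaces with the numerator fixed at 124,000:
#' `k = round(124000 * n^(-3/2))`, floored at 1.
#'
#' @param n Sequence length in nt (`n >= 1`).
#' @return Integer anchor count.
#' @examples
#' auto_k(100) # 124
#' @export
auto_k <- function(n) {
  stopifnot(n >= 1)
  max(1L, as.integer(round(124000 * n^(-1.5))))
}

#' Fuzzy related hishapes
#'
#' Given two hishapes alpha and beta and a helix-index threshold theta, a
#' hishape gamma is fuzzy related when every one of its hairpin helix indices
#' lies within theta of some hairpin index of alpha or beta:
#' `max_{t in phi(gamma)} min_{z in phi(alpha) u phi(beta)} |t - z| <= theta`.
#' The open chain (empty phi) always qualifies (the maximum over the empty
#' set is taken as 0). With `theta = 0` this reduces to exact related
#' hishapes, whose indices are drawn from `phi(alpha) u phi(beta)` only.
#'
#' @param alpha,beta `hishape` objects or hishape texts.
#' @param theta Non-negative helix-index distance threshold (default 1).
#' @param universe The candidate hishapes: a list of `hishape` objects, a
#'   character vector of hishape texts, or a [classify()] result.
#' @return The qualifying subset of `universe`, in its original form, with
#'   the logical selection vector attached as attribute `"selected"`.
#' @examples
#' fuzzy_related_hishapes("[10]", "[20]", theta = 1, universe = c("[11]", "[15]"))
#' @export
fuzzy_related_hishapes <- function(alpha, beta, theta = 1, universe) {
  stopifnot(theta >= 0)
  ref <- unique(c(extract_hairpin_indices(alpha),
                  extract_hairpin_indices(beta)))
  phis <- universe_phis(universe)
  sel <- vapply(phis, function(ph) {
    if (length(ph) == 0L) return(TRUE)
    if (length(ref) == 0L) return(FALSE)
    all(vapply(ph, function(t) min(abs(t - ref)), numeric(1)) <= theta + 1e-9)
  }, logical(1))
  out <- if (inherits(universe, "hishape_classification")) {
    res <- universe[sel, , drop = FALSE]
    attr(res, "phi") <- attr(universe, "phi")[sel]
    res
  } else {
    universe[sel]
  }
  attr(out, "selected") <- sel
  out
}

universe_phis <- function(universe) {
  if (inherits(universe, "hishape_classification")) {
    attr(universe, "phi")
  } else if (is.character(universe)) {
    lapply(universe, function(tx) parse_hishape(tx)$phi)
  } else {
    lapply(universe, extract_hairpin_indices)
  }
}

#' Minimax (widest-bottleneck) Dijkstra
#'
#' Modified Dijkstra search in which the cost of a path is the maximum edge
#' weight along it rather than the sum; returns the path minimizing that
#' maximum. Ties are broken deterministically by node index.
#'
#' @param weights Symmetric numeric matrix of non-negative edge weights;
#'   `NA` or `Inf` entries denote absent edges.
#' @param source,target Node indices (or names matching `rownames(weights)`).
#' @return List with `path` (node indices) and `bottleneck` (the minimized
#'   maximum edge weight; `-Inf` for `source == target`).
#' @export
minimax_dijkstra <- function(weights, source, target) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (is.character(source)) source <- match(source, rownames(weights))
  if (is.character(target)) target <- match(target, rownames(weights))
  source <- as.integer(source)
  target <- as.integer(target)
  nv <- nrow(weights)
  stopifnot(source >= 1, source <= nv, target >= 1, target <= nv)
  if (source == target) {
    return(list(path = source, bottleneck = -Inf))
  }
  best <- rep(Inf, nv)
  prev <- rep(NA_integer_, nv)
  done <- logical(nv)
  best[source] <- -Inf
  repeat {
    cand <- which(!done & best < Inf)
    if (length(cand) == 0L) break
    u <- cand[order(best[cand], cand)[1]]
    if (u == target) break
    done[u] <- TRUE
    for (v in seq_len(nv)) {
      w <- weights[u, v]
      if (v == u || is.na(w) || !is.finite(w)) next
      cost <- max(best[u], w)
      if (cost < best[v]) {
        best[v] <- cost
        prev[v] <- u
      }
    }
  }
  if (!is.finite(best[target]) || best[target] == Inf) {
    stop("unreachable: no path connects source and target")
  }
  path <- target
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, bottleneck = best[target])
}

new_folding_path <- function(steps, energies, start_energy) {
  if (is.null(steps)) {
    return(structure(list(steps = character(0), energies = numeric(0),
                          saddle = Inf, barrier = Inf),
                     class = "folding_path"))
  }
  saddle <- max(energies)
  structure(list(steps = steps, energies = energies, saddle = saddle,
                 barrier = saddle - start_energy),
            class = "folding_path")
}

#' @export
print.folding_path <- function(x, ...) {
  if (length(x$steps) == 0L) {
    cat("Folding path: unreachable (barrier Inf)\n")
    return(invisible(x))
  }
  cat("Folding path (", length(x$steps), " steps, barrier ",
      sprintf("%.2f", x$barrier), " kcal/mol, saddle ",
      sprintf("%.2f", x$saddle), ")\n", sep = "")
  for (m in seq_along(x$steps)) {
    cat(sprintf("  %s  %8.2f\n", x$steps[m], x$energies[m]))
  }
  invisible(x)
}

#' Direct-path barrier estimation by width-k BFS
#'
#' Estimates the energy barrier between two structures along direct paths:
#' paths whose intermediates contain only base pairs present in the start or
#' target structure. The search proceeds level-wise towards the target
#' (every move strictly reduces the base-pair distance to the target, using
#' the modified neighborhood of [neighbors()]), keeping the `k` lowest
#' candidates per level ranked by the running path maximum, then current
#' energy, then dot-bracket. The returned barrier is an upper bound on the
#' exact barrier.
#'
#' @inheritParams structure_energy
#' @inheritParams exact_barrier
#' @param k Search width (default 10).
#' @return A `folding_path`: `steps` (dot-brackets from S to T), `energies`,
#'   `saddle` (max energy along the path, kcal/mol) and `barrier`
#'   (saddle minus the start energy). An empty-path object with
#'   `barrier = Inf` signals that no direct path was found.
#' @export
direct_path_bfs <- function(seq, S, T, k = 10,
                            params = energy_parameters()) {
  sq <- as_rna_sequence(seq)
  ptS <- validate_structure(S, seq = sq)$pt
  ptT <- validate_structure(T, seq = sq)$pt
  res <- bfs_direct(sq, ptS, ptT, k, params)
  new_folding_path(res$steps, res$energies, energy_pt(sq$chars, ptS, params))
}

pair_keys <- function(pt) {
  prs <- pairs_from_pt(pt)
  if (nrow(prs) == 0L) character(0) else paste(prs[, 1], prs[, 2])
}

# core beam search; returns list(steps, energies) or list(NULL, NULL)
bfs_direct <- function(sq, ptS, ptT, k, params) {
  chars <- sq$chars
  sdb <- db_from_pt(ptS)
  tdb <- db_from_pt(ptT)
  eS <- energy_pt(chars, ptS, params)
  if (sdb == tdb) return(list(steps = sdb, energies = eS))

  allowed <- union(pair_keys(ptS), pair_keys(ptT))
  tkeys <- pair_keys(ptT)
  dist_to_t <- function(keys) length(setdiff(keys, tkeys)) +
    length(setdiff(tkeys, keys))

  entry <- list(pt = ptS, db = sdb, keys = pair_keys(ptS),
                path = sdb, energies = eS, maxE = eS)
  frontier <- list(entry)
  # best running path-maximum with which each state was already expanded;
  # a state is re-expanded only when reached with a strictly better maximum
  label <- new.env(parent = emptyenv())
  label[[sdb]] <- entry$maxE
  maxiter <- 2L * length(allowed) + 10L
  best <- NULL   # best completed path so far

  for (iter in seq_len(maxiter)) {
    cands <- list()
    for (en in frontier) {
      d0 <- dist_to_t(en$keys)
      for (nb in neighbor_pts(chars, en$pt)) {
        keys <- pair_keys(nb)
        if (!all(keys %in% allowed)) next        # not a direct intermediate
        if (dist_to_t(keys) >= d0) next          # monotone progress
        db <- db_from_pt(nb)
        e <- energy_pt(chars, nb, params)
        mx <- max(en$maxE, e)
        known <- label[[db]]
        if (db != tdb && !is.null(known) && mx >= known - 1e-12) next
        cands[[length(cands) + 1L]] <- list(
          pt = nb, db = db, keys = keys,
          path = c(en$path, db), energies = c(en$energies, e),
          maxE = mx)
      }
    }
    if (length(cands) == 0L) break
    ord <- order(vapply(cands, `[[`, numeric(1), "maxE"),
                 vapply(cands, function(x) x$energies[length(x$energies)],
                        numeric(1)),
                 vapply(cands, `[[`, character(1), "db"))
    cands <- cands[ord]
    # drop duplicate states, keeping the best-ranked representative
    seen <- new.env(parent = emptyenv())
    uniq <- list()
    for (cd in cands) {
      if (cd$db == tdb) {
        # a completed path; keep the best, but do not stop the search
        if (is.null(best) || cd$maxE < best$maxE) best <- cd
        next
      }
      if (is.null(seen[[cd$db]])) {
        seen[[cd$db]] <- TRUE
        uniq[[length(uniq) + 1L]] <- cd
      }
    }
    if (length(uniq) == 0L) break
    frontier <- uniq[seq_len(min(k, length(uniq)))]
    for (en in frontier) label[[en$db]] <- en$maxE
  }
  if (is.null(best)) list(steps = NULL, energies = NULL)
  else list(steps = best$path, energies = best$energies)
}

#' Heuristic folding pathways via fuzzy-related anchors (HiPath2-style)
#'
#' Estimates a low-barrier folding pathway between two structures. The node
#' list consists of the start, the target and the hishreps of the `N`
#' lowest-energy fuzzy related hishapes at abstraction level `h`
#' ([fuzzy_related_hishapes()]); pairwise segment barriers are estimated by
#' width-`k` direct-path BFS in both directions (the smaller saddle is kept)
#' and stored as absolute saddle heights; a minimax Dijkstra search then
#' finds the node sequence whose largest segment saddle is smallest, and the
#' winning segments are concatenated into a single folding path. The
#' direct S-T edge is always part of the graph, so the returned barrier never
#' exceeds the plain direct-path estimate.
#'
#' @inheritParams direct_path_bfs
#' @param width BFS width `k` for the segment searches (default 10).
#' @param theta Fuzzy threshold in helix-index units (default 1).
#' @param anchors `"auto"` (use [auto_k()]) or a non-negative integer `N`;
#'   `0` falls back to the direct path.
#' @param classification Optional precomputed [classify()] result at level
#'   `"h"` for `seq` (avoids re-enumeration).
#' @param cache Optional environment memoizing BFS segments across calls.
#' @return A `folding_path` (see [direct_path_bfs()]) with the anchor node
#'   list in attribute `"nodes"` and the segment-saddle matrix in `"M"`.
#' @export
hipath2 <- function(seq, S, T, width = 10, theta = 1, anchors = "auto",
                    params = energy_parameters(), classification = NULL,
                    cache = NULL) {
  sq <- as_rna_sequence(seq)
  ptS <- validate_structure(S, seq = sq)$pt
  ptT <- validate_structure(T, seq = sq)$pt
  sdb <- db_from_pt(ptS)
  tdb <- db_from_pt(ptT)
  eS <- energy_pt(sq$chars, ptS, params)
  if (sdb == tdb) {
    return(new_folding_path(sdb, eS, eS))
  }

  n_anchor <- if (identical(anchors, "auto")) auto_k(sq$n)
              else as.integer(anchors)
  anchor_db <- character(0)
  if (n_anchor > 0L) {
    if (is.null(classification)) {
      classification <- classify(sq, level = "h", params = params)
    }
    alpha <- map_structure(sq, new_structure(ptS), "h")
    beta <- map_structure(sq, new_structure(ptT), "h")
    rel <- fuzzy_related_hishapes(alpha, beta, theta, classification)
    anchor_db <- utils::head(rel$hishrep, n_anchor)
  }

  nodes <- unique(c(sdb, tdb, anchor_db))
  m <- length(nodes)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  segment <- function(a, b) {
    key <- paste(a, b, width, sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fw <- bfs_direct(sq, parse_dotbracket(a)$pt, parse_dotbracket(b)$pt,
                     width, params)
    bw <- bfs_direct(sq, parse_dotbracket(b)$pt, parse_dotbracket(a)$pt,
                     width, params)
    sf <- if (is.null(fw$steps)) Inf else max(fw$energies)
    sb <- if (is.null(bw$steps)) Inf else max(bw$energies)
    res <- if (sf <= sb) {
      list(saddle = sf, steps = fw$steps, energies = fw$energies)
    } else {
      list(saddle = sb, steps = rev(bw$steps), energies = rev(bw$energies))
    }
    cache[[key]] <- res
    rev_res <- list(saddle = res$saddle, steps = rev(res$steps),
                    energies = rev(res$energies))
    cache[[paste(b, a, width, sep = "|")]] <- rev_res
    res
  }

  M <- matrix(Inf, m, m, dimnames = list(nodes, nodes))
  segs <- vector("list", m * m)
  dim(segs) <- c(m, m)
  for (a in seq_len(m - 1L)) {
    for (b in seq.int(a + 1L, m)) {
      sg <- segment(nodes[a], nodes[b])
      M[a, b] <- M[b, a] <- sg$saddle
      segs[[a, b]] <- sg
      segs[[b, a]] <- list(saddle = sg$saddle, steps = rev(sg$steps),
                           energies = rev(sg$energies))
    }
  }

  route <- tryCatch(minimax_dijkstra(M, 1L, 2L), error = function(e) NULL)
  if (is.null(route)) {
    out <- new_folding_path(NULL, NULL, eS)
    attr(out, "nodes") <- nodes
    attr(out, "M") <- M
    return(out)
  }
  steps <- character(0)
  energies <- numeric(0)
  for (q in seq_len(length(route$path) - 1L)) {
    sg <- segs[[route$path[q], route$path[q + 1L]]]
    if (q > 1L) {
      # consecutive segments share their junction hishrep; drop the duplicate
      steps <- c(steps, sg$steps[-1L])
      energies <- c(energies, sg$energies[-1L])
    } else {
      steps <- c(steps, sg$steps)
      energies <- c(energies, sg$energies)
    }
  }
  out <- new_folding_path(steps, energies, eS)
  attr(out, "nodes") <- nodes
  attr(out, "M") <- M
  out
}
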