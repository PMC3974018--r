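#' Exact landscape graph of a small sequence
#'
#' Builds the full folding landscape: every lonely-pair-free structure as a
#' node (with its energy) and the modified single-pair neighborhood as the
#' (undirected) edge relation. Intended as an exact reference at desk scale;
#' heuristic barrier estimates can be checked against flooding this graph.
#'
#' @inheritParams structure_energy
#' @param max_len Refusal limit for building the full graph (default 30 nt).
#' @return List of class `landscape_graph` with `db` (dot-brackets),
#'   `energy`, and `adj` (adjacency list of node indices).
#' @export
landscape_graph <- function(seq, params = energy_parameters(), max_len = 30) {
  sq <- as_rna_sequence(seq)
  if (sq$n > max_len) {
    stop("sequence length ", sq$n, " exceeds the landscape limit (",
         max_len, " nt)")
  }
  space <- enumerate_structures(sq, params = params)
  pt_list <- attr(space, "pt_list")
  idx <- seq_len(nrow(space))
  names(idx) <- space$structure
  adj <- vector("list", nrow(space))
  for (v in idx) {
    nbs <- neighbor_pts(sq$chars, pt_list[[v]])
    adj[[v]] <- unname(idx[vapply(nbs, db_from_pt, character(1))])
  }
  structure(list(db = space$structure, energy = space$energy, adj = adj),
            class = "landscape_graph", n = sq$n)
}

#' Exact energy barrier by landscape flooding
#'
#' The exact saddle height between two structures is the minimum over all
#' landscape paths of the maximum energy along the path; the barrier is that
#' height minus the energy of the start. Computed by a best-first
#' (minimax-Dijkstra) sweep over the fully enumerated landscape, with
#' deterministic dot-bracket tie-breaking. `barrier(S, S) = 0` and
#' `barrier >= max(0, dG(T) - dG(S))` always hold.
#'
#' @inheritParams structure_energy
#' @param S,T Start and target structures (dot-bracket or
#'   `secondary_structure`).
#' @param graph Optional precomputed [landscape_graph()] for `seq`.
#' @param max_len Refusal limit (default 30 nt).
#' @return Barrier in kcal/mol, with the witnessing saddle height in
#'   attribute `"saddle"`.
#' @export
exact_barrier <- function(seq, S, T, params = energy_parameters(),
                          graph = NULL, max_len = 30) {
  sq <- as_rna_sequence(seq)
  if (is.null(graph)) graph <- landscape_graph(sq, params, max_len = max_len)
  sdb <- write_dotbracket(as_structure(S))
  tdb <- write_dotbracket(as_structure(T))
  src <- match(sdb, graph$db)
  dst <- match(tdb, graph$db)
  if (is.na(src)) stop("start structure is not in the landscape: ", sdb)
  if (is.na(dst)) stop("target structure is not in the landscape: ", tdb)

  nv <- length(graph$db)
  best <- rep(Inf, nv)               # minimal achievable path maximum
  done <- logical(nv)
  best[src] <- graph$energy[src]
  repeat {
    cand <- which(!done & is.finite(best))
    if (length(cand) == 0L) break
    # deterministic: smallest saddle, then dot-bracket order
    u <- cand[order(best[cand], graph$db[cand])[1]]
    if (u == dst) break
    done[u] <- TRUE
    for (v in graph$adj[[u]]) {
      cost <- max(best[u], graph$energy[v])
      if (cost < best[v]) best[v] <- cost
    }
  }
  if (!is.finite(best[dst])) {
    stop("unreachable: no landscape path connects the two structures")
  }
  b <- best[dst] - graph$energy[src]
  attr(b, "saddle") <- best[dst]
  b
}
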