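#' Modified single-pair neighborhood with lonely-pair repair
#'
#' Returns all structures reachable from `structure` by one base-pair move
#' under the lonely-pair-free move set. A pair is removed or added as usual;
#' if the raw result is valid it is a neighbor. If a removal leaves exactly
#' one lonely pair, that pair is deleted as well (the result differs by two
#' adjacent pairs). If an addition creates a lonely pair, an adjacent pair
#' (`(i-1, j+1)` or `(i+1, j-1)`) is closed when possible -- each closable
#' completion is a neighbor, which keeps the relation symmetric -- and the
#' move is discarded when neither exists.
#'
#' @inheritParams structure_energy
#' @param structure A valid lonely-pair-free `secondary_structure` or
#'   dot-bracket string.
#' @return List of `secondary_structure` objects, all valid, distinct from
#'   the input and from each other (possibly empty).
#' @examples
#' neighbors("GGAAACC", "((...))")
#' @export
neighbors <- function(seq, structure, params = energy_parameters()) {
  sq <- as_rna_sequence(seq)
  s <- validate_structure(structure, seq = sq)
  out_pt <- neighbor_pts(sq$chars, s$pt)
  lapply(out_pt, new_structure)
}

# core neighborhood on pair tables; returns deduplicated list of pair tables
neighbor_pts <- function(chars, pt) {
  n <- length(pt)
  self <- db_from_pt(pt)
  found <- new.env(parent = emptyenv())
  out <- list()
  keep <- function(cand) {
    db <- db_from_pt(cand)
    if (db != self && is.null(found[[db]])) {
      found[[db]] <- TRUE
      out[[length(out) + 1L]] <<- cand
    }
  }

  prs <- pairs_from_pt(pt)

  # removals
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, 1]; j <- prs[r, 2]
    cand <- pt
    cand[i] <- 0L; cand[j] <- 0L
    lonely <- lonely_near(cand, i, j)
    if (nrow(lonely) == 0L) {
      keep(cand)
    } else if (nrow(lonely) == 1L) {
      cand[lonely[1, 1]] <- 0L
      cand[lonely[1, 2]] <- 0L
      keep(cand)
    } # two lonely remnants: move discarded
  }

  # additions
  for (i in seq_len(max(0L, n - 4L))) {
    if (pt[i] != 0L) next
    for (j in seq.int(i + 4L, n)) {
      if (pt[j] != 0L) next
      if (!can_pair_bases(chars[i], chars[j])) next
      if (!addable(pt, i, j)) next
      cand <- pt
      cand[i] <- j; cand[j] <- i
      if (is_stacked(cand, i, j)) {
        keep(cand)
      } else {
        for (repaired in repair_addition(chars, cand, i, j)) keep(repaired)
      }
    }
  }

  out
}

# pairs adjacent to the removed (i,j) that are now lonely
lonely_near <- function(pt, i, j) {
  n <- length(pt)
  res <- matrix(integer(0), ncol = 2)
  if (i > 1 && pt[i - 1] == j + 1 && !is_stacked(pt, i - 1L, j + 1L)) {
    res <- rbind(res, c(i - 1L, j + 1L))
  }
  if (i + 1 <= n && pt[i + 1] == j - 1 && !is_stacked(pt, i + 1L, j - 1L)) {
    res <- rbind(res, c(i + 1L, j - 1L))
  }
  res
}

is_stacked <- function(pt, i, j) {
  n <- length(pt)
  (i + 1 <= n && pt[i + 1] == j - 1) ||
    (i - 1 >= 1 && j + 1 <= n && pt[i - 1] == j + 1)
}

# can pair (i,j) be inserted without crossing / position reuse?
addable <- function(pt, i, j) {
  if (pt[i] != 0L || pt[j] != 0L) return(FALSE)
  if (j - i < 4L) return(FALSE)
  inside <- if (i + 1 <= j - 1) pt[seq.int(i + 1L, j - 1L)] else integer(0)
  paired <- inside[inside != 0L]
  all(paired > i & paired < j)
}

# close an adjacent pair next to freshly added lonely (i,j); every closable
# completion is a neighbor (keeps the move relation symmetric)
repair_addition <- function(chars, pt, i, j) {
  n <- length(pt)
  out <- list()
  for (q in list(c(i - 1L, j + 1L), c(i + 1L, j - 1L))) {
    a <- q[1]; b <- q[2]
    if (a >= 1 && b <= n && b - a >= 4 &&
        can_pair_bases(chars[a], chars[b]) && addable(pt, a, b)) {
      cand <- pt
      cand[a] <- b; cand[b] <- a
      if (pt_is_nolp(cand)) out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Local optimality under the modified neighborhood
#'
#' A structure is locally optimal when no neighbor (see [neighbors()]) has
#' strictly lower free energy; equal-energy neighbors do not disqualify it.
#'
#' @inheritParams neighbors
#' @return Logical scalar.
#' @examples
#' is_locally_optimal("AAAA", "....")
#' @export
is_locally_optimal <- function(seq, structure, params = energy_parameters()) {
  sq <- as_rna_sequence(seq)
  s <- validate_structure(structure, seq = sq)
  e0 <- energy_pt(sq$chars, s$pt, params)
  for (nb in neighbor_pts(sq$chars, s$pt)) {
    if (energy_pt(sq$chars, nb, params) < e0 - 1e-12) return(FALSE)
  }
  TRUE
}
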