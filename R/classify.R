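#' Hishape classification of the folding space
#'
#' Enumerates the (optionally strictly-negative-filtered) folding space of a
#' sequence, maps every structure to its hishape at the requested abstraction
#' level, and aggregates the classes. Per class alpha the partition-function
#' contribution is `Z_alpha = sum_x exp(-dG(x)/kT)` over the class members,
#' the ensemble energy is `dG(alpha) = -kT log Z_alpha`, and the probability
#' is `P(alpha) = Z_alpha / sum_beta Z_beta` over the same (filtered) space.
#' The class representative (hishrep) is the minimum-free-energy member with
#' a lexicographic dot-bracket tie-break.
#'
#' @inheritParams structure_energy
#' @inheritParams map_structure
#' @param strictly_negative Restrict the space to strictly negative
#'   structures (see [is_strictly_negative()]) before classifying.
#' @param k_best Number of classes to return, ranked by hishrep energy with
#'   hishape-text tie-break; `Inf` (default) returns all. Probabilities are
#'   always computed over the full filtered space, not the returned head.
#' @param energy_band,max_len Passed to [enumerate_structures()].
#' @param space Optional precomputed result of [enumerate_structures()] for
#'   the same sequence and parameters, to avoid re-enumeration.
#' @return A data frame of class `hishape_classification` with columns
#'   `hishape`, `hishrep` (dot-bracket), `hishrep_energy`, `members`, `Z`,
#'   `ensemble_energy` and `probability`, plus attributes `level`, `kT`,
#'   `total_Z`, `n` and `phi` (list of hairpin-index sets per class).
#' @examples
#' classify("GGAAACC", level = "h")
#' @export
classify <- function(seq, level = "h", strictly_negative = FALSE,
                     k_best = Inf, params = energy_parameters(),
                     energy_band = NULL, max_len = 60, space = NULL) {
  lv <- normalize_level(level)
  sq <- as_rna_sequence(seq)
  if (is.null(space)) {
    space <- enumerate_structures(sq, params = params,
                                  energy_band = energy_band,
                                  max_len = max_len)
  }
  pt_list <- attr(space, "pt_list")
  keep <- rep(TRUE, nrow(space))
  if (strictly_negative) {
    keep <- vapply(pt_list, function(pt) sn_pt(sq$chars, pt, params),
                   logical(1))
  }
  db <- space$structure[keep]
  energy <- space$energy[keep]
  pts <- pt_list[keep]

  texts <- character(length(db))
  phis <- vector("list", length(db))
  for (m in seq_along(db)) {
    tree <- helix_tree(pts[[m]])
    h <- render_hishape(tree, lv)
    texts[m] <- h$text
    phis[[m]] <- h$phi
  }

  ktval <- kT(params)
  emin <- min(energy)                     # stabilized Boltzmann sums
  groups <- split(seq_along(db), texts)
  cls <- lapply(names(groups), function(tx) {
    idx <- groups[[tx]]
    # space is energy-sorted, so idx[1] is the hishrep (ties broken by db)
    rep_i <- idx[order(energy[idx], db[idx])[1]]
    Zs <- sum(exp(-(energy[idx] - emin) / ktval))
    data.frame(hishape = tx, hishrep = db[rep_i],
               hishrep_energy = energy[rep_i],
               members = length(idx), Zscaled = Zs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cls)
  phi_by_class <- lapply(names(groups), function(tx) {
    unique(phis[[groups[[tx]][1]]])
  })

  total_scaled <- sum(out$Zscaled)
  out$Z <- out$Zscaled * exp(-emin / ktval)
  out$ensemble_energy <- -ktval * (log(out$Zscaled) - emin / ktval)
  out$probability <- out$Zscaled / total_scaled
  out$Zscaled <- NULL

  ord <- order(out$hishrep_energy, out$hishape)
  out <- out[ord, , drop = FALSE]
  phi_by_class <- phi_by_class[ord]
  if (is.finite(k_best) && k_best < nrow(out)) {
    sel <- seq_len(k_best)
    out <- out[sel, , drop = FALSE]
    phi_by_class <- phi_by_class[sel]
  }
  rownames(out) <- NULL
  class(out) <- c("hishape_classification", "data.frame")
  attr(out, "level") <- lv
  attr(out, "kT") <- ktval
  attr(out, "total_Z") <- total_scaled * exp(-emin / ktval)
  attr(out, "n") <- sq$n
  attr(out, "phi") <- phi_by_class
  out
}

# hishape from a precomputed helix tree (shared by map_structure / classify)
render_hishape <- function(tree, lv) {
  nh <- nrow(tree$helices)
  value <- if (nh) (tree$helices[, "ii"] + tree$helices[, "ij"]) / 2 else numeric(0)
  render <- function(h) {
    kids <- which(tree$parent == h)
    kids <- kids[order(tree$helices[kids, "oi"])]
    kid_items <- unlist(lapply(kids, render), use.names = FALSE)
    k <- tree$kind[h]
    idx <- fmt_index(value[h])
    if (k == "hairpin") {
      idx
    } else if (k %in% c("bulge", "internal")) {
      if (lv == "a") c(paste0(idx, substr(k, 1, 1)), kid_items) else kid_items
    } else {
      group <- paste0("(", paste(kid_items, collapse = ","), ")")
      if (lv %in% c("m", "a")) paste0(idx, "m", group)
      else if (lv == "h+") group
      else kid_items
    }
  }
  tops <- which(tree$parent == 0L)
  tops <- tops[order(tree$helices[tops, "oi"])]
  items <- unlist(lapply(tops, render), use.names = FALSE)
  text <- if (length(items) == 0L) "[_]"
          else paste0("[", paste(items, collapse = ","), "]")
  list(text = text, phi = unname(value[tree$kind == "hairpin"]))
}

#' @export
print.hishape_classification <- function(x, ...) {
  cat("Hishape classification, level ", attr(x, "level"),
      " (", nrow(x), " classes, n = ", attr(x, "n"), " nt)\n", sep = "")
  print.data.frame(x, digits = 6)
  invisible(x)
}
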