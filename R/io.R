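#' Read RNA sequences from FASTA
#'
#' Reads a FASTA file and normalizes the records (uppercase, `T` to `U`),
#' preserving identifiers.
#'
#' @param path Path to a FASTA file.
#' @return List of [rna_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE),
    error = function(e) stop("cannot parse FASTA ", path, ": ",
                             conditionMessage(e)))
  if (length(recs) == 0) stop("no sequences in ", path)
  lapply(seq_along(recs), function(r) {
    rna_sequence(as.character(recs[[r]]), id = names(recs)[r])
  })
}

#' Write RNA sequences to FASTA
#'
#' @param seqs A single [rna_sequence()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  seqinr::write.fasta(lapply(seqs, function(s) s$seq),
                      names = vapply(seqs, function(s) s$id, character(1)),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

fmt6 <- function(x) sprintf("%.6f", x)

#' Write a hishape classification as TSV
#'
#' Columns: hishrep dot-bracket, free energy `dG`, hishape text and
#' probability `P`, with all floating-point output at 6 decimals.
#'
#' @param classification A [classify()] result.
#' @param path Output path or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_hishape_tsv <- function(classification, path = "") {
  lines <- c(paste("hishrep", "dG", "hishape", "P", sep = "\t"),
             paste(classification$hishrep,
                   fmt6(classification$hishrep_energy),
                   classification$hishape,
                   fmt6(classification$probability), sep = "\t"))
  writeLines(lines, con = if (nzchar(path)) path else stdout())
  invisible(path)
}

#' Write an occupancy trajectory as TSV
#'
#' Column 1 is the time in microseconds; one column per hishape follows.
#'
#' @param traj An `occupancy_trajectory` from [propagate()] or
#'   [simulate_kinetics()].
#' @param path Output path or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path = "") {
  states <- attr(traj, "states")
  header <- paste(c("time", states), collapse = "\t")
  rows <- apply(as.matrix(traj), 1, function(r) {
    paste(c(sprintf("%.6g", r[1]), fmt6(r[-1])), collapse = "\t")
  })
  writeLines(c(header, rows), con = if (nzchar(path)) path else stdout())
  invisible(path)
}

#' Write a folding path trace as TSV
#'
#' @param path_obj A `folding_path`.
#' @param path Output path or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_path_tsv <- function(path_obj, path = "") {
  lines <- c(paste("step", "structure", "energy", sep = "\t"),
             if (length(path_obj$steps)) {
               paste(seq_along(path_obj$steps), path_obj$steps,
                     fmt6(path_obj$energies), sep = "\t")
             })
  writeLines(lines, con = if (nzchar(path)) path else stdout())
  invisible(path)
}
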