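#' Pentablock chain topology
#'
#' Defines the symmetric linear C-B-A-B-C pentablock chain: `nC` beads of
#' species C at each free end, `nB` beads of B on each side, and `lA` beads of
#' A in the centre.  The bead sequence is palindromic and consecutive beads
#' are bonded, so a chain of length `2*nC + 2*nB + lA` carries one bond fewer
#' than it has beads.
#'
#' @param nC Beads per terminal C block (>= 1).
#' @param nB Beads per B block (>= 1).
#' @param lA Beads in the central A block (>= 1).
#' @return An object of class `chain_topology`: list with `nC`, `nB`, `lA`,
#'   `length`, `sequence` (character vector of species per bead) and `bonds`
#'   (two-column integer matrix of 1-based adjacent bead pairs).
#' @examples
#' chain_topology(3, 3, 6)   # the C3 B3 A6 B3 C3 reference chain, 18 beads
#' @export
chain_topology <- function(nC, nB, lA) {
  for (nm in c("nC", "nB", "lA")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 ||
        v != round(v))
      stop(sprintf("block length '%s' must be a positive integer", nm))
  }
  nC <- as.integer(nC); nB <- as.integer(nB); lA <- as.integer(lA)
  seqv <- c(rep("C", nC), rep("B", nB), rep("A", lA), rep("B", nB),
            rep("C", nC))
  len <- length(seqv)
  bonds <- cbind(seq_len(len - 1L), seq_len(len - 1L) + 1L)
  structure(list(nC = nC, nB = nB, lA = lA, length = len, sequence = seqv,
                 bonds = bonds),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("Pentablock chain C%d B%d A%d B%d C%d: %d beads, %d bonds\n",
              x$nC, x$nB, x$lA, x$nB, x$nC, x$length, nrow(x$bonds)))
  cat(" ", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}
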