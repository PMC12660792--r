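#' Experimentally important receptor residues for peptide contact analysis
#'
#' The mutagenesis-supported GnRH1 receptor residues used to score "important
#' contacts" during candidate selection, in author numbering.
#'
#' @return Tibble with columns `resno` and `resid`.
#' @export
gnrh1r_important_residues <- function() {
  tibble(
    resno = c(23L, 32L, 38L, 98L, 102L, 121L, 174L, 178L, 280L, 283L, 284L,
              286L, 290L, 302L, 306L, 308L, 309L),
    resid = c("LEU", "THR", "ARG", "ASP", "ASN", "LYS", "GLN", "PHE", "TRP",
              "TYR", "TYR", "LEU", "TYR", "ASP", "HIS", "PHE", "PHE")
  )
}

#' Inter-chain residue contacts of a docked pose
#'
#' A general contact is an inter-chain residue pair whose representative
#' atoms (Cbeta; Calpha for glycine) lie within `contact_cutoff` of each
#' other.  An important contact is a general contact whose receptor residue
#' belongs to `important_residues`.
#'
#' @param model A `structure_model` containing both chains.
#' @param peptide_chain,receptor_chain Chain identifiers.
#' @param contact_cutoff Distance cutoff in Angstrom (default 5).
#' @param important_residues Integer vector (or tibble with a `resno` column)
#'   of receptor residue numbers counted as important.
#' @return A `contact_report`: tibble of contacting pairs
#'   (`peptide_resno`, `peptide_resid`, `receptor_resno`, `receptor_resid`,
#'   `dist`, `important`) with attributes `n_general` and `n_important`.
#' @export
compute_contacts <- function(model, peptide_chain = "B", receptor_chain = "A",
                             contact_cutoff = 5,
                             important_residues = gnrh1r_important_residues()) {
  stopifnot(inherits(model, "structure_model"))
  if (is.data.frame(important_residues)) {
    important_residues <- important_residues$resno
  }
  pep <- representative_atoms(model, peptide_chain)
  rec <- representative_atoms(model, receptor_chain)
  if (nrow(pep) == 0) abort(sprintf("chain '%s' not present", peptide_chain))
  if (nrow(rec) == 0) abort(sprintf("chain '%s' not present", receptor_chain))
  pm <- cbind(pep$x, pep$y, pep$z)
  rm_ <- cbind(rec$x, rec$y, rec$z)
  d2 <- outer(rowSums(pm^2), rowSums(rm_^2), "+") - 2 * pm %*% t(rm_)
  d2[d2 < 0] <- 0
  hit <- which(sqrt(d2) < contact_cutoff, arr.ind = TRUE)
  pairs <- tibble(
    peptide_resno = pep$resno[hit[, 1]],
    peptide_resid = pep$resid[hit[, 1]],
    receptor_resno = rec$resno[hit[, 2]],
    receptor_resid = rec$resid[hit[, 2]],
    dist = sqrt(d2[hit]),
    important = rec$resno[hit[, 2]] %in% important_residues
  )
  pairs <- dplyr::arrange(pairs, .data$peptide_resno, .data$receptor_resno)
  attr(pairs, "n_general") <- nrow(pairs)
  attr(pairs, "n_important") <- sum(pairs$important)
  class(pairs) <- c("contact_report", class(pairs))
  pairs
}

# One representative atom per residue of a chain: CB, or CA for glycine.
# A non-glycine residue without a CB is an error, never a silent CA fallback.
representative_atoms <- function(model, chain) {
  atoms <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0) return(atoms)
  want <- ifelse(atoms$resid == "GLY", "CA", "CB")
  rep_at <- atoms[atoms$elety == want, , drop = FALSE]
  rep_at <- rep_at[!duplicated(rep_at$resno), , drop = FALSE]
  res <- dplyr::distinct(atoms, .data$resno, .data$resid)
  miss <- which(!res$resno %in% rep_at$resno)
  if (length(miss) > 0) {
    i <- miss[1]
    abort(sprintf("residue %s %s %d has no representative atom (%s)",
                  res$resid[i], chain, res$resno[i],
                  if (identical(res$resid[i], "GLY")) "CA" else "CB"))
  }
  rep_at[order(rep_at$resno), , drop = FALSE]
}

# Topology row indices of the representative atoms of a chain
rep_atom_indices <- function(model, chain) {
  atoms <- model$atoms
  want <- ifelse(atoms$resid == "GLY", "CA", "CB")
  idx <- which(atoms$chain == chain & atoms$elety == want)
  idx <- idx[!duplicated(atoms$resno[idx])]
  n_res <- length(unique(atoms$resno[atoms$chain == chain]))
  if (length(idx) != n_res) {
    # fall back to the checked path for a precise error message
    representative_atoms(model, chain)
  }
  idx[order(atoms$resno[idx])]
}
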