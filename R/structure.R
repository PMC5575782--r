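#' Read one chain of a PDB-format coordinate file
#'
#' Parses ATOM records for the named chain into an atom-level tibble.
#' HETATM records (including waters) and hydrogen atoms are skipped, so
#' downstream distances use heavy atoms only, matching how interface
#' criteria are usually applied to crystal structures.
#'
#' @param path PDB-format text file.
#' @param chain_id single chain identifier character.
#' @return A `structure_chain` tibble with columns `chain`, `resno`,
#'   `resid` (3-letter residue name), `elety` (atom name), `x`, `y`, `z`.
#' @export
read_structure <- function(path, chain_id) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  # drop hydrogens by element symbol when present, else by atom-name heuristic
  if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)), na.rm = TRUE)) {
    at <- at[is.na(at$elesy) | trimws(at$elesy) != "H", , drop = FALSE]
  } else {
    at <- at[!grepl("^[0-9]*H", trimws(at$elety)), , drop = FALSE]
  }
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0L) {
    abort(paste0("no ATOM records for chain `", chain_id, "` in ", path))
  }
  out <- tibble(
    chain = at$chain, resno = as.integer(at$resno), resid = at$resid,
    elety = at$elety, x = at$x, y = at$y, z = at$z
  )
  if (anyNA(out$x) || anyNA(out$y) || anyNA(out$z)) {
    abort(paste0("unparseable coordinates in ", path))
  }
  class(out) <- c("structure_chain", class(tibble()))
  out
}

#' @export
print.structure_chain <- function(x, ...) {
  cat("<structure_chain> chain ", x$chain[1L], ": ",
      length(unique(x$resno)), " residues, ", nrow(x), " heavy atoms\n",
      sep = "")
  NextMethod()
}

#' One-letter sequence of a structure chain
#'
#' @param chain a `structure_chain`.
#' @return Character scalar; unknown residue names become `X`.
#' @export
chain_sequence <- function(chain) {
  res <- chain |> distinct(.data$resno, .data$resid) |> arrange(.data$resno)
  aa1 <- bio3d::aa321(res$resid)
  aa1[is.na(aa1) | aa1 == ""] <- "X"
  paste(aa1, collapse = "")
}

#' Detect interface residues between two chains
#'
#' A residue of chain `a` is at the interface when any of its heavy atoms
#' lies within `cutoff` angstroms (inclusive) of any heavy atom of chain
#' `b`, and symmetrically. Distances are exact all-pairs Euclidean
#' distances, not grid-approximate.
#'
#' @param a,b `structure_chain` tibbles (see [read_structure()]).
#' @param cutoff contact distance in angstroms (default 4.0).
#' @param protein_a,protein_b family-member identifiers the chains
#'   represent, recorded in the returned interface sets.
#' @return A list of two tibbles `a` and `b`, each with `protein_id` and
#'   `native_pos` (the residue numbers at the interface).
#' @export
detect_interface <- function(a, b, cutoff = 4.0,
                             protein_a = "chain_a", protein_b = "chain_b") {
  if (cutoff <= 0) abort("cutoff must be positive")
  if (nrow(a) == 0L || nrow(b) == 0L) abort("chains must be non-empty")
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  # squared distances via the expansion |u-v|^2 = |u|^2 + |v|^2 - 2 u.v
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hit <- d2 <= cutoff^2 + 1e-12
  res_a <- sort(unique(a$resno[rowSums(hit) > 0L]))
  res_b <- sort(unique(b$resno[colSums(hit) > 0L]))
  list(
    a = tibble(protein_id = protein_a, native_pos = res_a),
    b = tibble(protein_id = protein_b, native_pos = res_b)
  )
}

#' Map structure residues to alignment columns
#'
#' Globally aligns the chain's one-letter sequence to the named family
#' member's ungapped sequence (BLOSUM62, affine gaps) and composes the
#' result with the member's residue map, yielding `resno -> column` for
#' every modeled residue that pairs with a member residue. Engineered
#' constructs and unmodeled loops are tolerated; an identity below
#' `min_identity` over the aligned (paired) length is an error.
#'
#' @param chain a `structure_chain`.
#' @param aln the family [alignment()].
#' @param protein_id the member the chain represents.
#' @param min_identity minimum fraction of identical paired residues
#'   (default 0.95).
#' @return A tibble `resno`, `native_pos`, `column`.
#' @export
map_structure_to_alignment <- function(chain, aln, protein_id,
                                       min_identity = 0.95) {
  cseq <- chain_sequence(chain)
  mseq <- ungapped_seq(aln, protein_id)
  # ends-free alignment: a crystallized construct is usually a fragment of
  # the full-length member, so terminal gaps carry no penalty
  pa <- Biostrings::pairwiseAlignment(
    cseq, mseq, type = "overlap",
    substitutionMatrix = default_submat(),
    gapOpening = 10, gapExtension = 0.5
  )
  pch <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sch <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  paired <- pch != "-" & sch != "-"
  ident <- sum(pch[paired] == sch[paired]) / sum(paired)
  if (ident < min_identity) {
    abort(sprintf(
      "chain/member identity %.3f below required %.3f for `%s`",
      ident, min_identity, protein_id
    ))
  }
  ip <- Biostrings::start(Biostrings::pattern(pa)) - 1L + cumsum(pch != "-")
  is_ <- Biostrings::start(Biostrings::subject(pa)) - 1L + cumsum(sch != "-")
  resnos <- sort(unique(chain$resno))
  rmap <- residue_map(aln)
  tibble(
    resno = resnos[ip[paired]],
    native_pos = is_[paired]
  ) |>
    mutate(column = map_to_column(rmap, protein_id, .data$native_pos))
}

#' Project MAP bins onto a structure
#'
#' Writes a PDB-format copy of the chain in which each atom's B-factor
#' field carries its residue's projection bin (two decimals); residues with
#' no scored MAP get 0.00. The output colors hotspot intensity when loaded
#' into a molecular viewer.
#'
#' @param chain a `structure_chain`.
#' @param mapping `resno -> column` tibble from
#'   [map_structure_to_alignment()].
#' @param scored a `map_scores` tibble (needs `column` and `bin`).
#' @param path output PDB file path.
#' @return `path`, invisibly.
#' @export
project_scores <- function(chain, mapping, scored, path) {
  bins <- mapping |>
    left_join(scored[, c("column", "bin")], by = "column") |>
    mutate(bin = tidyr::replace_na(.data$bin, 0L))
  b <- bins$bin[match(chain$resno, bins$resno)]
  b[is.na(b)] <- 0L
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(chain[, c("x", "y", "z")]))),
    resno = chain$resno,
    resid = chain$resid,
    eleno = seq_len(nrow(chain)),
    elety = chain$elety,
    chain = chain$chain,
    o = rep(1, nrow(chain)),
    b = round(as.numeric(b), 2)
  )
  invisible(path)
}
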