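aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Simulate a homologous protein family alignment
#'
#' Star-phylogeny sampling: an ancestor sequence is drawn from a uniform
#' 20-letter background; each descendant copies the ancestor letter at
#' column `j` with probability `conservation[j]` and otherwise draws
#' uniformly from the background. Contiguous gap segments (mean length 4)
#' are then inserted per sequence so that the expected gap fraction is
#' `gap_rate`. The star topology is deliberate: the column-composition
#' features this package computes do not depend on phylogenetic
#' covariance, so a tree adds nothing testable (a documented limitation
#' for realism).
#'
#' @param n_seqs number of sequences (>= 2).
#' @param length alignment length in columns.
#' @param conservation per-column copy probability in `[0, 1]`; a scalar is
#'   recycled (default 0.5).
#' @param gap_rate expected per-sequence gap fraction (default 0.02).
#' @param seed optional integer; the same seed reproduces the alignment
#'   exactly.
#' @return A `ptm_alignment` with rows `sim_01`, `sim_02`, ...
#' @export
simulate_family <- function(n_seqs = 40L, length = 300L, conservation = 0.5,
                            gap_rate = 0.02, seed = NULL) {
  if (n_seqs < 2L || length < 1L) abort("need n_seqs >= 2 and length >= 1")
  conservation <- rep_len(conservation, length)
  if (any(conservation < 0 | conservation > 1) || gap_rate < 0 ||
      gap_rate >= 1) {
    abort("conservation and gap_rate must be valid probabilities")
  }
  with_seed_maybe(seed, {
    ancestor <- sample(aa_alphabet, length, replace = TRUE)
    rows <- vapply(seq_len(n_seqs), function(i) {
      copy <- runif(length) < conservation
      letters_ <- ifelse(copy, ancestor,
                         sample(aa_alphabet, length, replace = TRUE))
      if (gap_rate > 0) {
        n_segs <- rpois(1L, gap_rate * length / 4)
        for (s in seq_len(n_segs)) {
          w <- 1L + rpois(1L, 3)
          start <- sample.int(max(1L, length - w + 1L), 1L)
          letters_[start:min(length, start + w - 1L)] <- "-"
        }
      }
      paste(letters_, collapse = "")
    }, character(1L))
    alignment(setNames(rows, sprintf("sim_%02d", seq_len(n_seqs))),
              organism = "synthetic", is_query = TRUE)
  })
}

#' Plant PTM hotspots and background sites into an alignment
#'
#' Emulates the empirical structure of family PTM data: a few hotspot
#' columns dense in phosphorylation, sparse background singletons, and
#' known-function labels concentrated around a subset of hotspots.
#' Hotspot columns are rewritten to high phospho-acceptor content
#' (`acceptor_conservation` of non-gap rows become S/T) and receive
#' `max(1, Poisson(ptms_per_hotspot))` phospho records on distinct
#' sequences. Functional hotspots are embedded in dense clusters the way
#' empirically functional sites are: their own records are labelled
#' known-function and a known-function neighbor MAP with `flank_ptms`
#' records is planted at both `-window` and `+window` columns, putting the
#' whole functional cluster near 14 PTMs — the density at which empirical
#' clusters reliably harbor functional sites. Background
#' columns receive exactly one unlabelled record and lie more than
#' `2 * window` columns from every hotspot; hotspots are spaced more than
#' `4 * window` columns apart so clusters never interact.
#'
#' @param aln a [alignment()], typically from [simulate_family()].
#' @param n_hotspots number of hotspot columns (default 5).
#' @param ptms_per_hotspot Poisson mean PTM count per hotspot (default 6).
#' @param n_background number of background singleton columns (default 30).
#' @param functional_fraction fraction of hotspots that are functional
#'   (default 0.4, i.e. 2 of 5).
#' @param window cluster half-width the spacing guards against (default 2).
#' @param flank_ptms records per known-function flank MAP (default 4).
#' @param acceptor_conservation fraction of non-gap rows forced to S/T at
#'   hotspot columns (default 0.95).
#' @param seed optional integer for exact reproducibility.
#' @return A list with `alignment` (letters rewritten at planted columns),
#'   `ptms` (validated record tibble), and `truth` (list of
#'   `hotspot_columns`, `functional_columns`, `background_columns`,
#'   `flank_columns`).
#' @export
plant_ptms <- function(aln, n_hotspots = 5L, ptms_per_hotspot = 6,
                       n_background = 30L, functional_fraction = 0.4,
                       window = 2L, flank_ptms = 4L,
                       acceptor_conservation = 0.95, seed = NULL) {
  L <- n_columns(aln)
  m <- alignment_matrix(aln)
  with_seed_maybe(seed, {
    lo <- 2L * window + 1L
    hi <- L - 2L * window
    if (hi < lo) abort("alignment too short for the requested window")
    cand <- sample(seq(lo, hi))
    hot <- integer(0L)
    for (cc in cand) {
      if (all(abs(cc - hot) > 4L * window)) hot <- c(hot, cc)
      if (length(hot) == n_hotspots) break
    }
    if (length(hot) < n_hotspots) {
      abort("could not place hotspots with the required spacing; lower n")
    }
    hot <- sort(hot)
    n_fun <- round(functional_fraction * n_hotspots)
    fun <- sort(hot[sample.int(length(hot), n_fun)])
    flank <- if (window > 0L && n_fun > 0L) {
      sort(c(fun - window, fun + window))
    } else integer(0L)
    bg_cand <- setdiff(seq_len(L),
                       unlist(lapply(hot, function(h)
                         (h - 2L * window):(h + 2L * window))))
    if (length(bg_cand) < n_background) {
      abort("not enough columns for background sites; lower n_background")
    }
    bg <- sort(bg_cand[sample.int(length(bg_cand), n_background)])

    recs <- list()
    add_rec <- function(row, col, known) {
      native <- sum(m[row, seq_len(col)] != "-")
      tibble(
        protein_id = rownames(m)[row], native_pos = native,
        residue = m[row, col], ptm_type = "phosphorylation",
        known_function = known, evidence = NA_character_,
        source = "simulated"
      )
    }
    force_acceptors <- function(col, n_force) {
      nongap <- which(m[, col] != "-")
      k <- min(length(nongap), n_force)
      pick <- nongap[sample.int(length(nongap), k)]
      m[pick, col] <<- sample(c("S", "T"), k, replace = TRUE,
                              prob = c(0.7, 0.3))
      pick
    }
    for (h in hot) {
      nongap <- which(m[, h] != "-")
      forced <- force_acceptors(h, ceiling(acceptor_conservation *
                                             length(nongap)))
      n_rec <- min(length(forced), max(1L, rpois(1L, ptms_per_hotspot)))
      rows <- forced[sample.int(length(forced), n_rec)]
      for (r in rows) recs[[length(recs) + 1L]] <- add_rec(r, h, h %in% fun)
    }
    for (fc in flank) {
      forced <- force_acceptors(fc, flank_ptms)
      for (r in forced) recs[[length(recs) + 1L]] <- add_rec(r, fc, TRUE)
    }
    for (bcol in bg) {
      forced <- force_acceptors(bcol, 1L)
      recs[[length(recs) + 1L]] <- add_rec(forced[1L], bcol, FALSE)
    }
    aln_out <- validate_alignment(tibble(
      seq_id = aln$seq_id, organism = aln$organism,
      is_query = aln$is_query,
      seq = unname(apply(m, 1L, paste, collapse = ""))
    ))
    ptms <- validate_ptms(bind_rows(recs), aln_out)
    list(
      alignment = aln_out,
      ptms = ptms,
      truth = list(
        hotspot_columns = hot,
        functional_columns = fun,
        background_columns = bg,
        flank_columns = flank
      )
    )
  })
}

#' Simulate a two-chain structure with a known contact interface
#'
#' Places single-C-alpha residues of chain A along a line at 6-angstrom
#' spacing. A designated set of residue pairs is planted in contact: the
#' chain-B partner sits at a distance drawn uniformly from
#' `[2.5, cutoff]` angstroms of its chain-A partner, while every other
#' inter-chain residue pair is at least `cutoff + 2` angstroms apart, so
#' [detect_interface()] at `cutoff` must recover exactly the planted
#' pairs.
#'
#' @param n_residues residues per chain.
#' @param n_contacts number of planted contact pairs
#'   (`<= n_residues`).
#' @param cutoff the contact cutoff the construction targets (default 4).
#' @param seed optional integer for exact reproducibility.
#' @return A list `a`, `b` (`structure_chain` tibbles) and `truth`
#'   (tibble `resno_a`, `resno_b`, `distance`).
#' @export
simulate_structure_pair <- function(n_residues = 50L, n_contacts = 7L,
                                    cutoff = 4.0, seed = NULL) {
  if (n_contacts > n_residues) abort("n_contacts must be <= n_residues")
  if (cutoff <= 2.5) abort("cutoff must exceed 2.5 angstroms")
  # with 6 A residue spacing the non-partner separation sqrt(36 + 2.5^2)
  # must still exceed cutoff + 2, which bounds the feasible cutoff
  if (cutoff > 4.5) abort("cutoff too large for the 6-angstrom lattice")
  with_seed_maybe(seed, {
    mk_chain <- function(chain_id, xyz, resno) {
      out <- tibble(
        chain = chain_id, resno = as.integer(resno), resid = "ALA",
        elety = "CA", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
      )
      class(out) <- c("structure_chain", class(tibble()))
      out
    }
    xa <- cbind(6 * seq_len(n_residues), 0, 0)
    idx_a <- sort(sample.int(n_residues, n_contacts))
    idx_b <- sort(sample.int(n_residues, n_contacts))
    d <- runif(n_contacts, 2.5, cutoff)
    xb <- cbind(6 * seq_len(n_residues), cutoff + 30, 0)
    if (n_contacts > 0L) {
      xb[idx_b, ] <- cbind(6 * idx_a, d, 0)
    }
    list(
      a = mk_chain("A", xa, seq_len(n_residues)),
      b = mk_chain("B", xb, seq_len(n_residues)),
      truth = tibble(resno_a = idx_a, resno_b = idx_b, distance = d)
    )
  })
}
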