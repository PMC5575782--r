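# Independent brute-force oracles used to validate the optimized paths.

`%+%` <- function(a, b) paste0(a, b)

# window statistics by direct scan over all MAPs
brute_window_stats <- function(cols, pc, kf, center, window) {
  near <- abs(cols - center) <= window
  other <- near & cols != center
  list(
    cpc = sum(pc[near]),
    nc = sum(other),
    nkc = sum(kf[other])
  )
}

# all-pairs interface scan over atom tables
brute_interface <- function(a, b, cutoff) {
  res_a <- integer(0)
  res_b <- integer(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= cutoff) {
        res_a <- c(res_a, a$resno[i])
        res_b <- c(res_b, b$resno[j])
      }
    }
  }
  list(a = sort(unique(res_a)), b = sort(unique(res_b)))
}

# exhaustive profile-alignment oracle: enumerate every monotone column
# pairing of an n-column and an m-column profile and score it with the same
# affine-gap convention (each maximal run of same-side gap columns costs
# open + (len - 1) * extend); returns the optimal score
exhaustive_profile_score <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  recurse <- function(i, j, score, prev) {
    if (i == n && j == m) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i < n && j < m) {
      recurse(i + 1L, j + 1L, score + S[i + 1L, j + 1L], "M")
    }
    if (i < n) {
      pen <- if (prev == "A") gap_extend else gap_open
      recurse(i + 1L, j, score + pen, "A")
    }
    if (j < m) {
      pen <- if (prev == "B") gap_extend else gap_open
      recurse(i, j + 1L, score + pen, "B")
    }
  }
  recurse(0L, 0L, 0, "")
  best
}

# expected-substitution score matrix between two alignments, computed
# independently of the package internals (naive per-column loops)
naive_colpair_scores <- function(a, b, submat) {
  alphabet <- intersect(rownames(submat), LETTERS)
  freq <- function(aln) {
    chars <- strsplit(aln$seq, "", fixed = TRUE)
    nc <- nchar(aln$seq[1])
    sapply(seq_len(nc), function(j) {
      col <- vapply(chars, `[`, character(1), j)
      col <- col[col != "-"]
      v <- setNames(numeric(length(alphabet)), alphabet)
      if (length(col)) {
        for (ch in col) v[ch] <- v[ch] + 1 / length(col)
      }
      v
    })
  }
  fa <- freq(a); fb <- freq(b)
  S <- matrix(0, ncol(fa), ncol(fb))
  for (i in seq_len(ncol(fa))) {
    for (j in seq_len(ncol(fb))) {
      S[i, j] <- sum(outer(fa[, i], fb[, j]) *
                       submat[alphabet, alphabet])
    }
  }
  S
}

random_small_profile <- function(n_rows, n_cols, gap_prob = 0.1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- sample(aa, n_cols, replace = TRUE)
    ch[runif(n_cols) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  # avoid all-gap rows which the container rejects as length-0 after write
  rows[rows == strrep("-", n_cols)] <- strrep("A", n_cols)
  alignment(setNames(rows, paste0("r", seq_len(n_rows), "_", n_cols,
                                  sample.int(1e6, 1))))
}

random_chain <- function(n_res, box = 30, chain_id = "A") {
  out <- tibble::tibble(
    chain = chain_id, resno = seq_len(n_res), resid = "ALA", elety = "CA",
    x = runif(n_res, 0, box), y = runif(n_res, 0, box),
    z = runif(n_res, 0, box)
  )
  class(out) <- c("structure_chain", class(tibble::tibble()))
  out
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "ptmhotspots", mustWork = TRUE)
}

make_ptm_row <- function(protein_id, pos, residue, type = "phosphorylation",
                         known = FALSE) {
  tibble::tibble(
    protein_id = protein_id, native_pos = as.integer(pos), residue = residue,
    ptm_type = type, known_function = known,
    evidence = NA_character_, source = "test"
  )
}
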