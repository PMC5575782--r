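#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI/EMBOSS (comment lines
#' starting with `#`, a header row of single-letter codes, then one labelled
#' row per residue).
#'
#' @param path path to the matrix file.
#' @return A numeric matrix with residue-letter dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) abort("not a substitution matrix file")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  lab <- vapply(rows, `[`, character(1L), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  if (anyNA(vals)) abort("unparseable value in substitution matrix")
  dimnames(vals) <- list(lab, header)
  vals
}

default_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# letter-frequency profile of an alignment: |alphabet| x n_columns matrix of
# per-column frequencies over NON-GAP rows (all-gap columns are all zero)
profile_frequencies <- function(aln, alphabet) {
  m <- alignment_matrix(aln)
  nc <- ncol(m)
  f <- matrix(0, nrow = length(alphabet), ncol = nc,
              dimnames = list(alphabet, NULL))
  for (j in seq_len(nc)) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tb <- table(factor(col, levels = alphabet))
      f[, j] <- as.numeric(tb) / length(col)
    }
  }
  f
}

#' Merge two alignments by profile-to-profile alignment
#'
#' Globally aligns the columns of two fixed sub-alignments without
#' disturbing either: the merged alignment contains every row of `a`
#' followed by every row of `b`, each input's columns appear in order and
#' are never split, and deleting the columns that are all-gap across one
#' input's rows recovers that input verbatim.
#'
#' The column-pair objective is the expected substitution score
#' \eqn{\sum_x \sum_y f_A(x) f_B(y) S(x,y)} with letter frequencies taken
#' over non-gap rows, so a column that is all-gap in one profile scores 0
#' against anything. Gaps are affine: a run of L inserted columns costs
#' `gap_open + (L-1) * gap_extend` (penalties are negative). Ties in the
#' traceback prefer column-pairing over inserting a gap into `b` over
#' inserting a gap into `a`, which makes the result deterministic.
#'
#' @param a,b `ptm_alignment` objects with disjoint `seq_id` sets.
#' @param submat substitution matrix (residue-letter dimnames); default
#'   BLOSUM62.
#' @param gap_open,gap_extend affine gap penalties (negative numbers).
#' @return The merged `ptm_alignment`, with attribute `"score"` holding the
#'   optimal objective value.
#' @export
profile_align <- function(a, b, submat = NULL,
                          gap_open = -10, gap_extend = -0.5) {
  stopifnot(inherits(a, "ptm_alignment"), inherits(b, "ptm_alignment"))
  if (length(intersect(a$seq_id, b$seq_id))) {
    abort("profiles share seq_id(s); they must be disjoint")
  }
  if (is.null(submat)) submat <- default_submat()
  alphabet <- intersect(rownames(submat), LETTERS)
  sm <- submat[alphabet, alphabet, drop = FALSE]
  fa <- profile_frequencies(a, alphabet)
  fb <- profile_frequencies(b, alphabet)
  S <- crossprod(fa, sm %*% fb)  # n_a x n_b expected-score matrix
  ops <- profile_dp(S, gap_open, gap_extend)
  merge_by_ops(a, b, ops$ops, ops$score)
}

# Global affine-gap DP over a precomputed column-pair score matrix.
# States: M (pair column i of a with column j of b), GA (column of a vs gap),
# GB (column of b vs gap). Returns the op string over {"M","A","B"} and the
# optimal score.
profile_dp <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L)
  GA <- matrix(NEG, n + 1L, m + 1L)
  GB <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) GA[2L:(n + 1L), 1L] <- gap_open + (0L:(n - 1L)) * gap_extend
  if (m >= 1L) GB[1L, 2L:(m + 1L)] <- gap_open + (0L:(m - 1L)) * gap_extend
  for (i in 1L:(n + 1L)) {
    for (j in 1L:(m + 1L)) {
      if (i > 1L && j > 1L) {
        M[i, j] <- S[i - 1L, j - 1L] +
          max(M[i - 1L, j - 1L], GA[i - 1L, j - 1L], GB[i - 1L, j - 1L])
      }
      if (i > 1L && !(i == 2L && j == 1L)) {
        GA[i, j] <- max(M[i - 1L, j] + gap_open,
                        GA[i - 1L, j] + gap_extend,
                        GB[i - 1L, j] + gap_open)
      }
      if (j > 1L && !(j == 2L && i == 1L)) {
        GB[i, j] <- max(M[i, j - 1L] + gap_open,
                        GA[i, j - 1L] + gap_open,
                        GB[i, j - 1L] + gap_extend)
      }
    }
  }
  # traceback; tie preference M > GA (gap in b) > GB (gap in a)
  i <- n + 1L; j <- m + 1L
  finals <- c(M = M[i, j], A = GA[i, j], B = GB[i, j])
  state <- names(finals)[which.max(finals)]
  score <- max(finals)
  ops <- character(0L)
  while (i > 1L || j > 1L) {
    if (state == "M") {
      ops <- c("M", ops)
      prev <- c(M = M[i - 1L, j - 1L], A = GA[i - 1L, j - 1L],
                B = GB[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      state <- names(prev)[which.max(prev)]
    } else if (state == "A") {
      ops <- c("A", ops)
      prev <- c(M = M[i - 1L, j] + gap_open,
                A = GA[i - 1L, j] + gap_extend,
                B = GB[i - 1L, j] + gap_open)
      i <- i - 1L
      state <- names(prev)[which.max(prev)]
    } else {
      ops <- c("B", ops)
      prev <- c(M = M[i, j - 1L] + gap_open,
                A = GA[i, j - 1L] + gap_open,
                B = GB[i, j - 1L] + gap_extend)
      j <- j - 1L
      state <- names(prev)[which.max(prev)]
    }
  }
  list(ops = ops, score = score)
}

merge_by_ops <- function(a, b, ops, score) {
  ma <- alignment_matrix(a)
  mb <- alignment_matrix(b)
  ia <- 0L; ib <- 0L
  cols_a <- integer(length(ops)); cols_b <- integer(length(ops))
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op != "B") ia <- ia + 1L
    if (op != "A") ib <- ib + 1L
    cols_a[k] <- if (op == "B") 0L else ia
    cols_b[k] <- if (op == "A") 0L else ib
  }
  take <- function(m, cols) {
    out <- matrix("-", nrow = nrow(m), ncol = length(cols))
    nz <- cols > 0L
    out[, nz] <- m[, cols[nz], drop = FALSE]
    unname(apply(out, 1L, paste, collapse = ""))
  }
  merged <- validate_alignment(tibble(
    seq_id = c(a$seq_id, b$seq_id),
    organism = c(a$organism, b$organism),
    is_query = c(a$is_query, b$is_query),
    seq = c(take(ma, cols_a), take(mb, cols_b))
  ))
  attr(merged, "score") <- score
  attr(merged, "ops") <- paste(ops, collapse = "")
  merged
}

#' Drop columns that are all-gap over a subset of rows
#'
#' Utility to recover an input profile from a merged alignment: keep only
#' the rows named in `seq_ids` and delete columns that are gaps in all of
#' them.
#'
#' @param aln a `ptm_alignment`.
#' @param seq_ids rows to keep.
#' @return A `ptm_alignment` over `seq_ids`.
#' @export
strip_allgap_columns <- function(aln, seq_ids) {
  sub <- aln[aln$seq_id %in% seq_ids, ]
  m <- alignment_matrix(validate_alignment(as_tibble(sub)))
  keep <- colSums(m != "-") > 0L
  validate_alignment(tibble(
    seq_id = sub$seq_id, organism = sub$organism,
    is_query = sub$is_query,
    seq = unname(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""))
  ))
}
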