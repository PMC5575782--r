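#' Construct a family alignment
#'
#' An alignment is a tibble with one row per sequence and columns `seq_id`,
#' `organism`, `is_query`, and `seq` (the gapped residue string, uppercase
#' letters and `-`). All rows must have the same gapped length. `is_query`
#' marks members of the focal sub-family (e.g. the plant 7TM-RGS proteins)
#' so that conservation statistics can be restricted to them.
#'
#' @param seqs named character vector of gapped sequences (names are
#'   sequence identifiers), or a data frame with at least `seq_id` and `seq`.
#' @param organism optional character vector of organism tags, recycled.
#' @param is_query logical vector, recycled; `TRUE` marks focal-family rows.
#' @return A `ptm_alignment` tibble.
#' @examples
#' aln <- alignment(c(a = "MK-S", b = "MKQS"))
#' n_columns(aln)
#' @export
alignment <- function(seqs, organism = NA_character_, is_query = TRUE) {
  if (is.data.frame(seqs)) {
    tbl <- as_tibble(seqs)
    if (!all(c("seq_id", "seq") %in% names(tbl))) {
      abort("alignment data frame needs `seq_id` and `seq` columns")
    }
    if (is.null(tbl$organism)) tbl$organism <- NA_character_
    if (is.null(tbl$is_query)) tbl$is_query <- TRUE
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      abort("sequences must be named by seq_id")
    }
    tbl <- tibble(
      seq_id = names(seqs),
      organism = rep_len(organism, length(seqs)),
      is_query = rep_len(is_query, length(seqs)),
      seq = unname(as.character(seqs))
    )
  }
  validate_alignment(tbl)
}

validate_alignment <- function(tbl) {
  tbl$seq <- unname(chartr(".", "-", toupper(tbl$seq)))
  if (nrow(tbl) < 1L) abort("alignment must contain at least one sequence")
  if (anyDuplicated(tbl$seq_id)) {
    abort(paste0(
      "duplicate seq_id in alignment: ",
      paste(unique(tbl$seq_id[duplicated(tbl$seq_id)]), collapse = ", ")
    ))
  }
  if (any(!nzchar(tbl$seq_id))) abort("empty seq_id in alignment")
  lens <- nchar(tbl$seq)
  if (any(lens == 0L)) abort("empty sequence in alignment")
  if (length(unique(lens)) > 1L) {
    ref <- lens[1L]
    bad <- tbl$seq_id[lens != ref][1L]
    abort(paste0(
      "alignment rows differ in length: `", bad, "` has ",
      lens[tbl$seq_id == bad][1L], " columns, expected ", ref
    ))
  }
  if (any(grepl("[^A-Z-]", tbl$seq))) {
    bad <- tbl$seq_id[grepl("[^A-Z-]", tbl$seq)][1L]
    abort(paste0("sequence `", bad, "` contains characters outside A-Z and '-'"))
  }
  tbl <- tbl[, c("seq_id", "organism", "is_query", "seq")]
  class(tbl) <- c("ptm_alignment", class(tibble()))
  tbl
}

#' @rdname alignment
#' @param aln a `ptm_alignment`.
#' @export
n_columns <- function(aln) {
  stopifnot(inherits(aln, "ptm_alignment"))
  nchar(aln$seq[1L])
}

#' @export
print.ptm_alignment <- function(x, ...) {
  cat("<ptm_alignment> ", nrow(x), " sequences x ", n_columns(x),
      " columns (", sum(x$is_query), " query rows)\n", sep = "")
  NextMethod()
}

#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA file into a [alignment()] tibble. Lowercase
#' residues are normalized to uppercase and `.` gaps to `-`. Header lines may
#' carry `organism=<tag>` and `query=0/1` tokens after the identifier.
#'
#' @param path path to an aligned FASTA file.
#' @return A `ptm_alignment` tibble.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no sequences in ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  org <- stringr::str_match(headers, "organism=(\\S+)")[, 2]
  qry <- stringr::str_match(headers, "query=(\\S+)")[, 2]
  is_query <- ifelse(is.na(qry), TRUE, qry %in% c("1", "true", "TRUE"))
  validate_alignment(tibble(
    seq_id = ids, organism = org, is_query = is_query,
    seq = unname(as.character(set))
  ))
}

#' Write an alignment to aligned FASTA
#'
#' The header of each record is `seq_id organism=<tag> query=<0/1>`
#' (the organism token is omitted when unknown), so that
#' [read_alignment()] round-trips rows, identifiers and metadata exactly.
#'
#' @param aln a `ptm_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "ptm_alignment"))
  hdr <- paste0(
    aln$seq_id,
    ifelse(is.na(aln$organism), "", paste0(" organism=", aln$organism)),
    paste0(" query=", as.integer(aln$is_query))
  )
  set <- Biostrings::BStringSet(setNames(aln$seq, hdr))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Ungapped sequence of one alignment row
#' @param aln a `ptm_alignment`.
#' @param seq_id sequence identifier.
#' @return character scalar, the residues with gaps removed.
#' @export
ungapped_seq <- function(aln, seq_id) {
  row <- aln$seq[match(seq_id, aln$seq_id)]
  if (is.na(row)) abort(paste0("unknown seq_id `", seq_id, "`"))
  gsub("-", "", row, fixed = TRUE)
}

#' Native-position/alignment-column residue map
#'
#' Builds the long-form bijection between each sequence's ungapped (native)
#' positions and its non-gap alignment columns. `to_column` is strictly
#' increasing within a sequence, and restricting to one sequence gives a
#' one-to-one map in both directions.
#'
#' @param aln a `ptm_alignment`.
#' @return A tibble with columns `seq_id`, `native_pos`, `column`, `residue`.
#' @examples
#' rm <- residue_map(alignment(c(a = "MK--S")))
#' rm$column[rm$native_pos == 3]  # 5
#' @export
residue_map <- function(aln) {
  stopifnot(inherits(aln, "ptm_alignment"))
  purrr::map_dfr(seq_len(nrow(aln)), function(i) {
    chars <- strsplit(aln$seq[i], "", fixed = TRUE)[[1L]]
    cols <- which(chars != "-")
    tibble(
      seq_id = aln$seq_id[i],
      native_pos = seq_along(cols),
      column = cols,
      residue = chars[cols]
    )
  })
}

#' Convert native positions to alignment columns (and back)
#'
#' @param rmap a residue map from [residue_map()].
#' @param seq_id sequence identifier.
#' @param native_pos integer vector of 1-based ungapped positions.
#' @return Integer vector of alignment columns.
#' @export
map_to_column <- function(rmap, seq_id, native_pos) {
  sub <- rmap[rmap$seq_id == seq_id, ]
  if (nrow(sub) == 0L) abort(paste0("no residue map for `", seq_id, "`"))
  idx <- match(native_pos, sub$native_pos)
  if (anyNA(idx)) {
    abort(paste0(
      "native position ", native_pos[which(is.na(idx))[1L]],
      " outside 1..", max(sub$native_pos), " for `", seq_id, "`"
    ))
  }
  sub$column[idx]
}

#' @rdname map_to_column
#' @param column integer vector of alignment columns; querying a gap column
#'   of this sequence is an error.
#' @export
map_to_native <- function(rmap, seq_id, column) {
  sub <- rmap[rmap$seq_id == seq_id, ]
  if (nrow(sub) == 0L) abort(paste0("no residue map for `", seq_id, "`"))
  idx <- match(column, sub$column)
  if (anyNA(idx)) {
    abort(paste0(
      "column ", column[which(is.na(idx))[1L]],
      " is a gap (or out of range) for `", seq_id, "`"
    ))
  }
  sub$native_pos[idx]
}

# character matrix view of an alignment (rows x columns); internal
alignment_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seq, "", fixed = TRUE)),
              nrow = nrow(aln), byrow = TRUE)
  rownames(m) <- aln$seq_id
  m
}
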