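#' @keywords internal
ptm_type_levels <- c(
  "phosphorylation", "ubiquitination", "acetylation", "methylation", "other"
)

normalize_ptm_type <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% ptm_type_levels, x, "other")
}

#' Read and validate a PTM site table
#'
#' Reads a tab-separated table of experimentally observed modifications with
#' header `protein_id native_pos residue ptm_type known_function evidence
#' source` (`evidence` and `source` optional). Every record is checked
#' against the alignment: the protein must be a row of `aln`, the position
#' must lie within its ungapped length, and the stated residue must equal
#' the sequence letter there. Exact duplicates (same protein, position and
#' PTM type) collapse to one record whose `known_function` is the OR over
#' duplicates; unknown PTM types map to `"other"`.
#'
#' @param path path to the TSV file. Lines starting with `#` are ignored.
#' @param aln the family [alignment()] the records refer to.
#' @return A tibble of validated PTM records with columns `protein_id`,
#'   `native_pos`, `residue`, `ptm_type`, `known_function`, `evidence`,
#'   `source`.
#' @export
read_ptm_table <- function(path, aln) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  req <- c("protein_id", "native_pos", "residue", "ptm_type", "known_function")
  miss <- setdiff(req, names(tbl))
  if (length(miss)) {
    abort(paste0("PTM table ", path, " lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (is.null(tbl$evidence)) tbl$evidence <- NA_character_
  if (is.null(tbl$source)) tbl$source <- NA_character_
  tbl <- tibble(
    protein_id = as.character(tbl$protein_id),
    native_pos = as.integer(tbl$native_pos),
    residue = toupper(as.character(tbl$residue)),
    ptm_type = normalize_ptm_type(as.character(tbl$ptm_type)),
    known_function = parse_flag(tbl$known_function),
    evidence = as.character(tbl$evidence),
    source = as.character(tbl$source)
  )
  validate_ptms(tbl, aln)
}

#' Validate PTM records against an alignment
#'
#' @param ptms a tibble shaped like the output of [read_ptm_table()].
#' @param aln the family [alignment()].
#' @return The validated, de-duplicated tibble (see [read_ptm_table()]).
#' @export
validate_ptms <- function(ptms, aln) {
  ptms <- as_tibble(ptms)
  unknown <- setdiff(unique(ptms$protein_id), aln$seq_id)
  if (length(unknown)) {
    abort(paste0("PTM records name protein(s) absent from the alignment: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(ptms$native_pos < 1L | is.na(ptms$native_pos))) {
    abort("native_pos must be a positive integer")
  }
  ungapped <- setNames(
    gsub("-", "", aln$seq, fixed = TRUE), aln$seq_id
  )
  for (i in seq_len(nrow(ptms))) {
    sq <- ungapped[[ptms$protein_id[i]]]
    pos <- ptms$native_pos[i]
    if (pos > nchar(sq)) {
      abort(paste0(
        "PTM position ", pos, " exceeds ungapped length ", nchar(sq),
        " of `", ptms$protein_id[i], "`"
      ))
    }
    found <- substr(sq, pos, pos)
    if (!is.na(ptms$residue[i]) && found != ptms$residue[i]) {
      abort(paste0(
        "residue mismatch for `", ptms$protein_id[i], "` position ", pos,
        ": table says ", ptms$residue[i], ", sequence has ", found
      ))
    }
    ptms$residue[i] <- found
  }
  ptms |>
    group_by(.data$protein_id, .data$native_pos, .data$ptm_type) |>
    summarise(
      residue = .data$residue[1L],
      known_function = any(.data$known_function),
      evidence = paste_unique(.data$evidence),
      source = paste_unique(.data$source),
      .groups = "drop"
    ) |>
    arrange(.data$protein_id, .data$native_pos, .data$ptm_type) |>
    relocate("protein_id", "native_pos", "residue", "ptm_type",
             "known_function", "evidence", "source")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("1", "true", "t", "yes")
  bad <- !x %in% c("0", "1", "true", "false", "t", "f", "yes", "no", "", "na")
  if (any(bad)) abort(paste0("unparseable known_function value: ", x[bad][1L]))
  out
}

paste_unique <- function(x) {
  x <- sort(unique(x[!is.na(x) & nzchar(x)]))
  if (!length(x)) NA_character_ else paste(x, collapse = ";")
}

#' Read region/domain annotations
#'
#' Regions are 1-based inclusive intervals, either in the native coordinates
#' of one protein (`scope = "native"`, `protein_id` required) or in merged
#' alignment coordinates (`scope = "alignment"`). Header:
#' `name scope protein_id start end`.
#'
#' @param path TSV file of region annotations.
#' @param aln optional [alignment()] used to check native intervals against
#'   ungapped lengths.
#' @return A tibble with columns `name`, `scope`, `protein_id`, `start`, `end`.
#' @export
read_regions <- function(path, aln = NULL) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  req <- c("name", "scope", "start", "end")
  miss <- setdiff(req, names(tbl))
  if (length(miss)) {
    abort(paste0("region table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (is.null(tbl$protein_id)) tbl$protein_id <- NA_character_
  tbl <- tibble(
    name = as.character(tbl$name),
    scope = as.character(tbl$scope),
    protein_id = as.character(tbl$protein_id),
    start = as.integer(tbl$start),
    end = as.integer(tbl$end)
  )
  if (any(!tbl$scope %in% c("native", "alignment"))) {
    abort("region scope must be 'native' or 'alignment'")
  }
  if (any(tbl$start > tbl$end)) abort("region start must be <= end")
  if (any(tbl$scope == "native" & is.na(tbl$protein_id))) {
    abort("native-scope regions require protein_id")
  }
  if (!is.null(aln)) {
    nat <- tbl[tbl$scope == "native", ]
    for (i in seq_len(nrow(nat))) {
      len <- nchar(ungapped_seq(aln, nat$protein_id[i]))
      if (nat$end[i] > len) {
        abort(paste0("region `", nat$name[i], "` exceeds ungapped length of `",
                     nat$protein_id[i], "`"))
      }
    }
  }
  tbl
}
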