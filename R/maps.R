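#' Group PTM records into modified alignment positions (MAPs)
#'
#' A MAP is an alignment column that harbors at least one experimentally
#' observed PTM in any family member. Each record's native position is
#' translated to its alignment column through the sequence's residue map;
#' records landing on the same column form one MAP.
#'
#' @param ptms validated PTM records (see [read_ptm_table()]).
#' @param aln the family [alignment()] (or a merged profile) containing every
#'   protein named in `ptms`.
#' @return A tibble with one row per MAP, sorted by `column`: `column`,
#'   `n_ptms` (count of distinct protein/position/type triples),
#'   `known_function` (any member record has functional evidence), and a
#'   `ptms` list-column holding the member records (with their `column`).
#' @examples
#' aln <- alignment(c(P1 = "MKS-", P2 = "MK-S"))
#' ptms <- validate_ptms(
#'   tibble::tibble(protein_id = c("P1", "P2"), native_pos = 3L,
#'                  residue = "S", ptm_type = "phosphorylation",
#'                  known_function = FALSE, evidence = NA, source = NA),
#'   aln)
#' build_maps(ptms, aln)
#' @export
build_maps <- function(ptms, aln) {
  rmap <- residue_map(aln)
  located <- ptms |>
    inner_join(rmap, by = c("protein_id" = "seq_id", "native_pos"),
               suffix = c("", ".aln"))
  if (nrow(located) != nrow(ptms)) {
    missing <- dplyr::anti_join(
      ptms, rmap, by = c("protein_id" = "seq_id", "native_pos"))
    abort(paste0(
      "PTM record could not be mapped: `", missing$protein_id[1L],
      "` position ", missing$native_pos[1L]
    ))
  }
  located |>
    select(-dplyr::any_of("residue.aln")) |>
    group_by(.data$column) |>
    tidyr::nest(.key = "ptms") |>
    ungroup() |>
    mutate(
      n_ptms = map_int(.data$ptms, nrow),
      known_function = map_lgl(.data$ptms, ~ any(.x$known_function))
    ) |>
    arrange(.data$column) |>
    select("column", "n_ptms", "known_function", "ptms")
}

#' Count distinct PTMs in one MAP
#'
#' Distinctness is over (protein, native position, PTM type) triples; the
#' same site modified by two different PTM types counts twice.
#'
#' @param map_ptms the member-record tibble of one MAP (a `ptms` list-column
#'   element of [build_maps()]).
#' @return Integer count.
#' @export
ptm_count <- function(map_ptms) {
  nrow(distinct(map_ptms, .data$protein_id, .data$native_pos, .data$ptm_type))
}
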