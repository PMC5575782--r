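phospho_acceptors <- c("S", "T", "Y")

acceptor_class <- function(ptm_type, observed_residues) {
  switch(ptm_type,
    phosphorylation = phospho_acceptors,
    ubiquitination = "K",
    acetylation = "K",
    methylation = c("K", "R"),
    sort(unique(observed_residues))
  )
}

#' Per-column conservation statistics
#'
#' For each requested column, over the chosen row scope:
#' `membership` = fraction of rows that are non-gap; `trc` (total residue
#' conservation) = frequency of the most common letter among non-gap rows;
#' `pac` (phospho-acceptor conservation) = fraction of non-gap rows carrying
#' S, T or Y. Columns that are all-gap in scope return zeros with
#' `degenerate = TRUE`.
#'
#' @param aln a [alignment()].
#' @param columns integer vector of 1-based columns; default all.
#' @param scope `"all"` rows or `"query"` rows only (the focal sub-family).
#' @return A tibble `column`, `membership`, `trc`, `pac`, `degenerate`.
#' @export
column_conservation <- function(aln, columns = NULL,
                                scope = c("all", "query")) {
  scope <- match.arg(scope)
  nc <- n_columns(aln)
  if (is.null(columns)) columns <- seq_len(nc)
  if (any(columns < 1L | columns > nc)) {
    abort(paste0("column index outside 1..", nc))
  }
  rows <- if (scope == "query") which(aln$is_query) else seq_len(nrow(aln))
  if (!length(rows)) abort("no rows in scope")
  m <- alignment_matrix(aln)[rows, , drop = FALSE]
  purrr::map_dfr(columns, function(j) {
    col <- m[, j]
    ng <- col[col != "-"]
    if (!length(ng)) {
      return(tibble(column = j, membership = 0, trc = 0, pac = 0,
                    degenerate = TRUE))
    }
    tibble(
      column = j,
      membership = length(ng) / length(col),
      trc = max(table(ng)) / length(ng),
      pac = sum(ng %in% phospho_acceptors) / length(ng),
      degenerate = FALSE
    )
  })
}

#' Cluster and neighborhood statistics for MAPs
#'
#' For each MAP column, within a +/- `window` column band:
#' `cpc` (cluster PTM count) sums the PTM counts of all MAPs in the band
#' including the target itself; `nc` counts neighboring MAPs (target
#' excluded); `nkc` counts neighboring MAPs that contain at least one
#' known-functional PTM (target excluded); `neighbor_known` is `nkc >= 1`.
#' Windows truncate silently at the alignment bounds.
#'
#' @param maps the MAP tibble from [build_maps()].
#' @param window integer half-width in alignment columns (>= 0).
#' @return `maps` with columns `pc`, `cpc`, `nc`, `nkc`, `neighbor_known`
#'   added.
#' @export
cluster_window_stats <- function(maps, window = 2L) {
  stopifnot(window >= 0L)
  pc <- map_int(maps$ptms, ptm_count)
  cols <- maps$column
  kf <- maps$known_function
  stats <- purrr::map_dfr(seq_along(cols), function(i) {
    near <- abs(cols - cols[i]) <= window
    other <- near & cols != cols[i]
    tibble(
      cpc = sum(pc[near]),
      nc = sum(other),
      nkc = sum(kf[other])
    )
  })
  maps |>
    mutate(pc = pc, cpc = stats$cpc, nc = stats$nc, nkc = stats$nkc,
           neighbor_known = stats$nkc >= 1L)
}

#' Interface residence of alignment columns
#'
#' A column resides at a protein-protein interface when any sequence's
#' (non-gap) residue at that column belongs to an interface set — a set of
#' native positions of a named family member derived from structure (see
#' [detect_interface()]).
#'
#' @param interfaces a tibble with columns `protein_id`, `native_pos` (rows
#'   may pool several interface sets), or `NULL` for no structural evidence.
#' @param aln the [alignment()] the positions refer to.
#' @return Sorted integer vector of interface columns (empty if
#'   `interfaces` is `NULL` or empty).
#' @export
interface_columns <- function(interfaces, aln) {
  if (is.null(interfaces) || nrow(interfaces) == 0L) return(integer(0L))
  unknown <- setdiff(unique(interfaces$protein_id), aln$seq_id)
  if (length(unknown)) {
    abort(paste0("interface set names unknown protein(s): ",
                 paste(unknown, collapse = ", ")))
  }
  rmap <- residue_map(aln)
  cols <- purrr::map2_int(
    interfaces$protein_id, interfaces$native_pos,
    function(p, i) map_to_column(rmap, p, i)
  )
  sort(unique(cols))
}

#' PTM-residue conservation of a MAP column
#'
#' The fraction of non-gap rows whose letter belongs to the acceptor class
#' of the MAP's dominant PTM type (phosphorylation: S/T/Y; ubiquitination
#' and acetylation: K; methylation: K/R; other: the exact modified letters
#' observed in the MAP). When several types tie for dominance the tie is
#' broken toward phosphorylation, then alphabetically.
#'
#' @param map_ptms member records of one MAP.
#' @param aln the [alignment()].
#' @param column the MAP's column.
#' @param scope row scope as in [column_conservation()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
ptm_residue_conservation <- function(map_ptms, aln, column,
                                     scope = c("all", "query")) {
  scope <- match.arg(scope)
  type <- dominant_ptm_type(map_ptms$ptm_type)
  cls <- acceptor_class(type, map_ptms$residue)
  rows <- if (scope == "query") which(aln$is_query) else seq_len(nrow(aln))
  col <- alignment_matrix(aln)[rows, column]
  ng <- col[col != "-"]
  if (!length(ng)) return(0)
  sum(ng %in% cls) / length(ng)
}

dominant_ptm_type <- function(types) {
  tb <- table(types)
  winners <- names(tb)[tb == max(tb)]
  if ("phosphorylation" %in% winners) "phosphorylation" else sort(winners)[1L]
}

#' Phosphorylation/ubiquitination crosstalk pairs
#'
#' Reports all same-protein pairs of a phosphorylation record and a
#' ubiquitination record whose native positions are within `window`
#' residues of each other (inclusive). Proximal phospho-ubiquitin pairs are
#' strongly associated with regulatory function.
#'
#' @param ptms validated PTM records.
#' @param window maximum residue separation (default 5, inclusive).
#' @return A tibble `protein_id`, `phospho_pos`, `ubiquitin_pos`,
#'   `distance`, sorted by protein then phospho position.
#' @export
crosstalk_pairs <- function(ptms, window = 5L) {
  ph <- ptms |> filter(.data$ptm_type == "phosphorylation") |>
    select("protein_id", phospho_pos = "native_pos")
  ub <- ptms |> filter(.data$ptm_type == "ubiquitination") |>
    select("protein_id", ubiquitin_pos = "native_pos")
  inner_join(ph, ub, by = "protein_id",
             relationship = "many-to-many") |>
    mutate(distance = abs(.data$phospho_pos - .data$ubiquitin_pos)) |>
    filter(.data$distance <= window) |>
    arrange(.data$protein_id, .data$phospho_pos, .data$ubiquitin_pos)
}

#' Compute the full feature vector for every MAP
#'
#' Assembles, per MAP: conservation features (`membership`, `trc`, `pac`,
#' `prc`), counts (`pc`, `cpc`, `nc`, `nkc`), and binary evidence flags
#' (`kf`: the MAP itself holds a known-functional PTM; `neighbor_known`;
#' `ppi`: the column resides at a detected interface). `member_ptms`
#' serializes the records as `protein:pos:type` for tabular output.
#'
#' @param maps MAP tibble from [build_maps()].
#' @param aln the [alignment()] (merged, if profiles were merged).
#' @param interfaces optional interface tibble (see [interface_columns()]).
#' @param window cluster half-width in columns (default 2).
#' @param scope conservation row scope, `"all"` (default) or `"query"`.
#' @return A tibble with one row per MAP and all feature columns.
#' @export
compute_features <- function(maps, aln, interfaces = NULL, window = 2L,
                             scope = c("all", "query")) {
  scope <- match.arg(scope)
  if (nrow(maps) == 0L) {
    return(tibble(
      column = integer(), membership = numeric(), trc = numeric(),
      pac = numeric(), prc = numeric(), pc = integer(), cpc = integer(),
      nc = integer(), nkc = integer(), kf = logical(),
      neighbor_known = logical(), ppi = logical(), member_ptms = character()
    ))
  }
  cons <- column_conservation(aln, maps$column, scope = scope)
  stats <- cluster_window_stats(maps, window = window)
  iface_cols <- interface_columns(interfaces, aln)
  tibble(
    column = maps$column,
    membership = cons$membership,
    trc = cons$trc,
    pac = cons$pac,
    prc = map_dbl(seq_len(nrow(maps)), function(i) {
      ptm_residue_conservation(maps$ptms[[i]], aln, maps$column[i],
                               scope = scope)
    }),
    pc = stats$pc,
    cpc = stats$cpc,
    nc = stats$nc,
    nkc = stats$nkc,
    kf = maps$known_function,
    neighbor_known = stats$neighbor_known,
    ppi = maps$column %in% iface_cols,
    member_ptms = map_chr(maps$ptms, function(p) {
      paste(sprintf("%s:%d:%s", p$protein_id, p$native_pos, p$ptm_type),
            collapse = ",")
    })
  )
}
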