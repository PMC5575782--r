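#' Candidate acceptor positions of one protein
#'
#' Native positions of a protein whose residue belongs to the candidate
#' acceptor set, optionally restricted to a native-coordinate interval
#' (e.g. the cytoplasmic portion of a receptor-like protein).
#'
#' @param aln a [alignment()].
#' @param protein_id sequence identifier.
#' @param residues candidate letters; S/T by default (tyrosine can be
#'   included for generality).
#' @param region optional `c(start, end)` native interval, inclusive.
#' @return Sorted integer vector of native positions.
#' @export
acceptor_positions <- function(aln, protein_id, residues = c("S", "T"),
                               region = NULL) {
  sq <- strsplit(ungapped_seq(aln, protein_id), "")[[1L]]
  pos <- which(sq %in% residues)
  if (!is.null(region)) pos <- pos[pos >= region[1L] & pos <= region[2L]]
  pos
}

#' Enrichment of observed sites in a region over random expectation
#'
#' The fold enrichment is the observed/expected ratio
#' \deqn{fold = (k/n) / (K/N)}
#' where `k` of the `n` observed sites and `K` of the `N` candidate
#' acceptor positions fall inside the region. A fold of 1 means the region
#' is hit exactly as often as uniform placement over candidates predicts.
#' When `K = 0` or `n = 0` the fold is undefined and flagged rather than
#' raising an error.
#'
#' @param site_positions native positions of the observed sites (must all
#'   be candidate positions).
#' @param candidate_positions native positions where a site is possible.
#' @param region_start,region_end inclusive native interval of the region.
#' @param region_name label carried into the result.
#' @return One-row tibble `region`, `k`, `n`, `K`, `N`, `fold`, `flag`.
#' @export
enrichment_fold <- function(site_positions, candidate_positions,
                            region_start, region_end,
                            region_name = "region") {
  site_positions <- unique(as.integer(site_positions))
  candidate_positions <- unique(as.integer(candidate_positions))
  stray <- setdiff(site_positions, candidate_positions)
  if (length(stray)) {
    abort(paste0("observed site at position ", stray[1L],
                 " is not a candidate position"))
  }
  n <- length(site_positions)
  N <- length(candidate_positions)
  inreg <- function(p) p >= region_start & p <= region_end
  k <- sum(inreg(site_positions))
  K <- sum(inreg(candidate_positions))
  if (K == 0L || n == 0L) {
    fold <- NA_real_
    flag <- "undefined"
  } else {
    fold <- (k / n) / (K / N)
    flag <- "ok"
  }
  tibble(region = region_name, k = k, n = n, K = K, N = N,
         fold = fold, flag = flag)
}

#' Region enrichment report for a PTM table
#'
#' Runs [enrichment_fold()] for every native-scope region annotation,
#' using that protein's observed phosphosites and its candidate acceptor
#' positions within an optional per-protein scope interval.
#'
#' @param ptms validated PTM records.
#' @param aln a [alignment()].
#' @param regions region tibble from [read_regions()]; only `native`-scope
#'   rows are used.
#' @param residues candidate acceptor letters (default S/T).
#' @param scope_regions optional tibble `protein_id`, `start`, `end`
#'   restricting sites and candidates per protein (e.g. the cytoplasmic
#'   portion); proteins absent from it use their full length.
#' @return A tibble with one [enrichment_fold()] row per region.
#' @export
enrichment_table <- function(ptms, aln, regions, residues = c("S", "T"),
                             scope_regions = NULL) {
  nat <- regions[regions$scope == "native", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(nat)), function(i) {
    pid <- nat$protein_id[i]
    scope <- NULL
    if (!is.null(scope_regions) && pid %in% scope_regions$protein_id) {
      sr <- scope_regions[scope_regions$protein_id == pid, ][1L, ]
      scope <- c(sr$start, sr$end)
    }
    cands <- acceptor_positions(aln, pid, residues = residues, region = scope)
    sites <- ptms |>
      filter(.data$protein_id == pid,
             .data$ptm_type == "phosphorylation",
             .data$residue %in% residues) |>
      pull(.data$native_pos)
    if (!is.null(scope)) sites <- sites[sites >= scope[1L] & sites <= scope[2L]]
    enrichment_fold(sites, cands, nat$start[i], nat$end[i],
                    region_name = paste0(nat$name[i], ":", pid))
  })
}

#' Conservation of site columns versus the phospho-capable background
#'
#' Compares mean conservation of the alignment columns harboring observed
#' sites against all other columns where phosphorylation is possible
#' (columns with at least one S/T/Y among the scope rows), optionally
#' within an alignment-coordinate region. Returns means of both total
#' residue conservation and acceptor conservation for the two column sets.
#'
#' @param aln a [alignment()].
#' @param site_columns integer columns harboring observed sites.
#' @param scope row scope, `"query"` (default: the focal sub-family, as for
#'   within-family conservation profiles) or `"all"`.
#' @param region optional `c(start, end)` alignment-column interval.
#' @param background optional explicit background columns; must be disjoint
#'   from `site_columns`. Default: all phospho-capable columns (in region)
#'   minus the site columns.
#' @return One-row tibble with `site_mean_trc`, `site_mean_pac`,
#'   `bg_mean_trc`, `bg_mean_pac`, `n_site`, `n_bg`, `flag`.
#' @export
conservation_comparison <- function(aln, site_columns,
                                    scope = c("query", "all"),
                                    region = NULL, background = NULL) {
  scope <- match.arg(scope)
  site_columns <- unique(as.integer(site_columns))
  cons <- column_conservation(aln, scope = scope)
  capable <- cons$column[cons$pac > 0]
  if (!is.null(region)) {
    capable <- capable[capable >= region[1L] & capable <= region[2L]]
    site_columns <- site_columns[site_columns >= region[1L] &
                                   site_columns <= region[2L]]
  }
  if (is.null(background)) {
    background <- setdiff(capable, site_columns)
  } else {
    background <- unique(as.integer(background))
    if (length(intersect(background, site_columns))) {
      abort("background columns must be disjoint from site columns")
    }
  }
  flag <- if (length(background) == 0L || length(site_columns) == 0L) {
    "undefined"
  } else "ok"
  mean_of <- function(cols, what) {
    if (!length(cols)) return(NA_real_)
    mean(cons[[what]][match(cols, cons$column)])
  }
  tibble(
    site_mean_trc = mean_of(site_columns, "trc"),
    site_mean_pac = mean_of(site_columns, "pac"),
    bg_mean_trc = mean_of(background, "trc"),
    bg_mean_pac = mean_of(background, "pac"),
    n_site = length(site_columns),
    n_bg = length(background),
    flag = flag
  )
}
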