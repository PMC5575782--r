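#' Integrative Score of a MAP
#'
#' The multiplicative prioritization score
#' \deqn{IS = CPC \cdot PC \cdot PRC \cdot W_1(NKC) \cdot W_2(PPI)}
#' where the conditional weight factors activate only when their evidence
#' channel is present: \eqn{W_1(NKC) = 1} when `nkc == 0` and
#' `w1 * nkc` otherwise (or a flat `w1` with `nkc_mode = "binary"`), and
#' \eqn{W_2(PPI) = 1} when `ppi` is false and `w2` otherwise. The score is
#' zero exactly when `pc == 0` or `prc == 0`.
#'
#' @param pc,cpc PTM count and cluster PTM count (non-negative integers).
#' @param prc PTM-residue conservation in `[0, 1]`.
#' @param nkc neighbor known-function count (non-negative integer).
#' @param ppi logical, interface residence.
#' @param w1,w2 conditional weight multipliers, `>= 1` (defaults 2).
#' @param nkc_mode `"count"` (default): the factor is `w1 * nkc`;
#'   `"binary"`: the factor is `w1` whenever `nkc > 0`.
#' @return Numeric vector of scores.
#' @examples
#' integrative_score(pc = 1, cpc = 2, prc = 0.5, nkc = 0, ppi = FALSE)  # 1
#' @export
integrative_score <- function(pc, cpc, prc, nkc, ppi, w1 = 2, w2 = 2,
                              nkc_mode = c("count", "binary")) {
  nkc_mode <- match.arg(nkc_mode)
  if (any(c(pc, cpc, prc, nkc) < 0)) abort("features must be non-negative")
  if (w1 < 1 || w2 < 1) abort("weights must be >= 1")
  f1 <- ifelse(nkc > 0,
               if (nkc_mode == "count") w1 * nkc else w1,
               1)
  f2 <- ifelse(ppi, w2, 1)
  cpc * pc * prc * f1 * f2
}

#' Score, rank and bin MAPs
#'
#' Applies [integrative_score()] to a feature table, ranks MAPs by
#' descending score (ties broken by higher `cpc`, then higher `pc`, then
#' lower column index) and assigns projection bins with [bin_scores()].
#'
#' @param features feature tibble from [compute_features()].
#' @param w1,w2,nkc_mode see [integrative_score()].
#' @param n_bins number of quantile bins for positive scores (default 5).
#' @return A `map_scores` tibble: `features` plus `is`, `rank`, `bin`,
#'   ordered by rank. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
score_maps <- function(features, w1 = 2, w2 = 2,
                       nkc_mode = c("count", "binary"), n_bins = 5L) {
  nkc_mode <- match.arg(nkc_mode)
  scored <- features |>
    mutate(is = integrative_score(
      pc = .data$pc, cpc = .data$cpc, prc = .data$prc, nkc = .data$nkc,
      ppi = .data$ppi, w1 = w1, w2 = w2, nkc_mode = nkc_mode
    )) |>
    rank_maps() |>
    bin_scores(n_bins = n_bins)
  class(scored) <- c("map_scores", class(tibble()))
  attr(scored, "weights") <- c(w1 = w1, w2 = w2)
  attr(scored, "nkc_mode") <- nkc_mode
  attr(scored, "n_bins") <- as.integer(n_bins)
  scored
}

#' Rank MAPs by Integrative Score
#'
#' Descending score; ties broken by higher cluster PTM count, then higher
#' PTM count, then lower column index — deterministic and independent of
#' input row order.
#'
#' @param scored a tibble with columns `is`, `cpc`, `pc`, `column`.
#' @return The tibble sorted with a 1-based `rank` column.
#' @export
rank_maps <- function(scored) {
  scored |>
    arrange(desc(.data$is), desc(.data$cpc), desc(.data$pc), .data$column) |>
    mutate(rank = row_number())
}

#' Assign projection bins to scored MAPs
#'
#' Zero-score MAPs get bin 0. Positive scores are split into `n_bins`
#' quantile bins (bin `n_bins` holds the highest scores); equal scores
#' always share a bin, so when all positive scores are identical every one
#' lands in the top bin.
#'
#' @param scored tibble with an `is` column.
#' @param n_bins integer `>= 1`.
#' @return `scored` with an integer `bin` column.
#' @export
bin_scores <- function(scored, n_bins = 5L) {
  if (n_bins < 1L) abort("n_bins must be >= 1")
  bin <- integer(nrow(scored))
  pos <- which(scored$is > 0)
  if (length(pos)) {
    r <- rank(scored$is[pos], ties.method = "max")
    bin[pos] <- as.integer(ceiling(n_bins * r / length(pos)))
  }
  scored$bin <- bin
  scored
}

#' @method tidy map_scores
#' @export
tidy.map_scores <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance map_scores
#' @export
glance.map_scores <- function(x, ...) {
  tibble(
    n_maps = nrow(x),
    n_ptms = sum(x$pc),
    n_positive = sum(x$is > 0),
    top_score = if (nrow(x)) max(x$is) else NA_real_,
    n_known_function = sum(x$kf),
    n_interface = sum(x$ppi)
  )
}

#' @export
print.map_scores <- function(x, ...) {
  w <- attr(x, "weights")
  cat("<map_scores> ", nrow(x), " MAPs, weights w1=", w[["w1"]],
      " w2=", w[["w2"]], ", ", attr(x, "n_bins"), " bins\n", sep = "")
  NextMethod()
}

#' Rank-score plot of scored MAPs
#'
#' @param object a `map_scores` tibble.
#' @param ... unused.
#' @return A ggplot: Integrative Score by rank, colored by projection bin,
#'   known-functional MAPs highlighted.
#' @method autoplot map_scores
#' @export
autoplot.map_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$rank, y = .data$is, color = factor(.data$bin)
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(
      data = object[object$kf, , drop = FALSE],
      shape = 1, size = 4, color = "black"
    ) +
    ggplot2::scale_color_viridis_d(name = "bin") +
    ggplot2::labs(
      x = "MAP rank", y = "Integrative Score",
      title = "MAP prioritization",
      subtitle = "circled points contain a known-functional PTM"
    ) +
    ggplot2::theme_minimal()
}

#' Conservation profile plot along the alignment
#'
#' Per-column total residue conservation and phospho-acceptor conservation,
#' with MAP columns marked.
#'
#' @param aln an [alignment()].
#' @param maps optional MAP tibble to mark.
#' @param scope row scope as in [column_conservation()].
#' @return A ggplot.
#' @export
plot_conservation_profile <- function(aln, maps = NULL,
                                      scope = c("all", "query")) {
  scope <- match.arg(scope)
  cons <- column_conservation(aln, scope = scope) |>
    tidyr::pivot_longer(c("trc", "pac"), names_to = "measure",
                        values_to = "value")
  p <- ggplot2::ggplot(cons, ggplot2::aes(
    x = .data$column, y = .data$value, color = .data$measure
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "alignment column", y = "conservation") +
    ggplot2::theme_minimal()
  if (!is.null(maps) && nrow(maps)) {
    p <- p + ggplot2::geom_vline(
      xintercept = maps$column, linetype = "dotted", alpha = 0.5
    )
  }
  p
}
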