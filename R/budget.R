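# Preference shares and budget comparison. Mean best-worst scores are
# shifted so the minimum maps to zero and normalised by the cumulative sum,
# yielding per-item percentage preference shares directly comparable to
# budget percentage allocations.

#' Convert best-worst scores to percentage preference shares
#'
#' Anchors the scores at zero by subtracting the minimum score (so the
#' lowest-scored item gets exactly 0%) and allocates each item a percentage
#' of the cumulative shifted sum. The transformation is affine-monotone:
#' shares preserve the score ranking and are invariant to adding a constant
#' to, or positively rescaling, all scores. An optional anchor offset
#' `anchor_offset = eps` anchors at `min(score) - eps` instead, giving the
#' lowest item a nonzero share.
#'
#' @param scores A tibble with columns `item_id` and `score` (e.g. from
#'   [bw_scores()]).
#' @param anchor_offset Non-negative offset below the minimum score at which
#'   to anchor (default 0: the minimum-score item receives exactly 0%).
#' @return The input with added columns `shifted` (score minus anchor) and
#'   `pref_share_pct` (percentages summing to 100) and `pref_rank`.
#' @export
#' @examples
#' preference_shares(tibble::tibble(item_id = c("a", "b", "c"),
#'                                  score = c(1, 0, -1)))
preference_shares <- function(scores, anchor_offset = 0) {
  if (anchor_offset < 0) abort("anchor_offset must be non-negative")
  s <- scores$score
  if (length(unique(s)) < 2L && anchor_offset == 0) {
    abort("all scores equal: shifted mass is zero and shares are undefined")
  }
  d <- s - min(s) + anchor_offset
  tibble::as_tibble(scores) |>
    dplyr::mutate(
      shifted = d,
      pref_share_pct = 100 * d / sum(d),
      pref_rank = rank_desc(.data$score)
    )
}

#' Compare preference shares with budget allocations
#'
#' Joins per-item preference shares with budget percentage shares and ranks
#' the two independently (descending, ties broken by input order). Budget
#' shares are taken as given — they need not sum to 100, since a national
#' budget typically contains lines outside the item list. When the budget
#' table carries a `budget_rank` column (published ranks, as in
#' [bws_catalogue()]), those ranks are used verbatim; otherwise ranks are
#' computed from the shares, which must then be present for every item.
#'
#' @param shares Output of [preference_shares()] (needs `item_id`,
#'   `pref_share_pct`, `pref_rank`).
#' @param budget A tibble with `item_id`, `budget_share_pct` and optionally
#'   `budget_rank` (e.g. [bws_catalogue()]).
#' @return A tibble of class `bws_budget_comparison` with per-item preference
#'   and budget shares and ranks, `rank_diff` (budget rank minus preference
#'   rank; positive = the budget ranks the item lower than respondents do)
#'   and `share_diff_pct` (preference minus budget share, percentage points).
#' @export
compare_with_budget <- function(shares, budget) {
  missing_items <- setdiff(shares$item_id, budget$item_id)
  if (length(missing_items) > 0L) {
    abort(paste0("no budget entry for item(s): ",
                 paste(missing_items, collapse = ", ")))
  }
  budget <- tibble::as_tibble(budget)
  if (!"budget_rank" %in% names(budget) || all(is.na(budget$budget_rank))) {
    if (anyNA(budget$budget_share_pct[match(shares$item_id, budget$item_id)])) {
      na_items <- budget$item_id[is.na(budget$budget_share_pct)]
      abort(paste0("missing budget share for item(s): ",
                   paste(intersect(shares$item_id, na_items), collapse = ", ")))
    }
    budget$budget_rank <- rank_desc(budget$budget_share_pct)
  }
  out <- shares |>
    dplyr::left_join(
      dplyr::select(budget, "item_id", "budget_share_pct", "budget_rank"),
      by = "item_id"
    ) |>
    dplyr::mutate(
      rank_diff = .data$budget_rank - .data$pref_rank,
      share_diff_pct = .data$pref_share_pct - .data$budget_share_pct
    )
  class(out) <- c("bws_budget_comparison", class(out))
  out
}
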