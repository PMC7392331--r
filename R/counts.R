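# Count-based ("best minus worst") scoring. For item j with best tally B_j
# and worst tally W_j over n respondents who each see the item r times, the
# mean best-worst score is s_j = (B_j - W_j) / (r * n), a number in [-1, 1].
# With respondent-level data the per-respondent score b_ij = (best_ij -
# worst_ij) / r gives SE_j = sd(b_ij) / sqrt(n) and a one-sample t-test of
# s_j = 0.

#' Tally best and worst choices per item
#'
#' @param responses A responses tibble.
#' @param catalogue Catalogue tibble fixing the item order; defaults to the
#'   one attached by [validate_responses()].
#' @return A tibble `item_id`, `best`, `worst` in catalogue order. Column
#'   sums of `best` and `worst` both equal the number of response records.
#' @export
best_worst_counts <- function(responses, catalogue = attr(responses, "catalogue")) {
  ids <- catalogue_ids(catalogue)
  tibble::tibble(
    item_id = ids,
    best = as.integer(tabulate(match(responses$best, ids), nbins = length(ids))),
    worst = as.integer(tabulate(match(responses$worst, ids), nbins = length(ids)))
  )
}

# per-respondent scores b_ij = (#best_ij - #worst_ij) / r, one row per
# (respondent, item), items in catalogue order
respondent_scores <- function(responses, catalogue = attr(responses, "catalogue"),
                              r = NULL) {
  ids <- catalogue_ids(catalogue)
  r <- r %||% infer_r(responses, length(ids))
  rids <- unique(responses$respondent_id)
  bi <- match(responses$best, ids)
  wi <- match(responses$worst, ids)
  ri <- match(responses$respondent_id, rids)
  J <- length(ids)
  n <- length(rids)
  bmat <- matrix(0L, n, J)
  wmat <- matrix(0L, n, J)
  for (idx in seq_along(ri)) {
    bmat[ri[idx], bi[idx]] <- bmat[ri[idx], bi[idx]] + 1L
    wmat[ri[idx], wi[idx]] <- wmat[ri[idx], wi[idx]] + 1L
  }
  strat <- responses$stratum[match(rids, responses$respondent_id)]
  list(scores = (bmat - wmat) / r, respondent_id = rids, stratum = strat,
       item_id = ids, r = r)
}

infer_r <- function(responses, J) {
  design <- attr(responses, "design")
  if (!is.null(design)) {
    counts <- table(design$item_id)
    if (length(unique(as.integer(counts))) != 1L) {
      abort("design is not frequency balanced; the count score's denominator presumes a uniform appearance count r")
    }
    return(as.integer(counts[1L]))
  }
  abort("cannot infer appearances per respondent r; pass `r` explicitly")
}

#' Mean best-worst scores with one-sample t-tests
#'
#' Computes per-item mean best-worst scores from respondent-level data, their
#' standard errors (standard deviation of per-respondent scores over
#' `sqrt(n)`), t statistics against zero, two-sided p-values from a Student t
#' with n - 1 degrees of freedom, and descending-score ranks (ties broken by
#' catalogue order). Scores always sum to zero over items on a complete
#' response set because every task contributes exactly one best and one worst.
#'
#' @inheritParams best_worst_counts
#' @param r Appearances of each item per respondent; inferred from the
#'   attached design when omitted (the design must be frequency balanced).
#' @return A tibble `item_id`, `best`, `worst`, `score`, `se`, `t`, `p`,
#'   `rank` with attributes `n_respondents` and `r`.
#' @seealso [bw_scores_from_counts()] for the aggregate-counts-only variant.
#' @export
bw_scores <- function(responses, catalogue = attr(responses, "catalogue"),
                      r = NULL) {
  rs <- respondent_scores(responses, catalogue, r)
  n <- length(rs$respondent_id)
  if (n == 0L) abort("no respondents")
  counts <- best_worst_counts(responses, catalogue)
  score <- colMeans(rs$scores)
  se <- apply(rs$scores, 2L, sd) / sqrt(n)
  tstat <- score / se
  out <- counts |>
    dplyr::mutate(
      score = score,
      se = se,
      t = tstat,
      p = 2 * pt(abs(tstat), df = n - 1L, lower.tail = FALSE),
      rank = rank_desc(score)
    )
  attr(out, "n_respondents") <- n
  attr(out, "r") <- rs$r
  class(out) <- c("bws_counts", class(out))
  out
}

#' Mean best-worst scores from aggregate counts
#'
#' When only the per-item best/worst tallies are available (as in a published
#' table), the mean score `s_j = (B_j - W_j) / (r n)` and the ranking are
#' still computable, but the standard errors, t statistics and p-values
#' require respondent-level data and are reported as `NA`.
#'
#' @param counts Tibble `item_id`, `best`, `worst` (e.g. [published_counts()]).
#' @param n Number of respondents.
#' @param r Appearances of each item per respondent.
#' @return A tibble like [bw_scores()], with `se`, `t`, `p` all `NA`.
#' @export
#' @examples
#' bw_scores_from_counts(published_counts("overall"), n = 432, r = 4)
bw_scores_from_counts <- function(counts, n = attr(counts, "n_respondents"),
                                  r = attr(counts, "appearances_per_respondent")) {
  if (is.null(n) || is.null(r) || n * r <= 0) {
    abort("need positive respondent count n and appearance count r")
  }
  score <- (counts$best - counts$worst) / (r * n)
  out <- tibble::as_tibble(counts) |>
    dplyr::mutate(
      score = score, se = NA_real_, t = NA_real_, p = NA_real_,
      rank = rank_desc(score)
    )
  attr(out, "n_respondents") <- as.integer(n)
  attr(out, "r") <- as.integer(r)
  class(out) <- c("bws_counts", class(out))
  out
}

#' Compare mean best-worst scores between two strata
#'
#' Per-item two-sample t-tests on the per-respondent scores of two strata.
#' The default is Welch's unequal-variance test; `pooled = TRUE` gives the
#' classical equal-variance test.
#'
#' @inheritParams bw_scores
#' @param stratum_a,stratum_b Stratum labels to compare; default the first
#'   two labels present.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return A tibble `item_id`, `score_a`, `se_a`, `score_b`, `se_b`, `t`,
#'   `df`, `p` (two-sided).
#' @export
compare_strata <- function(responses, catalogue = attr(responses, "catalogue"),
                           stratum_a = NULL, stratum_b = NULL, r = NULL,
                           pooled = FALSE) {
  rs <- respondent_scores(responses, catalogue, r)
  labels <- unique(rs$stratum)
  stratum_a <- stratum_a %||% labels[1L]
  stratum_b <- stratum_b %||% labels[2L]
  a <- rs$scores[rs$stratum == stratum_a, , drop = FALSE]
  b <- rs$scores[rs$stratum == stratum_b, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    abort("each stratum needs at least 2 respondents for a two-sample test")
  }
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, stats::var); vb <- apply(b, 2L, stats::var)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  tstat[se == 0] <- 0          # identical strata: no difference, t = 0
  df[se == 0] <- na + nb - 2
  tibble::tibble(
    item_id = rs$item_id,
    score_a = ma, se_a = sqrt(va / na),
    score_b = mb, se_b = sqrt(vb / nb),
    t = tstat, df = df,
    p = 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  )
}

# descending rank, ties broken by position (catalogue order)
rank_desc <- function(x) {
  as.integer(rank(-x, ties.method = "first"))
}
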