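# Packaged study constants: the 16 Uganda national-budget sectors, the published
# per-sector best/worst tallies (overall and by urban/rural stratum), the
# published conditional-logit utility estimates, and the 2017-18 national-budget
# percentage shares quoted in the source study. Only printed values are
# packaged; budget shares not quoted anywhere in the study text are NA.

.sector_ids <- c(
  "health", "water_env", "education", "agriculture", "works_transport",
  "social_dev", "security", "energy_mineral", "pub_sector_mgmt",
  "accountability", "justice_law_order", "ict", "lands_housing",
  "tourism_trade", "pub_admin", "legislature"
)

.sector_labels <- c(
  "Health", "Water and Environment", "Education", "Agriculture",
  "Works and Transport", "Social Development", "Security",
  "Energy and Mineral Development", "Public Sector Management",
  "Accountability", "Justice, Law and Order",
  "Information and Communication Technology",
  "Lands, Housing and Urban Development", "Tourism, Trade and Industry",
  "Public Administration", "Legislature"
)

#' Sector catalogue for the Uganda budget-preference study
#'
#' The 16 sectors of the Uganda national budget used as the item list of the
#' best-worst scaling survey, in canonical order. Where the study text quotes
#' the sector's percentage share of the 2017-18 national budget (and its rank
#' among all budget lines), those are included; shares the study does not print
#' are `NA`. The quoted shares need not sum to 100 because the full budget
#' contains lines outside this enumeration's quoted subset.
#'
#' @return A tibble with one row per sector and columns `item_id` (short stable
#'   token), `label` (display name), `budget_share_pct` (% of national budget,
#'   `NA` if not quoted) and `budget_rank` (published rank among the 16
#'   sectors, `NA` if not quoted).
#' @export
#' @examples
#' bws_catalogue()
bws_catalogue <- function() {
  tibble::tibble(
    item_id = .sector_ids,
    label = .sector_labels,
    budget_share_pct = c(
      6.4, 4.6, 21.3, 6.1, 22.1, 1.5, 10.0, NA, NA,
      NA, 7.2, 0.3, NA, NA, NA, NA
    ),
    budget_rank = c(
      6L, 10L, 2L, 7L, 1L, 11L, 3L, NA, NA,
      NA, 4L, 16L, NA, NA, NA, NA
    )
  )
}

#' Published per-sector best/worst tallies
#'
#' Per-sector counts of how often each sector was chosen most important
#' ("best") and least important ("worst"), as published for the full sample of
#' 432 respondents and for the urban (n = 217) and rural (n = 215) sub-samples.
#' Each respondent completed 16 tasks of 4 sectors, so each sector appeared 4
#' times per respondent.
#'
#' @param sample One of `"overall"`, `"urban"`, `"rural"`.
#' @return A tibble with columns `item_id`, `best`, `worst`, plus attributes
#'   `n_respondents` and `appearances_per_respondent` (always 4).
#' @seealso [bw_scores_from_counts()] to turn these into mean best-worst
#'   scores.
#' @export
#' @examples
#' published_counts("overall")
published_counts <- function(sample = c("overall", "urban", "rural")) {
  sample <- match.arg(sample)
  counts <- switch(sample,
    overall = list(
      n = 432L,
      best  = c(1417L, 1025L, 903L, 903L, 608L, 649L, 502L, 159L, 154L,
                133L, 65L, 166L, 68L, 59L, 46L, 55L),
      worst = c(45L, 169L, 128L, 218L, 244L, 326L, 312L, 388L, 470L,
                508L, 494L, 608L, 589L, 609L, 871L, 933L)
    ),
    urban = list(
      n = 217L,
      best  = c(744L, 515L, 457L, 433L, 283L, 341L, 249L, 80L, 87L,
                69L, 38L, 83L, 34L, 32L, 13L, 14L),
      worst = c(17L, 84L, 51L, 92L, 125L, 164L, 164L, 168L, 244L,
                254L, 240L, 268L, 285L, 292L, 485L, 539L)
    ),
    rural = list(
      n = 215L,
      best  = c(673L, 510L, 446L, 470L, 325L, 308L, 253L, 79L, 67L,
                64L, 27L, 83L, 34L, 27L, 33L, 41L),
      worst = c(28L, 85L, 77L, 126L, 119L, 162L, 148L, 220L, 226L,
                254L, 254L, 340L, 304L, 317L, 386L, 394L)
    )
  )
  out <- tibble::tibble(item_id = .sector_ids, best = counts$best, worst = counts$worst)
  attr(out, "n_respondents") <- counts$n
  attr(out, "appearances_per_respondent") <- 4L
  out
}

#' Published sequential conditional-logit utility estimates
#'
#' The per-sector utility estimates (effects-coded, zero-sum up to printed
#' rounding) published for the sequential best-worst conditional logit, with
#' standard errors, for the full sample and each stratum. These are primarily
#' useful as true utility vectors for [bws_scenario()] when validating
#' estimator recovery on simulated data.
#'
#' @param sample One of `"overall"`, `"urban"`, `"rural"`.
#' @return A tibble with columns `item_id`, `estimate`, `se`, `rank`.
#' @export
#' @examples
#' published_clogit_estimates()
published_clogit_estimates <- function(sample = c("overall", "urban", "rural")) {
  sample <- match.arg(sample)
  # rows in canonical catalogue order
  est <- switch(sample,
    overall = list(
      estimate = c(3.027, 1.611, 1.831, 1.686, 1.256, 1.100, 0.556,
                   -0.587, -0.980, -0.993, -1.336, -0.731, -1.471,
                   -1.600, -1.713, -1.655),
      se = c(0.064, 0.054, 0.053, 0.056, 0.056, 0.054, 0.056, 0.083,
             0.084, 0.090, 0.121, 0.084, 0.119, 0.127, 0.143, 0.131),
      rank = c(1L, 4L, 2L, 3L, 5L, 6L, 7L, 8L, 10L, 11L, 12L, 9L, 13L,
               14L, 16L, 15L)
    ),
    urban = list(
      estimate = c(3.333, 1.643, 1.907, 1.656, 1.165, 1.183, 0.569,
                   -0.523, -0.815, -0.911, -1.164, -0.661, -1.412,
                   -1.449, -2.228, -2.293),
      se = c(0.099, 0.078, 0.077, 0.080, 0.081, 0.078, 0.082, 0.116,
             0.114, 0.127, 0.160, 0.120, 0.169, 0.174, 0.265, 0.254),
      rank = c(1L, 4L, 2L, 3L, 6L, 5L, 7L, 8L, 10L, 11L, 12L, 9L, 13L,
               14L, 15L, 16L)
    ),
    rural = list(
      estimate = c(2.822, 1.605, 1.802, 1.766, 1.354, 1.057, 0.540,
                   -0.605, -1.164, -1.064, -1.530, -0.724, -1.473,
                   -1.720, -1.357, -1.308),
      se = c(0.083, 0.070, 0.071, 0.071, 0.073, 0.072, 0.076, 0.112,
             0.123, 0.125, 0.166, 0.114, 0.185, 0.185, 0.169, 0.153),
      rank = c(1L, 4L, 2L, 3L, 5L, 6L, 7L, 8L, 11L, 10L, 15L, 9L, 14L,
               16L, 13L, 12L)
    )
  )
  tibble::tibble(item_id = .sector_ids, estimate = est$estimate,
                 se = est$se, rank = est$rank)
}
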