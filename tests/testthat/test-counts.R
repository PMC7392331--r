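test_that("published overall tallies reproduce the printed scores and ranks", {
  counts <- published_counts("overall")
  expect_equal(counts$best[counts$item_id == "health"], 1417L)
  expect_equal(counts$worst[counts$item_id == "health"], 45L)
  expect_equal(counts$best[counts$item_id == "legislature"], 55L)
  expect_equal(counts$worst[counts$item_id == "legislature"], 933L)
  sc <- bw_scores_from_counts(counts)
  expect_equal(sc$score[sc$item_id == "water_env"], 856 / 1728)
  expect_equal(sc$score[sc$item_id == "agriculture"], 685 / 1728)
  expect_true(all(abs(sc$score - printed_overall) < 0.001))
  expect_equal(sc$rank, 1:16)
  # aggregate counts cannot support SEs or tests
  expect_true(all(is.na(sc$se)) && all(is.na(sc$t)) && all(is.na(sc$p)))
})

test_that("tallies equal a brute-force loop over a simulated record set", {
  scen <- survey_scenario(n = 125, utilities = centered_true_utilities(),
                         seed = 321)
  resp <- simulate_responses(scen)
  counts <- best_worst_counts(resp)
  oc <- oracle_counts(resp, bws_catalogue()$item_id)
  expect_equal(counts$best, oc$best)
  expect_equal(counts$worst, oc$worst)
  expect_equal(sum(counts$best), nrow(resp))
  expect_equal(sum(counts$worst), nrow(resp))
})

test_that("a single response tallies exactly one best and one worst", {
  cat4 <- small_catalogue(4)
  des4 <- tibble::tibble(task_id = 1L, item_id = cat4$item_id)
  resp <- validate_responses(
    tibble::tibble(respondent_id = "r1", stratum = "s", task_id = 1L,
                   best = "itm01", worst = "itm04"),
    des4, cat4
  )
  counts <- best_worst_counts(resp)
  expect_equal(counts$best, c(1L, 0L, 0L, 0L))
  expect_equal(counts$worst, c(0L, 0L, 0L, 1L))
})

test_that("scores are zero-sum, bounded, and match the aggregate identity", {
  scen <- survey_scenario(n = 150, utilities = centered_true_utilities(),
                         seed = 55)
  resp <- simulate_responses(scen)
  sc <- bw_scores(resp)
  expect_lt(abs(sum(sc$score)), 1e-12)
  expect_true(all(sc$score >= -1 & sc$score <= 1))
  # mean over respondents of b_ij equals (B_j - W_j) / (r n) exactly
  expect_equal(sc$score, (sc$best - sc$worst) / (4 * 150))
  expect_equal(sort(sc$rank), 1:16)
  # one-sample t matches stats::t.test on the per-respondent scores
  rs <- bwspref:::respondent_scores(resp)
  j <- which(rs$item_id == "health")
  tt <- t.test(rs$scores[, j])
  expect_equal(sc$t[sc$item_id == "health"], unname(tt$statistic))
  expect_equal(sc$p[sc$item_id == "health"], tt$p.value)
})

test_that("items with larger true utility earn larger expected scores", {
  # with every item in every task (k = J) all items share the same choice
  # context, so expected scores are strictly monotone in utility
  cat6 <- small_catalogue(6)
  des6 <- tibble::tibble(task_id = 1L, item_id = cat6$item_id)
  truth6 <- c(1.2, 0.7, 0.2, -0.2, -0.7, -1.2)
  scen <- bws_scenario(cat6, des6,
                       list(list(label = "s", n = 4000, utilities = truth6)),
                       sigma = 0, seed = 90)
  sc <- bw_scores(simulate_responses(scen))
  expect_equal(order(-sc$score), order(-truth6))
  # on the survey-shaped subset design, items meet unequal competitor sets
  # (120 item pairs vs 96 co-occurrence slots), so only the broad ordering
  # is preserved; closely-spaced items may swap ranks
  truth <- centered_true_utilities()
  scen16 <- survey_scenario(n = 2000, utilities = truth, seed = 90)
  sc16 <- bw_scores(simulate_responses(scen16))
  expect_gt(cor(sc16$score, truth, method = "spearman"), 0.95)
  ids <- bws_catalogue()$item_id
  expect_setequal(sc16$item_id[sc16$rank <= 4], ids[order(-truth)][1:4])
})

test_that("identical strata show no score differences", {
  scen <- survey_scenario(n = 40, utilities = centered_true_utilities(),
                         seed = 17)
  resp <- simulate_responses(scen)
  # same respondents duplicated under two labels
  dup <- dplyr::mutate(resp, stratum = "b",
                       respondent_id = paste0(respondent_id, "_b"))
  both <- validate_responses(dplyr::bind_rows(resp, dup),
                             attr(resp, "design"), bws_catalogue())
  cmp <- compare_strata(both, stratum_a = "all", stratum_b = "b")
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p == 1))
})

test_that("a stratum utility gap is detected by the two-sample test", {
  truth <- centered_true_utilities()
  shifted <- truth
  shifted[1] <- shifted[1] + 1
  des <- survey_design()
  scen <- bws_scenario(
    bws_catalogue(), des,
    strata = list(list(label = "a", n = 500, utilities = truth),
                  list(label = "b", n = 500, utilities = shifted)),
    sigma = 0, seed = 41
  )
  cmp <- compare_strata(simulate_responses(scen))
  expect_lt(cmp$p[cmp$item_id == "health"], 0.01)
  # pooled variant agrees closely at equal n
  cmp_pooled <- compare_strata(simulate_responses(scen), pooled = TRUE)
  expect_lt(cmp_pooled$p[cmp_pooled$item_id == "health"], 0.01)
})

test_that("degenerate stratum comparisons are rejected", {
  scen <- bws_scenario(
    bws_catalogue(), survey_design(),
    strata = list(list(label = "a", n = 5, utilities = rep(0, 16)),
                  list(label = "b", n = 1, utilities = rep(0, 16))),
    sigma = 0, seed = 3
  )
  resp <- simulate_responses(scen)
  expect_error(compare_strata(resp), "at least 2 respondents")
})

test_that("the count score requires a uniform appearance count", {
  # a frequency-imbalanced design has no single r; the statistic is refused
  cat8 <- small_catalogue(8)
  des <- generate_design(cat8, 4, 6, seed = 7)
  des$item_id[1] <- setdiff(cat8$item_id,
                            des$item_id[des$task_id == des$task_id[1]])[1]
  scen_des <- des
  resp <- validate_responses(
    tibble::tibble(respondent_id = "r1", stratum = "s",
                   task_id = unique(des$task_id),
                   best = vapply(split(des$item_id, des$task_id),
                                 `[`, "", 1L),
                   worst = vapply(split(des$item_id, des$task_id),
                                  `[`, "", 2L)),
    scen_des, cat8
  )
  expect_error(bw_scores(resp), "not frequency balanced")
})
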