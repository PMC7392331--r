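test_that("fully symmetric choice data give all-zero utilities", {
  # one task of four items; respondents cover every ordered (best, worst)
  # pair exactly once, so no item is preferred in any direction
  cat4 <- small_catalogue(4)
  des4 <- tibble::tibble(task_id = 1L, item_id = cat4$item_id)
  pairs <- expand.grid(best = cat4$item_id, worst = cat4$item_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$best != pairs$worst, ]
  resp <- validate_responses(
    tibble::tibble(respondent_id = sprintf("r%02d", seq_len(nrow(pairs))),
                   stratum = "s", task_id = 1L,
                   best = pairs$best, worst = pairs$worst),
    des4, cat4
  )
  fit <- fit_bws_clogit(expand_choice_long(resp), cat4)
  expect_lt(max(abs(fit$estimates)), 1e-6)
})

test_that("the fitted log-likelihood matches sequential enumeration", {
  # small instance: J = 4, k = 3, 5 respondents, 4 tasks
  cat4 <- small_catalogue(4)
  des <- generate_design(cat4, items_per_task = 3, n_tasks = 4, seed = 2)
  scen <- bws_scenario(cat4, des,
                       list(list(label = "s", n = 5,
                                 utilities = c(0.8, 0.2, -0.3, -0.7))),
                       sigma = 0, seed = 6)
  resp <- simulate_responses(scen)
  long <- expand_choice_long(resp)
  set.seed(99)
  for (i in 1:5) {
    gamma <- rnorm(4)
    util <- setNames(gamma, cat4$item_id)
    expect_equal(bws_clogit_loglik(long, util, cat4),
                 oracle_loglik(resp, des, util), tolerance = 1e-12)
  }
  # and the optimum the fitter reports evaluates to its own log-likelihood
  fit <- fit_bws_clogit(long, cat4)
  expect_equal(fit$logLik,
               oracle_loglik(resp, des, setNames(fit$estimates, cat4$item_id)),
               tolerance = 1e-10)
})

test_that("omitted-level recovery follows the stated formulas", {
  rec <- recover_omitted(c(0.5, 0.3),
                         matrix(c(0.04, 0.01, 0.01, 0.09), 2))
  expect_equal(rec$estimate, -0.8)
  expect_equal(rec$se, sqrt(0.15))
  rec0 <- recover_omitted(rep(0, 7), diag(7) * 0.1)
  expect_equal(rec0$estimate, 0)
  # delta-method oracle: SE of a'beta with a = -1 from the fitted vcov
  scen <- survey_scenario(n = 100, utilities = centered_true_utilities(),
                         seed = 23)
  fit <- fit_bws_clogit(expand_choice_long(simulate_responses(scen)),
                        bws_catalogue())
  a <- rep(-1, ncol(fit$vcov))
  expect_equal(fit$se[match(fit$omitted, fit$item_id)],
               sqrt(drop(t(a) %*% fit$vcov %*% a)))
  expect_error(recover_omitted(c(1, 2), diag(3)), "square matrix")
  expect_error(recover_omitted(c(1, 2), matrix(c(1, 0.5, 0, 1), 2)),
               "symmetric")
})

test_that("recovered utilities are invariant to coding choices", {
  scen <- survey_scenario(n = 120, utilities = centered_true_utilities(),
                         seed = 61)
  resp <- simulate_responses(scen)
  long <- expand_choice_long(resp)
  cat16 <- bws_catalogue()
  ref <- fit_bws_clogit(long, cat16)
  # different omitted categories
  for (om in c("health", "education", "accountability")) {
    alt <- fit_bws_clogit(long, cat16, omit = om)
    expect_lt(max(abs(alt$estimates - ref$estimates)), 1e-6)
    expect_lt(max(abs(alt$se - ref$se)), 1e-5)
  }
  # permuted catalogue order
  perm <- sample(16)
  cat_perm <- cat16[perm, ]
  alt <- fit_bws_clogit(long, cat_perm, omit = cat_perm$item_id[1])
  expect_lt(max(abs(alt$estimates[match(cat16$item_id, cat_perm$item_id)] -
                      ref$estimates)), 1e-6)
  expect_equal(sum(alt$estimates), 0, tolerance = 1e-10)
})

test_that("ranking is by descending estimate with catalogue-order ties", {
  scen <- survey_scenario(n = 80, utilities = centered_true_utilities(),
                         seed = 7)
  fit <- fit_bws_clogit(expand_choice_long(simulate_responses(scen)),
                        bws_catalogue())
  ri <- rank_items(fit)
  expect_equal(ri$rank, 1:16)
  expect_true(all(diff(ri$estimate) <= 0))
  expect_equal(sort(fit$rank), 1:16)
})

test_that("estimates broadly agree with the count ranking", {
  # the two analyses measure the same preferences but the count score is
  # exposed to competitor-set composition; they must agree on the clear
  # winner and correlate strongly overall, while adjacent near-ties may
  # swap (the published count and regression rankings differ the same way)
  scen <- survey_scenario(n = 2000, utilities = centered_true_utilities(),
                         seed = 111)
  resp <- simulate_responses(scen)
  sc <- bw_scores(resp)
  fit <- fit_bws_clogit(expand_choice_long(resp), bws_catalogue())
  expect_equal(sc$item_id[sc$rank == 1], fit$item_id[fit$rank == 1])
  expect_gt(cor(sc$rank, fit$rank, method = "spearman"), 0.9)
  # with identical contexts (k = J) the extremes agree exactly
  cat5 <- small_catalogue(5)
  des5 <- tibble::tibble(task_id = 1L, item_id = cat5$item_id)
  truth5 <- c(1.5, 0.5, 0, -0.5, -1.5)
  scen5 <- bws_scenario(cat5, des5,
                        list(list(label = "s", n = 1500,
                                  utilities = truth5)),
                        sigma = 0, seed = 112)
  resp5 <- simulate_responses(scen5)
  sc5 <- bw_scores(resp5)
  fit5 <- fit_bws_clogit(expand_choice_long(resp5), cat5)
  expect_equal(sc5$item_id[sc5$rank == 1], fit5$item_id[fit5$rank == 1])
  expect_equal(sc5$item_id[sc5$rank == 5], fit5$item_id[fit5$rank == 5])
})

test_that("estimates match an independent conditional-logit implementation", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  cat16 <- bws_catalogue()
  scen <- survey_scenario(n = 60, utilities = centered_true_utilities(),
                         seed = 13)
  long <- expand_choice_long(simulate_responses(scen))
  fit <- fit_bws_clogit(long, cat16)
  # effects-coded covariates times the stage weight, omitted = last item
  ids <- cat16$item_id
  J <- length(ids)
  X <- matrix(0, nrow(long), J - 1)
  idx <- match(long$item_id, ids)
  for (m in seq_len(J - 1)) {
    X[, m] <- long$weight * ((idx == m) - (idx == J))
  }
  df <- data.frame(chosen = long$chosen, gid = long$group_id, X)
  fml <- stats::as.formula(paste(
    "chosen ~", paste(sprintf("X%d", seq_len(J - 1)), collapse = " + "),
    "+ strata(gid)"
  ))
  colnames(df)[-(1:2)] <- sprintf("X%d", seq_len(J - 1))
  sfit <- survival::clogit(fml, data = df)
  expect_equal(unname(fit$beta), unname(coef(sfit)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(sfit)))), tolerance = 1e-4)
})

test_that("separation and malformed groups are flagged", {
  cat3 <- small_catalogue(3)
  des3 <- tibble::tibble(task_id = 1L, item_id = cat3$item_id)
  # item 1 always best, item 3 always worst: complete separation
  resp <- validate_responses(
    tibble::tibble(respondent_id = sprintf("r%d", 1:4), stratum = "s",
                   task_id = 1L, best = "itm01", worst = "itm03"),
    des3, cat3
  )
  long <- expand_choice_long(resp)
  expect_warning(
    tryCatch(fit_bws_clogit(long, cat3, max_iter = 30L),
             error = function(e) NULL),
    "separation"
  )
  bad <- dplyr::mutate(long, chosen = 0L)
  expect_error(fit_bws_clogit(bad, cat3), "exactly one chosen")
})

test_that("tidy and glance expose the fit in broom conventions", {
  scen <- survey_scenario(n = 50, utilities = centered_true_utilities(),
                         seed = 19)
  fit <- fit_bws_clogit(expand_choice_long(simulate_responses(scen)),
                        bws_catalogue())
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "rank", "omitted"))
  expect_equal(nrow(td), 16)
  expect_equal(sum(td$omitted), 1)
  expect_equal(sum(td$estimate), 0, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$logLik, 0)
  expect_equal(gl$df, 15)
  expect_equal(gl$n_groups, 50 * 16 * 2)
})
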