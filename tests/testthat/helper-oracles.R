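# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops over the raw response records, independent of the package's
# vectorised code paths.

small_catalogue <- function(J, prefix = "itm") {
  tibble::tibble(item_id = sprintf("%s%02d", prefix, seq_len(J)),
                 label = sprintf("Item %d", seq_len(J)))
}

survey_design <- function(seed = 1) {
  generate_design(bws_catalogue(), items_per_task = 4, n_tasks = 16,
                  seed = seed)
}

# one-stratum scenario on the survey-shaped design
survey_scenario <- function(n, utilities, sigma = 0, seed = 1,
                           design = survey_design()) {
  bws_scenario(bws_catalogue(), design,
               strata = list(list(label = "all", n = n,
                                  utilities = utilities)),
               sigma = sigma, seed = seed)
}

# brute-force per-item best/worst tally by looping over records
oracle_counts <- function(responses, ids) {
  best <- setNames(integer(length(ids)), ids)
  worst <- setNames(integer(length(ids)), ids)
  for (i in seq_len(nrow(responses))) {
    best[responses$best[i]] <- best[responses$best[i]] + 1L
    worst[responses$worst[i]] <- worst[responses$worst[i]] + 1L
  }
  list(best = unname(best), worst = unname(worst))
}

# sequential-likelihood enumeration oracle: sum over records of
# log P(best over task set) + log P(worst over remaining, negated utilities)
oracle_loglik <- function(responses, design, utilities) {
  task_items <- split(design$item_id, design$task_id)
  ll <- 0
  for (i in seq_len(nrow(responses))) {
    S <- task_items[[as.character(responses$task_id[i])]]
    v <- utilities[S]
    pb <- exp(v[responses$best[i]]) / sum(exp(v))
    rest <- setdiff(S, responses$best[i])
    vr <- utilities[rest]
    pw <- exp(-vr[responses$worst[i]]) / sum(exp(-vr))
    ll <- ll + log(pb) + log(pw)
  }
  as.numeric(ll)
}

# printed mean best-worst scores, canonical sector order
printed_overall <- c(0.793, 0.495, 0.448, 0.396, 0.210, 0.186, 0.109,
                    -0.132, -0.182, -0.217, -0.248, -0.255, -0.301, -0.318,
                    -0.477, -0.508)
printed_urban <- c(0.837, 0.496, 0.467, 0.392, 0.182, 0.203, 0.097,
                          -0.101, -0.180, -0.213, -0.232, -0.213, -0.289,
                          -0.299, -0.543, -0.604)
printed_rural <- c(0.750, 0.494, 0.429, 0.400, 0.239, 0.169, 0.122,
                          -0.163, -0.184, -0.220, -0.263, -0.298, -0.313,
                          -0.337, -0.410, -0.410)

centered_true_utilities <- function(sample = "overall") {
  u <- published_clogit_estimates(sample)$estimate
  u - mean(u)
}
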