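# Generative counterpart of the sequential best-worst conditional logit.
# Each respondent carries a latent utility vector; within a task the best item
# is a softmax draw over the task's items and the worst item a softmax draw
# with negated utilities over the items remaining after the best is removed.

#' Define a best-worst simulation scenario
#'
#' A scenario bundles the catalogue, the design, the per-stratum mean utility
#' vectors, the respondent-heterogeneity standard deviation and a seed.
#' Utility vectors are identified only up to an additive constant and are
#' centred to sum to zero before use, mirroring the effects-coding
#' identification of the estimator.
#'
#' @param catalogue Catalogue tibble (`item_id`, ...).
#' @param design Long-form design tibble.
#' @param strata A list of strata, each a list with elements `label`
#'   (character), `n` (respondents) and `utilities` (numeric vector, one entry
#'   per catalogue item, catalogue order).
#' @param sigma Standard deviation of the per-respondent, per-item normal
#'   perturbation added to the stratum mean utilities (`sigma = 0` gives the
#'   fixed-coefficient conditional logit exactly).
#' @param seed Integer seed.
#' @return A list of class `bws_scenario`.
#' @export
#' @examples
#' cat16 <- bws_catalogue()
#' des <- generate_design(cat16, 4, 16, seed = 1)
#' sc <- bws_scenario(cat16, des,
#'                    strata = list(list(label = "all", n = 10,
#'                                       utilities = rep(0, 16))),
#'                    sigma = 0, seed = 42)
bws_scenario <- function(catalogue, design, strata, sigma = 0, seed = 1L) {
  if (sigma < 0) {
    abort("sigma must be non-negative")
  }
  ids <- catalogue_ids(catalogue)
  strata <- purrr::map(strata, function(s) {
    if (is.null(s$label) || is.null(s$n) || is.null(s$utilities)) {
      abort("each stratum needs `label`, `n` and `utilities`")
    }
    u <- as.numeric(s$utilities)
    if (length(u) != length(ids) || any(!is.finite(u))) {
      abort(sprintf("stratum '%s': utilities must be %d finite numbers",
                    s$label, length(ids)))
    }
    if (s$n < 0) abort("stratum sizes must be >= 0")
    s$utilities <- u - mean(u)  # centre: utilities identified up to a constant
    s
  })
  structure(
    list(catalogue = tibble::as_tibble(catalogue), design = design,
         strata = strata, sigma = sigma, seed = as.integer(seed)),
    class = "bws_scenario"
  )
}

#' Read a simulation scenario from a YAML file
#'
#' Expected keys: `catalogue` (path to a catalogue CSV), `design` (path to a
#' design CSV), `strata` (list of `label`/`n`/`utilities`), `sigma`, `seed`.
#'
#' @param path YAML file path.
#' @return A `bws_scenario`.
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading scenario files requires the yaml package")
  }
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  catalogue <- readr::read_csv(resolve(y$catalogue), show_col_types = FALSE,
                               col_types = readr::cols(.default = "c"))
  design <- read_design(resolve(y$design))
  bws_scenario(catalogue, design, y$strata,
               sigma = y$sigma %||% 0, seed = y$seed %||% 1L)
}

#' Simulate sequential best-worst responses
#'
#' Draws respondent utility vectors `v_i = v_stratum + Normal(0, sigma^2)`
#' (independently per item), then for every task with item set `S` samples the
#' best item with probability `exp(v_ib) / sum_{j in S} exp(v_ij)` and the
#' worst item from the remainder with probability
#' `exp(-v_iw) / sum_{j in S \ b} exp(-v_ij)`. Fully reproducible for a given
#' scenario seed: heterogeneity draws come first, then one pair of uniform
#' draws per (respondent, task), in a fixed order.
#'
#' @param scenario A [bws_scenario()].
#' @return A validated responses tibble (`bws_responses`) with respondents
#'   labelled by stratum.
#' @export
simulate_responses <- function(scenario) {
  stopifnot(inherits(scenario, "bws_scenario"))
  ids <- catalogue_ids(scenario$catalogue)
  J <- length(ids)
  design <- scenario$design
  task_ids <- unique(design$task_id)
  task_items <- lapply(split(match(design$item_id, ids), design$task_id),
                       as.integer)
  task_items <- task_items[as.character(task_ids)]
  T_ <- length(task_ids)

  withr_seed(scenario$seed, {
    chunks <- purrr::imap(scenario$strata, function(s, sidx) {
      n <- as.integer(s$n)
      if (n == 0L) {
        return(NULL)
      }
      # per-respondent utilities: n x J
      U <- matrix(rep(s$utilities, each = n), nrow = n)
      if (scenario$sigma > 0) {
        U <- U + matrix(rnorm(n * J, sd = scenario$sigma), nrow = n)
      }
      rid <- sprintf("%s_%04d", s$label, seq_len(n))
      best <- matrix(0L, n, T_)
      worst <- matrix(0L, n, T_)
      for (t in seq_len(T_)) {
        S <- task_items[[t]]
        k <- length(S)
        eu <- exp(U[, S, drop = FALSE])
        pb <- eu / rowSums(eu)
        b_col <- categorical_draw(pb)                    # index into S
        en <- exp(-U[, S, drop = FALSE])
        en[cbind(seq_len(n), b_col)] <- 0                # remove chosen best
        pw <- en / rowSums(en)
        w_col <- categorical_draw(pw)
        best[, t] <- S[b_col]
        worst[, t] <- S[w_col]
      }
      tibble::tibble(
        respondent_id = rep(rid, each = T_),
        stratum = s$label,
        task_id = rep(task_ids, times = n),
        best = ids[as.vector(t(best))],
        worst = ids[as.vector(t(worst))]
      )
    })
    resp <- dplyr::bind_rows(chunks)
    validate_responses(resp, design, scenario$catalogue)
  })
}

# vectorised categorical draw: one column index per row of a probability
# matrix whose rows sum to 1
categorical_draw <- function(p) {
  u <- runif(nrow(p))
  cum <- t(apply(p, 1L, cumsum))
  pmin(as.integer(rowSums(u > cum) + 1L), ncol(p))
}
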