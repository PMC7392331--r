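# Sequential best-worst conditional logit, fitted by Newton-Raphson on the
# exact log-likelihood with analytic gradient and Hessian.
#
# Model: each choice group g (a best stage over a task's k items, or a worst
# stage over the k-1 items left after removing the chosen best) contributes
#   log P(g) = u_chosen(g) - log sum_{a in g} exp(u_a),
#   u_a = w_g * x_a' beta,
# where w_g is +1 for best groups and -1 for worst groups, and x_a is the
# effects-coded row of item a: +1 in its own column, or -1 in every column if
# a is the omitted item. Writing gamma for the full J-vector of item
# utilities with gamma_omit = -sum(beta), u_a = w_g * gamma_{item(a)}. The
# zero-sum constraint makes the model identified; the omitted item's estimate
# and standard error are recovered from the fitted beta and its
# variance-covariance matrix.

#' Fit the sequential best-worst conditional logit
#'
#' Maximum-likelihood fit of McFadden's conditional logit to stacked
#' best/worst choice groups (see [expand_choice_long()]) with effects-coded
#' item utilities: one shared coefficient per item across both stages, worst
#' stages entering with negated utilities. Newton-Raphson with analytic
#' gradient and Hessian and step-halving; the variance-covariance matrix is
#' the inverse observed information at the optimum. Standard errors treat
#' choice groups as independent (no respondent clustering), the conventional
#' conditional-logit variance.
#'
#' @param long A choice-long tibble from [expand_choice_long()].
#' @param catalogue Catalogue tibble fixing item order; defaults to first
#'   appearance order in `long`.
#' @param omit Item id of the effects-coding reference level (its coefficient
#'   is recovered as minus the sum of the others). Default: the last
#'   catalogue item. Fitted item utilities are invariant to this choice.
#' @param max_iter Maximum Newton iterations.
#' @param grad_tol Convergence threshold on the gradient max-norm.
#' @param ll_tol Convergence threshold on the relative log-likelihood change.
#' @return An object of class `bws_clogit`: see [tidy.bws_clogit()] and
#'   [glance.bws_clogit()] for tabular views. Contains the full J recovered
#'   estimates (`estimates`, summing to zero), their standard errors, the
#'   (J-1) x (J-1) variance-covariance matrix `vcov` of the non-omitted
#'   coefficients, ranks, the log-likelihood and convergence diagnostics.
#' @export
#' @examples
#' cat4 <- tibble::tibble(item_id = c("a", "b", "c", "d"))
#' des <- generate_design(cat4, 4, 1, seed = 1)
#' sc <- bws_scenario(cat4, des,
#'                    list(list(label = "s", n = 200,
#'                              utilities = c(1, 0.3, -0.3, -1))),
#'                    sigma = 0, seed = 9)
#' fit <- fit_bws_clogit(expand_choice_long(simulate_responses(sc)), cat4)
#' tidy(fit)
fit_bws_clogit <- function(long, catalogue = NULL, omit = NULL,
                           max_iter = 100L, grad_tol = 1e-8, ll_tol = 1e-10) {
  ids <- if (is.null(catalogue)) unique(long$item_id) else catalogue_ids(catalogue)
  J <- length(ids)
  omit <- omit %||% ids[J]
  o <- match(omit, ids)
  if (is.na(o)) abort(sprintf("omitted item '%s' not in catalogue", omit))

  dat <- clogit_data(long, ids)
  dat <- check_separation(dat, ids)

  # beta -> full zero-sum utility vector gamma
  to_gamma <- function(beta) {
    g <- numeric(J)
    g[-o] <- beta
    g[o] <- -sum(beta)
    g
  }
  # M: d gamma / d beta, J x (J-1)
  M <- matrix(0, J, J - 1L)
  M[cbind(seq_len(J)[-o], seq_len(J - 1L))] <- 1
  M[o, ] <- -1

  beta <- numeric(J - 1L)
  ll <- clogit_ll(dat, to_gamma(beta))
  converged <- FALSE
  iter <- 0L
  gmax <- Inf
  for (iter in seq_len(max_iter)) {
    gh <- clogit_grad_hess(dat, to_gamma(beta), J)
    grad <- drop(crossprod(M, gh$grad_gamma))
    H <- crossprod(M, gh$hess_gamma %*% M)
    gmax <- max(abs(grad))
    if (gmax < grad_tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(H, -grad), error = function(e) NULL)
    if (is.null(step)) {
      abort("singular Hessian in Newton step; the data may be degenerate")
    }
    new_beta <- beta + step
    new_ll <- clogit_ll(dat, to_gamma(new_beta))
    halved <- 0L
    while (!is.finite(new_ll) || new_ll < ll) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- clogit_ll(dat, to_gamma(new_beta))
      halved <- halved + 1L
      if (halved > 40L) break
    }
    if (abs(new_ll - ll) < ll_tol * (abs(ll) + 1e-12)) {
      beta <- new_beta
      ll <- new_ll
      converged <- TRUE
      break
    }
    beta <- new_beta
    ll <- new_ll
  }
  if (!converged) {
    abort(sprintf(
      "Newton did not converge in %d iterations (gradient max-norm %.3g, loglik %.6f)",
      max_iter, gmax, ll
    ))
  }
  gh <- clogit_grad_hess(dat, to_gamma(beta), J)
  H <- crossprod(M, gh$hess_gamma %*% M)
  V <- solve(-H)
  V <- (V + t(V)) / 2
  rec <- recover_omitted(beta, V)
  estimates <- to_gamma(beta)
  se <- numeric(J)
  se[-o] <- sqrt(diag(V))
  se[o] <- rec$se
  z <- estimates / se
  structure(
    list(
      item_id = ids,
      omitted = omit,
      estimates = estimates,
      se = se,
      z = z,
      p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
      rank = rank_desc(estimates),
      beta = setNames(beta, ids[-o]),
      vcov = V,
      logLik = ll,
      iterations = iter,
      grad_norm = max(abs(drop(crossprod(M, gh$grad_gamma)))),
      n_groups = dat$n_groups,
      n_obs = length(dat$item),
      separation = attr(dat, "separation") %||% FALSE
    ),
    class = "bws_clogit"
  )
}

# pre-indexed rows: item index, consecutive group index, weight, chosen
clogit_data <- function(long, ids) {
  item <- match(long$item_id, ids)
  if (anyNA(item)) abort("choice data contain items absent from the catalogue")
  grp <- match(long$group_id, unique(long$group_id))
  chosen <- as.integer(long$chosen)
  if (!all(tapply(chosen, grp, sum) == 1L)) {
    abort("every choice group must contain exactly one chosen row")
  }
  list(item = item, grp = grp, weight = as.numeric(long$weight),
       chosen = chosen, n_groups = max(grp))
}

check_separation <- function(dat, ids) {
  chosen_items <- unique(dat$item[dat$chosen == 1L])
  unchosen_items <- unique(dat$item[dat$chosen == 0L])
  missing <- setdiff(seq_along(ids), intersect(chosen_items, unchosen_items))
  if (length(missing) > 0L) {
    warn(sprintf(
      "possible separation: item(s) %s never chosen or never rejected; estimates may diverge",
      paste(ids[missing], collapse = ", ")
    ))
    attr(dat, "separation") <- TRUE
  }
  dat
}

# row probabilities within groups for utility vector gamma
clogit_probs <- function(dat, gamma) {
  u <- dat$weight * gamma[dat$item]
  m <- tapply(u, dat$grp, max)[dat$grp]
  eu <- exp(u - m)
  denom <- rowsum(eu, dat$grp, reorder = TRUE)[dat$grp]
  as.numeric(eu / denom)
}

clogit_ll <- function(dat, gamma) {
  p <- clogit_probs(dat, gamma)
  sum(log(p[dat$chosen == 1L]))
}

clogit_grad_hess <- function(dat, gamma, J) {
  p <- clogit_probs(dat, gamma)
  resid <- (dat$chosen - p) * dat$weight
  gg <- rowsum(resid, dat$item, reorder = TRUE)
  grad_full <- numeric(J)
  grad_full[as.integer(rownames(gg))] <- gg[, 1L]
  # Hessian of ll wrt gamma: -(diag(colsum p) - P'P), weights square to 1
  P <- Matrix::sparseMatrix(i = dat$grp, j = dat$item, x = p,
                            dims = c(dat$n_groups, J))
  PtP <- as.matrix(Matrix::crossprod(P))
  dvec <- numeric(J)
  cs <- rowsum(p, dat$item, reorder = TRUE)
  dvec[as.integer(rownames(cs))] <- cs[, 1L]
  hess_gamma <- -(diag(dvec, J) - PtP)
  list(grad_gamma = grad_full, hess_gamma = hess_gamma)
}

#' Log-likelihood of a utility vector under the sequential best-worst model
#'
#' Evaluates the stacked best/worst conditional-logit log-likelihood at an
#' arbitrary full-length item utility vector (no zero-sum constraint
#' required). Useful for profiling and for validating the fitted optimum
#' against independent computations.
#'
#' @param long Choice-long tibble.
#' @param utilities Named numeric vector of utilities, or unnamed in
#'   catalogue order.
#' @param catalogue Optional catalogue fixing item order.
#' @return The log-likelihood (scalar).
#' @export
bws_clogit_loglik <- function(long, utilities, catalogue = NULL) {
  ids <- if (is.null(catalogue)) unique(long$item_id) else catalogue_ids(catalogue)
  if (!is.null(names(utilities))) {
    utilities <- utilities[ids]
  }
  stopifnot(length(utilities) == length(ids))
  dat <- clogit_data(long, ids)
  clogit_ll(dat, as.numeric(utilities))
}

#' Recover the omitted effects-coded level
#'
#' For an effects-coded fit with non-omitted coefficients `beta` and
#' variance-covariance matrix `V`, the omitted level's coefficient is
#' `-sum(beta)` and its standard error `sqrt(sum(V))` (the delta-method
#' standard error of the linear combination with weights -1).
#'
#' @param beta Numeric vector of non-omitted coefficients.
#' @param V Symmetric variance-covariance matrix of `beta`.
#' @return A list with `estimate` and `se`.
#' @export
#' @examples
#' recover_omitted(c(0.5, 0.3), matrix(c(0.04, 0.01, 0.01, 0.09), 2))
recover_omitted <- function(beta, V) {
  if (!is.matrix(V) || nrow(V) != ncol(V) || nrow(V) != length(beta)) {
    abort("V must be a square matrix matching length(beta)")
  }
  if (max(abs(V - t(V))) > 1e-8 * (1 + max(abs(V)))) {
    abort("V must be symmetric")
  }
  s <- sum(V)
  if (s < -1e-12) {
    abort(sprintf(
      "negative variance sum (%.3g); V is not positive semi-definite (condition number %.3g)",
      s, kappa(V)
    ))
  }
  list(estimate = -sum(beta), se = sqrt(max(s, 0)))
}

#' Items of a fitted model in rank order
#'
#' @param fit A `bws_clogit` fit.
#' @return A tibble of items sorted by descending estimate (rank 1 first;
#'   ties broken by catalogue order).
#' @export
rank_items <- function(fit) {
  dplyr::arrange(tidy(fit), .data$rank)
}

#' @describeIn fit_bws_clogit Item-level tidy summary: one row per item with
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`, `rank`,
#'   `omitted`.
#' @param x A `bws_clogit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bws_clogit <- function(x, ...) {
  tibble::tibble(
    term = x$item_id,
    estimate = x$estimates,
    std.error = x$se,
    statistic = x$z,
    p.value = x$p,
    rank = x$rank,
    omitted = x$item_id == x$omitted
  )
}

#' @describeIn fit_bws_clogit One-row model summary with `logLik`, `df`,
#'   `iterations`, `converged`, `n_groups`, `n_obs`.
#' @exportS3Method generics::glance
glance.bws_clogit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik,
    df = length(x$beta),
    iterations = x$iterations,
    converged = TRUE,
    n_groups = x$n_groups,
    n_obs = x$n_obs,
    separation = x$separation
  )
}

#' @export
print.bws_clogit <- function(x, ...) {
  cat("Sequential best-worst conditional logit\n")
  cat(sprintf("  %d items (omitted level: %s), %d choice groups, logLik %.3f (%d iterations)\n",
              length(x$item_id), x$omitted, x$n_groups, x$logLik, x$iterations))
  print(tidy(x), n = length(x$item_id))
  invisible(x)
}
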