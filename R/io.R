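# Response data model and long-format expansion.
#
# A response set is a tibble with one row per (respondent, task):
#   respondent_id, stratum, task_id, best, worst
# The sequential best-then-worst expansion turns each response into two choice
# groups: a best-stage group over all k items of the task (coding weight +1,
# the best item chosen) and a worst-stage group over the k-1 remaining items
# (coding weight -1, the worst item chosen).

#' Read and validate a best-worst responses CSV
#'
#' Reads a responses file (`respondent_id,stratum,task_id,best,worst`, UTF-8,
#' header mandatory) and validates every row against the design and catalogue:
#' the best and worst item must differ, both must belong to the task's item
#' set, items must exist in the catalogue, and each (respondent, task) pair
#' may appear at most once. Validation errors cite the offending data row
#' number.
#'
#' @param path Path to the responses CSV.
#' @param design Long-form design tibble ([generate_design()]/[read_design()]).
#' @param catalogue Catalogue tibble with `item_id`.
#' @return A validated responses tibble (class `bws_responses`).
#' @export
read_responses <- function(path, design, catalogue) {
  resp <- readr::read_csv(
    path,
    col_types = readr::cols(
      respondent_id = "c", stratum = "c", task_id = "i",
      best = "c", worst = "c"
    ),
    show_col_types = FALSE
  )
  validate_responses(resp, design, catalogue)
}

#' Validate an in-memory responses tibble
#'
#' @param responses Tibble with columns `respondent_id`, `stratum`, `task_id`,
#'   `best`, `worst`.
#' @inheritParams read_responses
#' @return The responses tibble, classed `bws_responses`, unchanged in content.
#' @export
validate_responses <- function(responses, design, catalogue) {
  required <- c("respondent_id", "stratum", "task_id", "best", "worst")
  missing <- setdiff(required, names(responses))
  if (length(missing) > 0L) {
    abort(paste0("responses missing columns: ", paste(missing, collapse = ", ")))
  }
  ids <- catalogue_ids(catalogue)
  task_items <- split(design$item_id, design$task_id)

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0L) {
      abort(sprintf("%s (row%s %s)", what,
                    if (length(rows) > 1L) "s" else "",
                    paste(head(rows, 5L), collapse = ", ")))
    }
  }
  bad(responses$best == responses$worst, "best and worst item must differ")
  bad(!(responses$best %in% ids), "unknown best item_id")
  bad(!(responses$worst %in% ids), "unknown worst item_id")
  bad(!(as.character(responses$task_id) %in% names(task_items)),
      "task_id not present in design")
  in_task <- function(item, task) {
    mapply(function(i, t) i %in% task_items[[as.character(t)]], item, task,
           USE.NAMES = FALSE)
  }
  if (nrow(responses) > 0L) {
    bad(!in_task(responses$best, responses$task_id),
        "best item not in the task's item set")
    bad(!in_task(responses$worst, responses$task_id),
        "worst item not in the task's item set")
  }
  dup <- duplicated(responses[, c("respondent_id", "task_id")])
  bad(dup, "duplicate (respondent_id, task_id) pair")

  out <- tibble::as_tibble(responses)
  class(out) <- c("bws_responses", class(out))
  attr(out, "design") <- design
  attr(out, "catalogue") <- tibble::as_tibble(catalogue)
  out
}

#' Expand responses into stacked best/worst choice groups
#'
#' Implements the sequential best-then-worst expansion: per (respondent,
#' task), a best-stage group containing all k task items with coding weight
#' +1 (the chosen row is the best item), then a worst-stage group containing
#' the k - 1 items remaining after removing the best, with coding weight -1
#' (the chosen row is the worst item). Each group gets a unique `group_id`,
#' the stratum key of the conditional logit.
#'
#' @param responses A validated `bws_responses` tibble.
#' @param design Design tibble; defaults to the one attached by
#'   [validate_responses()].
#' @param allow_incomplete If `FALSE` (default), every respondent must have a
#'   response for every design task; set `TRUE` to expand whatever tasks are
#'   present.
#' @return A tibble with columns `respondent_id`, `task_id`, `stage`
#'   (`"best"`/`"worst"`), `group_id`, `item_id`, `weight` (+1/-1), `chosen`
#'   (0/1). Row count is `n_responses * (2k - 1)`.
#' @export
#' @examples
#' design <- generate_design(4, items_per_task = 4, n_tasks = 1, seed = 1)
#' resp <- tibble::tibble(respondent_id = "r1", stratum = "all", task_id = 1L,
#'                        best = "item01", worst = "item04")
#' expand_choice_long(validate_responses(resp, design,
#'                    tibble::tibble(item_id = sprintf("item%02d", 1:4))))
expand_choice_long <- function(responses, design = attr(responses, "design"),
                               allow_incomplete = FALSE) {
  if (is.null(design)) {
    abort("no design available; pass `design` or validate the responses first")
  }
  if (!allow_incomplete) {
    n_tasks <- length(unique(design$task_id))
    per_resp <- table(responses$respondent_id)
    if (nrow(responses) > 0L && any(per_resp != n_tasks)) {
      short <- names(per_resp)[per_resp != n_tasks]
      abort(sprintf(
        "incomplete response set: %d respondent(s) without all %d tasks (e.g. %s); use allow_incomplete = TRUE",
        length(short), n_tasks, short[1L]
      ))
    }
  }
  task_items <- split(design$item_id, design$task_id)
  n <- nrow(responses)
  if (n == 0L) {
    return(tibble::tibble(respondent_id = character(), task_id = integer(),
                          stage = character(), group_id = integer(),
                          item_id = character(), weight = double(),
                          chosen = integer()))
  }
  ti <- task_items[as.character(responses$task_id)]
  kk <- lengths(ti)
  # best stage: all k task items per response
  b_rep <- rep.int(seq_len(n), kk)
  b_items <- unlist(ti, use.names = FALSE)
  # worst stage: same items minus the chosen best
  keep <- b_items != responses$best[b_rep]
  w_rep <- b_rep[keep]
  w_items <- b_items[keep]

  out <- tibble::tibble(
    resp_row = c(b_rep, w_rep),
    stage = rep(c("best", "worst"), c(length(b_items), length(w_items))),
    item_id = c(b_items, w_items),
    weight = rep(c(1, -1), c(length(b_items), length(w_items))),
    chosen = as.integer(c(b_items == responses$best[b_rep],
                          w_items == responses$worst[w_rep]))
  )
  # order groups as (response, best-stage then worst-stage), rows contiguous
  out <- out[order(out$resp_row, out$stage == "worst"), ]
  out$respondent_id <- responses$respondent_id[out$resp_row]
  out$task_id <- responses$task_id[out$resp_row]
  out$resp_row <- NULL
  key <- paste(out$respondent_id, out$task_id, out$stage, sep = "\r")
  out$group_id <- match(key, unique(key))
  dplyr::select(out, "respondent_id", "task_id", "stage", "group_id",
                "item_id", "weight", "chosen")
}

#' Recover best/worst responses from expanded choice data
#'
#' The inverse of [expand_choice_long()]: reads each group's chosen row back
#' into a (respondent, task, best, worst) record.
#'
#' @param long A choice-long tibble from [expand_choice_long()].
#' @return A responses tibble (without stratum labels, which the expansion
#'   does not carry).
#' @export
collapse_choice_long <- function(long) {
  long |>
    dplyr::filter(.data$chosen == 1L) |>
    dplyr::select("respondent_id", "task_id", "stage", "item_id") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "item_id") |>
    dplyr::rename(best = "best", worst = "worst") |>
    dplyr::arrange(.data$respondent_id, .data$task_id)
}

#' Write any result table to CSV
#'
#' Serializes a result tibble (counts, scores, fits, comparisons) as CSV with
#' the column order preserved and doubles written at full round-trip
#' precision.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a responses tibble to the interchange CSV
#'
#' @param responses Responses tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(
    tibble::as_tibble(responses)[, c("respondent_id", "stratum", "task_id",
                                     "best", "worst")],
    path
  )
  invisible(path)
}
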