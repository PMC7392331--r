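# Frequency-balanced choice-task designs. A design assigns each of T tasks a
# set of k distinct items from a catalogue of J, with every item appearing
# exactly r = T*k/J times. Construction is a seeded greedy fill (items with
# the fewest appearances so far go first) followed by pairwise swap descent on
# the range of the pairwise co-occurrence counts.

#' Generate a frequency-balanced best-worst choice-task design
#'
#' Builds `n_tasks` choice tasks of `items_per_task` distinct items each such
#' that every item appears exactly `n_tasks * items_per_task / n_items` times
#' across the design. After the balanced greedy construction, pairs of
#' same-item-count assignments are swapped between tasks while any swap
#' strictly reduces the spread (max minus min) of pairwise co-occurrence
#' counts, approximating an orthogonal main-effects design. The result is
#' deterministic for a given seed.
#'
#' @param items A catalogue tibble with an `item_id` column (see
#'   [bws_catalogue()]), or an integer giving the number of items, in which
#'   case ids `item01`, `item02`, ... are generated.
#' @param items_per_task Number of items shown per task (k).
#' @param n_tasks Number of tasks (T). `n_tasks * items_per_task` must be
#'   divisible by the number of items.
#' @param seed Integer seed controlling tie-breaking in the greedy fill.
#' @return A tibble of class `bws_design` in long form with columns `task_id`
#'   (1-based integer) and `item_id`; `items_per_task` rows per task.
#' @seealso [validate_design()] for balance diagnostics,
#'   [write_design()]/[read_design()] for the wide CSV interchange format.
#' @export
#' @examples
#' d <- generate_design(bws_catalogue(), items_per_task = 4, n_tasks = 16, seed = 1)
#' validate_design(d)$frequency_balanced
generate_design <- function(items, items_per_task, n_tasks, seed = 1L) {
  if (is.numeric(items) && length(items) == 1L) {
    item_ids <- sprintf("item%02d", seq_len(items))
  } else {
    item_ids <- catalogue_ids(items)
  }
  J <- length(item_ids)
  k <- as.integer(items_per_task)
  T_ <- as.integer(n_tasks)
  if (k < 2L || J < k) {
    abort(sprintf(
      "infeasible design: need n_items >= items_per_task >= 2, got J = %d, k = %d",
      J, k
    ))
  }
  if ((T_ * k) %% J != 0L) {
    abort(sprintf(
      "n_tasks * items_per_task must be divisible by n_items: T = %d, k = %d, J = %d",
      T_, k, J
    ))
  }
  r <- (T_ * k) %/% J

  tasks <- withr_seed(seed, greedy_fill(J, k, T_))
  tasks <- swap_descent(tasks, J)

  out <- tibble::tibble(
    task_id = rep(seq_len(T_), each = k),
    item_id = item_ids[as.vector(t(tasks))]
  )
  class(out) <- c("bws_design", class(out))
  attr(out, "n_items") <- J
  attr(out, "items_per_task") <- k
  attr(out, "n_tasks") <- T_
  attr(out, "appearances_per_item") <- r
  out
}

# Greedy balanced fill: fill tasks one at a time, always taking the item with
# the fewest appearances so far (most remaining quota) that is not yet in the
# task; ties broken by a seeded random priority, then catalogue order. Retries
# with a fresh priority stream in the rare case the tail of the fill strands
# fewer than k items with remaining quota.
greedy_fill <- function(J, k, T_, max_restarts = 50L) {
  r <- (T_ * k) %/% J
  for (attempt in seq_len(max_restarts)) {
    priority <- runif(J)
    used <- integer(J)
    tasks <- matrix(0L, nrow = T_, ncol = k)
    ok <- TRUE
    for (t in seq_len(T_)) {
      in_task <- logical(J)
      for (slot in seq_len(k)) {
        avail <- which(!in_task & used < r)
        if (length(avail) == 0L) {
          ok <- FALSE
          break
        }
        pick <- avail[order(used[avail], -priority[avail], avail)][1L]
        tasks[t, slot] <- pick
        in_task[pick] <- TRUE
        used[pick] <- used[pick] + 1L
      }
      if (!ok) break
    }
    if (ok) {
      return(tasks)
    }
  }
  abort("greedy design fill failed after restarts; check J, k, T")
}

cooccurrence_from_tasks <- function(tasks, J) {
  co <- matrix(0L, J, J)
  for (t in seq_len(nrow(tasks))) {
    s <- tasks[t, ]
    co[s, s] <- co[s, s] + 1L
  }
  diag(co) <- 0L
  co
}

co_range <- function(co) {
  off <- co[upper.tri(co)]
  max(off) - min(off)
}

# Pairwise swap descent: exchange item x in task a with item y in task b
# (appearance frequencies preserved) whenever it improves the co-occurrence
# balance, judged lexicographically on (range, sum of squares) of the
# off-diagonal co-occurrence counts. The sum-of-squares tie-break lets the
# descent level out individual high pairs even when a single swap cannot yet
# lower the global range; the range itself never increases. Repeats until no
# improving swap exists.
swap_descent <- function(tasks, J, max_passes = 200L) {
  objective <- function(tt) {
    co <- cooccurrence_from_tasks(tt, J)
    off <- co[upper.tri(co)]
    c(max(off) - min(off), sum(off^2))
  }
  best <- objective(tasks)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (a in seq_len(nrow(tasks))) {
      for (b in seq_len(nrow(tasks))) {
        if (a == b) next
        for (ia in seq_len(ncol(tasks))) {
          x <- tasks[a, ia]
          if (x %in% tasks[b, ]) next
          for (ib in seq_len(ncol(tasks))) {
            y <- tasks[b, ib]
            if (y == x || y %in% tasks[a, ]) next
            cand <- tasks
            cand[a, ia] <- y
            cand[b, ib] <- x
            obj <- objective(cand)
            if (obj[1L] < best[1L] ||
                (obj[1L] == best[1L] && obj[2L] < best[2L])) {
              tasks <- cand
              best <- obj
              improved <- TRUE
              break  # slot (a, ia) now holds y; re-enter with fresh x
            }
          }
        }
      }
    }
    if (!improved) break
  }
  tasks
}

#' Diagnose balance of a choice-task design
#'
#' Tallies per-item appearance counts, the pairwise co-occurrence matrix and
#' the within-task positional frequencies of a design, and flags whether the
#' design is frequency balanced (every item appearing equally often). Purely
#' diagnostic: imbalanced designs are reported, not rejected.
#'
#' @param design A design tibble from [generate_design()] or [read_design()]
#'   (long form: `task_id`, `item_id`).
#' @return A list of class `bws_design_diagnostics` with elements
#'   `appearances` (tibble `item_id`, `n_appearances`), `cooccurrence`
#'   (symmetric J x J count matrix, zero diagonal), `cooccurrence_range`
#'   (named vector `min`, `max`, `range` over off-diagonal cells),
#'   `positional` (tibble `item_id`, `position`, `n`), and logical
#'   `frequency_balanced`.
#' @export
validate_design <- function(design) {
  stopifnot(all(c("task_id", "item_id") %in% names(design)))
  item_ids <- design_item_ids(design)
  J <- length(item_ids)
  by_task <- split(match(design$item_id, item_ids), design$task_id)

  appearances <- tibble::tibble(
    item_id = item_ids,
    n_appearances = as.integer(tabulate(match(design$item_id, item_ids), nbins = J))
  )

  co <- matrix(0L, J, J, dimnames = list(item_ids, item_ids))
  for (s in by_task) {
    co[s, s] <- co[s, s] + 1L
  }
  diag(co) <- 0L
  off <- co[upper.tri(co)]

  positional <- design |>
    dplyr::group_by(.data$task_id) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::count(.data$item_id, .data$position)

  out <- list(
    appearances = appearances,
    cooccurrence = co,
    cooccurrence_range = c(min = min(off), max = max(off), range = max(off) - min(off)),
    positional = positional,
    frequency_balanced = length(unique(appearances$n_appearances)) == 1L
  )
  class(out) <- "bws_design_diagnostics"
  out
}

#' @export
print.bws_design_diagnostics <- function(x, ...) {
  cat("BWS design diagnostics\n")
  cat(sprintf("  items: %d, appearance counts: %s\n",
              nrow(x$appearances),
              paste(range(x$appearances$n_appearances), collapse = "-")))
  cat(sprintf("  frequency balanced: %s\n", x$frequency_balanced))
  cat(sprintf("  co-occurrence min/max/range: %d/%d/%d\n",
              x$cooccurrence_range["min"], x$cooccurrence_range["max"],
              x$cooccurrence_range["range"]))
  invisible(x)
}

#' Write / read a design in the wide CSV interchange format
#'
#' The interchange format is one row per task with header
#' `task_id,item_1,...,item_k`.
#'
#' @param design A long-form design tibble.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a long-form design tibble as produced by [generate_design()].
#' @export
write_design <- function(design, path) {
  wide <- design |>
    dplyr::group_by(.data$task_id) |>
    dplyr::mutate(slot = paste0("item_", dplyr::row_number())) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "slot", values_from = "item_id")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(task_id = "i", .default = "c"))
  item_cols <- grep("^item_", names(wide), value = TRUE)
  out <- wide |>
    tidyr::pivot_longer(dplyr::all_of(item_cols),
                        names_to = "slot", values_to = "item_id") |>
    dplyr::arrange(.data$task_id) |>
    dplyr::select("task_id", "item_id")
  k <- length(item_cols)
  J <- length(unique(out$item_id))
  class(out) <- c("bws_design", class(out))
  attr(out, "n_items") <- J
  attr(out, "items_per_task") <- k
  attr(out, "n_tasks") <- length(unique(out$task_id))
  attr(out, "appearances_per_item") <- nrow(out) %/% J
  out
}

# ---- internal helpers ----

catalogue_ids <- function(catalogue) {
  if (!is.data.frame(catalogue) || !"item_id" %in% names(catalogue)) {
    abort("catalogue must be a data frame with an `item_id` column")
  }
  ids <- as.character(catalogue$item_id)
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    abort("catalogue item_ids must be unique and non-empty")
  }
  ids
}

# item ids in canonical order: catalogue order if a `catalogue` attribute is
# around, otherwise first-appearance order in the design
design_item_ids <- function(design) {
  unique(design$item_id)
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
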