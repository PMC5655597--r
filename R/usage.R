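# Outcome statistics of a usage study: per-item usage rates conditional
# on the true latent value, expected usage, overuse classification, active
# bank/domain size, overused-active overlap, and estimation accuracy.

#' Tabulate item usage counts by grid value
#'
#' Counts each item once per CAT in which it appears, grouped by the
#' simulees' grid value, and derives usage rates and mean test lengths.
#' The counting identity
#' \eqn{\sum_i \mathrm{rate}(i \mid g) = \overline{\mathrm{length}}(g)}
#' holds exactly (over the counted items).
#'
#' With \code{include_initial = FALSE} the uniformly random warm-up items
#' are dropped from the counts and the table's mean test length refers to
#' the adaptive part only, keeping the identity exact. This is the setting
#' under which the published usage tables are reproducible: counting
#' per-respondent random starts would mark most of the bank active at any
#' realistic number of replicates and dilute every usage statistic.
#'
#' @param results list of \code{cat_result} (e.g. a \code{mcat_study});
#'   each must carry a \code{grid_value}.
#' @param bank the \code{\link{item_bank}} the study ran on.
#' @param include_initial count the random initial items (default) or
#'   only the adaptively selected ones.
#' @return object of class \code{usage_table} with fields
#'   \code{grid_values}, \code{replicates}, \code{counts} (items x grid),
#'   \code{usage_rate}, \code{mean_test_length}, plus bank descriptors.
#' @export
compute_usage_rates <- function(results, bank, include_initial = TRUE) {
  n_items <- length(bank$items)
  if (!length(results)) {
    gv <- numeric(0)
    return(new_usage_table(bank, gv, integer(0),
                           matrix(0L, n_items, 0), numeric(0)))
  }
  ids <- lapply(results, function(r) {
    n0 <- if (include_initial) 0L else r$n_initial %||% 0L
    if (n0 > 0L) r$items[-seq_len(n0)] else r$items
  })
  idx <- lapply(ids, function(v) {
    i <- match(v, bank$item_id)
    if (anyNA(i)) stop("administered item id not in bank: ",
                       paste(v[is.na(i)], collapse = ", "))
    i
  })
  gv_each <- vapply(results, `[[`, 0, "grid_value")
  if (anyNA(gv_each)) stop("every result must carry a grid_value")
  grid_values <- sort(unique(gv_each))
  g_of <- match(gv_each, grid_values)
  counts <- matrix(0L, n_items, length(grid_values),
                   dimnames = list(bank$item_id, format(grid_values)))
  replicates <- tabulate(g_of, nbins = length(grid_values))
  for (k in seq_along(results)) {
    u <- idx[[k]]
    if (anyDuplicated(u)) stop("result ", k, " administers an item twice")
    counts[u, g_of[k]] <- counts[u, g_of[k]] + 1L
  }
  mean_len <- as.numeric(colSums(counts) / replicates)
  new_usage_table(bank, grid_values, replicates, counts, mean_len)
}

new_usage_table <- function(bank, grid_values, replicates, counts,
                            mean_len) {
  rate <- if (ncol(counts)) sweep(counts, 2, pmax(replicates, 1L), "/")
          else counts + 0
  structure(
    list(grid_values = grid_values,
         replicates = replicates,
         counts = counts,
         usage_rate = rate,
         mean_test_length = mean_len,
         item_id = bank$item_id,
         item_domain = bank$domain,
         domain_labels = bank$domain_labels,
         n_items = length(bank$items)),
    class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("<usage_table> %d items x %d grid values\n",
              x$n_items, length(x$grid_values)))
  if (!is.null(x$summary)) {
    cat("summary (percent):\n")
    print(x$summary, digits = 3)
  }
  invisible(x)
}

round_half_up <- function(x) ifelse(is.na(x), NA_real_, floor(x + 0.5))

#' Classify overuse and summarize active bank size
#'
#' An item is \emph{overused} at grid value \eqn{g} when its usage rate
#' strictly exceeds the expected usage rate, defined as the mean test
#' length at \eqn{g} divided by the \emph{total} bank size (the same
#' denominator is used when classifying within domains). An item is
#' \emph{active} when its usage rate is positive. Per-domain percentages
#' divide by the domain size, the total row by the bank size; overlap is
#' \code{100 * n_overused / n_active} (missing when nothing is active).
#'
#' @param table a \code{usage_table} from \code{\link{compute_usage_rates}}.
#' @param bank the matching \code{\link{item_bank}}.
#' @return the \code{usage_table} augmented with \code{expected_usage},
#'   logical matrices \code{overused} and \code{active}, and a
#'   \code{summary} data frame (full precision; rendering rounds).
#' @export
classify_and_summarize <- function(table, bank) {
  stopifnot(inherits(table, "usage_table"))
  n_bank <- table$n_items
  expected <- table$mean_test_length / n_bank
  overused <- sweep(table$usage_rate, 2, expected, ">")
  active <- table$usage_rate > 0
  D <- length(table$domain_labels)
  groups <- c(list(Total = seq_len(n_bank)),
              stats::setNames(lapply(seq_len(D),
                                     function(d) which(table$item_domain == d)),
                              table$domain_labels))
  rows <- lapply(seq_along(table$grid_values), function(gi) {
    one <- lapply(names(groups), function(nm) {
      g <- groups[[nm]]
      n_act <- sum(active[g, gi])
      n_ov <- sum(overused[g, gi])
      data.frame(grid_value = table$grid_values[gi], group = nm,
                 group_size = length(g), n_active = n_act,
                 n_overused = n_ov,
                 active_pct = 100 * n_act / length(g),
                 overused_pct = 100 * n_ov / length(g),
                 overlap_pct = if (n_act > 0) 100 * n_ov / n_act
                               else NA_real_)
    })
    do.call(rbind, one)
  })
  table$expected_usage <- expected
  table$overused <- overused
  table$active <- active
  table$summary <- do.call(rbind, rows)
  rownames(table$summary) <- NULL
  table
}

#' Estimation accuracy by grid value and dimension
#'
#' Root-mean-square error and bias of the final latent-trait estimates
#' against the generating values, per dimension within each grid value and
#' pooled over the grid (pooled rows have \code{grid_value = NA}).
#'
#' @param results non-empty list of \code{cat_result} carrying
#'   \code{true_theta}.
#' @return data frame with columns \code{grid_value}, \code{dimension},
#'   \code{n}, \code{bias}, \code{rmse}.
#' @export
accuracy_metrics <- function(results) {
  if (!length(results)) stop("no results to summarize")
  err <- t(vapply(results, function(r) r$theta_final - r$true_theta,
                  numeric(length(results[[1]]$true_theta))))
  gv <- vapply(results, function(r) r$grid_value %||% NA_real_, 0)
  D <- ncol(err)
  block <- function(rows, g) {
    data.frame(grid_value = g, dimension = seq_len(D), n = length(rows),
               bias = colMeans(err[rows, , drop = FALSE]),
               rmse = sqrt(colMeans(err[rows, , drop = FALSE]^2)))
  }
  out <- list()
  if (!anyNA(gv)) {
    for (g in sort(unique(gv)))
      out[[length(out) + 1L]] <- block(which(gv == g), g)
  }
  out[[length(out) + 1L]] <- block(seq_along(results), NA_real_)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flat per-step records linking usage to item parameters
#'
#' One record per item step (threshold), carrying the item's
#' discrimination, the step location and the item's maximal usage rate
#' over the grid — the data behind the classic discrimination-vs-location
#' scatter whose dot size encodes usage.
#'
#' @param table a summarized \code{usage_table}.
#' @param bank the matching \code{\link{item_bank}}.
#' @return data frame with one row per (item, step).
#' @export
usage_vs_parameters_report <- function(table, bank) {
  stopifnot(inherits(table, "usage_table"))
  max_rate <- if (ncol(table$usage_rate))
    apply(table$usage_rate, 1, max) else rep(0, table$n_items)
  recs <- lapply(seq_along(bank$items), function(i) {
    b <- bank$betas[[i]]
    data.frame(item_id = bank$item_id[i],
               domain = bank$domain[i],
               domain_label = bank$domain_labels[bank$domain[i]],
               alpha = bank$alpha[i],
               step = seq_along(b),
               beta = b,
               max_usage_rate = unname(max_rate[i]))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
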