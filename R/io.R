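# File formats, run configuration and command-line entry points.
#
# Bank CSV: a comment header block ("# key: value" lines) carries the
# domain labels and the latent correlation matrix (one "# correlation:"
# line per row); the body has columns item_id, domain, alpha, b1..b4 with
# trailing thresholds left blank for items with fewer categories.

#' Write an item bank to CSV
#'
#' @param bank an \code{\link{item_bank}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  max_m <- max(bank$n_categories) - 1L
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# mcatsim item bank",
    paste0("# domain_labels: ", paste(bank$domain_labels, collapse = ",")),
    paste0("# correlation: ",
           apply(bank$correlation, 1, paste, collapse = ","))), con)
  bcols <- vapply(seq_len(max_m), function(j)
    vapply(bank$betas, function(b)
      if (j <= length(b)) sprintf("%.15g", b[j]) else "", ""),
    character(length(bank$items)))
  df <- data.frame(item_id = bank$item_id,
                   domain = bank$domain_labels[bank$domain],
                   alpha = sprintf("%.15g", bank$alpha))
  df <- cbind(df, stats::setNames(as.data.frame(bcols),
                                  paste0("b", seq_len(max_m))))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an item bank from CSV
#'
#' Accepts either the native "difficulty" parametrization (\eqn{\beta})
#' or the IRTPRO-style "easiness" parameter \eqn{c}, which is converted
#' via \eqn{\beta = -c} before validation; thresholds must be strictly
#' increasing after conversion. The domain column may hold labels or
#' 1-based indices.
#'
#' @param path CSV written by \code{\link{write_item_bank}} (or
#'   hand-transcribed in the same layout).
#' @param parametrization \code{"difficulty"} or \code{"easiness"}.
#' @return an \code{\link{item_bank}}.
#' @export
read_item_bank <- function(path, parametrization = c("difficulty",
                                                     "easiness")) {
  parametrization <- match.arg(parametrization)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  get_vals <- function(key) {
    v <- sub(paste0("^#\\s*", key, ":\\s*"), "",
             grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE))
    lapply(strsplit(v, ","), trimws)
  }
  labels <- unlist(get_vals("domain_labels"))
  corr_rows <- get_vals("correlation")
  if (!length(labels) || !length(corr_rows))
    stop("bank file lacks '# domain_labels:' / '# correlation:' header lines")
  correlation <- do.call(rbind, lapply(corr_rows, as.numeric))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("item_id", "domain", "alpha")
  if (!all(need %in% names(df)))
    stop("bank file must have columns item_id, domain, alpha, b1..")
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("b", "", bcols)))]
  dom <- suppressWarnings(as.integer(df$domain))
  lab_idx <- match(df$domain, labels)
  dom[is.na(dom)] <- lab_idx[is.na(dom)]
  if (anyNA(dom))
    stop("unknown domain '", df$domain[which(is.na(dom))[1]],
         "' at row ", which(is.na(dom))[1])
  items <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    b <- suppressWarnings(as.numeric(unlist(df[r, bcols])))
    b <- b[!is.na(b)]
    if (parametrization == "easiness") b <- -b
    items[[r]] <- tryCatch(
      item_parameters(as.character(df$item_id[r]), dom[r], df$alpha[r], b),
      error = function(e)
        stop("row ", r, " (", df$item_id[r], "): ", conditionMessage(e),
             call. = FALSE))
  }
  item_bank(items, correlation, labels)
}

#' Read a flat key-value configuration file
#'
#' One \code{key: value} pair per line (\code{#} comments and blank lines
#' ignored); values that parse as numbers are converted.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  if (any(vapply(kv, length, 0L) != 3L))
    stop("malformed config line: ",
         lines[which(vapply(kv, length, 0L) != 3L)[1]])
  out <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, vapply(kv, function(m) trimws(m[2]), ""))
}

#' Write study outputs
#'
#' Emits, under \code{path}: a per-respondent CAT log
#' (\code{cat_log.csv}), a long per-item usage table
#' (\code{item_usage.csv}), summary tables of active bank size, overused
#' items and overlap in percent with one row per grid value and one
#' column per domain plus the total bank
#' (\code{active_size.csv}, \code{overused.csv}, \code{overlap.csv};
#' percentages rounded half-up to integers), an accuracy table
#' (\code{accuracy.csv}) and a JSON run manifest (\code{manifest.json}).
#'
#' @param results list of \code{cat_result} (e.g. from
#'   \code{\link{run_study}}).
#' @param table a summarized \code{usage_table} for the same results.
#' @param path output directory (created if missing).
#' @param seed master seed recorded in the manifest.
#' @param config optional \code{\link{cat_config}} recorded in the
#'   manifest.
#' @return character vector of file paths, invisibly.
#' @export
write_outputs <- function(results, table, path, seed = NA_integer_,
                          config = NULL) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory ", path)
  D <- length(results[[1]]$theta_final)
  log_df <- do.call(rbind, lapply(results, function(r) {
    row <- data.frame(respondent_id = r$respondent_id,
                      grid_value = r$grid_value,
                      test_length = r$test_length,
                      n_initial = r$n_initial %||% 0L,
                      converged = r$converged)
    for (d in seq_len(D)) row[[paste0("true_theta_", d)]] <- r$true_theta[d]
    for (d in seq_len(D)) row[[paste0("theta_", d)]] <- r$theta_final[d]
    for (d in seq_len(D)) row[[paste0("se_", d)]] <- r$se_final[d]
    row$items <- paste(r$items, collapse = ";")
    row$categories <- paste(r$categories, collapse = ";")
    row
  }))
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(path, name)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wr(log_df, "cat_log.csv")

  usage_long <- do.call(rbind, lapply(seq_along(table$grid_values),
    function(gi) data.frame(
      item_id = table$item_id,
      domain = table$domain_labels[table$item_domain],
      grid_value = table$grid_values[gi],
      count = table$counts[, gi],
      usage_rate = table$usage_rate[, gi],
      overused = table$overused[, gi],
      active = table$active[, gi])))
  wr(usage_long, "item_usage.csv")

  wide <- function(metric) {
    s <- table$summary
    groups <- unique(s$group)
    out <- data.frame(theta = table$grid_values)
    for (g in groups)
      out[[g]] <- round_half_up(s[[metric]][s$group == g])
    out
  }
  wr(wide("active_pct"), "active_size.csv")
  wr(wide("overused_pct"), "overused.csv")
  wr(wide("overlap_pct"), "overlap.csv")
  wr(accuracy_metrics(results), "accuracy.csv")

  manifest <- list(
    seed = seed,
    n_respondents = length(results),
    bank_size = table$n_items,
    domain_labels = table$domain_labels,
    config = if (!is.null(config)) unclass(config[!vapply(config, is.null, TRUE)]),
    package_version = as.character(utils::packageVersion("mcatsim")))
  f <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

# ---- command line ----------------------------------------------------------

cli_bank <- function(opt) {
  if (!is.null(opt$bank)) read_item_bank(opt$bank, opt$parametrization)
  else generate_item_bank(bank_recipe(seed = opt$seed))
}

#' Command-line entry point
#'
#' Subcommands: \code{generate-bank} (synthetic recipe to bank CSV),
#' \code{run-cat} (one respondent, for debugging), \code{run-study}
#' (full grid simulation plus summary tables), \code{summarize} and
#' \code{accuracy} (recompute tables from a stored \code{cat_log.csv}).
#' Common flags: \code{--seed}, \code{--config}, \code{--out},
#' \code{--threads}, \code{--verbose}. An installed wrapper script lives
#' at \code{system.file("cli", "mcat", package = "mcatsim")}.
#'
#' @param args character vector of command-line arguments (the first is
#'   the subcommand).
#' @return invisibly, the subcommand's main object.
#' @export
mcat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mcat <generate-bank|run-cat|run-study|summarize|accuracy> [options]"
  if (!length(args)) { message(usage); return(invisible(NULL)) }
  cmd <- args[1]
  rest <- args[-1]
  opts <- list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "flat key: value config file"),
    optparse::make_option("--out", type = "character", default = "mcat_out"),
    optparse::make_option("--threads", type = "integer", default = 1L),
    optparse::make_option("--verbose", action = "store_true", default = FALSE),
    optparse::make_option("--bank", type = "character", default = NULL,
                          help = "bank CSV (default: synthetic recipe)"),
    optparse::make_option("--parametrization", type = "character",
                          default = "difficulty"),
    optparse::make_option("--theta", type = "character", default = NULL,
                          help = "comma-separated true theta (run-cat)"),
    optparse::make_option("--grid-lo", type = "double", default = -2),
    optparse::make_option("--grid-hi", type = "double", default = 2),
    optparse::make_option("--grid-step", type = "double", default = 0.2),
    optparse::make_option("--replicates", type = "integer", default = 1000L),
    optparse::make_option("--se-threshold", type = "double", default = 0.316),
    optparse::make_option("--max-length", type = "integer", default = NULL),
    optparse::make_option("--log", type = "character", default = NULL,
                          help = "cat_log.csv path (summarize/accuracy)"))
  opt <- optparse::parse_args(
    optparse::OptionParser(option_list = opts, usage = usage), args = rest)
  if (!is.null(opt$config)) {
    cfg <- read_run_config(opt$config)
    for (k in names(cfg)) opt[[k]] <- cfg[[k]]
  }
  say <- function(...) if (isTRUE(opt$verbose)) message(...)

  config <- cat_config(se_threshold = opt$`se-threshold`,
                       max_length = opt$`max-length`)
  design <- study_design(opt$`grid-lo`, opt$`grid-hi`, opt$`grid-step`,
                         opt$replicates, seed = opt$seed)

  obj <- switch(
    cmd,
    "generate-bank" = {
      bank <- generate_item_bank(bank_recipe(seed = opt$seed))
      write_item_bank(bank, opt$out)
      say("wrote ", opt$out)
      bank
    },
    "run-cat" = {
      bank <- cli_bank(opt)
      theta <- if (is.null(opt$theta)) numeric(bank$n_dimensions)
               else as.numeric(strsplit(opt$theta, ",")[[1]])
      config$seed <- opt$seed
      res <- run_cat(bank, theta, config)
      print(res)
      res
    },
    "run-study" = {
      bank <- cli_bank(opt)
      say("running ", length(design_grid_values(design)), " x ",
          design$replicates_per_point, " CATs on ", length(bank), " items")
      study <- run_study(bank, design, config, threads = opt$threads)
      tab <- classify_and_summarize(compute_usage_rates(study, bank), bank)
      write_outputs(study, tab, opt$out, seed = opt$seed, config = config)
      say("wrote outputs to ", opt$out)
      study
    },
    "summarize" = ,
    "accuracy" = {
      if (is.null(opt$log) || is.null(opt$bank))
        stop(cmd, " needs --log cat_log.csv and --bank bank.csv")
      bank <- read_item_bank(opt$bank, opt$parametrization)
      results <- read_cat_log(opt$log)
      if (cmd == "accuracy") {
        acc <- accuracy_metrics(results)
        utils::write.csv(acc, file.path(opt$out), row.names = FALSE)
        acc
      } else {
        tab <- classify_and_summarize(compute_usage_rates(results, bank),
                                      bank)
        write_outputs(results, tab, opt$out)
        tab
      }
    },
    stop("unknown subcommand '", cmd, "'\n", usage))
  invisible(obj)
}

#' Re-load per-respondent CAT results from a log CSV
#'
#' @param path a \code{cat_log.csv} written by \code{\link{write_outputs}}.
#' @return list of \code{cat_result}-shaped records.
#' @export
read_cat_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  D <- sum(grepl("^theta_[0-9]+$", names(df)))
  lapply(seq_len(nrow(df)), function(r) {
    structure(list(
      respondent_id = df$respondent_id[r],
      grid_value = df$grid_value[r],
      true_theta = as.numeric(df[r, paste0("true_theta_", seq_len(D))]),
      items = strsplit(df$items[r], ";")[[1]],
      categories = as.integer(strsplit(df$categories[r], ";")[[1]]),
      theta_final = as.numeric(df[r, paste0("theta_", seq_len(D))]),
      se_final = as.numeric(df[r, paste0("se_", seq_len(D))]),
      test_length = df$test_length[r],
      n_initial = if ("n_initial" %in% names(df)) df$n_initial[r] else 0L,
      converged = df$converged[r]), class = "cat_result")
  })
}
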