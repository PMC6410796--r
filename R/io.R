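#' Read a review log
#'
#' The canonical dialect is a headered CSV with columns `learner_id`,
#' `item_id`, `t_days` (days since the pair's first exposure),
#' `session_seen`, `session_correct`, and optionally `scheduler`. The
#' `duolingo-hlr` dialect accepts the public half-life-regression log layout
#' (`p_recall, timestamp, delta, user_id, learning_language, ui_language,
#' lexeme_id, lexeme_string, history_seen, history_correct, session_seen,
#' session_correct`); timestamps are converted to days from each
#' (user, lexeme) pair's first appearance.
#'
#' @param path File path.
#' @param dialect `"canonical"` (default) or `"duolingo-hlr"`.
#' @return A review-log tibble sorted by learner, item, time.
#' @export
read_review_log <- function(path, dialect = c("canonical", "duolingo-hlr")) {
  dialect <- match.arg(dialect)
  if (dialect == "duolingo-hlr") {
    raw <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("timestamp", "user_id", "lexeme_id", "session_seen",
              "session_correct")
    if (!all(need %in% names(raw))) {
      stop("not a duolingo-hlr log: missing ",
           paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
    }
    log <- raw |>
      dplyr::group_by(.data$user_id, .data$lexeme_id) |>
      dplyr::mutate(t_days = (.data$timestamp - min(.data$timestamp)) / 86400) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        learner_id = as.character(.data$user_id),
        item_id = as.character(.data$lexeme_id),
        t_days = .data$t_days,
        session_seen = as.integer(.data$session_seen),
        session_correct = as.integer(.data$session_correct)
      )
  } else {
    log <- readr::read_csv(
      path,
      col_types = readr::cols(
        learner_id = readr::col_character(),
        item_id = readr::col_character(),
        t_days = readr::col_double(),
        session_seen = readr::col_integer(),
        session_correct = readr::col_integer(),
        .default = readr::col_guess()
      )
    )
    need <- c("learner_id", "item_id", "t_days", "session_seen",
              "session_correct")
    if (!all(need %in% names(log))) {
      stop("not a canonical review log: missing ",
           paste(setdiff(need, names(log)), collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(log$session_correct > log$session_seen |
                 log$session_correct < 0 | log$session_seen < 1 |
                 log$t_days < 0 | !is.finite(log$t_days))
  if (length(bad) > 0) {
    stop(sprintf("malformed review row at line %d (counting the header)",
                 bad[1] + 1L), call. = FALSE)
  }
  log <- dplyr::arrange(log, .data$learner_id, .data$item_id, .data$t_days)
  nonmono <- log |>
    dplyr::group_by(.data$learner_id, .data$item_id) |>
    dplyr::filter(any(duplicated(.data$t_days))) |>
    dplyr::ungroup()
  if (nrow(nonmono) > 0) {
    stop(sprintf(
      "non-increasing review times for pair (%s, %s)",
      nonmono$learner_id[1], nonmono$item_id[1]
    ), call. = FALSE)
  }
  log
}

#' Write a review log
#'
#' Canonical CSV writer; times serialized with 6 decimal places so files
#' are byte-stable across platforms and round-trip through
#' [read_review_log()] unchanged.
#'
#' @param log A review-log tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_review_log <- function(log, path) {
  cols <- intersect(
    c("learner_id", "item_id", "t_days", "session_seen", "session_correct",
      "scheduler"),
    names(log)
  )
  out <- dplyr::mutate(log[, cols],
                       t_days = sprintf("%.6f", .data$t_days))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write memory-model parameter files
#'
#' Delimited text with the global `alpha`, `beta` estimates in a two-line
#' header followed by the per-item initial forgetting rates:
#' ```
#' alpha,0.31
#' beta,0.18
#' item_id,n0
#' i001,0.052
#' ```
#'
#' @param fit A `memory_fit` (or compatible list) to serialise.
#' @param path File path.
#' @return `read_params()` returns a list with `alpha`, `beta` and an
#'   `items` tibble, usable wherever a `memory_fit` is accepted.
#' @export
write_params <- function(fit, path) {
  lines <- c(
    sprintf("alpha,%.10g", fit$alpha),
    sprintf("beta,%.10g", fit$beta),
    "item_id,n0",
    sprintf("%s,%.10g", fit$items$item_id, fit$items$n0)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "alpha,") ||
      !startsWith(lines[2], "beta,") || lines[3] != "item_id,n0") {
    stop("malformed parameters file: ", path, call. = FALSE)
  }
  items <- readr::read_csv(I(lines[-(1:2)]),
                           col_types = readr::cols(
                             item_id = readr::col_character(),
                             n0 = readr::col_double()
                           ))
  list(
    alpha = as.numeric(sub("alpha,", "", lines[1], fixed = TRUE)),
    beta = as.numeric(sub("beta,", "", lines[2], fixed = TRUE)),
    items = items
  )
}

#' Default configuration file
#'
#' Writes/parses the flat `key = value` configuration consumed by the
#' command-line `simulate` subcommand. Every simulator default appears in
#' the shipped file.
#'
#' @param path File path.
#' @return `read_config()` returns a named list with numeric values parsed.
#' @export
write_default_config <- function(path) {
  writeLines(c(
    "# spacedrep simulation configuration (key = value)",
    "n_learners = 60",
    "items_per_learner = 10",
    "tf = 30",
    "# scheduler: memorize | uniform | threshold | mixed",
    "scheduler = mixed",
    "q = 1.0",
    "mu = 0.2",
    "c = 0.5",
    "zeta = 2.0",
    "m_th = 0.6",
    "n0_meanlog = -3.2188758248682006",  # log(0.04)
    "n0_sdlog = 1.0",
    "alpha = 0.3",
    "beta = 0.2",
    "attempts = 1",
    "test_delay = 7"
  ), path)
  invisible(path)
}

#' @rdname write_default_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(sub("\\s*#.*$", "", lines), "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), ""))
}

config_to_population <- function(cfg, seed) {
  if (cfg$alpha < 0 || cfg$alpha > 1) {
    stop("config constraint violated: alpha must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$beta < 0) {
    stop("config constraint violated: beta must be nonnegative", call. = FALSE)
  }
  scheds <- switch(as.character(cfg$scheduler),
    memorize = list(memorize = scheduler_memorize(cfg$q)),
    uniform = list(uniform = scheduler_uniform(cfg$mu)),
    threshold = list(threshold = scheduler_threshold(cfg$c, cfg$zeta, cfg$m_th)),
    mixed = list(
      memorize = scheduler_memorize(cfg$q),
      uniform = scheduler_uniform(cfg$mu),
      threshold = scheduler_threshold(cfg$c, cfg$zeta, cfg$m_th)
    ),
    stop("config constraint violated: unknown scheduler '", cfg$scheduler, "'",
         call. = FALSE)
  )
  population_config(
    n_learners = cfg$n_learners, items_per_learner = cfg$items_per_learner,
    schedulers = scheds, tf = cfg$tf,
    n0_meanlog = cfg$n0_meanlog, n0_sdlog = cfg$n0_sdlog,
    alpha = cfg$alpha, beta = cfg$beta, attempts = cfg$attempts,
    test_delay = if (!is.null(cfg$test_delay) && cfg$test_delay > 0) {
      cfg$test_delay
    } else NULL,
    seed = seed
  )
}

#' Generate the canned fixture logs
#'
#' Emits one small log per scheduler plus a mixed natural-experiment log
#' (all three arms, held-out test reviews) and the matching true-parameter
#' file and default config. Deterministic: regenerating from the same seed
#' yields byte-identical files.
#'
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param n_learners,items_per_learner Size of each fixture population.
#' @return Named character vector of the written paths.
#' @export
make_fixtures <- function(seed, dir, n_learners = 10, items_per_learner = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    memorize = scheduler_memorize(1),
    uniform = scheduler_uniform(0.2),
    threshold = scheduler_threshold(0.5, 2, 0.6)
  )
  paths <- character(0)
  for (nm in names(specs)) {
    cfg <- population_config(n_learners, items_per_learner, specs[nm],
                             tf = 30, seed = seed + match(nm, names(specs)))
    p <- file.path(dir, paste0(nm, ".csv"))
    write_review_log(simulate_population(cfg), p)
    paths[nm] <- p
  }
  mixed_cfg <- population_config(3 * n_learners, items_per_learner, specs,
                                 tf = 30, test_delay = 7, seed = seed)
  paths["mixed"] <- file.path(dir, "mixed.csv")
  write_review_log(simulate_population(mixed_cfg), paths["mixed"])
  items <- population_items(mixed_cfg)
  paths["params"] <- file.path(dir, "params.csv")
  write_params(list(alpha = mixed_cfg$alpha, beta = mixed_cfg$beta,
                    items = items), paths["params"])
  paths["config"] <- file.path(dir, "config.txt")
  write_default_config(paths["config"])
  paths
}
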