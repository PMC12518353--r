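fmt_num <- function(x) sprintf("%.17g", x)

serialize_draws <- function(d) {
  paste(sprintf("%d:%.17g", d$bin, d$value), collapse = ";")
}

parse_draws <- function(s, multiplier) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble::tibble(bin = integer(), value = numeric(),
                          raw = numeric()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bin <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  value <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  tibble::tibble(bin = bin, value = value, raw = value * multiplier)
}

#' Write and read trial tables
#'
#' The canonical on-disk layout is wide: one CSV row per trial, with the bin
#' counts as columns `n1..n5` and the draws serialized into a single
#' `draws` column of `bin:value` pairs (normalized values, full double
#' precision) separated by semicolons. `read_trials()` validates every row
#' (counts summing to the budget, draw count matching the budget, draw
#' values inside their bin's interval, estimates within \[0, multiplier\])
#' and reports offending row numbers. A long layout (one row per draw,
#' columns `participant_id, trial_index, condition, budget, multiplier,
#' bin, value, estimate_raw`) can be imported with `layout = "long"`.
#'
#' @param trials Trial tibble (as from [simulate_experiment()]).
#' @param path CSV file path.
#' @param layout `"wide"` (canonical) or `"long"`.
#' @return `read_trials()` returns the trial tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  nb <- length(bin_cols(trials))
  df <- data.frame(
    participant_id = trials$participant_id,
    trial_index = trials$trial_index,
    condition = trials$condition,
    budget = trials$budget,
    multiplier = fmt_num(trials$multiplier),
    trials[, paste0("n", seq_len(nb))],
    estimate_raw = fmt_num(trials$estimate_raw),
    draws = vapply(trials$draws, serialize_draws, character(1)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (layout == "long") return(read_trials_long(raw))
  nbc <- grep("^n[0-9]+$", names(raw), value = TRUE)
  required <- c("participant_id", "trial_index", "condition", "budget",
                "multiplier", "estimate_raw", "draws")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L || length(nbc) == 0L) {
    stop("missing columns: ",
         paste(c(missing_cols, if (length(nbc) == 0L) "n1..n5"),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(tibble::tibble(
      participant_id = integer(), trial_index = integer(),
      condition = character(), budget = integer(), multiplier = numeric(),
      !!!stats::setNames(rep(list(integer()), 5), paste0("n", 1:5)),
      estimate_raw = numeric(), draws = list()
    ))
  }
  trials <- tibble::tibble(
    participant_id = as.integer(raw$participant_id),
    trial_index = as.integer(raw$trial_index),
    condition = raw$condition,
    budget = as.integer(raw$budget),
    multiplier = as.numeric(raw$multiplier)
  )
  for (cc in nbc) trials[[cc]] <- as.integer(raw[[cc]])
  trials$estimate_raw <- as.numeric(raw$estimate_raw)
  trials$draws <- lapply(seq_len(nrow(raw)), function(i) {
    parse_draws(raw$draws[i], trials$multiplier[i])
  })
  validate_trials(trials)
  trials[, c("participant_id", "trial_index", "condition", "budget",
             "multiplier", nbc, "estimate_raw", "draws")]
}

read_trials_long <- function(raw) {
  required <- c("participant_id", "trial_index", "condition", "budget",
                "multiplier", "bin", "value", "estimate_raw")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(raw$participant_id, raw$trial_index, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    r1 <- raw[idx[1], ]
    bins <- as.integer(raw$bin[idx])
    vals <- as.numeric(raw$value[idx])
    counts <- tabulate(bins, nbins = 5L)
    out <- tibble::tibble(
      participant_id = as.integer(r1$participant_id),
      trial_index = as.integer(r1$trial_index),
      condition = r1$condition, budget = as.integer(r1$budget),
      multiplier = as.numeric(r1$multiplier)
    )
    for (k in 1:5) out[[paste0("n", k)]] <- counts[k]
    out$estimate_raw <- as.numeric(r1$estimate_raw)
    out$draws <- list(tibble::tibble(bin = bins, value = vals,
                                     raw = vals * out$multiplier))
    out
  })
  trials <- dplyr::bind_rows(rows)
  validate_trials(trials)
  trials
}

validate_trials <- function(trials) {
  nb <- length(bin_cols(trials))
  edges <- seq(0, 1, length.out = nb + 1L)
  problems <- character()
  cm <- counts_matrix(trials)
  bad_sum <- which(rowSums(cm) != trials$budget)
  if (length(bad_sum) > 0L) {
    problems <- c(problems, paste0("row ", bad_sum,
                                   ": counts do not sum to budget"))
  }
  for (i in seq_len(nrow(trials))) {
    d <- trials$draws[[i]]
    if (nrow(d) != trials$budget[i]) {
      problems <- c(problems, paste0("row ", i,
                                     ": number of draws != budget"))
      next
    }
    lo <- edges[d$bin]
    hi <- edges[d$bin + 1L]
    ok <- d$value >= lo - 1e-12 &
      (d$value < hi | (d$bin == nb & d$value <= 1 + 1e-12))
    if (!all(ok)) {
      problems <- c(problems, paste0("row ", i,
                                     ": draw value outside its bin"))
    }
  }
  bad_est <- which(trials$estimate_raw < -1e-9 |
                     trials$estimate_raw > trials$multiplier + 1e-9)
  if (length(bad_est) > 0L) {
    problems <- c(problems, paste0("row ", bad_est,
                                   ": estimate outside [0, multiplier]"))
  }
  if (length(problems) > 0L) {
    stop("invalid trial table:\n  ",
         paste(utils::head(problems, 10L), collapse = "\n  "),
         call. = FALSE)
  }
  invisible(trials)
}

#' Write a JSON run report
#'
#' Bundles arbitrary result sections with the master seed, a hash of the
#' configuration, package version, and timestamp, so any output artifact can
#' be traced to the run that produced it.
#'
#' @param sections Named list of result objects (coerced by jsonlite).
#' @param path Output JSON path.
#' @param seed Master seed of the run.
#' @param config Named list of configuration values (hashed into the
#'   report).
#' @return `path`, invisibly.
#' @export
run_report <- function(sections, path, seed, config = list()) {
  cfg_str <- paste(names(config), unlist(lapply(config, paste,
                                                collapse = ",")),
                   sep = "=", collapse = ";")
  report <- c(
    list(meta = list(
      package = "samplefence",
      version = as.character(utils::packageVersion("samplefence")),
      seed = seed,
      config = config,
      config_hash = sprintf("%08x", as.integer(
        if (nzchar(cfg_str)) {
          sum(utf8ToInt(cfg_str) * seq_along(utf8ToInt(cfg_str))) %% 2^31
        } else 0
      )),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )),
    sections
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
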