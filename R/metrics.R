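option_means <- function(trials, means = NULL) {
  if (!is.null(means)) return(means)
  exp_id <- unique(trials$experiment_id)
  exp_id <- exp_id[!is.na(exp_id)]
  if (length(exp_id) != 1)
    stop("trials span ", length(exp_id), " experiment ids; ",
         "pass `means` explicitly")
  d <- bandit_design(exp_id)
  setNames(d$options$mean_outcome, d$options$option_id)
}

#' Correct choice rate in the learning phase
#'
#' Proportion of free learning trials on which the subject chose the option
#' with the highest objective mean among the options selectable on that
#' trial (so trials where the highest-mean option is displayed but
#' unavailable are scored against the best available one). Forced trials
#' are excluded. Contexts with no eligible trials are reported as `NA`.
#'
#' @param trials trial records (any phases; only free learning trials count).
#' @param means named vector of objective mean outcomes per option; defaults
#'   to the built-in design named by the records' `experiment_id`.
#' @return data frame `context_id`, `n_trials`, `correct_rate`, with the
#'   overall rate in attribute `"overall"`.
#' @export
correct_choice_rate <- function(trials, means = NULL) {
  means <- option_means(trials, means)
  lt <- trials[trials$phase == "learning" & !trials$forced, , drop = FALSE]
  contexts <- sort(unique(trials$context_id[trials$phase == "learning"]))
  correct <- logical(nrow(lt))
  for (t in seq_len(nrow(lt))) {
    so <- schedule_options(lt[t, ])
    av <- so$ids[so$avail]
    best <- av[which.max(means[av])]
    correct[t] <- identical(lt$choice[t], best)
  }
  out <- do.call(rbind, lapply(contexts, function(cx) {
    idx <- lt$context_id == cx
    data.frame(context_id = cx, n_trials = sum(idx),
               correct_rate = if (any(idx)) mean(correct[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(out, "overall") <- if (nrow(lt)) mean(correct) else NA_real_
  out
}

#' Transfer-phase choice rate per option
#'
#' Number of times an option is chosen divided by the number of times it is
#' presented. Rates do not sum to 1 across options: every transfer trial
#' presents two options and counts toward both denominators. Options never
#' presented are omitted.
#'
#' @param trials trial records (only `phase == "transfer"` rows are used).
#' @return data frame `option_id`, `n_presented`, `n_chosen`, `choice_rate`.
#' @export
transfer_choice_rate <- function(trials) {
  tr <- trials[trials$phase == "transfer", , drop = FALSE]
  opts <- sort(unique(c(tr$option1, tr$option2)))
  shown <- vapply(opts, function(o)
    sum(tr$option1 == o) + sum(tr$option2 == o), 0)
  chosen <- vapply(opts, function(o) sum(tr$choice == o), 0)
  data.frame(option_id = opts, n_presented = unname(shown),
             n_chosen = unname(chosen),
             choice_rate = unname(chosen / shown), stringsAsFactors = FALSE)
}

#' Explicit-rating summary per option
#'
#' Mean reported value per option and its deviation from the option's
#' objective mean outcome.
#'
#' @inheritParams correct_choice_rate
#' @return data frame `option_id`, `n_ratings`, `mean_rating`,
#'   `objective_mean`, `deviation` (mean rating minus objective mean).
#' @export
explicit_summary <- function(trials, means = NULL) {
  means <- option_means(trials, means)
  ex <- trials[trials$phase == "explicit", , drop = FALSE]
  opts <- sort(unique(ex$option1))
  do.call(rbind, lapply(opts, function(o) {
    r <- ex$rating[ex$option1 == o]
    data.frame(option_id = o, n_ratings = length(r), mean_rating = mean(r),
               objective_mean = unname(means[o]),
               deviation = mean(r) - unname(means[o]),
               stringsAsFactors = FALSE)
  }))
}

#' Subject- and cohort-level behavioral summary
#'
#' The three readouts of learning: per-context correct choice rate in the
#' learning phase, per-option transfer choice rate, and per-option mean
#' explicit rating. Subject-level tables carry one row per subject x
#' context/option; cohort tables average the subject means.
#'
#' @inheritParams correct_choice_rate
#' @return a list of class `cohort_summary` with elements `learning`,
#'   `transfer`, `explicit` (subject level) and `learning_cohort`,
#'   `transfer_cohort`, `explicit_cohort` (subject means averaged).
#' @export
cohort_summary <- function(trials, means = NULL) {
  means <- option_means(trials, means)
  per_subject <- function(f) {
    do.call(rbind, lapply(split(trials, trials$subject_id), f))
  }
  learning <- per_subject(function(x) {
    r <- correct_choice_rate(x, means)
    cbind(subject_id = x$subject_id[1], r)
  })
  transfer <- per_subject(function(x)
    cbind(subject_id = x$subject_id[1], transfer_choice_rate(x)))
  explicit <- if (any(trials$phase == "explicit")) {
    per_subject(function(x)
      cbind(subject_id = x$subject_id[1], explicit_summary(x, means)))
  } else NULL
  rownames(learning) <- rownames(transfer) <- NULL
  agg <- function(df, key, val) {
    if (is.null(df)) return(NULL)
    out <- aggregate(df[[val]], list(df[[key]]), mean)
    names(out) <- c(key, val)
    out
  }
  structure(list(
    learning = learning, transfer = transfer, explicit = explicit,
    learning_cohort = agg(learning, "context_id", "correct_rate"),
    transfer_cohort = agg(transfer, "option_id", "choice_rate"),
    explicit_cohort = agg(explicit, "option_id", "mean_rating")),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n  learning correct rate by context:\n")
  print(x$learning_cohort, row.names = FALSE)
  cat("  transfer choice rate by option:\n")
  print(x$transfer_cohort, row.names = FALSE)
  if (!is.null(x$explicit_cohort)) {
    cat("  mean explicit rating by option:\n")
    print(x$explicit_cohort, row.names = FALSE)
  }
  invisible(x)
}

trial_schema <- c(
  subject_id = "character", experiment_id = "character",
  phase = "character", trial_index = "integer", context_id = "character",
  option1 = "character", option2 = "character", option3 = "character",
  available1 = "logical", available2 = "logical", available3 = "logical",
  forced = "logical", choice = "character", outcome1 = "numeric",
  outcome2 = "numeric", outcome3 = "numeric", rating = "numeric")

#' Read and write trial-record CSV files
#'
#' The on-disk format is a UTF-8 comma-separated file with one header row
#' and one row per trial; empty fields encode missing values. `read_trials()`
#' validates the schema and basic semantic rules (known phase labels,
#' ratings within 0-100, free learning trials with a recorded choice among
#' the presented options) and reports offending file lines.
#'
#' @param path CSV file path.
#' @param records a trial-record data frame (as produced by
#'   [simulate_agent()] / [simulate_cohort()]).
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, colClasses = unname(trial_schema),
                 na.strings = "", stringsAsFactors = FALSE)
  missing <- setdiff(names(trial_schema), names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df <- df[names(trial_schema)]
  line <- function(i) i + 1L  # header occupies line 1
  bad <- which(!df$phase %in% c("learning", "transfer", "explicit"))
  if (length(bad))
    stop("unknown phase label at line(s) ",
         paste(line(head(bad, 5)), collapse = ", "))
  bad <- which(df$phase == "explicit" &
                 (is.na(df$rating) | df$rating < 0 | df$rating > 100))
  if (length(bad))
    stop("explicit rating missing or outside [0,100] at line(s) ",
         paste(line(head(bad, 5)), collapse = ", "))
  bad <- which(df$phase != "explicit" & !is.na(df$rating))
  if (length(bad))
    stop("rating on a non-explicit row at line(s) ",
         paste(line(head(bad, 5)), collapse = ", "))
  bad <- which(df$phase == "learning" & !df$forced & is.na(df$choice))
  if (length(bad))
    stop("free learning trial without a choice at line(s) ",
         paste(line(head(bad, 5)), collapse = ", "))
  opts <- cbind(df$option1, df$option2, df$option3)
  has_choice <- !is.na(df$choice)
  ok <- rowSums(opts == df$choice, na.rm = TRUE) > 0
  bad <- which(has_choice & !ok)
  if (length(bad))
    stop("choice not among presented options at line(s) ",
         paste(line(head(bad, 5)), collapse = ", "))
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(records, path) {
  write.csv(records[names(trial_schema)], path, row.names = FALSE, na = "")
  invisible(path)
}
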