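#' Factorial bandit task designs
#'
#' Constructs one of the eight built-in experimental designs. Each design has
#' four learning contexts (fixed pairs or triplets of options) crossing
#' outcome-range amplitude (narrow vs wide) with either set size (binary vs
#' trinary, Experiments 1-2) or availability of the highest-value option
#' (Experiment 3). Option mean outcomes are drawn from \{14, 32, 50, 68, 86\}
#' points and realized outcomes are sampled around them with variance 4.
#'
#' Designs:
#' \describe{
#'   \item{1a/1b/1c}{contexts NB \[14,50\], NT \[14,32,50\], WB \[14,86\],
#'     WT \[14,50,86\]; versions b/c add 5 forced-choice trials per option
#'     with complete (b) or partial (c) feedback.}
#'   \item{2a/2b/2c}{contexts NB \[50,86\], NT \[50,68,86\], WB \[14,86\],
#'     WT \[14,50,86\]; forced trials as above.}
#'   \item{3a/3b}{four trinary contexts crossing range (narrow \[14,32,50\]
#'     vs wide \[14,50,86\]) with availability: in the NB/WB contexts the
#'     highest-mean option is displayed but not selectable on 50\% (3a) or
#'     75\% (3b) of trials.}
#' }
#'
#' @param experiment_id one of `"1a","1b","1c","2a","2b","2c","3a","3b"`.
#' @return an object of class `bandit_design`: a list with elements
#'   `experiment_id`, `contexts` (each with `context_id`, `label`, `means`,
#'   `option_ids`, `outcome_sd`, `n_repetitions`, `unavailable_fraction`),
#'   `forced_per_option`, `forced_feedback`, `transfer_reps_per_pair`,
#'   `explicit_reps_per_cue`, and an `options` lookup table.
#' @seealso [learning_schedule()], [transfer_schedule()], [explicit_schedule()]
#' @examples
#' d <- bandit_design("1a")
#' vapply(d$contexts, function(ct) length(ct$means), integer(1))
#' @export
bandit_design <- function(experiment_id) {
  ids <- c("1a", "1b", "1c", "2a", "2b", "2c", "3a", "3b")
  if (length(experiment_id) != 1L || !experiment_id %in% ids) {
    stop("unknown experiment_id ", deparse(experiment_id),
         "; valid identifiers: ", paste(ids, collapse = ", "))
  }
  exp_num <- substr(experiment_id, 1, 1)
  version <- substr(experiment_id, 2, 2)

  narrow <- switch(exp_num, "1" = c(14, 32, 50), "2" = c(50, 68, 86),
                   "3" = c(14, 32, 50))
  wide <- c(14, 50, 86)

  if (exp_num %in% c("1", "2")) {
    ctx <- list(
      list(label = "NB", means = narrow[c(1, 3)]),
      list(label = "NT", means = narrow),
      list(label = "WB", means = wide[c(1, 3)]),
      list(label = "WT", means = wide)
    )
    ctx <- lapply(ctx, function(x) { x$unavailable_fraction <- 0; x })
    forced_per_option <- if (version == "a") 0L else 5L
    forced_feedback <- switch(version, a = "none", b = "complete",
                              c = "partial")
    transfer_reps <- 4L
    explicit_reps <- 4L
  } else {
    frac <- if (version == "a") 0.5 else 0.75
    ctx <- list(
      list(label = "NB", means = narrow, unavailable_fraction = frac),
      list(label = "NT", means = narrow, unavailable_fraction = 0),
      list(label = "WB", means = wide, unavailable_fraction = frac),
      list(label = "WT", means = wide, unavailable_fraction = 0)
    )
    forced_per_option <- 0L
    forced_feedback <- "none"
    transfer_reps <- 2L
    explicit_reps <- 2L
  }

  contexts <- lapply(ctx, function(x) {
    list(context_id = x$label, label = x$label, means = x$means,
         option_ids = paste0(x$label, x$means), outcome_sd = 2,
         n_repetitions = 45L, unavailable_fraction = x$unavailable_fraction)
  })
  names(contexts) <- vapply(contexts, `[[`, "", "context_id")
  new_bandit_design(experiment_id, contexts, forced_per_option,
                    forced_feedback, transfer_reps, explicit_reps)
}

new_bandit_design <- function(experiment_id, contexts, forced_per_option,
                              forced_feedback, transfer_reps_per_pair,
                              explicit_reps_per_cue) {
  opts <- do.call(rbind, lapply(contexts, function(ct) {
    stopifnot(length(ct$means) >= 2, length(ct$means) <= 3,
              !anyDuplicated(ct$means))
    data.frame(option_id = ct$option_ids, context_id = ct$context_id,
               mean_outcome = ct$means, stringsAsFactors = FALSE)
  }))
  rownames(opts) <- NULL
  if (anyDuplicated(opts$option_id))
    stop("option ids must be unique within an experiment")
  structure(
    list(experiment_id = experiment_id, contexts = contexts,
         forced_per_option = as.integer(forced_per_option),
         forced_feedback = forced_feedback,
         transfer_reps_per_pair = as.integer(transfer_reps_per_pair),
         explicit_reps_per_cue = as.integer(explicit_reps_per_cue),
         options = opts),
    class = "bandit_design")
}

#' @export
print.bandit_design <- function(x, ...) {
  cat("Bandit task design", x$experiment_id, "\n")
  for (ct in x$contexts) {
    cat(sprintf("  %s: [%s] x %d reps", ct$label,
                paste(ct$means, collapse = ","), ct$n_repetitions))
    if (ct$unavailable_fraction > 0)
      cat(sprintf(" (high option unavailable on %.0f%% of trials)",
                  100 * ct$unavailable_fraction))
    cat("\n")
  }
  cat(sprintf("  forced trials: %d per option (%s feedback)\n",
              x$forced_per_option, x$forced_feedback))
  cat(sprintf("  transfer: %d reps per pair; explicit: %d reps per cue\n",
              x$transfer_reps_per_pair, x$explicit_reps_per_cue))
  invisible(x)
}

empty_schedule <- function(n) {
  data.frame(phase = character(n), trial = integer(n),
             context_id = NA_character_, option1 = NA_character_,
             option2 = NA_character_, option3 = NA_character_,
             available1 = NA, available2 = NA, available3 = NA,
             forced_option = NA_character_, feedback = NA_character_,
             stringsAsFactors = FALSE)
}

context_rows <- function(ct, available_high, forced_option, feedback) {
  row <- empty_schedule(1L)
  row$phase <- "learning"
  row$context_id <- ct$context_id
  k <- length(ct$option_ids)
  row[1, paste0("option", seq_len(k))] <- ct$option_ids
  avail <- rep(TRUE, k)
  if (!available_high) avail[which.max(ct$means)] <- FALSE
  if (!is.na(forced_option)) avail <- ct$option_ids == forced_option
  row[1, paste0("available", seq_len(k))] <- avail
  row$forced_option <- forced_option
  row$feedback <- feedback
  row
}

#' Generate a learning-phase trial schedule
#'
#' Expands a design into an ordered learning-phase schedule: 45 free trials
#' per context, plus (versions b/c) 5 forced-choice trials per option, all
#' shuffled deterministically by `seed`. For Experiment 3 designs, the stated
#' fraction of each affected context's free trials marks the highest-mean
#' option as displayed-but-unavailable; 50% of 45 is realized as 22/23 trials
#' (which affected context receives 23 alternates with the seed), 75% as 34.
#'
#' @param design a [bandit_design()].
#' @param seed integer seed controlling the shuffle.
#' @return a data frame with one row per trial: `phase`, `trial`,
#'   `context_id`, `option1..3`, `available1..3`, `forced_option`, `feedback`.
#' @examples
#' nrow(learning_schedule(bandit_design("1a"), seed = 1))  # 180
#' nrow(learning_schedule(bandit_design("1b"), seed = 1))  # 230
#' @export
learning_schedule <- function(design, seed) {
  stopifnot(inherits(design, "bandit_design"))
  affected <- which(vapply(design$contexts, function(ct)
    ct$unavailable_fraction > 0, logical(1)))
  rows <- list()
  a_idx <- 0L
  for (ct in design$contexts) {
    n <- ct$n_repetitions
    n_unavail <- 0L
    if (ct$unavailable_fraction > 0) {
      a_idx <- a_idx + 1L
      target <- ct$unavailable_fraction * n
      if (target == floor(target)) {
        n_unavail <- as.integer(target)
      } else if (ct$unavailable_fraction == 0.5) {
        # split 22/23 across the two affected contexts, alternating by seed
        n_unavail <- if ((seed + a_idx) %% 2 == 0) ceiling(target)
                     else floor(target)
      } else {
        n_unavail <- as.integer(round(target))
      }
    }
    free <- c(rep(FALSE, n_unavail), rep(TRUE, n - n_unavail))
    for (av in free)
      rows[[length(rows) + 1L]] <-
        context_rows(ct, av, NA_character_, "complete")
    if (design$forced_per_option > 0) {
      for (opt in ct$option_ids)
        for (i in seq_len(design$forced_per_option))
          rows[[length(rows) + 1L]] <-
            context_rows(ct, TRUE, opt, design$forced_feedback)
    }
  }
  out <- do.call(rbind, rows)
  out <- with_seed(seed, out[sample(nrow(out)), ])
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enumerate all unordered transfer-phase cue pairs
#'
#' @param cue_ids character vector of at least two distinct cue identifiers.
#' @return a two-column character matrix, one row per unordered pair, in
#'   lexicographic canonical order; 10 cues give 45 pairs, 12 give 66.
#' @examples
#' nrow(transfer_pairs(letters[1:10]))  # 45
#' @export
transfer_pairs <- function(cue_ids) {
  if (anyDuplicated(cue_ids))
    stop("duplicate cue ids: ",
         paste(unique(cue_ids[duplicated(cue_ids)]), collapse = ", "))
  if (length(cue_ids) < 2) stop("need at least two cues")
  t(combn(sort(cue_ids), 2L))
}

#' Generate a transfer-phase trial schedule
#'
#' Every unordered pair of cues appears exactly `transfer_reps_per_pair`
#' times (4 in Experiments 1-2, 2 in Experiment 3), shuffled by `seed`;
#' no outcome feedback is delivered.
#'
#' @inheritParams learning_schedule
#' @return a trial-schedule data frame (`phase == "transfer"`).
#' @examples
#' nrow(transfer_schedule(bandit_design("1a"), seed = 1))  # 180
#' nrow(transfer_schedule(bandit_design("3a"), seed = 1))  # 132
#' @export
transfer_schedule <- function(design, seed) {
  stopifnot(inherits(design, "bandit_design"))
  pairs <- transfer_pairs(design$options$option_id)
  idx <- rep(seq_len(nrow(pairs)), times = design$transfer_reps_per_pair)
  out <- empty_schedule(length(idx))
  out$phase <- "transfer"
  out$option1 <- pairs[idx, 1]
  out$option2 <- pairs[idx, 2]
  out$available1 <- TRUE
  out$available2 <- TRUE
  out$feedback <- "none"
  out <- with_seed(seed, out[sample(nrow(out)), ])
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Generate an explicit-rating phase schedule
#'
#' Each cue is presented alone `explicit_reps_per_cue` times (4 in
#' Experiments 1-2, 2 in Experiment 3) for a 0-100 value rating.
#'
#' @inheritParams learning_schedule
#' @return a trial-schedule data frame (`phase == "explicit"`).
#' @examples
#' nrow(explicit_schedule(bandit_design("1a"), seed = 1))  # 40
#' @export
explicit_schedule <- function(design, seed) {
  stopifnot(inherits(design, "bandit_design"))
  cues <- rep(design$options$option_id, times = design$explicit_reps_per_cue)
  out <- empty_schedule(length(cues))
  out$phase <- "explicit"
  out$option1 <- cues
  out$available1 <- TRUE
  out$feedback <- "none"
  out <- with_seed(seed, out[sample(nrow(out)), ])
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Sample realized outcomes for an option
#'
#' Outcomes are drawn from a normal distribution around the option's mean
#' (variance 4 in the built-in designs), rounded to the nearest integer
#' point and clipped to the 0-100 payoff scale shown to participants.
#'
#' @param mean_outcome mean outcome in points.
#' @param sd outcome standard deviation in points (default 2).
#' @param n number of draws.
#' @return integer-valued outcomes in \[0, 100\].
#' @examples
#' sample_outcome(50, sd = 0)  # exactly 50
#' @export
sample_outcome <- function(mean_outcome, sd = 2, n = 1L) {
  stopifnot(sd >= 0)
  pmin(pmax(round(rnorm(n, mean_outcome, sd)), 0), 100)
}

#' Read or write a design as a plain-text config file
#'
#' Designs serialize to YAML so that new factorial designs can be registered
#' without code changes.
#'
#' @param design a [bandit_design()].
#' @param path file path.
#' @return `read_design()` returns a `bandit_design`; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "bandit_design"))
  x <- unclass(design)
  x$options <- NULL
  x$contexts <- unname(x$contexts)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  contexts <- lapply(x$contexts, function(ct) {
    list(context_id = ct$context_id, label = ct$label,
         means = as.numeric(ct$means),
         option_ids = as.character(ct$option_ids),
         outcome_sd = as.numeric(ct$outcome_sd),
         n_repetitions = as.integer(ct$n_repetitions),
         unavailable_fraction = as.numeric(ct$unavailable_fraction))
  })
  names(contexts) <- vapply(contexts, `[[`, "", "context_id")
  new_bandit_design(x$experiment_id, contexts, x$forced_per_option,
                    x$forced_feedback, x$transfer_reps_per_pair,
                    x$explicit_reps_per_cue)
}
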