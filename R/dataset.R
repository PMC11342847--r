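# Choice datasets: per-subject trial tables, CSV round-trips, and synthetic
# cohorts of simulated agents with a planted trait-parameter link.

CHOICE_COLUMNS <- c("subject_id", "block_type", "trial", "choice",
                    "outcome_a", "outcome_b", "points")

#' Validate a choice dataset
#'
#' Checks the trial-table schema: required columns, block types, integer card
#' outcomes in 1..13, choices in {a, b}, and the points identity (chosen minus
#' unchosen outcome). Violations are reported with the offending row numbers.
#'
#' @param data Data frame of trial records.
#' @return The data invisibly (or an error).
#' @export
validate_choice_data <- function(data) {
  missing <- setdiff(CHOICE_COLUMNS, names(data))
  if (length(missing)) {
    stop("choice data is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) return(invisible(data))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("choice data: %s (first at row %d)", what, i[1]), call. = FALSE)
    }
  }
  bad_row(!data$block_type %in% BLOCK_TYPES, "unknown block_type")
  for (col in c("outcome_a", "outcome_b")) {
    v <- data[[col]]
    bad_row(!is.finite(v) | v != as.integer(v) | v < 1 | v > 13,
            sprintf("%s must be an integer card value in 1..13", col))
  }
  bad_row(!data$choice %in% c("a", "b"), "choice must be 'a' or 'b'")
  bad_row(!is.finite(data$trial) | data$trial < 1, "trial must be a positive index")
  expected <- ifelse(data$choice == "a",
                     data$outcome_a - data$outcome_b,
                     data$outcome_b - data$outcome_a)
  bad_row(data$points != expected, "points must equal chosen minus unchosen outcome")
  invisible(data)
}

#' Read / write choice data CSV
#'
#' Plain CSV with header columns `subject_id, block_type, trial, choice,
#' outcome_a, outcome_b, points` (outcomes on the 1..13 card scale). Reading
#' validates the schema; an empty file with a header yields an empty dataset.
#'
#' @param path File path.
#' @return `read_choice_data`: validated data frame of trial records.
#' @export
read_choice_data <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character",
                                         block_type = "character",
                                         choice = "character"))
  validate_choice_data(data)
  data
}

#' @rdname read_choice_data
#' @param data Data frame of trial records.
#' @export
write_choice_data <- function(data, path) {
  validate_choice_data(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a trait table CSV
#'
#' Columns `subject_id, trait_score` (a single numeric sum-score per subject).
#'
#' @param path File path.
#' @export
read_trait_table <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  missing <- setdiff(c("subject_id", "trait_score"), names(data))
  if (length(missing)) {
    stop("trait table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data
}

#' @rdname read_trait_table
#' @param data Data frame with `subject_id` and `trait_score`.
#' @export
write_trait_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_param_sampler <- function(model) {
  switch(model,
    rw1   = function(n) data.frame(alpha = stats::runif(n, 0.1, 0.9),
                                   beta = stats::runif(n, 2, 10)),
    rw2   = function(n) data.frame(alpha_pos = stats::runif(n, 0.1, 0.9),
                                   alpha_neg = stats::runif(n, 0.1, 0.9),
                                   beta = stats::runif(n, 2, 10)),
    peirs = function(n) data.frame(alpha_q = stats::runif(n, 0.1, 0.9),
                                   alpha_s = stats::runif(n, 0.1, 0.9),
                                   omega = stats::runif(n, -5, 5),
                                   s0 = stats::runif(n, 0.05, 0.5),
                                   beta = stats::runif(n, 2, 10)),
    cvar  = function(n) data.frame(eta = stats::runif(n, -0.8, 0.8),
                                   beta = stats::runif(n, 2, 10))
  )
}

#' Cohort specification
#'
#' Describes a synthetic cohort: how many agents, which generating model, how
#' generating parameters are sampled, and how the trait score is linked to the
#' risk parameter eta. For Bayesian-CVaR cohorts the trait is
#' `intercept + slope * eta + N(0, noise_sd)` (negative slope by default,
#' emulating an empirical negative link between rumination-like traits and
#' risk seeking); for other models the trait is an uncorrelated control,
#' `intercept + N(0, noise_sd)`.
#'
#' @param n_agents Number of simulated subjects (>= 1).
#' @param model Generating model (`"rw1"`, `"rw2"`, `"peirs"`, `"cvar"`).
#' @param param_sampler Optional function `n -> data.frame` of generating
#'   parameters (one row per agent); defaults per model.
#' @param trait_link List with `slope`, `intercept`, `noise_sd` (>= 0).
#' @param seed Optional integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_agents, model, param_sampler = NULL,
                        trait_link = list(slope = -30, intercept = 40, noise_sd = 5),
                        seed = NULL) {
  check_model(model)
  if (!is.numeric(n_agents) || n_agents < 0) stop("n_agents must be >= 0", call. = FALSE)
  if (trait_link$noise_sd < 0) stop("trait noise_sd must be >= 0", call. = FALSE)
  structure(list(n_agents = as.integer(n_agents), model = model,
                 param_sampler = param_sampler %||% default_param_sampler(model),
                 trait_link = trait_link, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Each agent plays one block of each of the eight block types (30 trials per
#' block by default) under its generating parameters, via [simulate_block()].
#' Per-agent RNG streams are derived deterministically from the cohort seed,
#' so generation is bit-reproducible.
#'
#' @param cohort A [cohort_spec()].
#' @param config A [task_config()].
#' @param n_grid,updatevar Belief-grid resolution and evidence variance for
#'   `"cvar"` agents.
#' @return List with `choices` (trial table, 8 blocks x n_trials rows per
#'   agent), `traits` (`subject_id`, `trait_score`) and `params` (generating
#'   parameters per agent, for recovery studies).
#' @export
generate_cohort <- function(cohort, config = task_config(),
                            n_grid = 481, updatevar = 0.009) {
  stopifnot(inherits(cohort, "cohort_spec"))
  run <- function() {
    n <- cohort$n_agents
    ids <- sprintf("S%03d", seq_len(n))
    params <- cohort$param_sampler(n)
    if (n > 0 && nrow(params) != n) {
      stop("param_sampler must return one row per agent", call. = FALSE)
    }
    link <- cohort$trait_link
    trait <- if (cohort$model == "cvar" && n > 0) {
      link$intercept + link$slope * params$eta + stats::rnorm(n, 0, link$noise_sd)
    } else if (n > 0) {
      link$intercept + stats::rnorm(n, 0, link$noise_sd)
    } else {
      numeric(0)
    }
    specs <- lapply(BLOCK_TYPES, make_block_spec, config = config)
    agent_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0)
    choices <- vector("list", n)
    for (i in seq_len(n)) {
      p <- as.list(params[i, , drop = FALSE])
      blocks <- withr::with_seed(agent_seeds[i], lapply(specs, function(spec) {
        sim <- simulate_block(cohort$model, p, spec,
                              n_grid = n_grid, updatevar = updatevar)
        data.frame(subject_id = ids[i], block_type = spec$block_type,
                   trial = seq_len(spec$n_trials), choice = sim$choice,
                   outcome_a = sim$outcome_a, outcome_b = sim$outcome_b,
                   points = sim$points)
      }))
      choices[[i]] <- do.call(rbind, blocks)
    }
    choices <- if (n > 0) do.call(rbind, choices) else
      stats::setNames(data.frame(matrix(nrow = 0, ncol = length(CHOICE_COLUMNS))),
                      CHOICE_COLUMNS)
    rownames(choices) <- NULL
    list(choices = choices,
         traits = data.frame(subject_id = ids, trait_score = trait),
         params = cbind(data.frame(subject_id = ids), params))
  }
  if (is.null(cohort$seed)) run() else withr::with_seed(cohort$seed, run())
}
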