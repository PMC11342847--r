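# Card support is the thirteen poker ranks (ace = 1 .. king = 13); the global
# mean across decks is 7, the midpoint of the support.
CARD_VALUES <- 1:13

BLOCK_TYPES <- c("BHBL", "NHNL", "BHNL", "NHBL",
                 "BHNH", "BLNL", "BiHNH", "BiLNL")
SAME_MEAN_BLOCKS <- c("BHNH", "BLNL", "BiHNH", "BiLNL")
DIFF_MEAN_BLOCKS <- c("BHBL", "NHNL", "BHNL", "NHBL")

# deck kind used on the a / b side of each block type; "a" is the higher-mean
# deck, or the broader deck when means are equal
BLOCK_DECKS <- list(
  BHBL  = c(a = "BH",  b = "BL"),
  NHNL  = c(a = "NH",  b = "NL"),
  BHNL  = c(a = "BH",  b = "NL"),
  NHBL  = c(a = "NH",  b = "BL"),
  BHNH  = c(a = "BH",  b = "NH"),
  BLNL  = c(a = "BL",  b = "NL"),
  BiHNH = c(a = "BiH", b = "NH"),
  BiLNL = c(a = "BiL", b = "NL")
)

#' Rescale card values to the unit interval
#'
#' Maps the card scale 1..13 linearly onto \[0.01, 0.99\], the outcome scale on
#' which all learning models operate. The global card mean 7 maps to 0.5, the
#' initial expected value of every model.
#'
#' @param v Numeric vector of card values in \[1, 13\].
#' @return Numeric vector on \[0.01, 0.99\].
#' @seealso [unrescale_card()] for the inverse map.
#' @examples
#' rescale_card(c(1, 7, 13))
#' @export
rescale_card <- function(v) {
  if (!is.numeric(v) || anyNA(v) || any(v < 1 | v > 13)) {
    stop("card values must be numeric in [1, 13]", call. = FALSE)
  }
  0.01 + (v - 1) * (0.98 / 12)
}

#' @rdname rescale_card
#' @param r Numeric vector of rescaled values in \[0.01, 0.99\].
#' @export
unrescale_card <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0.01 - 1e-12 | r > 0.99 + 1e-12)) {
    stop("rescaled values must be numeric in [0.01, 0.99]", call. = FALSE)
  }
  1 + (r - 0.01) * (12 / 0.98)
}

pmf_mean <- function(p) sum(CARD_VALUES * p)
pmf_var  <- function(p) sum(CARD_VALUES^2 * p) - pmf_mean(p)^2

# discretized Gaussian on 1..13 whose *renormalized* mean equals `mean`
# exactly; the location parameter is solved because truncation at the support
# edges shifts the naive mean
discretized_gaussian_pmf <- function(mean, sd) {
  raw <- function(mu) {
    p <- stats::dnorm(CARD_VALUES, mu, sd)
    p / sum(p)
  }
  f <- function(mu) pmf_mean(raw(mu)) - mean
  mu <- stats::uniroot(f, c(mean - 3 * sd, mean + 3 * sd),
                       tol = .Machine$double.eps^0.75)$root
  raw(mu)
}

# two-component mixture with modes near `modes`; the component weight is the
# exact solution of w * m1 + (1 - w) * m2 = mean
bimodal_pmf <- function(mean, modes = c(3, 12), sd = 1.2) {
  p1 <- stats::dnorm(CARD_VALUES, modes[1], sd); p1 <- p1 / sum(p1)
  p2 <- stats::dnorm(CARD_VALUES, modes[2], sd); p2 <- p2 / sum(p2)
  m1 <- pmf_mean(p1); m2 <- pmf_mean(p2)
  w <- (m2 - mean) / (m2 - m1)
  if (w <= 0 || w >= 1) stop("bimodal target mean outside component means", call. = FALSE)
  w * p1 + (1 - w) * p2
}

#' Default deck distributions
#'
#' Returns the six default deck pmfs over card values 1..13: narrow-high (NH),
#' narrow-low (NL), broad-high (BH), broad-low (BL), bimodal-high (BiH) and
#' bimodal-low (BiL). High decks have mean exactly 8, low decks mean exactly 6.
#' Narrow decks are discretized Gaussians with sd about 1, broad decks sd about
#' 2.5, and bimodal decks are two-component mixtures with modes near 3 and 12
#' whose variance exceeds the broad decks'.
#'
#' @return Named list of six pmfs (numeric vectors of length 13 summing to 1).
#' @export
default_decks <- function() {
  list(
    NH  = discretized_gaussian_pmf(8, 1.0),
    NL  = discretized_gaussian_pmf(6, 1.0),
    BH  = discretized_gaussian_pmf(8, 2.5),
    BL  = discretized_gaussian_pmf(6, 2.5),
    BiH = bimodal_pmf(8),
    BiL = bimodal_pmf(6)
  )
}

deck_target_mean <- function(kind) {
  if (grepl("H$", kind)) 8 else 6
}

n_local_modes <- function(p) {
  n <- length(p)
  sum(vapply(seq_len(n), function(i) {
    left  <- if (i == 1) -Inf else p[i - 1]
    right <- if (i == n) -Inf else p[i + 1]
    p[i] > left && p[i] > right
  }, logical(1)))
}

validate_pmf <- function(p, kind) {
  if (length(p) != 13 || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop(sprintf("deck '%s': pmf must be length 13, nonnegative, sum to 1", kind),
         call. = FALSE)
  }
  if (abs(pmf_mean(p) - deck_target_mean(kind)) > 1e-9) {
    stop(sprintf("deck '%s': mean must be %d (got %.12f)", kind,
                 deck_target_mean(kind), pmf_mean(p)), call. = FALSE)
  }
  if (grepl("^Bi", kind) && n_local_modes(p) < 2) {
    stop(sprintf("deck '%s': bimodal pmf must have two local modes", kind),
         call. = FALSE)
  }
  invisible(p)
}

#' Task configuration
#'
#' Bundles the number of trials per block and the deck pmfs. Individual decks
#' can be overridden, subject to the mean constraints (high decks mean 8, low
#' decks mean 6) which are enforced.
#'
#' @param n_trials Trials per block (default 30).
#' @param decks Named list of pmf overrides for any of NH, NL, BH, BL, BiH, BiL.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_trials = 30, decks = list()) {
  if (!is.numeric(n_trials) || n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  d <- default_decks()
  unknown <- setdiff(names(decks), names(d))
  if (length(unknown)) stop("unknown deck kind(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  d[names(decks)] <- decks
  for (k in names(d)) validate_pmf(d[[k]], k)
  structure(list(n_trials = as.integer(n_trials), decks = d), class = "task_config")
}

#' Construct a block specification
#'
#' A block pairs two decks for `n_trials` trials of simultaneous (full)
#' feedback. Deck "a" is the higher-mean deck, or the broader deck when the
#' means are equal.
#'
#' @param block_type One of `"BHBL"`, `"NHNL"`, `"BHNL"`, `"NHBL"`, `"BHNH"`,
#'   `"BLNL"`, `"BiHNH"`, `"BiLNL"`.
#' @param config A [task_config()]; defaults to the standard configuration.
#' @return A list of class `block_spec` with elements `block_type`, `deck_a`,
#'   `deck_b`, `n_trials`.
#' @examples
#' spec <- make_block_spec("BHNH")
#' sum(spec$deck_a)  # pmfs are normalized
#' @export
make_block_spec <- function(block_type, config = task_config()) {
  if (!block_type %in% BLOCK_TYPES) {
    stop("unknown block type '", block_type, "'; expected one of ",
         paste(BLOCK_TYPES, collapse = ", "), call. = FALSE)
  }
  kinds <- BLOCK_DECKS[[block_type]]
  pa <- config$decks[[kinds["a"]]]
  pb <- config$decks[[kinds["b"]]]
  if (block_type %in% SAME_MEAN_BLOCKS) {
    if (abs(pmf_mean(pa) - pmf_mean(pb)) > 1e-9) {
      stop("same-mean block '", block_type, "': deck means differ", call. = FALSE)
    }
    if (pmf_var(pa) <= pmf_var(pb)) {
      stop("same-mean block '", block_type, "': deck a must be broader than deck b",
           call. = FALSE)
    }
  } else {
    if (pmf_mean(pa) <= pmf_mean(pb)) {
      stop("different-mean block '", block_type, "': deck a must have higher mean",
           call. = FALSE)
    }
  }
  structure(list(block_type = block_type, deck_a = pa, deck_b = pb,
                 n_trials = config$n_trials),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("<block_spec %s: %d trials>\n", x$block_type, x$n_trials))
  cat(sprintf("  deck a: mean %.3f  var %.3f\n", pmf_mean(x$deck_a), pmf_var(x$deck_a)))
  cat(sprintf("  deck b: mean %.3f  var %.3f\n", pmf_mean(x$deck_b), pmf_var(x$deck_b)))
  invisible(x)
}

#' Draw paired outcome sequences for a block
#'
#' Draws `spec$n_trials` i.i.d. card values from each deck's pmf. Both decks
#' are revealed every trial (full feedback), so the streams are independent of
#' any agent's choices.
#'
#' @param spec A [make_block_spec()] result.
#' @param seed Optional integer seed; the draw is reproducible given the seed
#'   and leaves the global RNG state untouched.
#' @return List with integer vectors `outcome_a` and `outcome_b` (card scale).
#' @export
sample_trial_outcomes <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  draw <- function() {
    list(
      outcome_a = sample(CARD_VALUES, spec$n_trials, replace = TRUE, prob = spec$deck_a),
      outcome_b = sample(CARD_VALUES, spec$n_trials, replace = TRUE, prob = spec$deck_b)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
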