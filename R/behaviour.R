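# Model-free analysis stage: per-block choice rates, pro-variance bias,
# exclusion rules, and trait correlations.

#' Per-block choice rates
#'
#' Percentage of trials on which option a (the higher-mean option in
#' different-mean blocks, the broader option in same-mean blocks) was chosen,
#' for each subject and block.
#'
#' @param data Trial table (validated against the choice schema).
#' @return Data frame with `subject_id`, `block_type`, `pct_a`, `n_trials`.
#' @export
block_choice_rates <- function(data) {
  validate_choice_data(data)
  if (nrow(data) == 0) {
    return(data.frame(subject_id = character(0), block_type = character(0),
                      pct_a = numeric(0), n_trials = integer(0)))
  }
  agg <- stats::aggregate(choice ~ subject_id + block_type, data = data,
                          FUN = function(ch) c(pct = 100 * mean(ch == "a"),
                                               n = length(ch)))
  out <- data.frame(subject_id = agg$subject_id, block_type = agg$block_type,
                    pct_a = agg$choice[, "pct"],
                    n_trials = as.integer(agg$choice[, "n"]))
  out[order(out$subject_id, match(out$block_type, BLOCK_TYPES)), ]
}

#' Pro-variance bias from same-mean block rates
#'
#' The unweighted mean of the broader-option choice rates in the four
#' same-mean blocks (BHNH, BLNL, BiHNH, BiLNL), plus the unimodal-only
#' (BHNH, BLNL) and bimodal-only (BiHNH, BiLNL) sub-means.
#'
#' @param rates Numeric vector of the four same-mean block rates in percent;
#'   either named by block type or in the order BHNH, BLNL, BiHNH, BiLNL.
#' @return Named numeric `c(overall =, unimodal =, bimodal =)`.
#' @export
provariance_bias <- function(rates) {
  if (length(rates) != 4 || anyNA(rates)) {
    stop("need the four same-mean block rates (BHNH, BLNL, BiHNH, BiLNL)",
         call. = FALSE)
  }
  if (!is.null(names(rates))) {
    missing <- setdiff(SAME_MEAN_BLOCKS, names(rates))
    if (length(missing)) stop("missing same-mean block rate(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    rates <- rates[SAME_MEAN_BLOCKS]
  }
  c(overall = mean(rates),
    unimodal = mean(rates[1:2]),
    bimodal = mean(rates[3:4]))
}

#' Per-subject behavioural summaries
#'
#' One row per subject: the eight per-block choice rates (columns
#' `pct_<block>`), the mean accuracy across the four different-mean blocks,
#' the pro-variance bias (mean of the four same-mean block rates) with its
#' unimodal and bimodal sub-means, and a completeness flag (all eight blocks
#' present).
#'
#' @param data Trial table covering one or more subjects.
#' @return Data frame of subject summaries.
#' @export
subject_summaries <- function(data) {
  rates <- block_choice_rates(data)
  ids <- unique(rates$subject_id)
  rows <- lapply(ids, function(id) {
    r <- rates[rates$subject_id == id, ]
    v <- stats::setNames(rep(NA_real_, length(BLOCK_TYPES)), BLOCK_TYPES)
    v[r$block_type] <- r$pct_a
    row <- data.frame(subject_id = id)
    for (b in BLOCK_TYPES) row[[paste0("pct_", b)]] <- v[[b]]
    row$complete <- !anyNA(v)
    row$mean_accuracy_diffmean <- mean(v[DIFF_MEAN_BLOCKS])
    if (!anyNA(v[SAME_MEAN_BLOCKS])) {
      pv <- provariance_bias(v[SAME_MEAN_BLOCKS])
      row$provariance_bias <- pv[["overall"]]
      row$provariance_unimodal <- pv[["unimodal"]]
      row$provariance_bimodal <- pv[["bimodal"]]
    } else {
      row$provariance_bias <- NA_real_
      row$provariance_unimodal <- NA_real_
      row$provariance_bimodal <- NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the pre-specified exclusion rules
#'
#' Rule 1 excludes subjects whose mean accuracy across the four
#' different-mean blocks is below 60 percent (exactly 60 is retained). Rule 2
#' excludes subjects who chose the same option on every trial of at least one
#' same-mean block. Subjects with incomplete block data are flagged
#' separately, not silently dropped. Idempotent: re-applying to the retained
#' set removes no one.
#'
#' @param summaries Data frame from [subject_summaries()].
#' @param accuracy_threshold Rule-1 threshold in percent (default 60).
#' @return List with `retained` (summary rows passing all rules) and `log`
#'   (data frame `subject_id`, `rule` for every non-retained subject, where
#'   `rule` is `"low_diffmean_accuracy"`, `"constant_same_mean_block"` or
#'   `"incomplete"`).
#' @export
apply_exclusions <- function(summaries, accuracy_threshold = 60) {
  same_cols <- paste0("pct_", SAME_MEAN_BLOCKS)
  rule <- character(nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    if (!isTRUE(s$complete)) {
      rule[i] <- "incomplete"
    } else if (s$mean_accuracy_diffmean < accuracy_threshold) {
      rule[i] <- "low_diffmean_accuracy"
    } else if (any(unlist(s[same_cols]) %in% c(0, 100))) {
      rule[i] <- "constant_same_mean_block"
    }
  }
  keep <- rule == ""
  list(retained = summaries[keep, , drop = FALSE],
       log = data.frame(subject_id = summaries$subject_id[!keep],
                        rule = rule[!keep]))
}

#' Pearson correlation of a behavioural measure with a trait score
#'
#' Standard product-moment correlation with a two-tailed p value from the t
#' distribution on n - 2 degrees of freedom.
#'
#' @param values Per-subject measure (numeric).
#' @param traits Per-subject trait score, same length and order.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_with_trait <- function(values, traits) {
  if (length(values) != length(traits)) {
    stop("values and traits must be paired (same length)", call. = FALSE)
  }
  ok <- is.finite(values) & is.finite(traits)
  values <- values[ok]; traits <- traits[ok]
  if (length(values) < 3) stop("need at least 3 paired finite observations",
                               call. = FALSE)
  if (stats::sd(values) == 0 || stats::sd(traits) == 0) {
    stop("zero variance in values or traits", call. = FALSE)
  }
  ct <- stats::cor.test(values, traits, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values))
}
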