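# The norm-adjustment statistic S = (P2 - P1) / (NI - P1), its inclusion
# rules (0 <= S <= 1 conform rounds enter the main analyses; anticonformity
# S < 0 and overshoot S > 1 are excluded; fillers have NI = P1 so S is
# undefined) and the trial-level summaries.

#' Adjustment weight of a wave-2 rating
#'
#' `S = (P2 - P1) / (NI - P1)`: the weight placed on the normative
#' information when forming the new rating, since
#' `P2 = (1 - S) * P1 + S * NI`. Vectorized. When `NI = P1` (filler trial)
#' the weight is undefined and `NA` is returned as the filler marker; the
#' function never divides by zero.
#'
#' @param P1 wave-1 rating(s), 1-11
#' @param P2 wave-2 rating(s), 1-11
#' @param NI normative information shown, 1-11
#' @return numeric vector of S values, `NA` on filler trials
#' @export
compute_adjustment <- function(P1, P2, NI) {
  assert_ratings(P1, P2, NI)
  n <- max(length(P1), length(P2), length(NI))
  P1 <- rep_len(P1, n); P2 <- rep_len(P2, n); NI <- rep_len(NI, n)
  ifelse(NI == P1, NA_real_, (P2 - P1) / (NI - P1))
}

#' Round class of an adjustment weight
#'
#' Conform when `0 <= S <= 1` (the second rating is a weighted average of
#' the first and the cue; both boundaries included), anticonform when
#' `S < 0`, overshoot when `S > 1`; the filler marker (`NA`) passes through
#' as class `"filler"`.
#'
#' @param S adjustment weight(s) from [compute_adjustment()]
#' @return factor with levels conform, anticonform, overshoot, filler
#' @export
classify_round <- function(S) {
  cls <- ifelse(is.na(S), "filler",
                ifelse(S < 0, "anticonform",
                       ifelse(S > 1, "overshoot", "conform")))
  factor(cls, levels = c("conform", "anticonform", "overshoot", "filler"))
}

#' Updating strategy of a conform round
#'
#' `stay` keeps the initial rating (S = 0), `copy` adopts the cue (S = 1),
#' `compromise` lands in between. On the integer rating grid S is an exact
#' multiple of `1/|NI - P1|`, so the default tolerance is 0; a small
#' tolerance (e.g. 0.05) is appropriate for continuous re-analyses.
#'
#' @param S adjustment weight(s); every value must be a conform round
#' @param tol half-width around 0 and 1 treated as stay/copy
#' @return factor with levels stay, compromise, copy
#' @export
classify_strategy <- function(S, tol = 0) {
  if (any(is.na(S)) || any(S < 0 - 1e-12) || any(S > 1 + 1e-12)) {
    stop("classify_strategy is defined on conform rounds only (0 <= S <= 1)",
         call. = FALSE)
  }
  out <- ifelse(abs(S) <= tol, "stay",
                ifelse(abs(S - 1) <= tol, "copy", "compromise"))
  factor(out, levels = c("stay", "compromise", "copy"))
}

#' Score a trial table into adjustment records
#'
#' Adds `S`, `round_class`, `strategy` (defined for conform rounds, `none`
#' otherwise) and `abs_change = |P2 - P1|` to a trial table carrying wave-2
#' responses.
#'
#' @param trials data frame with at least `P1`, `NI`, `P2`
#' @param tol strategy tolerance, see [classify_strategy()]
#' @return the input with scoring columns appended
#' @export
score_trials <- function(trials, tol = 0) {
  check_columns(trials, c("P1", "NI", "P2"), "trials")
  trials$S <- compute_adjustment(trials$P1, trials$P2, trials$NI)
  trials$round_class <- classify_round(trials$S)
  strat <- rep("none", nrow(trials))
  conform <- trials$round_class == "conform"
  if (any(conform)) {
    strat[conform] <- as.character(classify_strategy(trials$S[conform], tol))
  }
  trials$strategy <- factor(strat,
                            levels = c("stay", "compromise", "copy", "none"))
  trials$abs_change <- abs(trials$P2 - trials$P1)
  trials
}

conform_only <- function(records) {
  records[records$round_class == "conform", , drop = FALSE]
}

mean_sem <- function(x) {
  n <- length(x)
  data.frame(mean_S = mean(x),
             sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
             n = n)
}

#' Mean adjustment by social source
#'
#' Trial-level means (each conform round one observation) and, secondarily,
#' participant-level means (each participant's mean one observation), per
#' source. Sources with no conform rounds are reported with `NA`.
#'
#' @param records scored records from [score_trials()] with a `block` column
#' @return data frame: `source`, `level` (trial/participant), `mean_S`,
#'   `sem`, `n`
#' @export
summarize_by_source <- function(records) {
  check_columns(records, c("block", "round_class", "S"), "records")
  rec <- conform_only(records)
  out <- list()
  for (src in c("popular", "majority")) {
    s <- rec$S[rec$block == src]
    row_t <- if (length(s)) mean_sem(s) else
      data.frame(mean_S = NA_real_, sem = NA_real_, n = 0L)
    out[[length(out) + 1L]] <- cbind(source = src, level = "trial", row_t)
    if (length(s)) {
      pm <- tapply(s, rec$participant[rec$block == src], mean)
      row_p <- mean_sem(as.numeric(pm))
    } else {
      row_p <- data.frame(mean_S = NA_real_, sem = NA_real_, n = 0L)
    }
    out[[length(out) + 1L]] <- cbind(source = src, level = "participant",
                                     row_p)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Mean adjustment by direction and domain
#'
#' Trial-level mean S and s.e.m. for the four normative cells
#' (extreme/moderate x risk/prosocial). Empty cells are reported with `NA`,
#' not dropped.
#'
#' @param records scored records with `direction` and `domain` columns
#' @return data frame: `direction`, `domain`, `mean_S`, `sem`, `n`
#' @export
summarize_by_direction_domain <- function(records) {
  check_columns(records, c("direction", "domain", "round_class", "S"),
                "records")
  rec <- conform_only(records)
  grid <- expand.grid(direction = c("extreme", "moderate"),
                      domain = c("risk", "prosocial"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    s <- rec$S[rec$direction == grid$direction[i] &
                 rec$domain == grid$domain[i]]
    row <- if (length(s)) mean_sem(s) else
      data.frame(mean_S = NA_real_, sem = NA_real_, n = 0L)
    cbind(grid[i, , drop = FALSE], row)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Strategy shares per source
#'
#' Proportions of stay / compromise / copy among conform rounds, per social
#' source; the three proportions sum to 1 within each source.
#'
#' @param records scored records
#' @return data frame: `source`, `strategy`, `proportion`, `n`
#' @export
strategy_proportions <- function(records) {
  check_columns(records, c("block", "round_class", "strategy"), "records")
  rec <- conform_only(records)
  out <- list()
  for (src in c("popular", "majority")) {
    st <- rec$strategy[rec$block == src]
    tot <- length(st)
    for (lv in c("stay", "compromise", "copy")) {
      out[[length(out) + 1L]] <- data.frame(
        source = src, strategy = lv,
        proportion = if (tot) sum(st == lv) / tot else NA_real_,
        n = sum(st == lv), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Mean absolute rating change: filler versus normative trials
#'
#' The filler mean gauges baseline rating drift between waves; the
#' normative mean gauges movement under peer information.
#'
#' @param records scored records
#' @return data frame: `type` (filler/normative), `mean_abs_change`, `n`
#' @export
filler_summary <- function(records) {
  check_columns(records, c("direction", "abs_change"), "records")
  fill <- records$abs_change[records$direction == "filler"]
  norm <- records$abs_change[records$direction != "filler"]
  data.frame(type = c("filler", "normative"),
             mean_abs_change = c(if (length(fill)) mean(fill) else NA_real_,
                                 if (length(norm)) mean(norm) else NA_real_),
             n = c(length(fill), length(norm)),
             stringsAsFactors = FALSE)
}

#' Rating histograms by domain and wave
#'
#' Counts over the eleven rating bins for wave-1 ratings (all items) and
#' wave-2 responses (designed trials), per domain.
#'
#' @param wave1 long wave-1 ratings
#' @param trials trial table with `P2`
#' @return data frame: `wave`, `domain`, `rating`, `count`
#' @export
rating_distributions <- function(wave1, trials) {
  check_columns(wave1, c("domain", "rating"), "wave1")
  check_columns(trials, c("domain", "P2"), "trials")
  bins <- RATING_MIN:RATING_MAX
  out <- list()
  for (dom in unique(wave1$domain)) {
    w1 <- wave1$rating[wave1$domain == dom]
    w2 <- trials$P2[trials$domain == dom & !is.na(trials$P2)]
    out[[length(out) + 1L]] <- data.frame(
      wave = rep(c("wave1", "wave2"), each = length(bins)),
      domain = dom, rating = rep(bins, 2),
      count = c(tabulate(factor(w1, levels = bins), length(bins)),
                tabulate(factor(w2, levels = bins), length(bins))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
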