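# Wave-2 design builder: 12 items per participant in two source blocks
# (popular peer / majority), each block 2 extreme + 2 moderate + 2 filler
# trials crossed with 3 risk + 3 prosocial items, normative information at a
# fixed rating distance from the participant's wave-1 rating.

#' Wave-2 design specification
#'
#' The default layout is fully crossed within block: one extreme, one
#' moderate and one filler trial per domain per block, which is the unique
#' layout satisfying both stated marginals (2/2/2 directions and 3/3
#' domains per 6-trial block) symmetrically.
#'
#' @param distance target |NI - P1| on normative trials (rating units)
#' @param risk_window,prosocial_window admissible wave-1 ratings for
#'   normative trials: initial disapproval of risk (P1 near 3) and approval
#'   of prosocial behaviour (P1 near 9)
#' @param relax_distances fallback distances (nearest first) when no item
#'   supports the target distance in a cell
#' @return list of class `pn_design_spec`
#' @export
design_spec <- function(distance = 2L,
                        risk_window = 2:4,
                        prosocial_window = 8:10,
                        relax_distances = c(1L, 3L)) {
  structure(list(items_per_participant = 12L,
                 blocks = c("popular", "majority"),
                 trials_per_block = 6L,
                 distance = as.integer(distance),
                 risk_window = as.integer(risk_window),
                 prosocial_window = as.integer(prosocial_window),
                 relax_distances = as.integer(relax_distances)),
            class = "pn_design_spec")
}

# items x participants integer matrix of one classroom's wave-1 ratings
class_rating_matrix <- function(wave1, classroom_id) {
  w <- wave1[wave1$classroom == classroom_id, , drop = FALSE]
  items <- sort(unique(w$item))
  parts <- sort(unique(w$participant))
  m <- matrix(NA_integer_, length(items), length(parts),
              dimnames = list(items, parts))
  m[cbind(match(w$item, items), match(w$participant, parts))] <- w$rating
  if (anyNA(m)) stop("wave-1 ratings are incomplete for classroom ",
                     classroom_id, call. = FALSE)
  m
}

# Required NI for a direction x domain cell: towards the domain's pole
# (risk pole = 1, prosocial pole = 11) for extreme trials, away for moderate.
required_ni <- function(P1, direction, domain, distance) {
  towards_pole <- (direction == "extreme")
  sign <- if (domain == "risk") -1L else 1L
  if (!towards_pole) sign <- -sign
  ni <- P1 + sign * distance
  if (ni < RATING_MIN || ni > RATING_MAX) NA_integer_ else as.integer(ni)
}

# First top-five peer (rank order, focal excluded) holding `value`; NA if none
top5_peer_with <- function(ratings_row, ranking, exclude, value) {
  peers <- utils::head(setdiff(ranking$participant, exclude), 5L)
  for (p in peers) if (ratings_row[[p]] == value) return(p)
  NA_character_
}

#' Candidate items per design cell for one participant
#'
#' For each source x direction x domain cell, lists the items whose wave-1
#' rating lies in the domain's target window and whose required normative
#' information (P1 +/- distance towards the cell's pole) is actually
#' obtainable from the cell's source: the self-excluded classroom mode
#' equals it (majority) or some top-five peer holds it (popular). Filler
#' candidates are items (any P1) for which the source's cue equals P1.
#'
#' @param participant focal participant id
#' @param wave1 long wave-1 ratings
#' @param item_bank from [generate_item_bank()]
#' @param ranking classroom [popularity_ranking()]
#' @param classroom_id classroom id
#' @param spec a [design_spec()]
#' @param distance override of `spec$distance` (used by the relaxation path)
#' @return named list (cell id `source.direction.domain`) of data frames
#'   `item`, `P1`, `NI`, `peer`
#' @export
eligible_items <- function(participant, wave1, item_bank, ranking,
                           classroom_id, spec = design_spec(),
                           distance = spec$distance) {
  m <- class_rating_matrix(wave1, classroom_id)
  eligible_items_m(participant, m, item_bank, ranking, spec, distance)
}

# matrix-based worker so build_design can reuse one classroom matrix
eligible_items_m <- function(participant, m, item_bank, ranking, spec,
                             distance) {
  out <- list()
  peers5 <- utils::head(setdiff(ranking$participant, participant), 5L)
  for (src in c("popular", "majority")) {
    for (dom in c("risk", "prosocial")) {
      window <- if (dom == "risk") spec$risk_window else spec$prosocial_window
      dom_items <- item_bank$item[item_bank$domain == dom]
      for (dir in c("extreme", "moderate", "filler")) {
        rows <- list()
        for (it in dom_items) {
          P1 <- m[it, participant]
          if (dir == "filler") {
            ni <- P1                          # filler: cue equals P1
          } else {
            if (!(P1 %in% window)) next
            ni <- required_ni(P1, dir, dom, distance)
            if (is.na(ni)) next
          }
          peer <- NA_character_
          if (src == "majority") {
            others <- m[it, colnames(m) != participant]
            if (rating_mode(others) != ni) next
          } else {
            hit <- FALSE
            for (p in peers5) if (m[it, p] == ni) { peer <- p; hit <- TRUE; break }
            if (!hit) next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            item = it, P1 = as.integer(P1), NI = as.integer(ni), peer = peer,
            stringsAsFactors = FALSE)
        }
        out[[paste(src, dir, dom, sep = ".")]] <-
          if (length(rows)) do.call(rbind, rows) else
            data.frame(item = character(), P1 = integer(), NI = integer(),
                       peer = character(), stringsAsFactors = FALSE)
      }
    }
  }
  out
}

#' Build the wave-2 design for one classroom
#'
#' Fills the 12 cells (2 sources x {extreme, moderate, filler} x 2 domains)
#' per participant with distinct items, scarcest cell first with random
#' tie-breaking, which maximizes the chance that rare cells get the items
#' only they can use. A normative cell with no exact-distance candidate is
#' retried at the relaxation distances (nearest first) and the resulting
#' trial flagged `relaxed`. Participants for whom some cell stays unfilled
#' are excluded as undesignable, with the failing cell logged. Block order
#' (popular-first vs majority-first) alternates across designable
#' participants; trial order within block is randomized.
#'
#' @param classroom a `pn_classroom`
#' @param wave1 long wave-1 ratings
#' @param item_bank item bank
#' @param ranking classroom [popularity_ranking()]
#' @param spec a [design_spec()]
#' @param seed optional RNG seed
#' @return list of class `pn_design`: `trials` (one row per trial),
#'   `excluded` (participant, reason), `relaxation_rate`
#' @export
build_design <- function(classroom, wave1, item_bank, ranking,
                         spec = design_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- class_rating_matrix(wave1, classroom$id)
  all_trials <- list()
  excluded <- list()
  n_designable <- 0L
  for (pid in classroom$participants$id) {
    elig <- eligible_items_m(pid, m, item_bank, ranking, spec, spec$distance)
    counts <- vapply(elig, nrow, integer(1))
    fill_order <- names(sort(counts))   # scarcest cell first
    used <- character()
    chosen <- list()
    failed_cell <- NULL
    for (cell in fill_order) {
      cand <- elig[[cell]]
      cand <- cand[!(cand$item %in% used), , drop = FALSE]
      relaxed <- FALSE
      if (nrow(cand) == 0 && !grepl("filler", cell)) {
        parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
        # relaxation ladder: distance 1 then 3 at the target window, then
        # the target distance and fallbacks again with the P1 window
        # widened by one rating. All fallback trials are flagged relaxed.
        ladder <- rbind(
          data.frame(d = spec$relax_distances, widen = FALSE),
          data.frame(d = c(spec$distance, spec$relax_distances), widen = TRUE))
        for (i in seq_len(nrow(ladder))) {
          alt <- eligible_cell_at(pid, m, item_bank, ranking, spec,
                                  parts[1], parts[2], parts[3],
                                  ladder$d[i], widen = ladder$widen[i])
          alt <- alt[!(alt$item %in% used), , drop = FALSE]
          if (nrow(alt) > 0) { cand <- alt; relaxed <- TRUE; break }
        }
      }
      if (nrow(cand) == 0) { failed_cell <- cell; break }
      pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      pick$relaxed <- relaxed
      pick$cell <- cell
      used <- c(used, pick$item)
      chosen[[cell]] <- pick
    }
    if (!is.null(failed_cell)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        participant = pid, reason = paste0("no_candidate:", failed_cell),
        stringsAsFactors = FALSE)
      next
    }
    n_designable <- n_designable + 1L
    order_first <- if (n_designable %% 2L == 1L) "popular" else "majority"
    block_order <- paste0(order_first, "_first")
    df <- do.call(rbind, chosen)
    cell_parts <- do.call(rbind, strsplit(df$cell, ".", fixed = TRUE))
    df$block <- cell_parts[, 1]
    df$direction <- cell_parts[, 2]
    df$domain <- cell_parts[, 3]
    df$cell <- NULL
    df$participant <- pid
    df$classroom <- classroom$id
    df$block_order <- block_order
    blocks <- if (order_first == "popular") c("popular", "majority") else
      c("majority", "popular")
    df_out <- list()
    for (b in seq_along(blocks)) {
      bdf <- df[df$block == blocks[b], , drop = FALSE]
      bdf <- bdf[sample.int(nrow(bdf)), , drop = FALSE]
      bdf$trial_index <- (b - 1L) * spec$trials_per_block +
        seq_len(nrow(bdf))
      df_out[[b]] <- bdf
    }
    all_trials[[pid]] <- do.call(rbind, df_out)
  }
  trials <- if (length(all_trials)) {
    do.call(rbind, c(all_trials, make.row.names = FALSE))
  } else {
    data.frame()
  }
  if (nrow(trials)) {
    trials <- trials[, c("participant", "classroom", "item", "domain",
                         "block", "block_order", "trial_index", "direction",
                         "P1", "NI", "relaxed", "peer")]
  }
  relax_rate <- if (nrow(trials) > 0 && any(trials$direction != "filler")) {
    mean(trials$relaxed[trials$direction != "filler"])
  } else NA_real_
  structure(list(trials = trials,
                 excluded = if (length(excluded)) {
                   do.call(rbind, excluded)
                 } else {
                   data.frame(participant = character(), reason = character(),
                              stringsAsFactors = FALSE)
                 },
                 relaxation_rate = relax_rate),
            class = "pn_design")
}

# single-cell eligibility at an arbitrary distance (relaxation path);
# `widen` extends the P1 window by one rating on each side
eligible_cell_at <- function(participant, m, item_bank, ranking, spec,
                             src, dir, dom, distance, widen = FALSE) {
  window <- if (dom == "risk") spec$risk_window else spec$prosocial_window
  if (widen) {
    window <- seq(max(RATING_MIN, min(window) - 1L),
                  min(RATING_MAX, max(window) + 1L))
  }
  peers5 <- utils::head(setdiff(ranking$participant, participant), 5L)
  rows <- list()
  for (it in item_bank$item[item_bank$domain == dom]) {
    P1 <- m[it, participant]
    if (!(P1 %in% window)) next
    ni <- required_ni(P1, dir, dom, distance)
    if (is.na(ni)) next
    peer <- NA_character_
    if (src == "majority") {
      if (rating_mode(m[it, colnames(m) != participant]) != ni) next
    } else {
      hit <- FALSE
      for (p in peers5) if (m[it, p] == ni) { peer <- p; hit <- TRUE; break }
      if (!hit) next
    }
    rows[[length(rows) + 1L]] <- data.frame(item = it, P1 = as.integer(P1),
                                            NI = as.integer(ni), peer = peer,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(item = character(), P1 = integer(), NI = integer(),
               peer = character(), stringsAsFactors = FALSE)
}

#' Structural checks on a built design
#'
#' Report-only (never raises): per participant, verifies 12 trials, 6 per
#' block, the 2 extreme / 2 moderate / 2 filler and 3 risk / 3 prosocial
#' block marginals, distinct items, |NI - P1| equal to the target distance
#' on non-relaxed normative trials, NI = P1 on fillers, and direction labels
#' consistent with NI (a trial labelled extreme/moderate must move).
#'
#' @param trials trials data frame (a `pn_design$trials`)
#' @param spec the [design_spec()] the design was built under
#' @return list: `per_participant` check data frame, `ok` overall flag,
#'   `relaxation_rate`, `distance_table` histogram of |NI - P1|
#' @export
validate_design <- function(trials, spec = design_spec()) {
  if (is.null(trials) || nrow(trials) == 0) {
    return(list(per_participant = data.frame(), ok = TRUE,
                relaxation_rate = NA_real_, distance_table = table(integer())))
  }
  per <- lapply(split(trials, trials$participant), function(tr) {
    nonfill <- tr[tr$direction != "filler", , drop = FALSE]
    fill <- tr[tr$direction == "filler", , drop = FALSE]
    blk <- table(tr$block)
    dirs <- table(tr$block, tr$direction)
    doms <- table(tr$block, tr$domain)
    exact <- nonfill[!nonfill$relaxed, , drop = FALSE]
    data.frame(
      participant = tr$participant[1],
      n_trials = nrow(tr),
      n_per_block_ok = all(blk == spec$trials_per_block),
      direction_counts_ok = all(dirs == 2L),
      domain_counts_ok = all(doms == 3L),
      items_distinct = !anyDuplicated(tr$item),
      distance_ok = all(abs(exact$NI - exact$P1) == spec$distance),
      fillers_ok = all(fill$NI == fill$P1),
      direction_labels_ok = all(nonfill$NI != nonfill$P1),
      relaxed_n = sum(nonfill$relaxed),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, make.row.names = FALSE))
  check_cols <- setdiff(names(per), c("participant", "n_trials", "relaxed_n"))
  ok <- all(per$n_trials == spec$items_per_participant) &&
    all(vapply(per[check_cols], all, logical(1)))
  nonfill <- trials[trials$direction != "filler", , drop = FALSE]
  list(per_participant = per,
       ok = ok,
       relaxation_rate = mean(nonfill$relaxed),
       distance_table = table(abs(nonfill$NI - nonfill$P1)))
}
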