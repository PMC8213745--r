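# Shared fixture builders. Everything is constructed in code; no files.

# seven-pupil classroom with a hand-set nomination pattern:
# p2 gets 3 nominations, p3 gets 2, p1 gets 1, p4 gets 1, rest 0
tiny_classroom <- function() {
  ids <- paste0("p", 1:7)
  participants <- data.frame(id = ids, classroom = "c01",
                             age = seq(13, 16, length.out = 7),
                             gender = "f", stringsAsFactors = FALSE)
  participants$age_z <- as.numeric(scale(participants$age))
  participants$school_year <- c(1L, 1L, 3L, 3L, 3L, 5L, 5L)
  nominations <- data.frame(
    nominator = ids,
    nominee = c("p2", "p3", "p2", "p2", "p3", "p1", "p4"),
    stringsAsFactors = FALSE)
  structure(list(id = "c01", participants = participants,
                 nominations = nominations),
            class = "pn_classroom")
}

# long wave-1 table for tiny_classroom over arbitrary items;
# `ratings` is a named list item -> integer vector of length 7 (p1..p7)
tiny_wave1 <- function(ratings, domain = "risk") {
  ids <- paste0("p", 1:7)
  do.call(rbind, lapply(names(ratings), function(it) {
    data.frame(participant = ids, classroom = "c01", item = it,
               domain = domain, rating = as.integer(ratings[[it]]),
               stringsAsFactors = FALSE)
  }))
}

# minimal scored-record frame for the inference module
make_records <- function(S, participant, block = "popular",
                         direction = "extreme", domain = "risk",
                         age_z = 0) {
  df <- data.frame(S = S, participant = participant, block = block,
                   direction = direction, domain = domain, age_z = age_z,
                   stringsAsFactors = FALSE)
  df$round_class <- classify_round(df$S)
  df$strategy <- factor(
    ifelse(df$round_class == "conform",
           as.character(classify_strategy(pmin(pmax(df$S, 0), 1))), "none"),
    levels = c("stay", "compromise", "copy", "none"))
  df
}

# simulate a balanced source x direction x domain trial set with per-source
# adjustment means, through the full update -> scoring path
simulate_source_trials <- function(n_participants, means_by_source,
                                   sd = 0.25, integer_grid = TRUE) {
  cells <- expand.grid(direction = c("extreme", "moderate"),
                       domain = c("risk", "prosocial"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (src in names(means_by_source)) {
    for (i in seq_len(nrow(cells))) {
      P1 <- if (cells$domain[i] == "risk") 3L else 9L
      NI <- required_ni_pub(P1, cells$direction[i], cells$domain[i])
      S <- rtrunc_unit(n_participants, means_by_source[[src]], sd)
      P2 <- apply_update(P1, NI, S, integer_grid = integer_grid)
      out[[length(out) + 1L]] <- data.frame(
        participant = paste0("p", seq_len(n_participants)),
        block = src, direction = cells$direction[i],
        domain = cells$domain[i], P1 = P1, NI = NI, P2 = P2,
        stringsAsFactors = FALSE)
    }
  }
  score_trials(do.call(rbind, out))
}

# public mirror of the cell -> NI rule (risk pole 1, prosocial pole 11)
required_ni_pub <- function(P1, direction, domain, distance = 2L) {
  sgn <- if (domain == "risk") -1L else 1L
  if (direction == "moderate") sgn <- -sgn
  P1 + sgn * distance
}
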