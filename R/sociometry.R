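# Sociometric source identification: the classroom majority (mode rating)
# and popular peers (top-five most nominated on "who is most popular?").

#' Rank classroom members by nomination in-degree
#'
#' Every classroom member appears, including those never nominated (count 0).
#' Ties are broken by participant id so the ranking - and hence the top-five
#' - is deterministic and independent of edge-list order.
#'
#' @param classroom a `pn_classroom` (elements `participants`, `nominations`)
#' @return data frame `participant`, `n_nominations`, ordered descending
#' @export
popularity_ranking <- function(classroom) {
  noms <- classroom$nominations
  if (is.null(noms) || nrow(noms) == 0) {
    stop("classroom has no nominations; popularity is undefined", call. = FALSE)
  }
  ids <- classroom$participants$id
  counts <- vapply(ids, function(i) sum(noms$nominee == i), integer(1))
  out <- data.frame(participant = ids, n_nominations = counts,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_nominations, out$participant), , drop = FALSE]
}

# Mode with ties broken towards the smallest rating (deterministic and
# auditable; the alternative "closest to the classroom mean" adds complexity
# for no analytical gain).
rating_mode <- function(x) {
  tab <- table(x)
  as.integer(min(as.integer(names(tab)[tab == max(tab)])))
}

#' Majority norm: classmates' modal rating for an item
#'
#' The focal participant's own rating is excluded - the "most chosen rating
#' in your classroom" logically describes the others.
#'
#' @param wave1 long wave-1 ratings (`participant`, `classroom`, `item`,
#'   `rating`)
#' @param item item id
#' @param classroom_id classroom id
#' @param exclude focal participant id to drop before taking the mode
#' @return integer NI in 1-11
#' @export
majority_norm <- function(wave1, item, classroom_id, exclude) {
  r <- wave1$rating[wave1$item == item & wave1$classroom == classroom_id &
                      wave1$participant != exclude]
  if (length(r) < 2) {
    stop("need at least 2 classmates' ratings to define a majority norm",
         call. = FALSE)
  }
  rating_mode(r)
}

#' Popular-peer norm: a top-five nominee's rating for an item
#'
#' Walks the five most-nominated classmates (after dropping the focal
#' participant, so a popular focal participant still observes a peer) in
#' rank order. Without `required_value` the first peer's rating is returned;
#' with it, the first top-five peer whose rating equals `required_value`
#' supplies the cue, and `NA` signals "cue unavailable" (the design builder
#' treats this as ineligibility, not an error).
#'
#' @param wave1 long wave-1 ratings
#' @param item item id
#' @param ranking a [popularity_ranking()] result
#' @param exclude focal participant id
#' @param required_value optional rating the cue must equal
#' @return integer NI, with attribute `"peer"` naming the supplying peer;
#'   `NA` if no top-five peer satisfies the requirement
#' @export
popular_norm <- function(wave1, item, ranking, exclude, required_value = NULL) {
  peers <- setdiff(ranking$participant, exclude)
  top5 <- utils::head(peers, 5L)
  for (p in top5) {
    r <- wave1$rating[wave1$item == item & wave1$participant == p]
    if (length(r) != 1) next
    if (is.null(required_value) || r == required_value) {
      return(structure(as.integer(r), peer = p))
    }
  }
  NA_integer_
}
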