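## Multi-rater consensus labeling: voting protocol with adjudication and
## nondiagnostic exclusion, plus patient-disjoint split assignment.

#' Consensus HER2 score from multiple raters
#'
#' Voting protocol: (1) if nondiagnostic flags form a majority of the
#' ratings, the core is excluded as nondiagnostic; (2) if a unique score is
#' shared by at least two raters and no other score ties that count, it is
#' the consensus; (3) if two or more scores tie at the maximal count (>= 2),
#' or no score reaches two votes, an adjudicator score that matches one of
#' the candidate scores decides, otherwise the core is excluded as
#' discordant.  Candidates are the tied modal scores in a tie, or all
#' distinct rated scores when nothing reached two votes (the adjudicator's
#' matching vote then creates the required two-rater agreement).
#'
#' @param scores character vector of rater scores: \code{"0","1+","2+",
#'   "3+"} (also bare \code{"1","2","3"}) or \code{"ND"} for a
#'   nondiagnostic flag.
#' @param adjudicator optional single adjudicator score (same symbols,
#'   no \code{"ND"}).
#' @return List: \code{label} (ordered factor or NA), \code{excluded}
#'   (logical), \code{reason} (\code{"consensus"}, \code{"adjudicated"},
#'   \code{"nondiagnostic"} or \code{"discordant"}).
#' @examples
#' consensusScore(c("3+", "3+", "3+", "2+", "3+"))      # 3+
#' consensusScore(c("1+", "2+", "1+", "2+", "0"), "2+") # adjudicated 2+
#' @export
consensusScore <- function(scores, adjudicator = NULL) {
  if (!length(scores)) stop("scores must be non-empty")
  scores <- as.character(scores)
  nd <- toupper(scores) == "ND"
  if (sum(nd) * 2L > length(scores))
    return(list(label = NA, excluded = TRUE, reason = "nondiagnostic"))
  rated <- as.character(asScoreLabel(scores[!nd]))
  if (!is.null(adjudicator) && length(adjudicator) == 1L &&
      !is.na(adjudicator))
    adjudicator <- as.character(asScoreLabel(adjudicator))
  else adjudicator <- NULL
  if (!length(rated))
    return(list(label = NA, excluded = TRUE, reason = "nondiagnostic"))
  cnt <- table(rated)
  topN <- max(cnt)
  modal <- names(cnt)[cnt == topN]
  if (topN >= 2L && length(modal) == 1L)
    return(list(label = asScoreLabel(modal), excluded = FALSE,
                reason = "consensus"))
  ## tie among >= 2 modal scores, or no score with >= 2 votes
  candidates <- if (topN >= 2L) modal else names(cnt)
  if (!is.null(adjudicator) && adjudicator %in% candidates)
    return(list(label = asScoreLabel(adjudicator), excluded = FALSE,
                reason = "adjudicated"))
  list(label = NA, excluded = TRUE, reason = "discordant")
}

#' Consensus for a ratings table
#'
#' @param ratings data.frame with columns \code{core_id}, \code{rater_id},
#'   \code{score} (one row per rating; score in 0/1/2/3/ND).
#' @param adjudications optional data.frame \code{core_id},
#'   \code{score}.
#' @return data.frame core_id, consensus (NA when excluded), excluded,
#'   reason.
#' @export
consensusTable <- function(ratings, adjudications = NULL) {
  need <- c("core_id", "rater_id", "score")
  if (!all(need %in% names(ratings)))
    stop("ratings needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ratings[, c("core_id", "rater_id")]))
    stop("duplicate (core_id, rater_id) ratings")
  adj <- if (is.null(adjudications)) character(0)
         else stats::setNames(as.character(adjudications$score),
                              adjudications$core_id)
  ids <- unique(ratings$core_id)
  rows <- lapply(ids, function(id) {
    res <- consensusScore(ratings$score[ratings$core_id == id],
                          if (id %in% names(adj)) adj[[id]] else NULL)
    data.frame(core_id = id,
               consensus = if (res$excluded) NA_character_
                           else as.character(res$label),
               excluded = res$excluded, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply consensus labels and assign patient-disjoint splits
#'
#' Drops excluded cores, attaches the consensus label to the manifest, and
#' assigns train/validation/test splits *by patient* so no patient's cores
#' leak across splits.
#'
#' @param manifest data.frame with columns \code{core_id} and
#'   \code{patient_id}.
#' @param consensus output of \code{\link{consensusTable}} covering every
#'   manifest core.
#' @param splitFractions named fractions summing to 1, default
#'   \code{c(train = 0.7, val = 0.1, test = 0.2)}.
#' @param seed RNG seed for the patient shuffle.
#' @return The filtered manifest with columns \code{consensus} and
#'   \code{split}; zero rows (with a warning) if everything was excluded.
#' @export
applyLabels <- function(manifest, consensus,
                        splitFractions = c(train = 0.7, val = 0.1,
                                           test = 0.2),
                        seed = 1L) {
  if (!all(c("core_id", "patient_id") %in% names(manifest)))
    stop("manifest needs core_id and patient_id columns")
  missing <- setdiff(manifest$core_id, consensus$core_id)
  if (length(missing))
    stop("no consensus result for core(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (abs(sum(splitFractions) - 1) > 1e-9)
    stop("splitFractions must sum to 1")
  m <- merge(manifest, consensus[, c("core_id", "consensus", "excluded")],
             by = "core_id", sort = FALSE)
  m <- m[!m$excluded, setdiff(names(m), "excluded"), drop = FALSE]
  if (!nrow(m)) {
    warning("all cores excluded; returning empty manifest")
    m$split <- character(0)
    return(m)
  }
  pats <- unique(m$patient_id)
  withSeed(deriveSeed(seed, 17L), {
    pats <- sample(pats)
  })
  cuts <- round(cumsum(splitFractions) * length(pats))
  assign <- character(length(pats))
  lo <- 1L
  for (s in seq_along(splitFractions)) {
    hi <- cuts[s]
    if (hi >= lo) assign[lo:hi] <- names(splitFractions)[s]
    lo <- hi + 1L
  }
  names(assign) <- pats
  m$split <- assign[as.character(m$patient_id)]
  m
}
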