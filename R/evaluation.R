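## Validation statistics: ROC/AUROC over labeled rankings and rank
## correlation between screens.

label_vector <- function(ranking, labels) {
  stopifnot(all(c("enzyme_id", "is_positive") %in% names(labels)))
  m <- match(ranking$enzyme_id, labels$enzyme_id)
  if (anyNA(m))
    stop_plp("plpscreen_statistics_error",
             "ranking contains enzymes without labels: %s",
             paste(utils::head(ranking$enzyme_id[is.na(m)], 3),
                   collapse = ", "))
  as.logical(labels$is_positive[m])
}

#' Area under the ROC curve of a labeled ranking
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, ties counting one half.
#' Rank 1 is the best position; ties in the underlying metric receive
#' average ranks.
#'
#' @param ranking a `ranking_table` from [rank_enzymes()] (or any data
#'   frame with `enzyme_id` and `rank`, optionally the ranked metric
#'   column named in `ranking$method`).
#' @param labels data frame with `enzyme_id` and logical/0-1
#'   `is_positive`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(ranking, labels) {
  pos <- label_vector(ranking, labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_plp("plpscreen_statistics_error",
             "need at least one positive and one negative label")
  ## "score" = goodness = -rank position; average ties come from the
  ## metric values when available so equal metric values tie properly
  score <- -ranking_positions(ranking)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Rank positions with metric ties collapsed: rows with an equal value of
## the ranked metric share an average position.
ranking_positions <- function(ranking) {
  method <- if ("method" %in% names(ranking)) ranking$method[1] else NULL
  if (!is.null(method) && method %in% names(ranking)) {
    v <- ranking[[method]]
    asc <- method %in% c("LCE", "BCE", "LCaaE", "BCaaE")
    return(rank(if (asc) v else -v, ties.method = "average"))
  }
  as.numeric(ranking$rank)
}

#' ROC curve of a labeled ranking
#'
#' Threshold sweep over rank positions from best to worst; each distinct
#' metric value contributes one step.  The area under the returned
#' staircase equals [auroc()] exactly.
#'
#' @inheritParams auroc
#' @return list of class `roc_curve`: `points` (data frame fpr, tpr from
#'   (0,0) to (1,1)) and `auroc`.
#' @export
roc_curve <- function(ranking, labels) {
  pos <- label_vector(ranking, labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_plp("plpscreen_statistics_error",
             "need at least one positive and one negative label")
  posn <- ranking_positions(ranking)
  ord <- order(posn)
  pos <- pos[ord]; posn <- posn[ord]
  tpr <- c(0); fpr <- c(0)
  for (thr in unique(posn)) {
    sel <- posn <= thr
    tpr <- c(tpr, sum(pos & sel) / n1)
    fpr <- c(fpr, sum(!pos & sel) / n0)
  }
  a <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auroc = a),
            class = "roc_curve")
}

#' Spearman rank correlation between two screens
#'
#' Correlation of rank positions over the enzymes shared by both
#' rankings, with average-rank tie handling.
#'
#' @param rankingA,rankingB `ranking_table`s (or data frames with
#'   `enzyme_id` and `rank`).
#' @return Spearman rho in \[-1, 1\].
#' @export
rank_correlation <- function(rankingA, rankingB) {
  shared <- intersect(rankingA$enzyme_id, rankingB$enzyme_id)
  if (length(shared) < 3)
    stop_plp("plpscreen_statistics_error",
             "need at least 3 shared enzymes (have %d)", length(shared))
  ra <- rankingA$rank[match(shared, rankingA$enzyme_id)]
  rb <- rankingB$rank[match(shared, rankingB$enzyme_id)]
  stats::cor(ra, rb, method = "spearman")
}

#' Read a validation-label table
#'
#' Tab-separated with header `enzyme_id, is_positive, category`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_labels_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out$is_positive <- as.logical(out$is_positive)
  out
}
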