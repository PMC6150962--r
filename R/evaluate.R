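#' Neighborhood affinity between two complexes
#'
#' `NA(p, q) = |p intersect q|^2 / (|p| * |q|)`, the standard overlap score
#' for deciding whether a predicted complex matches a gold complex.
#'
#' @param p,q Character vectors of member IDs (non-empty).
#' @return A number in `[0, 1]`; symmetric in its arguments.
#' @export
na_score <- function(p, q) {
  p <- unique(p); q <- unique(q)
  if (length(p) == 0 || length(q) == 0) stop("empty complex")
  length(intersect(p, q))^2 / (length(p) * length(q))
}

#' Match predictions to a gold standard and score them
#'
#' A predicted complex counts as matched if its neighborhood affinity with
#' at least one gold complex is `>= na_thres` ("not lower than" 0.25 by
#' convention), and vice versa for gold complexes; matching is many-to-many
#' with no exclusivity. Precision is the matched fraction of predictions,
#' recall the matched fraction of gold complexes, and the F-score their
#' harmonic mean (0 when both are 0).
#'
#' @param predicted List of character vectors.
#' @param gold Non-empty list of character vectors.
#' @param na_thres Matching threshold in `(0, 1]`; default 0.25.
#' @return An object of class `complex_eval`: counts, `precision`,
#'   `recall`, `f_score`, and `pair_matches` (data frame of matched pairs
#'   with their NA scores).
#' @export
match_and_score <- function(predicted, gold, na_thres = 0.25) {
  if (length(gold) == 0) stop("gold-standard complex list is empty")
  stopifnot(na_thres > 0, na_thres <= 1)
  np <- length(predicted); ng <- length(gold)
  pi_ <- integer(0); gi_ <- integer(0); nas <- numeric(0)
  if (np > 0) {
    for (i in seq_len(np)) {
      for (j in seq_len(ng)) {
        s <- na_score(predicted[[i]], gold[[j]])
        if (s >= na_thres) {
          pi_ <- c(pi_, i); gi_ <- c(gi_, j); nas <- c(nas, s)
        }
      }
    }
  }
  matched_pred <- length(unique(pi_))
  matched_gold <- length(unique(gi_))
  precision <- if (np == 0) 0 else matched_pred / np
  recall <- matched_gold / ng
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(n_predicted = np, n_gold = ng,
                 matched_pred = matched_pred, matched_gold = matched_gold,
                 precision = precision, recall = recall, f_score = f,
                 na_threshold = na_thres,
                 pair_matches = data.frame(predicted = pi_, gold = gi_,
                                           na = nas)),
            class = "complex_eval")
}

#' @export
print.complex_eval <- function(x, ...) {
  cat("Complex-set evaluation (NA >=", x$na_threshold, ")\n")
  cat(sprintf("  predicted: %d (matched %d)   gold: %d (matched %d)\n",
              x$n_predicted, x$matched_pred, x$n_gold, x$matched_gold))
  cat(sprintf("  precision %.4f   recall %.4f   F-score %.4f\n",
              x$precision, x$recall, x$f_score))
  invisible(x)
}
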