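#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for a balanced panel in which every item is
#' rated by the same number of raters.  With `n_ij` the count of raters
#' assigning item i to category j, per-item agreement is
#' `P_i = sum_j n_ij (n_ij - 1) / (n (n - 1))`, and
#' `kappa = (Pbar - Pe) / (1 - Pe)` where `Pe = sum_j q_j^2` with `q_j` the
#' marginal category proportions.  When every item is unanimous `Pbar = 1`
#' and kappa is returned as 1 (the chance-correction denominator can vanish
#' when only one category is ever used).
#'
#' @param ratings Either a rating table (data frame with columns
#'   `sample_id`, `rater_id`, `category`) or an item-by-category count
#'   matrix.
#' @param categories Optional category levels (default: observed).
#' @return Fleiss' kappa in [-1, 1].
#' @examples
#' counts <- rbind(c(3, 0), c(2, 1), c(1, 2))
#' fleiss_kappa(counts)
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  counts <- .rating_counts(ratings, categories)
  n <- unique(rowSums(counts))
  if (length(n) != 1L)
    stop("unbalanced panel: every item must have the same number of ratings",
         call. = FALSE)
  if (n < 2) stop("need at least 2 raters per item", call. = FALSE)
  P_i <- rowSums(counts * (counts - 1)) / (n * (n - 1))
  P_bar <- mean(P_i)
  q <- colSums(counts) / sum(counts)
  P_e <- sum(q^2)
  if (P_bar == 1) return(1)
  (P_bar - P_e) / (1 - P_e)
}

.rating_counts <- function(ratings, categories = NULL) {
  if (is.matrix(ratings)) return(ratings)
  stopifnot(is.data.frame(ratings),
            all(c("sample_id", "rater_id", "category") %in% names(ratings)))
  if (anyDuplicated(ratings[c("sample_id", "rater_id")]))
    stop("each (sample_id, rater_id) pair may appear at most once",
         call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(ratings$category))
  as.matrix(table(factor(ratings$sample_id, levels = unique(ratings$sample_id)),
                  factor(ratings$category, levels = categories)))
}

#' Cohen's kappa for two ratings of the same items
#'
#' @param a,b Factors/vectors of paired categorical ratings.
#' @return Cohen's kappa; 1 when agreement is perfect.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- union(unique(as.character(a)), unique(as.character(b)))
  tab <- table(factor(a, lev), factor(b, lev))
  p <- tab / sum(tab)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (po == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Two-way random-effects intraclass correlation
#'
#' ICC for absolute agreement under the two-way random model, computed from
#' the mean squares of the items-by-raters ANOVA decomposition.  The
#' single-measure form ICC(2,1) is
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`; the
#' average-measure form ICC(2,k) is available via `unit = "average"`.
#'
#' @param scores Numeric matrix, items in rows, raters in columns, no
#'   missing cells.
#' @param unit `"single"` (default) or `"average"`.
#' @return The intraclass correlation coefficient.
#' @examples
#' m <- cbind(r1 = c(9, 6, 8, 7), r2 = c(2, 1, 4, 1), r3 = c(5, 3, 6, 2))
#' icc_two_way_random(m)
#' @export
icc_two_way_random <- function(scores, unit = c("single", "average")) {
  unit <- match.arg(unit)
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("no missing cells allowed", call. = FALSE)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) stop("need at least 2 items and 2 raters", call. = FALSE)
  grand <- mean(scores)
  row_m <- rowMeans(scores); col_m <- colMeans(scores)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((scores - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot == 0) stop("zero total variance; ICC undefined", call. = FALSE)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (unit == "single")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
}

#' Screen a rating table down to pure samples
#'
#' A sample is "pure" when at least `min_agree` raters chose the same
#' category from the target set (modal/breathy/pressed, i.e. excluding
#' "none") and every one of those agreeing raters reported a confidence of
#' at least `min_conf`.  All other samples (including "none"-majority
#' distractors) are rejected.  The rule is monotone: raising either
#' threshold can only shrink the pure set.
#'
#' @param ratings Rating table: data frame with columns `sample_id`,
#'   `rater_id`, `category`, `confidence`.
#' @param min_agree Minimum number of agreeing raters (default 4 of 5).
#' @param min_conf Minimum confidence of each agreeing rater (default 0.8).
#' @param target_categories Label categories eligible as pure types.
#' @return A `screened_dataset`: list with `pure_labels` (named character
#'   vector, sample_id -> category), `rejected_ids`, `counts_by_type`, and
#'   the thresholds used.
#' @export
filter_pure <- function(ratings, min_agree = 4, min_conf = 0.8,
                        target_categories = c("modal", "breathy", "pressed")) {
  stopifnot(is.data.frame(ratings),
            all(c("sample_id", "rater_id", "category", "confidence") %in%
                  names(ratings)))
  if (any(ratings$confidence < 0 | ratings$confidence > 1))
    stop("confidence must lie in [0, 1]", call. = FALSE)
  ids <- unique(ratings$sample_id)
  lab <- vapply(split(ratings, factor(ratings$sample_id, levels = ids)),
                function(d) {
    for (cat in target_categories) {
      # agreeing raters are those choosing the category at/above the
      # confidence gate; at least min_agree of them are required
      if (sum(d$category == cat & d$confidence >= min_conf) >= min_agree)
        return(cat)
    }
    NA_character_
  }, "")
  pure <- lab[!is.na(lab)]
  structure(
    list(pure_labels = pure,
         rejected_ids = ids[is.na(lab)],
         counts_by_type = table(factor(pure, levels = target_categories)),
         min_agree = min_agree, min_conf = min_conf),
    class = "screened_dataset")
}

#' @export
print.screened_dataset <- function(x, ...) {
  n <- length(x$pure_labels) + length(x$rejected_ids)
  cat(sprintf("Screened dataset: %d of %d samples pure (>= %d raters agreeing, confidence >= %.2f)\n",
              length(x$pure_labels), n, x$min_agree, x$min_conf))
  print(x$counts_by_type)
  invisible(x)
}

#' Intra-rater reliability on duplicated samples
#'
#' For each rater, pairs each duplicated sample's two ratings and computes
#' Cohen's kappa on the paired categories; mean confidence on the pairs is
#' reported alongside.
#'
#' @param ratings Rating table including duplicate rows.
#' @param duplicate_map Two-column matrix/data frame of paired sample ids
#'   (original, duplicate).  Defaults to the table's `duplicate_map`
#'   attribute, as written by [simulate_panel()].
#' @return Data frame with one row per rater: `rater_id`, `kappa`,
#'   `n_pairs`.
#' @export
intra_rater_reliability <- function(ratings,
                                    duplicate_map = attr(ratings, "duplicate_map")) {
  if (is.null(duplicate_map) || nrow(duplicate_map) == 0)
    stop("no duplicate_map available", call. = FALSE)
  raters <- sort(unique(ratings$rater_id))
  out <- lapply(raters, function(r) {
    d <- ratings[ratings$rater_id == r, ]
    first <- d$category[match(duplicate_map[[1]], d$sample_id)]
    second <- d$category[match(duplicate_map[[2]], d$sample_id)]
    ok <- !is.na(first) & !is.na(second)
    data.frame(rater_id = r, kappa = cohen_kappa(first[ok], second[ok]),
               n_pairs = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
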