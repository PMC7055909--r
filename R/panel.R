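#' Specify a simulated rater panel
#'
#' @param n_raters Number of raters (default 5).
#' @param rater_confusion Either one 4x4 row-stochastic matrix over the
#'   categories (modal, breathy, pressed, none) shared by all raters, or a
#'   list of one such matrix per rater.  Row i gives the probability of
#'   each reported category when the true category is i.  Default is the
#'   identity (perfectly accurate raters).
#' @param confidence Per-rater confidence model: either a single function
#'   `function(n)` drawing n values in [0, 1], a list of such functions
#'   (one per rater), or a numeric constant.  Default `Beta(9, 1.5)`
#'   (mean ~0.86, most mass above 0.8), chosen as a plausible model of
#'   confident expert raters.
#' @param n_duplicates Number of samples re-rated by every rater for the
#'   intra-rater design (default 0).
#' @return A `panel_spec`.
#' @export
panel_spec <- function(n_raters = 5,
                       rater_confusion = diag(4),
                       confidence = function(n) stats::rbeta(n, 9, 1.5),
                       n_duplicates = 0) {
  cats <- c("modal", "breathy", "pressed", "none")
  if (!is.list(rater_confusion))
    rater_confusion <- rep(list(rater_confusion), n_raters)
  if (length(rater_confusion) != n_raters)
    stop("need one confusion matrix per rater (or one shared)", call. = FALSE)
  rater_confusion <- lapply(rater_confusion, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(4L, 4L)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9))
      stop("each confusion matrix must be 4x4 row-stochastic", call. = FALSE)
    dimnames(m) <- list(cats, cats)
    m
  })
  if (is.numeric(confidence)) {
    const <- confidence
    confidence <- function(n) rep(const, n)
  }
  if (!is.list(confidence)) confidence <- rep(list(confidence), n_raters)
  structure(
    list(n_raters = n_raters, rater_confusion = rater_confusion,
         confidence = confidence, n_duplicates = n_duplicates,
         categories = cats),
    class = "panel_spec")
}

#' Simulate an auditory-perceptual rating panel
#'
#' Produces one rating row per (sample, rater): the reported category is
#' drawn from the rater's confusion-matrix row for the sample's true
#' category, and a confidence value is drawn from the rater's confidence
#' model.  The first `n_duplicates` samples are additionally presented a
#' second time (ids suffixed `"_dup"`), each rater re-rating them
#' independently; the pairing is recorded in the result's
#' `duplicate_map` attribute.
#'
#' @param truth_labels Character vector of true categories, one per sample
#'   (values among modal/breathy/pressed/none); names are used as sample
#'   ids when present.
#' @param spec A [panel_spec()].
#' @param seed Integer seed for reproducibility.
#' @return Data frame with columns `sample_id`, `rater_id`, `category`,
#'   `confidence`, and attribute `duplicate_map`.
#' @examples
#' tab <- simulate_panel(c("modal", "breathy", "pressed"), panel_spec(), seed = 1)
#' head(tab)
#' @export
simulate_panel <- function(truth_labels, spec = panel_spec(), seed = NULL) {
  stopifnot(inherits(spec, "panel_spec"), length(truth_labels) > 0)
  ids <- names(truth_labels)
  truth_labels <- as.character(truth_labels)
  if (!all(truth_labels %in% spec$categories))
    stop("truth labels must be among: ",
         paste(spec$categories, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- sprintf("sample_%04d", seq_along(truth_labels))
  n_dup <- min(spec$n_duplicates, length(truth_labels))
  all_ids <- c(ids, if (n_dup > 0) paste0(ids[seq_len(n_dup)], "_dup"))
  all_truth <- c(truth_labels,
                 if (n_dup > 0) truth_labels[seq_len(n_dup)])

  rows <- vector("list", spec$n_raters)
  for (r in seq_len(spec$n_raters)) {
    conf_mat <- spec$rater_confusion[[r]]
    cat_idx <- match(all_truth, spec$categories)
    rated <- vapply(cat_idx, function(i)
      sample(spec$categories, 1, prob = conf_mat[i, ]), "")
    rows[[r]] <- data.frame(
      sample_id = all_ids,
      rater_id = sprintf("rater_%d", r),
      category = rated,
      confidence = pmin(1, pmax(0, spec$confidence[[r]](length(all_ids)))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dup_map <- if (n_dup > 0)
    data.frame(original = ids[seq_len(n_dup)],
               duplicate = paste0(ids[seq_len(n_dup)], "_dup"),
               stringsAsFactors = FALSE)
  else data.frame(original = character(), duplicate = character())
  attr(out, "duplicate_map") <- dup_map
  out
}
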