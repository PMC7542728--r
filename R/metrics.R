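utils::globalVariables(c("chamber", "value", "model", "metric"))

# Segmentation quality metrics and the two-model comparison report:
# Dice coefficient, percent area variation, paired Wilcoxon signed-rank test,
# and median [IQR] summaries arranged per view x chamber x metric.

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; ranges from 0 (no overlap) to 1
#' (perfect agreement). Two empty masks are in perfect agreement (1).
#'
#' @param maskA,maskB Logical (or 0/1) matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    cs_abort("mask shapes differ", "cs_shape_error")
  a <- as.logical(maskA); b <- as.logical(maskB)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Percent area variation between predicted and ground-truth masks
#'
#' Absolute area difference divided by the ground-truth area:
#' `|area(pred) - area(truth)| / area(truth)`.
#'
#' @param pred,truth Logical (or 0/1) matrices of identical shape; `truth`
#'   must be non-empty.
#' @return Nonnegative scalar.
#' @export
percent_area_variation <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    cs_abort("mask shapes differ", "cs_shape_error")
  at <- sum(as.logical(truth))
  if (at == 0) cs_abort("ground-truth mask is empty; ratio undefined",
                        "cs_degenerate_error")
  abs(sum(as.logical(pred)) - at) / at
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped; absolute differences are ranked with average ranks for ties. With
#' at most `exact_max` non-zero differences and no ties, the exact signed-rank
#' distribution is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Equal-length numeric vectors of paired observations
#'   (length >= 6).
#' @param paired If `FALSE`, falls back to the unpaired rank-sum test via
#'   [stats::wilcox.test()].
#' @param exact_max Largest n for the exact branch (default 25).
#' @return List with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n` (non-zero pairs) and `method`.
#' @export
paired_wilcoxon <- function(x, y, paired = TRUE, exact_max = 25) {
  if (length(x) != length(y))
    cs_abort("x and y must have equal length", "cs_stat_error")
  if (length(x) < 6)
    cs_abort("at least 6 pairs are required", "cs_stat_error")
  if (!paired) {
    w <- stats::wilcox.test(x, y)
    return(list(statistic = unname(w$statistic), p_value = w$p.value,
                n = length(x), method = "rank_sum"))
  }
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) cs_abort("all paired differences are zero", "cs_degenerate_error")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    p <- 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    method <- "normal_approx"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation (R quantile type 7); the convention is
#' recorded in the result since published tables rarely state theirs.
#'
#' @param values Non-empty numeric vector.
#' @return A `summary_stat`: `median`, `q1`, `q3`, `n`, `convention`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) cs_abort("empty vector", "cs_stat_error")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(median = q[2], q1 = q[1], q3 = q[3], n = length(values),
                 convention = "linear interpolation (type 7)"),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.4g [%.4g-%.4g] (n=%d)\n", x$median, x$q1, x$q3, x$n))
  invisible(x)
}

#' Compare two segmentation models on a common held-out set
#'
#' Runs both models on every test frame, computes per-frame per-chamber Dice
#' and percent area variation against ground truth, and reports median [IQR]
#' per model with a paired Wilcoxon signed-rank p-value per chamber x metric —
#' the standard table shape for contrasting a synthetic-trained against a
#' directly trained network. Frames whose ground truth lacks a chamber are
#' excluded from that chamber's rows. Comparisons where every paired
#' difference is zero are flagged degenerate (`p_value = NA`).
#'
#' @param modelA,modelB Trained segmentation models ([train_unet()]).
#' @param test_pairs List of `list(frame, mask, view)` entries, disjoint from
#'   both models' training data (caller contract); at least 6 frames.
#' @param model_names Length-2 character; column labels for the two models.
#' @return A `comparison_report`: `table` (tibble with view, chamber, metric,
#'   medians/quartiles for both models, `p_value`, `n`, `degenerate`),
#'   `per_frame` (tidy per-frame values), and metadata.
#' @export
compare_training_sources <- function(modelA, modelB, test_pairs,
                                     model_names = c("model_a", "model_b")) {
  if (length(test_pairs) < 6)
    cs_abort("at least 6 test frames are required", "cs_stat_error")
  view <- toupper(test_pairs[[1]]$view %||% "SAX")
  chambers <- chambers_for_view(view)
  rows <- list()
  for (i in seq_along(test_pairs)) {
    tp <- test_pairs[[i]]
    predA <- predict_segmentation(modelA, tp$frame)
    predB <- predict_segmentation(modelB, tp$frame)
    truth <- chamber_masks(tp$mask, view)
    for (ch in chambers) {
      if (sum(truth[[ch]]) == 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        frame = i, chamber = ch,
        dice_a = dice_coefficient(predA[[ch]], truth[[ch]]),
        dice_b = dice_coefficient(predB[[ch]], truth[[ch]]),
        pav_a = percent_area_variation(predA[[ch]], truth[[ch]]),
        pav_b = percent_area_variation(predB[[ch]], truth[[ch]])
      )
    }
  }
  per_frame <- do.call(rbind, rows)
  tab <- list()
  for (metric in c("dice", "percent_variation")) {
    cols <- if (metric == "dice") c("dice_a", "dice_b") else c("pav_a", "pav_b")
    for (ch in chambers) {
      sub <- per_frame[per_frame$chamber == ch, ]
      if (nrow(sub) == 0) next
      va <- sub[[cols[1]]]; vb <- sub[[cols[2]]]
      sa <- median_iqr(va); sb <- median_iqr(vb)
      degen <- all(vb - va == 0)
      p <- if (degen) NA_real_ else
        tryCatch(paired_wilcoxon(va, vb)$p_value, cardiosynth_error = function(e) NA_real_)
      tab[[length(tab) + 1L]] <- tibble::tibble(
        view = view, chamber = ch, metric = metric,
        median_a = sa$median, q1_a = sa$q1, q3_a = sa$q3,
        median_b = sb$median, q1_b = sb$q1, q3_b = sb$q3,
        p_value = p, n = nrow(sub), degenerate = degen
      )
    }
  }
  structure(list(table = do.call(rbind, tab), per_frame = per_frame,
                 model_names = model_names, view = view,
                 quartile_convention = "linear interpolation (type 7)"),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s view; models: %s vs %s\n",
              x$view, x$model_names[1], x$model_names[2]))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Tidy a comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return The report's table as a tibble, one row per
#'   view x chamber x metric.
#' @export
tidy.comparison_report <- function(x, ...) x$table

#' @rdname tidy.comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  dice <- x$table[x$table$metric == "dice", ]
  tibble::tibble(
    view = x$view,
    n_frames = max(x$per_frame$frame),
    n_chambers = length(unique(x$table$chamber)),
    min_median_dice_a = min(dice$median_a),
    min_median_dice_b = min(dice$median_b),
    n_significant = sum(x$table$p_value < 0.05, na.rm = TRUE)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot per-frame metric distributions for a comparison report
#'
#' Boxplots of per-frame Dice and percent area variation per chamber for the
#' two models.
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.comparison_report <- function(object, ...) {
  pf <- object$per_frame
  long <- rbind(
    data.frame(chamber = pf$chamber, metric = "dice",
               model = object$model_names[1], value = pf$dice_a),
    data.frame(chamber = pf$chamber, metric = "dice",
               model = object$model_names[2], value = pf$dice_b),
    data.frame(chamber = pf$chamber, metric = "percent_variation",
               model = object$model_names[1], value = pf$pav_a),
    data.frame(chamber = pf$chamber, metric = "percent_variation",
               model = object$model_names[2], value = pf$pav_b)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = chamber, y = value, fill = model)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste(object$view, "segmentation accuracy")) +
    ggplot2::theme_minimal()
}
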