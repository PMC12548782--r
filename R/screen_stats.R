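#' Aggregate per-cell features to well summaries
#'
#' Computes per-well mean and median of every feature over QC-passing cells,
#' joined to a plate layout. Wells without a single unflagged cell are
#' dropped with a warning.
#'
#' @param cell_features data.frame with a `well` column, one row per cell;
#'   cells with `qc_pass == FALSE` or `feature_valid == FALSE` (when those
#'   columns are present) are excluded.
#' @param layout plate layout data.frame with columns `well`, `condition`
#'   and optionally `plate`, `replicate`, `control` (logical).
#' @param features character vector of feature columns; defaults to all
#'   numeric columns not used as identifiers.
#' @return long-format data.frame: `plate`, `well`, `condition`,
#'   `replicate`, `feature`, `mean`, `median`, `n_cells`.
#' @export
aggregate_wells <- function(cell_features, layout, features = NULL) {
  if (!"well" %in% names(cell_features))
    stop("cell_features needs a 'well' column", call. = FALSE)
  if (!all(c("well", "condition") %in% names(layout)))
    stop("layout needs 'well' and 'condition' columns", call. = FALSE)
  missing_wells <- setdiff(unique(cell_features$well), layout$well)
  if (length(missing_wells))
    stop(sprintf("wells not in layout: %s",
                 paste(missing_wells, collapse = ", ")), call. = FALSE)
  cf <- cell_features
  if ("qc_pass" %in% names(cf)) cf <- cf[cf$qc_pass %in% TRUE, ]
  if ("feature_valid" %in% names(cf)) cf <- cf[cf$feature_valid %in% TRUE, ]
  if (is.null(features)) {
    drop_cols <- c("well", "plate", "field", "label", "cell", "replicate",
                   "area_out_of_range", "border", "out_of_focus", "qc_pass",
                   "feature_valid", "focus_score")
    features <- names(cf)[vapply(cf, is.numeric, logical(1))]
    features <- setdiff(features, drop_cols)
  }
  if (!"plate" %in% names(layout)) layout$plate <- 1L
  if (!"replicate" %in% names(layout)) layout$replicate <- 1L

  empty <- setdiff(layout$well, unique(cf$well))
  if (length(empty) && any(layout$well %in% unique(cell_features$well) &
                           layout$well %in% empty))
    warning(sprintf("well(s) without unflagged cells dropped: %s",
                    paste(intersect(empty, unique(cell_features$well)),
                          collapse = ", ")))
  rows <- lapply(split(cf, cf$well), function(d) {
    w <- d$well[1L]
    lay <- layout[layout$well == w, ][1L, ]
    do.call(rbind, lapply(features, function(f) {
      v <- d[[f]][is.finite(d[[f]])]
      if (!length(v)) return(NULL)
      data.frame(plate = lay$plate, well = w, condition = lay$condition,
                 replicate = lay$replicate, feature = f,
                 mean = mean(v), median = stats::median(v),
                 n_cells = length(v))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Control-referenced Z-score matrix of a screen
#'
#' For every plate and feature, `Z = (well statistic - control mean) /
#' control SD` (SD with n-1 denominator) over that plate's control wells;
#' condition-level entries average the Z of the condition's wells, then
#' across plates. Entries where the control SD is zero are `NA` and listed
#' in the `flagged` attribute, never infinite.
#'
#' @param wells well summary table from [aggregate_wells()].
#' @param controls either a condition label identifying control wells, or a
#'   character vector of control well ids.
#' @param stat well statistic to score: `"mean"` or `"median"`.
#' @return A `ScreenMatrix`: numeric matrix (conditions x features) with
#'   attributes `controls`, `stat`, `flagged`.
#' @export
zscore_matrix <- function(wells, controls, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  w <- wells
  is_ctrl <- if (all(controls %in% w$condition)) w$condition %in% controls
             else w$well %in% controls
  if (!any(is_ctrl)) stop("no control wells found", call. = FALSE)
  w$is_ctrl <- is_ctrl
  conds <- unique(w$condition)
  feats <- unique(w$feature)
  plates <- unique(w$plate)
  acc <- array(NA_real_, c(length(conds), length(feats), length(plates)),
               dimnames = list(conds, feats, NULL))
  flagged <- character(0)
  for (pi in seq_along(plates)) {
    wp <- w[w$plate == plates[pi], ]
    for (f in feats) {
      ctrl_vals <- wp[[stat]][wp$feature == f & wp$is_ctrl]
      if (length(ctrl_vals) < 2L)
        stop(sprintf("need >= 2 control wells per plate (feature '%s')", f),
             call. = FALSE)
      mu <- mean(ctrl_vals); sdv <- stats::sd(ctrl_vals)
      for (cn in conds) {
        vals <- wp[[stat]][wp$feature == f & wp$condition == cn]
        if (!length(vals)) next
        if (sdv == 0) {
          flagged <- c(flagged, sprintf("%s/%s/plate %s", cn, f, plates[pi]))
          next
        }
        acc[cn, f, pi] <- mean((vals - mu) / sdv)
      }
    }
  }
  z <- apply(acc, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(z, controls = controls, stat = stat, flagged = unique(flagged),
            class = c("ScreenMatrix", "matrix", "array"))
}

#' Two-sample Student's t-test with significance stars
#'
#' Two-tailed t-test between replicate-level values of two conditions,
#' pooled-variance by default (`welch = TRUE` for the Welch variant). Stars
#' follow the thresholds `*` p < 0.05, `**` p < 0.01, `***` p < 0.005;
#' `"n.s."` otherwise.
#'
#' @param group_a,group_b numeric vectors of replicate values (each n >= 2).
#' @param welch use the Welch unequal-variance test.
#' @return data.frame with `t`, `df`, `p`, `stars`.
#' @export
ttest_conditions <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    # degenerate: no within-group variance
    if (mean(group_a) == mean(group_b)) {
      t <- 0; p <- 1; df <- length(group_a) + length(group_b) - 2L
    } else {
      t <- sign(mean(group_a) - mean(group_b)) * Inf; p <- 0
      df <- length(group_a) + length(group_b) - 2L
    }
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = !welch)
    t <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  data.frame(t = t, df = df, p = p, stars = significance_stars(p))
}

#' @rdname ttest_conditions
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.005, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' Hierarchical clustering of condition profiles
#'
#' Agglomerative clustering of the rows of a Z-score matrix, by default with
#' correlation distance (1 - Pearson) and average linkage. Rows containing
#' undefined entries are dropped (`na_action = "drop"`) or imputed with the
#' feature mean (`"impute"`). The leaf order is the deterministic
#' `stats::hclust` order for the given row order.
#'
#' @param mat `ScreenMatrix` or plain numeric matrix (rows = conditions).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage agglomeration method, default `"average"`.
#' @param na_action `"drop"` or `"impute"`.
#' @return list with `hclust`, `order` (leaf labels left to right),
#'   `newick` (the dendrogram as a Newick string), `distance`, `linkage`.
#' @export
cluster_profiles <- function(mat, distance = c("correlation", "euclidean"),
                             linkage = "average",
                             na_action = c("drop", "impute")) {
  distance <- match.arg(distance)
  na_action <- match.arg(na_action)
  m <- unclass(mat)
  attr(m, "controls") <- attr(m, "stat") <- attr(m, "flagged") <- NULL
  if (anyNA(m)) {
    if (na_action == "drop") m <- m[stats::complete.cases(m), , drop = FALSE]
    else for (j in seq_len(ncol(m)))
      m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  if (nrow(m) < 1L) stop("no complete rows to cluster", call. = FALSE)
  if (nrow(m) == 1L) {
    return(list(hclust = NULL, order = rownames(m),
                newick = sprintf("(%s);", rownames(m)),
                distance = distance, linkage = linkage))
  }
  d <- if (distance == "correlation") {
    if (ncol(m) < 2L)
      stop("correlation distance needs >= 2 features", call. = FALSE)
    stats::as.dist(1 - stats::cor(t(m)))
  } else stats::dist(m)
  d[d < 0] <- 0
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order],
       newick = ape::write.tree(phy), distance = distance, linkage = linkage)
}

#' Single-cell feature-vs-feature linear regression
#'
#' Ordinary least squares of one per-cell feature on another, with the
#' Pearson correlation and its p-value — the single-cell dot-plot regression
#' used to relate, e.g., translation activity to the ER expansion ratio.
#'
#' @param x,y numeric vectors of per-cell values (paired; NA pairs dropped).
#' @return data.frame with `slope`, `intercept`, `r`, `p`, `n`, `flagged`
#'   (TRUE when x or y is constant and r is undefined).
#' @export
single_cell_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired cells", call. = FALSE)
  if (stats::sd(x) == 0)
    return(data.frame(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                      p = NA_real_, n = length(x), flagged = TRUE))
  fit <- stats::lm(y ~ x)
  if (stats::sd(y) == 0)
    return(data.frame(slope = 0, intercept = mean(y), r = NA_real_,
                      p = NA_real_, n = length(x), flagged = TRUE))
  ct <- stats::cor.test(x, y)
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             r = unname(ct$estimate), p = ct$p.value, n = length(x),
             flagged = FALSE)
}
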