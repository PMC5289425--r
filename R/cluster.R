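#' Row-normalize a response matrix
#'
#' Each row is centered by its mean and scaled by its sample standard
#' deviation (n - 1 convention). Zero-variance rows cannot be normalized;
#' they are dropped with a warning and listed in the `dropped` attribute.
#' The operation is idempotent.
#'
#' @param mat numeric matrix (rows: entities, columns: observations),
#'   >= 2 columns.
#' @return the normalized matrix with attribute `dropped`.
#' @export
normalize_rows <- function(mat) {
  assert_that(is.matrix(mat) && ncol(mat) >= 2,
              "need a matrix with at least 2 columns")
  sds <- apply(mat, 1, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (all(drop)) stop_config("all rows have zero variance")
  if (any(drop))
    warning(sprintf("dropped %d constant row(s): %s", sum(drop),
                    paste(utils::head(rownames(mat)[drop], 5),
                          collapse = ", ")), call. = FALSE)
  kept <- mat[!drop, , drop = FALSE]
  out <- t(scale(t(kept)))
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- rownames(mat)[drop]
  out
}

#' Ward hierarchical clustering of a response matrix
#'
#' Agglomerative clustering with Ward's minimum variance criterion
#' (`ward.D2` on unsquared Euclidean distances by default) along the
#' chosen axis, cut into `k` groups. The dendrogram can be exported as a
#' Newick string.
#'
#' @param mat numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @param k number of groups to cut, <= number of items.
#' @param method linkage passed to [stats::hclust()]; default `"ward.D2"`.
#' @return list with `tree` (hclust), `labels` (named cluster ids) and
#'   `newick` (character).
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns"), k = 2,
                                 method = "ward.D2") {
  axis <- match.arg(axis)
  x <- if (axis == "columns") t(mat) else mat
  assert_that(k <= nrow(x), "k (%d) exceeds item count (%d)", k, nrow(x))
  d <- stats::dist(x, method = "euclidean")
  tree <- stats::hclust(d, method = method)
  labels <- stats::cutree(tree, k = k)
  list(tree = tree, labels = labels, newick = hclust_to_newick(tree))
}

#' Convert an hclust tree to Newick format
#'
#' @param tree an [stats::hclust()] object.
#' @return single Newick string with merge heights as branch lengths.
#' @export
hclust_to_newick <- function(tree) {
  lab <- tree$labels %||% as.character(seq_along(tree$order))
  node <- function(i, parent_h) {
    if (i < 0) {  # leaf
      sprintf("%s:%.6g", gsub("[,():;]", "_", lab[-i]), parent_h)
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%.6g",
              node(tree$merge[i, 1], h), node(tree$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- length(tree$height)
  h <- tree$height[n]
  paste0("(", node(tree$merge[n, 1], h), ",",
         node(tree$merge[n, 2], h), ");")
}

#' Principal component analysis of a response matrix
#'
#' Column-centered PCA over the observations (rows of the input are
#' entities; observations are columns, transposed internally so each
#' observation is a point). Explained-variance fractions are
#' non-increasing and sum to 1.
#'
#' @param mat numeric matrix (entities x observations).
#' @param observations `"columns"` (default) or `"rows"`.
#' @return list with `scores` (observations x components) and
#'   `explained_variance_fractions`.
#' @export
run_pca <- function(mat, observations = c("columns", "rows")) {
  observations <- match.arg(observations)
  x <- if (observations == "columns") t(mat) else mat
  assert_that(nrow(x) >= 2, "need at least 2 observations")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  assert_that(sum(v) > 0, "rank-0 input")
  list(scores = p$x, explained_variance_fractions = v / sum(v))
}

#' Two-sample comparison of drug groups
#'
#' Student two-sample t-test with pooled variance (Welch by option) on a
#' per-drug scalar variable, reporting the t statistic, raw p, the
#' 95 percent confidence interval of mean(group_a) - mean(group_b), and
#' optionally Benjamini-Hochberg adjustment over a declared family of
#' comparisons.
#'
#' @param values named numeric vector (names: drugs).
#' @param group_a,group_b disjoint, non-empty drug vectors (>= 2 each).
#' @param variable label for the compared variable.
#' @param welch use the Welch (unequal variance) test.
#' @return an object of class `group_comparison` (one-row data.frame with
#'   `variable`, `t`, `df`, `p_raw`, `ci_lo`, `ci_hi`, `mean_a`,
#'   `mean_b`).
#' @export
compare_groups <- function(values, group_a, group_b, variable = "value",
                           welch = FALSE) {
  assert_that(length(intersect(group_a, group_b)) == 0,
              "groups must be disjoint")
  a <- values[group_a]; b <- values[group_b]
  assert_that(length(a) >= 2 && length(b) >= 2 && !anyNA(a) && !anyNA(b),
              "each group needs >= 2 non-missing values")
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
    stop_config("zero pooled variance; comparison undefined")
  tt <- stats::t.test(a, b, var.equal = !welch)
  out <- data.frame(variable = variable,
                    t = unname(tt$statistic), df = unname(tt$parameter),
                    p_raw = tt$p.value,
                    ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                    mean_a = mean(a), mean_b = mean(b),
                    stringsAsFactors = FALSE)
  structure(out, class = c("group_comparison", "data.frame"))
}

#' Benjamini-Hochberg adjustment over a family of group comparisons
#'
#' @param comparisons list of [compare_groups()] results (or a data.frame
#'   with a `p_raw` column).
#' @return single data.frame with a `p_adjusted` column appended.
#' @export
adjust_comparisons <- function(comparisons) {
  df <- if (is.data.frame(comparisons)) comparisons
        else do.call(rbind, comparisons)
  df$p_adjusted <- stats::p.adjust(df$p_raw, method = "BH")
  df
}
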