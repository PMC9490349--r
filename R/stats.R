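#' Descriptive statistics block
#'
#' Minimum, maximum, mean and sample standard deviation (n - 1 denominator),
#' the summary block conventional for assemblage tables. Accepts a bare
#' numeric vector or a data frame plus column (and optional grouping).
#'
#' @param x numeric vector or data frame.
#' @param var unquoted column name when `x` is a data frame.
#' @param by optional unquoted grouping column.
#' @param na.rm drop missing values (row-wise exclusion); excluded counts
#'   are reported in the `n_missing` column.
#' @return a tibble with columns `n`, `n_missing`, `min`, `max`, `mean`,
#'   `sd` (one row per group).
#' @export
describe_distribution <- function(x, var = NULL, by = NULL, na.rm = TRUE) {
  one <- function(v) {
    miss <- sum(is.na(v))
    if (na.rm) v <- v[!is.na(v)]
    if (length(v) == 0)
      abort("no values to describe", class = "percussr_parameter")
    tibble::tibble(
      n = length(v), n_missing = miss,
      min = min(v), max = max(v), mean = mean(v),
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_
    )
  }
  if (is.data.frame(x)) {
    var <- enquo(var)
    by <- enquo(by)
    if (quo_is_null(var)) abort("supply `var` for data-frame input")
    vals <- eval_tidy(var, x)
    if (quo_is_null(by)) return(one(vals))
    g <- eval_tidy(by, x)
    out <- lapply(split(vals, g), one)
    return(dplyr::bind_cols(
      tibble::tibble(group = names(out)),
      dplyr::bind_rows(out)
    ))
  }
  one(x)
}

# rank-based helpers ---------------------------------------------------------

tie_sizes <- function(r) {
  tab <- table(r)
  as.numeric(tab[tab > 1])
}

new_percussr_test <- function(method, statistic, p.value, df = NA_integer_,
                              groups = NULL, n = NULL, correction = "none",
                              alpha = 0.05, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, df = df,
           p.value = p.value, groups = groups, n = n,
           correction = correction, alpha = alpha), extra),
    class = "percussr_test"
  )
}

#' @export
print.percussr_test <- function(x, ...) {
  cat(sprintf("<%s>\n", x$method))
  st <- paste(names(x$statistic), "=", formatC(x$statistic, digits = 4,
                                               format = "g"))
  cat("  ", paste(st, collapse = ", "),
      if (!is.na(x$df)) sprintf(", df = %d", x$df) else "",
      sprintf(", p = %.4g", x$p.value), "\n", sep = "")
  if (!is.null(x$n))
    cat("  n: ", paste(names(x$n), x$n, sep = " = ", collapse = ", "), "\n",
        sep = "")
  if (isTRUE(x$exact)) cat("  exact p by enumeration\n")
  invisible(x)
}

#' @export
tidy.percussr_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = unname(x$statistic[1]),
    statistic_name = names(x$statistic)[1],
    df = x$df,
    p.value = x$p.value,
    exact = isTRUE(x$exact),
    correction = x$correction
  )
}

#' @export
glance.percussr_test <- function(x, ...) tidy(x, ...)

resolve_two_groups <- function(x, y, var, group) {
  if (is.data.frame(x)) {
    var <- enquo(var); group <- enquo(group)
    if (quo_is_null(var) || quo_is_null(group))
      abort("supply `var` and `group` for data-frame input")
    v <- eval_tidy(var, x)
    g <- as.character(eval_tidy(group, x))
    keep <- !is.na(v) & !is.na(g)
    v <- v[keep]; g <- g[keep]
    lev <- unique(g)
    if (length(lev) != 2)
      abort("grouping column must have exactly 2 levels")
    list(a = v[g == lev[1]], b = v[g == lev[2]], labels = lev)
  } else {
    list(a = x[!is.na(x)], b = y[!is.na(y)], labels = c("a", "b"))
  }
}

#' Mann-Whitney U test
#'
#' Two-sample rank test. The reported statistic is `U = min(U1, U2)` (both
#' orientations are kept in the result). The two-sided p-value is exact —
#' by full enumeration of the permutation distribution of U — when the
#' pooled sample size is at most 12 and there are no ties, and otherwise
#' uses the normal approximation with tie-corrected variance and a
#' continuity correction. `exact` can force either path (forcing exact with
#' ties yields the conditional permutation p-value).
#'
#' @param x numeric vector (first sample) or a data frame.
#' @param y numeric vector (second sample) when `x` is a vector.
#' @param var,group unquoted value/group columns for data-frame input.
#' @param exact logical or `NULL` (auto rule above).
#' @return a `percussr_test` with statistic `U`, fields `u1`, `u2`, `z`
#'   (NA when exact) and `exact`.
#' @export
mann_whitney_u <- function(x, y = NULL, var = NULL, group = NULL,
                           exact = NULL) {
  gg <- resolve_two_groups(x, y, {{ var }}, {{ group }})
  a <- gg$a; b <- gg$b
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1)
    abort("both samples must be non-empty", class = "percussr_parameter")
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- any(duplicated(pooled))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  mid <- n1 * n2 / 2
  if (is.null(exact)) exact <- (n1 + n2) <= 12 && !ties
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    uperm <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(uperm - mid) >= abs(u1 - mid) - 1e-9)
    z <- NA_real_
  } else {
    N <- n1 + n2
    ts <- tie_sizes(pooled)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ts^3 - ts) / (N * (N - 1)))
    if (sigma2 <= 0)
      abort("all values identical; test degenerate",
            class = "percussr_degenerate")
    cc <- if (u1 == mid) 0 else 0.5 * sign(u1 - mid)
    z <- (u1 - mid - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_percussr_test(
    "mann_whitney_u", c(U = u), p,
    groups = setNames(c(n1, n2), gg$labels),
    n = setNames(c(n1, n2), gg$labels),
    extra = list(u1 = u1, u2 = u2, z = z, exact = exact, ties = ties)
  )
}

resolve_k_groups <- function(x, g, var, group) {
  if (is.data.frame(x)) {
    var <- enquo(var); group <- enquo(group)
    if (quo_is_null(var) || quo_is_null(group))
      abort("supply `var` and `group` for data-frame input")
    v <- eval_tidy(var, x)
    gg <- as.character(eval_tidy(group, x))
  } else if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x))) names(x) <- paste0("g", seq_along(x))
    v <- unlist(x, use.names = FALSE)
    gg <- rep(names(x), lengths(x))
  } else {
    v <- x
    gg <- as.character(g)
  }
  keep <- !is.na(v) & !is.na(gg)
  split(v[keep], gg[keep])
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction, chi-squared reference distribution on
#' k - 1 degrees of freedom.
#'
#' @param x numeric vector, list of numeric vectors (one per group), or a
#'   data frame.
#' @param g group labels when `x` is a vector.
#' @param var,group unquoted columns for data-frame input.
#' @return a `percussr_test` with statistic `H` and `df`.
#' @export
kruskal_wallis <- function(x, g = NULL, var = NULL, group = NULL) {
  grp <- resolve_k_groups(x, g, {{ var }}, {{ group }})
  k <- length(grp)
  if (k < 2) abort("need at least 2 groups", class = "percussr_parameter")
  v <- unlist(grp, use.names = FALSE)
  N <- length(v)
  if (N < 3) abort("need at least 3 observations", class = "percussr_parameter")
  r <- rank(v)
  gidx <- rep(seq_len(k), lengths(grp))
  Ri <- tapply(r, gidx, sum)
  ni <- lengths(grp)
  H0 <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ts <- tie_sizes(v)
  corr <- 1 - sum(ts^3 - ts) / (N^3 - N)
  if (corr <= 0)
    abort("all values identical; test degenerate",
          class = "percussr_degenerate")
  H <- H0 / corr
  df <- k - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  new_percussr_test("kruskal_wallis", c(H = H), p, df = as.integer(df),
                    groups = setNames(ni, names(grp)),
                    n = setNames(ni, names(grp)))
}

#' Dunn's post hoc test
#'
#' Pairwise follow-up to a Kruskal-Wallis test using the pooled-rank z
#' statistic with tie-corrected variance; p-values are two-sided and
#' Bonferroni-adjusted over the k(k-1)/2 comparisons by default.
#'
#' @param x,g,var,group as in [kruskal_wallis()]; needs >= 3 groups (with
#'   two groups use [mann_whitney_u()]).
#' @param correction `"bonferroni"` or `"none"`.
#' @return a tibble of class `dunn_posthoc`: one row per pair with `z`,
#'   `p.value`, `p.adj`.
#' @export
dunn_posthoc <- function(x, g = NULL, var = NULL, group = NULL,
                         correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  grp <- resolve_k_groups(x, g, {{ var }}, {{ group }})
  k <- length(grp)
  if (k < 3)
    abort("Dunn's test needs >= 3 groups (use mann_whitney_u for 2)",
          class = "percussr_parameter")
  v <- unlist(grp, use.names = FALSE)
  N <- length(v)
  r <- rank(v)
  gidx <- rep(seq_len(k), lengths(grp))
  rbar <- tapply(r, gidx, mean)
  ni <- lengths(grp)
  ts <- tie_sizes(v)
  s2 <- N * (N + 1) / 12 - sum(ts^3 - ts) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(s2 * (1 / ni[i1] + 1 / ni[i2]))
    z <- (rbar[i1] - rbar[i2]) / se
    tibble::tibble(
      group1 = names(grp)[i1], group2 = names(grp)[i2],
      n1 = ni[i1], n2 = ni[i2], z = unname(z),
      p.value = 2 * stats::pnorm(-abs(unname(z)))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p.adj <- stats::p.adjust(out$p.value, method =
                                 if (correction == "bonferroni") "bonferroni"
                               else "none")
  attr(out, "correction") <- correction
  attr(out, "alpha") <- 0.05
  class(out) <- c("dunn_posthoc", class(out))
  out
}

#' @export
tidy.dunn_posthoc <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("group1", "group2", "n1", "n2", "z",
                                 "p.value", "p.adj")])
}

#' Principal component analysis of assemblage measures
#'
#' PCA on the correlation matrix by default: the assemblage variable set
#' mixes counts, percentages and millimetres, so variables are standardized
#' to unit variance (set `standardize = FALSE` for covariance PCA).
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive. Rows with missing values are dropped and counted.
#'
#' @param data data frame of observations x variables.
#' @param variables character vector of numeric columns to use; default all
#'   numeric columns.
#' @param standardize scale variables to unit variance?
#' @param group optional unquoted column carried into the scores.
#' @return an object of class `percussr_pca`: `scores` (tibble),
#'   `loadings` (matrix), `percent_variance`, `sdev`, `n_dropped`.
#' @export
run_pca <- function(data, variables = NULL, standardize = TRUE,
                    group = NULL) {
  stopifnot(is.data.frame(data))
  group <- enquo(group)
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, TRUE)]
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("missing variable column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "percussr_schema")
  x <- as.matrix(data[, variables, drop = FALSE])
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values dropped from PCA")
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3) abort("PCA needs >= 3 complete observations",
                         class = "percussr_parameter")
  if (length(variables) < 2) abort("PCA needs >= 2 variables",
                                   class = "percussr_parameter")
  vars0 <- apply(x, 2, stats::var)
  if (standardize && any(vars0 == 0))
    abort(paste0("zero-variance variable under standardization: ",
                 paste(variables[vars0 == 0], collapse = ", ")),
          class = "percussr_degenerate")
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  if (!quo_is_null(group)) {
    gvals <- eval_tidy(group, data)[keep]
    scores <- dplyr::bind_cols(tibble::tibble(group = gvals), scores)
  }
  structure(
    list(scores = scores, loadings = pc$rotation,
         percent_variance = pct, sdev = pc$sdev,
         variables = variables, standardize = standardize,
         n_dropped = n_dropped),
    class = "percussr_pca"
  )
}

#' @export
print.percussr_pca <- function(x, ...) {
  cat(sprintf("<percussr_pca> %d components over %d variables\n",
              length(x$percent_variance), length(x$variables)))
  cat("  % variance:",
      paste(sprintf("PC%d %.1f", seq_along(x$percent_variance),
                    x$percent_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.percussr_pca <- function(x, ...) {
  ld <- x$loadings
  tibble::tibble(
    variable = rep(rownames(ld), ncol(ld)),
    component = rep(colnames(ld), each = nrow(ld)),
    loading = as.vector(ld)
  )
}

#' @export
glance.percussr_pca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$loadings),
    sdev = x$sdev,
    percent_variance = x$percent_variance,
    cumulative_percent = cumsum(x$percent_variance)
  )
}

#' The standard per-tool use-wear comparison variables
#'
#' The nine spatial-patterning measures compared between assemblages:
#' number of discrete use-wear areas, PA, pit density, and the min/mean/max
#' of DAC and DAE.
#' @return character vector of column names.
#' @export
comparison_variables <- function() {
  c("n_discrete_use_wear", "pa_percent", "density_per_cm2",
    "dac_mean_mm", "dac_min_mm", "dac_max_mm",
    "dae_mean_mm", "dae_min_mm", "dae_max_mm")
}

#' Compare two assemblages of per-tool use-wear summaries
#'
#' Runs one Mann-Whitney U test per comparison variable (rows missing that
#' variable are excluded pairwise) and a pooled PCA over all rows with the
#' assemblage label carried into the scores.
#'
#' @param table_a,table_b per-tool summary tables (e.g. from
#'   [planform_summary()] rows or [generate_assemblage()]).
#' @param variables columns to test; default [comparison_variables()].
#' @param labels length-2 labels for the two assemblages.
#' @param alpha significance level for flagging.
#' @return an object of class `assemblage_comparison`: `tests` (tibble with
#'   `measure`, `U`, `p.value`, `significant`), `pca` (a `percussr_pca`).
#' @export
compare_assemblages <- function(table_a, table_b,
                                variables = comparison_variables(),
                                labels = c("A", "B"), alpha = 0.05) {
  if (!is.data.frame(table_a) || nrow(table_a) == 0 ||
      !is.data.frame(table_b) || nrow(table_b) == 0)
    abort("both assemblage tables must be non-empty data frames",
          class = "percussr_parameter")
  for (tb in list(table_a, table_b)) {
    missing_cols <- setdiff(variables, names(tb))
    if (length(missing_cols) > 0)
      abort(paste0("missing variable column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "percussr_schema")
  }
  tests <- lapply(variables, function(v) {
    a <- table_a[[v]][!is.na(table_a[[v]])]
    b <- table_b[[v]][!is.na(table_b[[v]])]
    tt <- mann_whitney_u(a, b)
    tibble::tibble(
      measure = v, n_a = length(a), n_b = length(b),
      U = unname(tt$statistic), p.value = tt$p.value,
      exact = isTRUE(tt$exact),
      significant = tt$p.value < alpha
    )
  })
  tests <- dplyr::bind_rows(tests)
  pooled <- dplyr::bind_rows(
    dplyr::mutate(table_a[, variables, drop = FALSE],
                  assemblage = labels[1]),
    dplyr::mutate(table_b[, variables, drop = FALSE],
                  assemblage = labels[2])
  )
  pca <- run_pca(pooled, variables = variables, group = assemblage)
  structure(
    list(tests = tests, pca = pca, labels = labels, alpha = alpha),
    class = "assemblage_comparison"
  )
}

#' @export
print.assemblage_comparison <- function(x, ...) {
  cat(sprintf("<assemblage_comparison> %s vs %s (alpha = %g)\n",
              x$labels[1], x$labels[2], x$alpha))
  print(as.data.frame(x$tests), row.names = FALSE)
  cat(sprintf("PCA: PC1+PC2 explain %.2f%% of variance\n",
              sum(x$pca$percent_variance[1:2])))
  invisible(x)
}

#' @export
tidy.assemblage_comparison <- function(x, ...) x$tests
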