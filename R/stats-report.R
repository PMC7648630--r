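#' Welch two-sample t test (unequal variances)
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-tailed p
#' from the t distribution — the "row analyzed individually, without
#' assuming a consistent SD" test. Degenerate rows where both groups have
#' zero variance follow a stated convention: equal means give t = 0, p = 1;
#' unequal means are exact separation (t = +/-Inf, p = 0) and are flagged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `exact_separation` (logical).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_validation("each group needs >= 2 values")
  }
  if (anyNA(a) || anyNA(b)) stop_validation("NA values not allowed")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      return(list(t = 0, df = na + nb - 2, p = 1, mean_a = ma, mean_b = mb,
                  sd_a = 0, sd_b = 0, exact_separation = FALSE))
    }
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p = 0,
                mean_a = ma, mean_b = mb, sd_a = 0, sd_b = 0,
                exact_separation = TRUE))
  }
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(t = tstat, df = df, p = p, mean_a = ma, mean_b = mb,
       sd_a = sqrt(va), sd_b = sqrt(vb), exact_separation = FALSE)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' P values are sorted ascending; hypothesis i (in sort order, m tests in
#' total) is rejected iff `p_(i) <= 1 - (1 - alpha)^(1/(m - i + 1))` and all
#' earlier hypotheses were rejected. Adjusted p values are the running
#' maximum of `1 - (1 - p_(i))^(m - i + 1)`, clipped to \[0, 1\], reported
#' in the input order.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @param alpha family-wise error rate, default 0.05.
#' @return List: `significant` (logical, input order), `p_adjusted`
#'   (numeric, input order), `alpha`.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_validation("p values must lie in [0, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must be in (0, 1)")
  }
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  k <- m - seq_len(m) + 1  # remaining hypotheses at each step
  crit <- 1 - (1 - alpha)^(1 / k)
  step_ok <- ps <= crit
  # step-down: stop at the first acceptance
  rej_sorted <- cumprod(step_ok) == 1
  adj_sorted <- pmin(cummax(1 - (1 - ps)^k), 1)
  significant <- logical(m); p_adj <- numeric(m)
  significant[ord] <- rej_sorted
  p_adj[ord] <- adj_sorted
  list(significant = significant, p_adjusted = p_adj, alpha = alpha)
}

#' Two-group comparison report over measurement rows
#'
#' Runs a Welch t test per row and the Holm-Sidak step-down correction
#' across rows, reporting group means with SD — the multiple-t-test group
#' comparison used for MLI/AST readouts.
#'
#' @param data either a named list of `list(a = values, b = values)` rows,
#'   or a long data frame with row-label, group and value columns (exactly
#'   two group levels).
#' @param alpha family-wise error rate, default 0.05.
#' @param row_col,group_col,value_col column names for the data-frame input.
#' @param groups optional length-2 character vector fixing which group is A
#'   and which is B (defaults to sorted unique levels).
#' @return A `test_report` data frame: `row`, `t`, `df`, `p`, `p_adj`,
#'   `significant`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `n_a`, `n_b`, with
#'   attributes `alpha`, `groups`, `method`.
#' @export
compare_groups <- function(data, alpha = 0.05, row_col = "row",
                           group_col = "group", value_col = "value",
                           groups = NULL) {
  if (is.data.frame(data)) {
    for (cn in c(row_col, group_col, value_col)) {
      if (!cn %in% names(data)) stop_validation("missing column: ", cn)
    }
    lv <- if (is.null(groups)) sort(unique(as.character(data[[group_col]])))
          else groups
    if (length(lv) != 2L) {
      stop_validation("exactly two groups required, got: ",
                      paste(lv, collapse = ", "))
    }
    labels <- unique(as.character(data[[row_col]]))
    rows <- lapply(labels, function(lab) {
      d <- data[data[[row_col]] == lab, ]
      list(a = d[[value_col]][d[[group_col]] == lv[1L]],
           b = d[[value_col]][d[[group_col]] == lv[2L]])
    })
    names(rows) <- labels
  } else {
    rows <- data
    lv <- c("a", "b")
    if (is.null(names(rows)) || anyDuplicated(names(rows))) {
      stop_validation("rows must be uniquely named")
    }
  }
  tests <- lapply(rows, function(r) welch_t(r$a, r$b))
  hs <- holm_sidak(vapply(tests, `[[`, 0, "p"), alpha = alpha)
  out <- data.frame(
    row = names(rows),
    t = vapply(tests, `[[`, 0, "t"),
    df = vapply(tests, `[[`, 0, "df"),
    p = vapply(tests, `[[`, 0, "p"),
    p_adj = hs$p_adjusted,
    significant = hs$significant,
    mean_a = vapply(tests, `[[`, 0, "mean_a"),
    sd_a = vapply(tests, `[[`, 0, "sd_a"),
    mean_b = vapply(tests, `[[`, 0, "mean_b"),
    sd_b = vapply(tests, `[[`, 0, "sd_b"),
    n_a = vapply(rows, function(r) length(r$a), 0L),
    n_b = vapply(rows, function(r) length(r$b), 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- lv
  attr(out, "method") <- "Welch t, Holm-Sidak step-down"
  class(out) <- c("test_report", "data.frame")
  out
}
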