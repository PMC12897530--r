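#' Per-participant behavioral summaries
#'
#' Arithmetic means of the three response channels across all partners
#' (the "Ave" behavioral variables used in the behavior-level biomarker
#' screen).
#'
#' @param behavior Validated behavior table.
#' @return Data frame `participant_id, ave_attractiveness,
#'   ave_trustworthiness, ave_amount` (plus `group` when present).
#' @export
behavior_summaries <- function(behavior) {
  if (nrow(behavior) == 0) stop("empty dataset", call. = FALSE)
  blocks <- split_participants(behavior)
  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(participant_id = as.character(b$participant_id[1]),
               group = if (!is.null(b$group)) as.character(b$group[1])
                       else NA_character_,
               ave_attractiveness = mean(b$attractiveness),
               ave_trustworthiness = mean(b$trustworthiness),
               ave_amount = mean(b$amount))
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (`stats::p.adjust(method = "BH")`):
#' order-preserving, monotone, capped at 1. `NA` entries pass through
#' as `NA` and do not count toward the family size.
#'
#' @param p P-values in `[0, 1]`.
#' @return Q-values aligned with the input.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Correlation screen between two participant-level tables
#'
#' One correlation per (x variable, metabolite) pair, computed on
#' pairwise-complete observations, with two-sided p-values and BH
#' q-values assigned across the full pair grid of the screen. Pairs
#' with fewer than `min_n` complete observations are reported with
#' missing `r`/`p` and excluded from the FDR family.
#'
#' @param x_table Data frame: `participant_id` plus numeric variable
#'   columns (behavior summaries or parameter estimates).
#' @param y_table Biomarker data frame: `participant_id` plus numeric
#'   metabolite columns.
#' @param method `"pearson"` or `"spearman"`.
#' @param fdr_level Significance level on q.
#' @param min_n Minimum complete pairs per correlation.
#' @return Data frame `x_name, y_name, method, n, r, p, q, significant`.
#' @export
correlate <- function(x_table, y_table, method = c("pearson", "spearman"),
                      fdr_level = 0.05, min_n = 3) {
  method <- match.arg(method)
  shared <- intersect(as.character(x_table$participant_id),
                      as.character(y_table$participant_id))
  if (length(shared) < min_n)
    stop("fewer than ", min_n, " overlapping participants", call. = FALSE)
  xi <- x_table[match(shared, as.character(x_table$participant_id)), ]
  yi <- y_table[match(shared, as.character(y_table$participant_id)), ]
  x_vars <- setdiff(names(xi)[vapply(xi, is.numeric, TRUE)], "participant_id")
  y_vars <- setdiff(names(yi)[vapply(yi, is.numeric, TRUE)], "participant_id")

  grid <- expand.grid(x_name = x_vars, y_name = y_vars,
                      stringsAsFactors = FALSE)
  nk <- rk <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    x <- xi[[grid$x_name[k]]]
    y <- yi[[grid$y_name[k]]]
    keep <- is.finite(x) & is.finite(y)
    nk[k] <- sum(keep)
    if (nk[k] < min_n) next
    x <- x[keep]; y <- y[keep]
    if (sd(x) == 0 || sd(y) == 0) next
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    rk[k] <- cor(x, y)  # Pearson on ranks = tie-corrected Spearman rho
  }
  # two-sided p via the t-approximation: t = r * sqrt((n-2)/(1-r^2))
  pk <- rep(NA_real_, nrow(grid))
  ok <- !is.na(rk) & nk > 2
  tstat <- rk[ok] * sqrt((nk[ok] - 2) / pmax(1 - rk[ok]^2, 1e-300))
  pk[ok] <- 2 * stats::pt(-abs(tstat), df = nk[ok] - 2)
  out <- data.frame(x_name = grid$x_name, y_name = grid$y_name,
                    method = method, n = as.integer(nk), r = rk, p = pk)
  out$q <- bh_fdr(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr_level
  out
}

# Two-sided rank-sum test. Small groups (both <= max_exact) get an
# exact permutation p-value by complete enumeration of splits, which is
# valid under ties; larger samples use the normal approximation with
# tie correction. The statistic is the Mann-Whitney U for x.
rank_sum_test <- function(x, y, max_exact = 10) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= max_exact && n2 <= max_exact) {
    idx <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(r[idx], nrow = n1))
    mu <- n1 * (n1 + n2 + 1) / 2
    w_obs <- sum(r[seq_len(n1)])
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                  correct = TRUE)$p.value)
  }
  list(statistic = U, p_value = p)
}

#' Two-group comparison of a participant-level variable
#'
#' Two-sided test of group difference. `"wilcoxon_rank_sum"` and
#' `"mann_whitney_u"` are the same rank-sum procedure exposed under
#' both names; `"welch_t"` is the unequal-variance t-test.
#'
#' @param values Numeric per-participant values.
#' @param groups Two-level group labels aligned with `values`.
#' @param test Test name.
#' @return List `statistic`, `p_value`, `test`.
#' @export
group_compare <- function(values, groups,
                          test = c("wilcoxon_rank_sum", "welch_t",
                                   "mann_whitney_u")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("need exactly two groups", call. = FALSE)
  x <- values[groups == lv[1]]
  y <- values[groups == lv[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 members", call. = FALSE)
  if (test == "welch_t") {
    if (sd(x) == 0 && sd(y) == 0)
      stop("degenerate groups: zero variance in both", call. = FALSE)
    ht <- t.test(x, y, var.equal = FALSE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                test = test))
  }
  rs <- rank_sum_test(x, y)
  list(statistic = rs$statistic, p_value = rs$p_value, test = test)
}

#' Per-partner group test on latent evaluations
#'
#' For every photographed partner, compares the HC and MDD
#' distributions of the latent evaluation E_ij with a two-sided
#' Mann-Whitney U test, and counts the partners significant at `alpha`.
#' Evaluations are supplied as a participants x partners matrix
#' (posterior means from full-data fits, or the generator's ground
#' truth on synthetic cohorts).
#'
#' @param evaluations Numeric matrix, participants in rows (rownames =
#'   participant ids), partners in columns.
#' @param groups Named or aligned group labels (two levels).
#' @param alpha Per-partner significance line.
#' @return List: `per_partner` (data frame `partner_id, U, p`),
#'   `n_significant`, `n_partners`, `cumulative` (sorted p-values for
#'   cumulative-distribution plots).
#' @export
per_partner_evaluation_test <- function(evaluations, groups, alpha = 0.05) {
  if (anyNA(evaluations))
    stop("every participant needs an evaluation for every partner",
         call. = FALSE)
  if (!is.null(names(groups)) && !is.null(rownames(evaluations)))
    groups <- groups[rownames(evaluations)]
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("need exactly two groups", call. = FALSE)
  per <- lapply(seq_len(ncol(evaluations)), function(j) {
    x <- evaluations[groups == lv[1], j]
    y <- evaluations[groups == lv[2], j]
    ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                       exact = FALSE, correct = TRUE))
    data.frame(partner_id = colnames(evaluations)[j] %||% j,
               U = unname(ht$statistic), p = ht$p.value)
  })
  per <- do.call(rbind, per)
  list(per_partner = per, n_significant = sum(per$p < alpha),
       n_partners = nrow(per), cumulative = sort(per$p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster an association matrix for heatmap export
#'
#' Average-linkage hierarchical clustering of the correlation matrix
#' rows and columns (distance 1 - r), producing the ordered matrix and
#' leaf orders a heatmap needs. Requires a complete r grid; missing
#' entries indicate pairs that need a pairwise-complete rerun.
#'
#' @param associations Output of [correlate()].
#' @param path Optional CSV path for the ordered matrix.
#' @return List: `matrix` (ordered r matrix), `row_order`, `col_order`.
#' @export
cluster_heatmap_export <- function(associations, path = NULL) {
  if (anyNA(associations$r))
    stop("missing correlations; rerun the screen with pairwise-complete data",
         call. = FALSE)
  m <- with(associations,
            tapply(r, list(x_name, y_name), identity))
  storage.mode(m) <- "double"
  order_of <- function(mat) {
    if (nrow(mat) < 2) return(seq_len(nrow(mat)))
    d <- as.dist(1 - cor(t(mat)))
    if (anyNA(d)) d <- as.dist(dist(mat))
    hclust(d, method = "average")$order
  }
  ro <- if (nrow(m) >= 3) order_of(m) else seq_len(nrow(m))
  co <- if (ncol(m) >= 3) order_of(t(m)) else seq_len(ncol(m))
  out <- m[ro, co, drop = FALSE]
  if (!is.null(path))
    write.csv(data.frame(x_name = rownames(out), out, check.names = FALSE),
              path, row.names = FALSE)
  invisible(list(matrix = out, row_order = rownames(m)[ro],
                 col_order = colnames(m)[co]))
}
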