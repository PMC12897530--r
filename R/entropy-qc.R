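QC_CHANNELS <- c("attractiveness", "trustworthiness", "amount")

#' Shannon entropy of a discrete response sequence
#'
#' Measures how varied a participant's responses are: `S = -sum p_k
#' log(p_k)` over the empirical frequencies of the distinct responses.
#' Repetitive, low-engagement responding gives entropy near zero; using
#' many options roughly evenly gives entropy near `log(k)`.
#'
#' @param values Nonempty vector of categorical/discrete responses.
#' @param base Logarithm base; 2 (bits) by default.
#' @return Nonnegative scalar entropy.
#' @export
shannon_entropy <- function(values, base = 2) {
  if (length(values) == 0) stop("empty response sequence", call. = FALSE)
  p <- tabulate(factor(values)) / length(values)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Per-participant, per-channel entropy report
#'
#' @param behavior Validated behavior table.
#' @param base Entropy log base.
#' @param threshold Pass threshold; a channel passes when its entropy is
#'   at or above it.
#' @return Data frame `participant_id, channel, entropy, n_distinct,
#'   passes`, one row per participant and channel.
#' @export
entropy_report <- function(behavior, base = 2, threshold = 1.5) {
  blocks <- split_participants(behavior)
  rows <- lapply(names(blocks), function(id) {
    b <- blocks[[id]]
    data.frame(
      participant_id = id,
      channel = QC_CHANNELS,
      entropy = vapply(QC_CHANNELS,
                       function(ch) shannon_entropy(b[[ch]], base), 0),
      n_distinct = vapply(QC_CHANNELS,
                          function(ch) length(unique(b[[ch]])), 0L),
      row.names = NULL)
  })
  rep <- do.call(rbind, rows)
  rep$passes <- as.integer(rep$entropy >= threshold)
  rep
}

#' Histogram of distinct-option counts with per-bin entropy
#'
#' For each number `k` of distinct responses used on a channel, counts
#' the participants per group who used exactly `k` options and reports
#' the mean and SD of their channel entropy. This is the diagnostic that
#' motivates the entropy exclusion threshold: participants using three
#' or fewer investment options sit below 1.5 bits on average.
#'
#' @param behavior Validated behavior table (needs a `group` column; a
#'   single pseudo-group is assumed if absent).
#' @param channel One of `"attractiveness"`, `"trustworthiness"`,
#'   `"amount"`.
#' @param base Entropy log base.
#' @return Data frame with one row per observed `k`: group counts,
#'   `mean_entropy`, `sd_entropy`, `n`.
#' @export
distinct_option_histogram <- function(behavior, channel = "amount", base = 2) {
  if (!channel %in% QC_CHANNELS)
    stop("unknown channel: ", channel, call. = FALSE)
  if (nrow(behavior) == 0) stop("empty dataset", call. = FALSE)
  if (is.null(behavior$group)) behavior$group <- "all"
  blocks <- split_participants(behavior)
  per <- data.frame(
    participant_id = names(blocks),
    group = vapply(blocks, function(b) as.character(b$group[1]), ""),
    k = vapply(blocks, function(b) length(unique(b[[channel]])), 0L),
    entropy = vapply(blocks, function(b) shannon_entropy(b[[channel]], base), 0),
    row.names = NULL)
  groups <- sort(unique(per$group))
  out <- lapply(sort(unique(per$k)), function(k) {
    sub <- per[per$k == k, ]
    counts <- setNames(
      vapply(groups, function(g) sum(sub$group == g), 0L),
      paste0("n_", groups))
    cbind(data.frame(k = k),
          as.data.frame(as.list(counts)),
          data.frame(n = nrow(sub),
                     mean_entropy = mean(sub$entropy),
                     sd_entropy = if (nrow(sub) > 1) sd(sub$entropy) else NA_real_))
  })
  do.call(rbind, out)
}

#' Exclude non-serious participants by response entropy
#'
#' A participant's channel fails when its Shannon entropy falls below
#' the threshold; a participant is dropped when ANY of the selected
#' channels fails (parameter estimation needs all three channels
#' jointly, so exclusion is participant-level). The default screens the
#' investment-amount channel at 1.5 bits.
#'
#' @param behavior Validated behavior table.
#' @param threshold Entropy cutoff (same base as `base`), >= 0.
#' @param channels Channels whose failure excludes a participant.
#' @param base Entropy log base.
#' @return List with `retained` (filtered behavior table), `report`
#'   (full [entropy_report()] for every participant), and
#'   `excluded_ids`.
#' @export
qc_filter <- function(behavior, threshold = 1.5, channels = "amount",
                      base = 2) {
  stopifnot(threshold >= 0, all(channels %in% QC_CHANNELS))
  rep <- entropy_report(behavior, base = base, threshold = threshold)
  fail <- rep[rep$channel %in% channels & rep$entropy < threshold, ]
  excluded <- unique(fail$participant_id)
  retained <- behavior[!behavior$participant_id %in% excluded, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, report = rep, excluded_ids = excluded)
}

#' Group comparison of response entropies
#'
#' Two-sided Wilcoxon rank-sum test comparing the channel entropies of
#' the two diagnostic groups, optionally after dropping low-entropy
#' outliers (the sensitivity analysis that removes entries below 0.5).
#'
#' @param report Output of [entropy_report()] joined with group labels,
#'   i.e. a data frame with `participant_id, channel, entropy, group`.
#' @param channel Channel to compare.
#' @param exclude_below Optional entropy floor; entries strictly below
#'   it are removed before testing.
#' @return List `statistic` (rank-sum W), `p_value`, `n` per group.
#' @export
entropy_group_test <- function(report, channel, exclude_below = NULL) {
  sub <- report[report$channel == channel, ]
  if (!is.null(exclude_below)) sub <- sub[sub$entropy >= exclude_below, ]
  groups <- unique(as.character(sub$group))
  if (length(groups) != 2 || any(table(sub$group) == 0))
    stop("need both groups represented after exclusion", call. = FALSE)
  x <- sub$entropy[sub$group == groups[1]]
  y <- sub$entropy[sub$group == groups[2]]
  rs <- rank_sum_test(x, y)
  list(statistic = rs$statistic, p_value = rs$p_value,
       n = setNames(c(length(x), length(y)), groups))
}
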