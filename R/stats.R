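# Non-parametric group comparisons at seat-off: exact rank tests for the
# small samples typical of STS studies, medians with 25-75% interquartile
# ranges, and the per-participant aggregation (mean over repetitions for
# performance, range over repetitions for variability).

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Uses full enumeration of the permutation distribution of the rank sum
#' (midranks, so ties are handled exactly) whenever the number of group
#' assignments is small enough; falls back to the exact tie-free Wilcoxon
#' distribution, then to the normal approximation with continuity
#' correction. The two-sided p-value is the proportion of assignments
#' whose rank-sum deviates from its mean by at least the observed
#' deviation.
#'
#' @param x,y numeric samples.
#' @param max_enum largest number of assignments enumerated exactly.
#' @return list with `p.value`, `statistic` (rank sum of `x`), `method`.
#' @export
rank_sum_test <- function(x, y, max_enum = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L) stop("need at least 2 observations per group")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (m + n + 1) / 2
  if (choose(m + n, m) <= max_enum) {
    cmb <- utils::combn(m + n, m)
    Wp <- colSums(matrix(r[cmb], nrow = m))
    p <- mean(abs(Wp - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else if (!anyDuplicated(r)) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact distribution"
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(p.value = p, statistic = W, method = method)
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired test on `x - y` (zeros dropped, midranks on ties). Enumerates
#' all sign assignments exactly for small samples; otherwise uses the
#' exact tie-free signed-rank distribution or the normal approximation.
#'
#' @param x,y paired numeric samples.
#' @param max_n largest sample size for full sign enumeration.
#' @return list with `p.value`, `statistic` (positive-rank sum), `method`.
#' @export
signed_rank_test <- function(x, y, max_n = 14L) {
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are tied at zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= max_n) {
    Vp <- vapply(0:(2^n - 1), function(bits) {
      sum(r[bitwAnd(bits, 2^(0:(n - 1))) > 0])
    }, numeric(1))
    p <- mean(abs(Vp - mu) >= abs(V - mu) - 1e-9)
    method <- "exact enumeration"
  } else if (!anyDuplicated(r)) {
    p <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    method <- "exact distribution"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(p.value = p, statistic = V, method = method)
}

#' Seat-off metric rows for one accepted repetition
#'
#' Reads each balance metric at the seat-off sample and appends the two
#' durations (total STS `t_stance - t_init`, rise `t_stance - t_seatoff`).
#'
#' @param static an [static_metrics()] data.frame.
#' @param dynamic a [dynamic_metrics()] data.frame.
#' @param events an accepted `sts_events`.
#' @param participant,group,condition,repetition row identifiers.
#' @return long data.frame (participant, group, condition, repetition,
#'   metric, value, flagged).
#' @export
extract_seatoff_values <- function(static, dynamic, events, participant,
                                   group, condition = "side", repetition = 1L) {
  if (!isTRUE(events$accepted)) return(NULL)
  i <- events$i_seatoff
  vals <- c(d_bg = static$d_bg[i], com_cop_dist = static$com_cop_dist[i],
            com_speed = static$com_speed[i],
            avg_ang_speed = static$avg_ang_speed[i],
            wz = dynamic$wz[i], d_bf = dynamic$d_bf[i],
            fpe_cop_t = dynamic$fpe_cop_t[i], fpe_cop_s = dynamic$fpe_cop_s[i],
            sts_duration = events$t_stance - events$t_init,
            rise_duration = events$t_stance - events$t_seatoff)
  data.frame(participant = participant, group = group, condition = condition,
             repetition = repetition, metric = names(vals),
             value = unname(vals), flagged = is.na(unname(vals)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate seat-off rows per participant
#'
#' Mean over repetitions (group performance contrasts) and range over
#' repetitions (within-subject variability contrasts) per participant,
#' metric and condition.
#'
#' @param rows row-bound output of [extract_seatoff_values()].
#' @return data.frame with columns participant, group, condition, metric,
#'   `mean`, `range`, `n_reps`.
#' @export
seatoff_table <- function(rows) {
  stopifnot(nrow(rows) > 0)
  key <- interaction(rows$participant, rows$condition, rows$metric, drop = TRUE)
  agg <- lapply(split(rows, key), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(participant = d$participant[1L], group = d$group[1L],
               condition = d$condition[1L], metric = d$metric[1L],
               mean = if (length(v)) mean(v) else NA_real_,
               range = if (length(v) >= 2L) max(v) - min(v) else NA_real_,
               n_reps = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Group comparison of seat-off metrics
#'
#' Unpaired design: per metric, compares the per-participant values
#' between the two groups with the exact rank-sum test and reports
#' medians and 25-75% interquartile ranges (linear-interpolation
#' quantiles, type 7). Paired design: per metric and group, compares two
#' conditions within participants with the exact signed-rank test.
#'
#' @param tab a [seatoff_table()] data.frame.
#' @param design `"unpaired"` or `"paired"`.
#' @param value `"mean"` (performance) or `"range"` (variability).
#' @param conditions for the paired design, the two condition labels.
#' @return data.frame, one row per metric (and per group when paired),
#'   with medians, IQR bounds and the p-value.
#' @export
compare_groups <- function(tab, design = c("unpaired", "paired"),
                           value = c("mean", "range"),
                           conditions = NULL) {
  design <- match.arg(design)
  value <- match.arg(value)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                    type = 7, names = FALSE)
  out <- list()
  if (design == "unpaired") {
    groups <- sort(unique(tab$group))
    if (length(groups) != 2L) stop("unpaired design needs exactly 2 groups")
    for (met in unique(tab$metric)) {
      d <- tab[tab$metric == met, ]
      v1 <- d[[value]][d$group == groups[1L]]
      v2 <- d[[value]][d$group == groups[2L]]
      v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
      if (length(v1) < 2L || length(v2) < 2L) next
      q1 <- qs(v1); q2 <- qs(v2)
      ts <- rank_sum_test(v1, v2)
      out[[met]] <- data.frame(
        metric = met, group1 = groups[1L], group2 = groups[2L],
        median1 = q1[2L], iqr1_lo = q1[1L], iqr1_hi = q1[3L],
        median2 = q2[2L], iqr2_lo = q2[1L], iqr2_hi = q2[3L],
        p = ts$p.value, method = ts$method, stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(conditions)) conditions <- sort(unique(tab$condition))
    stopifnot(length(conditions) == 2L)
    for (met in unique(tab$metric)) {
      for (grp in sort(unique(tab$group))) {
        d <- tab[tab$metric == met & tab$group == grp, ]
        w <- merge(d[d$condition == conditions[1L], c("participant", value)],
                   d[d$condition == conditions[2L], c("participant", value)],
                   by = "participant")
        if (nrow(w) < 2L) next
        ts <- signed_rank_test(w[[2L]], w[[3L]])
        q1 <- qs(w[[2L]]); q2 <- qs(w[[3L]])
        out[[paste(met, grp)]] <- data.frame(
          metric = met, group = grp,
          cond1 = conditions[1L], cond2 = conditions[2L],
          median1 = q1[2L], median2 = q2[2L],
          p = ts$p.value, method = ts$method, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
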