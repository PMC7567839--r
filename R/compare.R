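## Two-sided Wilcoxon (Mann-Whitney) rank-sum comparisons of shift metrics
## across strongest-predictor groups and life-history groups.
##
## The statistic and p-value are computed here rather than delegated, so the
## exact-enumeration and approximation conventions are fixed and documented:
## exact p by enumeration of the null U distribution when n1 + n2 <= 12 and
## there are no ties, otherwise a normal approximation with midranks, tie
## correction and continuity correction.

#' Two-sided Wilcoxon rank-sum test
#'
#' The Mann-Whitney statistic is `U = R1 - n1 (n1 + 1) / 2`, with `R1` the
#' midrank sum of `x`.  For tie-free samples with `n1 + n2 <= 12` the
#' two-sided p-value is exact: `2 * min(P(U <= u), P(U >= u))` under the
#' enumerated null distribution, capped at 1.  Otherwise
#' `z = (U - n1 n2 / 2 -/+ 0.5) / sigma` with the tie-corrected
#' `sigma^2 = (n1 n2 / 12) ((N + 1) - sum(t^3 - t) / (N (N - 1)))`,
#' and `p = 2 * pnorm(-|z|)`.  Identical samples give p = 1.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact mode;
#'   default `NULL` chooses it when `n1 + n2 <= 12` and there are no ties.
#' @return list with `U`, `p`, `n1`, `n2`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be nonempty")
  N <- n1 + n2
  r <- rank(c(x, y))
  ties <- table(r)
  has_ties <- any(ties > 1)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- exact %||% (N <= 12 && !has_ties)
  if (use_exact && has_ties) {
    stop("exact mode requires tie-free samples")
  }
  if (use_exact) {
    ## null distribution of U by enumeration of all rank assignments
    cmb <- utils::combn(N, n1)  # tie-free ranks are exactly 1..N
    u_all <- colSums(matrix(cmb, nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_all <= U), mean(u_all >= U))
    method <- "exact"
  } else {
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
    dev <- U - n1 * n2 / 2
    if (sigma2 <= 0 || dev == 0) {
      p <- 1
    } else {
      z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  list(U = U, p = min(1, p), n1 = n1, n2 = n2, method = method)
}

#' Pairwise rank-sum comparisons of one metric across groups
#'
#' Every unordered pair of group labels is tested two-sided; groups with
#' fewer than 3 members are flagged as low-power.  Holm adjustment across
#' the pairs is reported in `p_holm` but the unadjusted `p` is the primary
#' output.
#'
#' @param values numeric metric values (one per species).
#' @param groups group label per value.
#' @param adjust `"none"` (default) or `"holm"`; either way both columns
#'   are returned, the flag only selects which one `p_reported` mirrors.
#' @return data.frame with one row per group pair (`group_a`, `group_b`,
#'   `n_a`, `n_b`, `U`, `p`, `p_holm`, `p_reported`, `low_power`).
#' @export
pairwise_compare <- function(values, groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  labs <- sort(unique(groups))
  if (length(labs) < 2) stop("need at least two groups with data")
  prs <- utils::combn(labs, 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    xa <- values[groups == a]; xb <- values[groups == b]
    t <- rank_sum_test(xa, xb)
    data.frame(group_a = a, group_b = b, n_a = t$n1, n_b = t$n2,
               U = t$U, p = t$p, method = t$method,
               low_power = t$n1 < 3 || t$n2 < 3)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$p_reported <- if (adjust == "holm") out$p_holm else out$p
  out
}

#' Group summaries of a metric
#'
#' @inheritParams pairwise_compare
#' @return data.frame with per-group n, median, mean, and quartiles.
#' @export
group_summary <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), median = stats::median(v),
               mean = mean(v), q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  rownames(out) <- NULL
  out
}

#' All pairwise comparisons for the standard metrics and groupings
#'
#' Joins the range-metrics table to species groups (strongest predictor per
#' season, and life history) and runs [pairwise_compare()] for each of
#' `shift_km`, `pct_area_change`, `d_north`, `d_south`, per season and
#' grouping.
#'
#' @param metrics output of [range_metrics_table()].
#' @param strongest data.frame `species, season, strongest_predictor`.
#' @param life_history data.frame `species, life_history`.
#' @param adjust passed to [pairwise_compare()].
#' @return list with `comparisons` and `summaries` data.frames.
#' @export
compare_all <- function(metrics, strongest, life_history,
                        adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  metric_cols <- c("shift_km", "pct_area_change", "d_north", "d_south")
  comp <- list(); summ <- list()
  for (se in sort(unique(metrics$season))) {
    m <- metrics[metrics$season == se, , drop = FALSE]
    st <- strongest[strongest$season == se, , drop = FALSE]
    m$strongest_predictor <-
      st$strongest_predictor[match(m$species, st$species)]
    m$life_history <- life_history$life_history[match(m$species,
                                                      life_history$species)]
    for (grouping in c("strongest_predictor", "life_history")) {
      for (mc in metric_cols) {
        res <- tryCatch(pairwise_compare(m[[mc]], m[[grouping]], adjust),
                        error = function(e) NULL)
        if (is.null(res)) next
        res <- cbind(data.frame(metric = mc, grouping = grouping,
                                season = se), res)
        comp[[length(comp) + 1]] <- res
        gs <- cbind(data.frame(metric = mc, grouping = grouping,
                               season = se),
                    group_summary(m[[mc]], m[[grouping]]))
        summ[[length(summ) + 1]] <- gs
      }
    }
  }
  list(comparisons = do.call(rbind, comp), summaries = do.call(rbind, summ))
}
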