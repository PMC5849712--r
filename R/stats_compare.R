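#' Likelihood-ratio G-test of independence
#'
#' G = 2 * sum O * ln(O/E) over the cells of a contingency table, with
#' E = row total x column total / grand total; cells with O = 0 contribute
#' nothing.  The statistic is referred to the chi-square upper tail with
#' (r-1)(c-1) degrees of freedom.  The optional Williams correction divides
#' G by q = 1 + ((N * sum(1/row) - 1)(N * sum(1/col) - 1)) /
#' (6N(r-1)(c-1)).
#'
#' @param table matrix of non-negative integer counts, >= 2 rows and
#'   columns, grand total > 0.
#' @param williams_correction apply the Williams correction.
#' @return list `statistic`, `df`, `p_value`.
#' @export
g_test <- function(table, williams_correction = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  N <- sum(table)
  if (N <= 0) stop("grand total must be positive")
  rs <- rowSums(table)
  cs <- colSums(table)
  E <- outer(rs, cs) / N
  O <- table
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  if (williams_correction) {
    q <- 1 + ((N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1)) /
      (6 * N * df)
    G <- G / q
  }
  list(statistic = G, df = df,
       p_value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties.  For small samples
#' (`min(n, m) <= exact_limit`) the null distribution of the rank sum is
#' enumerated exactly over all assignments of the pooled ranks to the first
#' sample, and the two-sided p-value is the probability of a rank sum at
#' least as far from its null mean as the observed one.  Larger samples use
#' the normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param sample_a,sample_b numeric vectors of (length) observations.
#' @param exact_limit largest `min(n, m)` for which the exact distribution
#'   is enumerated (default 8).
#' @return list `statistic` (rank sum of `sample_a`), `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b, exact_limit = 8L) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  n <- length(sample_a)
  m <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  if (min(n, m) <= exact_limit) {
    idx <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[idx], nrow = n))
    p <- mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = w_obs, p_value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- n * m / 12 * ((n + m + 1) -
                            sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(statistic = w_obs, p_value = 1,
                               method = "normal"))
  dev <- w_obs - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w_obs, p_value = p, method = "normal")
}

#' Event-length summary by AS type and conservation class
#'
#' Mean (two decimals) and median event length per type for ECAS and
#' non-ECAS events, with a two-sided Wilcoxon rank-sum p-value per type.
#' The p-value is NA when either class has fewer than two lengths.
#'
#' @param classified_events events carrying a `conservation` column;
#'   typically the distinct-signature rows.
#' @param types AS types to summarize.
#' @return data frame `event_type`, `n_ecas`, `mean_ecas`, `median_ecas`,
#'   `n_non`, `mean_non`, `median_non`, `p_value`.
#' @export
length_summary <- function(classified_events,
                           types = c("ES", "IR", "AltD", "AltA")) {
  rows <- lapply(types, function(t) {
    a <- classified_events$event_length[
      classified_events$event_type == t &
        classified_events$conservation == "ECAS"]
    b <- classified_events$event_length[
      classified_events$event_type == t &
        classified_events$conservation == "non-ECAS"]
    p <- if (length(a) >= 2L && length(b) >= 2L) {
      tryCatch(wilcoxon_rank_sum(a, b)$p_value, error = function(e)
        NA_real_)
    } else NA_real_
    data.frame(
      event_type = t, n_ecas = length(a),
      mean_ecas = if (length(a)) round(mean(a), 2) else NA_real_,
      median_ecas = if (length(a)) stats::median(a) else NA_real_,
      n_non = length(b),
      mean_non = if (length(b)) round(mean(b), 2) else NA_real_,
      median_non = if (length(b)) stats::median(b) else NA_real_,
      p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genic-region distribution of events by conservation class
#'
#' Shares of events in CDS, 5'UTR and 3'UTR per conservation class (events
#' with spanning or missing labels are excluded so shares sum to 100), and
#' a per-region 2x2 G-test of class x in-region/not.
#'
#' @param classified_events events carrying `conservation` and `region`.
#' @return list with `shares` (`region`, `pct_ecas`, `pct_non`) and `tests`
#'   (`region`, `statistic`, `p_value`).
#' @export
position_comparison <- function(classified_events) {
  regions <- c("CDS", "5UTR", "3UTR")
  ev <- classified_events[classified_events$region %in% regions, ,
                          drop = FALSE]
  n_e <- sum(ev$conservation == "ECAS")
  n_n <- sum(ev$conservation == "non-ECAS")
  shares <- data.frame(
    region = regions,
    pct_ecas = vapply(regions, function(rg)
      if (n_e > 0) round(100 * sum(ev$region == rg &
        ev$conservation == "ECAS") / n_e, 2) else NA_real_, numeric(1)),
    pct_non = vapply(regions, function(rg)
      if (n_n > 0) round(100 * sum(ev$region == rg &
        ev$conservation == "non-ECAS") / n_n, 2) else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE)
  tests <- lapply(regions, function(rg) {
    tab <- rbind(
      c(sum(ev$region == rg & ev$conservation == "ECAS"),
        sum(ev$region != rg & ev$conservation == "ECAS")),
      c(sum(ev$region == rg & ev$conservation == "non-ECAS"),
        sum(ev$region != rg & ev$conservation == "non-ECAS")))
    res <- tryCatch(g_test(tab), error = function(e)
      list(statistic = NA_real_, p_value = NA_real_))
    data.frame(region = rg, statistic = res$statistic,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  rownames(shares) <- NULL
  list(shares = shares, tests = do.call(rbind, tests))
}
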