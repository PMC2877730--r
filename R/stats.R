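# Cohort statistics: Mann-Whitney U with exact small-sample p values,
# per-group summaries (detection rates, median ratios, mean +/- sem
# amounts), and pairwise comparison tables.

# exact null distribution of U for group sizes m, n: counts of subsets of
# size m from ranks 1..(m+n) by rank sum (classic counting recursion)
.u_counts <- function(m, n) {
  maxu <- m * n
  # dp[k + 1, u + 1] = number of k-subsets of the first i ranks with U = u
  dp <- matrix(0, nrow = m + 1L, ncol = maxu + 1L)
  dp[1L, 1L] <- 1
  for (i in seq_len(m + n)) {
    for (k in rev(seq_len(min(i, m)))) {
      # adding rank i as the k-th member contributes (i - k) to U
      add <- i - k
      if (add > maxu) next
      src <- dp[k, seq_len(maxu + 1L - add)]
      idx <- (add + 1L):(maxu + 1L)
      dp[k + 1L, idx] <- dp[k + 1L, idx] + src
    }
  }
  dp[m + 1L, ]
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. The two-sided p value is
#' exact (full null distribution by the counting recursion) when
#' `nA * nB <= 400` and there are no ties; otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return List with `U` (for group `a`), `p` (two-sided), and `method`
#'   (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && na * nb <= 400) {
    counts <- .u_counts(na, nb)
    total <- sum(counts)
    lower <- sum(counts[seq_len(U + 1L)]) / total
    upper <- sum(counts[(U + 1L):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
    return(list(U = U, p = p, method = "exact"))
  }
  N <- na + nb
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  mu <- na * nb / 2
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p = min(1, 2 * pnorm(-z)), method = "normal")
}

#' Summarize a quantified cohort
#'
#' Detection rate uses all samples; ratio and amount summaries use only
#' samples whose internal standard was detected (excluded samples are
#' counted in `n_standard_missing`, not silently dropped).
#'
#' @param results List of `quant_result` (see [quantify_groups()]).
#' @param label Group label.
#' @return Object of class `cohort_summary`: per-species detection rate
#'   (%), median ratio, mean and sem of amounts (fmol; sem reported as 0
#'   with `n1_flag` when n = 1), plus the raw per-sample ratio/amount
#'   matrices used by [compare_cohorts()].
#' @export
summarize_cohort <- function(results, label = "group") {
  stopifnot(length(results) >= 1L)
  species <- names(results[[1]]$ratio)
  nall <- length(results)
  ok <- vapply(results, function(r) isTRUE(r$standard_detected), TRUE)
  ratios <- do.call(rbind, lapply(results, function(r) r$ratio))
  amounts <- do.call(rbind, lapply(results, function(r) r$amount))
  detected <- do.call(rbind, lapply(results, function(r) r$detected))
  n_used <- sum(ok)
  summ <- data.frame(
    species = species,
    detection_rate = 100 * colMeans(detected[, species, drop = FALSE]),
    median_ratio = apply(ratios[ok, species, drop = FALSE], 2, median),
    mean_amount = colMeans(amounts[ok, species, drop = FALSE]),
    sem_amount = if (n_used > 1)
      apply(amounts[ok, species, drop = FALSE], 2, sd) / sqrt(n_used)
    else 0,
    row.names = NULL
  )
  structure(list(label = label, n = nall, n_used = n_used,
                 n_standard_missing = nall - n_used,
                 n1_flag = n_used == 1L, summary = summ,
                 ratios = ratios[ok, species, drop = FALSE],
                 amounts = amounts[ok, species, drop = FALSE]),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s (n = %d%s)\n", x$label, x$n,
              if (x$n_standard_missing > 0)
                sprintf(", %d excluded: standard undetected",
                        x$n_standard_missing) else ""))
  print(x$summary)
  invisible(x)
}

.stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' Compare cohorts pairwise
#'
#' One row per species and pairing: group medians, Mann-Whitney U and
#' two-sided p on the per-sample ratios, significance stars at 0.05 / 0.01.
#'
#' @param summaries List of [summarize_cohort()] objects.
#' @param pairings Data frame with columns `a` and `b` of group labels.
#' @return Data frame comparison table.
#' @export
compare_cohorts <- function(summaries, pairings) {
  labels <- vapply(summaries, function(s) s$label, "")
  rows <- list()
  for (r in seq_len(nrow(pairings))) {
    ia <- match(pairings$a[r], labels)
    ib <- match(pairings$b[r], labels)
    if (is.na(ia) || is.na(ib))
      stop("unknown group label in pairing: ", pairings$a[r], " vs ",
           pairings$b[r], call. = FALSE)
    sa <- summaries[[ia]]; sb <- summaries[[ib]]
    shared <- intersect(colnames(sa$ratios), colnames(sb$ratios))
    if (length(shared) == 0L)
      stop("paired groups share no species", call. = FALSE)
    for (sp in shared) {
      mw <- mann_whitney(sa$ratios[, sp], sb$ratios[, sp])
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, group_a = sa$label, group_b = sb$label,
        n_a = nrow(sa$ratios), n_b = nrow(sb$ratios),
        median_a = median(sa$ratios[, sp]),
        median_b = median(sb$ratios[, sp]),
        U = mw$U, p = mw$p, signif = .stars(mw$p),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
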