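# One-way ANOVA with Duncan's multiple-range test and compact letter
# display, the group-separation procedure used throughout the reporting
# layer (P < 0.05 by default).

#' One-way ANOVA with Duncan's multiple-range letters
#'
#' Runs a one-way fixed-effects ANOVA across the groups, then Duncan's
#' multiple-range test: means are sorted in descending order and the
#' critical range for a span of `p` means is
#' `qtukey((1 - alpha)^(p - 1), p, df_error) * sqrt(MSE / n_h)`, with `n_h`
#' the harmonic mean of the group sizes. Groups sharing a letter are not
#' significantly different. When every group has zero within-group variance
#' the letters fall back to exact equality of means.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Protection level per comparison (default 0.05).
#' @return `list(F, p_value, df, means, n, letters, critical_ranges)`;
#'   `letters` is a named character vector (a compact letter display).
#' @export
anova_duncan <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list")
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs n >= 2")
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  N <- sum(n)
  dfe <- N - k
  grand <- mean(unlist(groups))
  sse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  ssb <- sum(n * (means - grand)^2)
  mse <- sse / dfe
  msb <- ssb / (k - 1)

  if (mse == 0) {
    # degenerate: letters by exact equality of means
    uniq <- sort(unique(means), decreasing = TRUE)
    letters_ <- stats::setNames(letters[match(means, uniq)], names(groups))
    return(list(F = if (msb > 0) Inf else NA_real_,
                p_value = if (msb > 0) 0 else NA_real_,
                df = c(k - 1L, dfe), means = means, n = n,
                letters = letters_, critical_ranges = rep(0, k - 1L)))
  }

  Fstat <- msb / mse
  pval <- stats::pf(Fstat, k - 1, dfe, lower.tail = FALSE)

  nh <- k / sum(1 / n)                      # harmonic mean group size
  se <- sqrt(mse / nh)
  spans <- 2:k
  crit <- vapply(spans, function(p)
    stats::qtukey((1 - alpha)^(p - 1), p, dfe) * se, numeric(1))
  names(crit) <- paste0("span_", spans)

  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  # maximal non-significant stretches in the sorted order: [i, j] is
  # non-significant when the extreme difference is below the critical range
  # for its span
  nonsig <- function(i, j) {
    if (i == j) return(TRUE)
    (ms[i] - ms[j]) <= crit[[paste0("span_", j - i + 1)]]
  }
  stretches <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig(i, j + 1)) j <- j + 1
    stretches[[length(stretches) + 1L]] <- c(i, j)
  }
  # keep maximal stretches only
  keep <- vapply(seq_along(stretches), function(s) {
    !any(vapply(seq_along(stretches), function(t) {
      t != s && stretches[[t]][1] <= stretches[[s]][1] &&
        stretches[[t]][2] >= stretches[[s]][2]
    }, logical(1)))
  }, logical(1))
  stretches <- stretches[keep]
  lab <- rep("", k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]][1]:stretches[[s]][2]
    lab[rng] <- paste0(lab[rng], letters[s])
  }
  letters_ <- stats::setNames(character(k), names(groups))
  letters_[names(ms)] <- lab

  list(F = Fstat, p_value = pval, df = c(k - 1L, dfe), means = means,
       n = n, letters = letters_, critical_ranges = crit)
}
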