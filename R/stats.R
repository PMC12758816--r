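#' Relative seizure delay
#'
#' Percentage change of the stimulated inter-seizure interval with
#' respect to the matched control interval:
#' `100 * (isi_stim - isi_ctrl) / isi_ctrl`.
#'
#' @param isi_stim Stimulated ISI (s); vectorized.
#' @param isi_ctrl Control ISI (s); must be positive.
#' @return Relative delay in percent.
#' @export
relative_delay <- function(isi_stim, isi_ctrl) {
  if (any(isi_ctrl <= 0)) stop("control ISI must be strictly positive")
  100 * (isi_stim - isi_ctrl) / isi_ctrl
}

#' Spearman rank correlation with p-value
#'
#' Rank correlation using average ranks for ties. The two-sided p-value
#' is computed by exhaustive permutation enumeration for fewer than 10
#' pairs, and by the t-approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y Paired numeric vectors, at least 4 observations.
#' @return List with `r` and `p`; `r` is `NA` (with a warning) when
#'   either variable is constant.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("at least 4 paired observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- all_permutations(n)
    # Pearson correlation of ranks over all permutations, via the
    # cross-product sum (means/sds are permutation-invariant)
    s_perm <- matrix(ry[perms], nrow(perms)) %*% (rx - mean(rx))
    denom <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    p <- mean(abs(s_perm / denom) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

# All permutations of 1..n as a matrix (n! rows); n <= 9.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric vectors; at least 3 points, `x` not constant.
#' @return List with `slope`, `intercept` and the fitted `lm` object.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("degenerate design: x is constant")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), fit = fit)
}

#' Seizure-delay statistics for a trial table
#'
#' Computes the Spearman correlation between stimulation length and
#' relative seizure delay, and the least-squares regression of delay on
#' length. Both are reported twice: for the full table and with flagged
#' outliers (absolute studentized residual above 3) removed.
#'
#' @param lengths Stimulation lengths (s).
#' @param delays Relative seizure delays (%).
#' @return List with elements `all` and `no_outlier`, each containing
#'   `r`, `p`, `slope`, `intercept`, `n`; plus `outliers`, the indices of
#'   flagged trials.
#' @export
delay_stats <- function(lengths, delays) {
  stopifnot(length(lengths) == length(delays))
  fit <- linear_fit(lengths, delays)
  rs <- stats::rstudent(fit$fit)
  out_idx <- unname(which(abs(rs) > 3))
  sp <- spearman(lengths, delays)
  all <- list(r = sp$r, p = sp$p, slope = fit$slope,
              intercept = fit$intercept, n = length(lengths))
  if (length(out_idx) && length(lengths) - length(out_idx) >= 4) {
    keep <- setdiff(seq_along(lengths), out_idx)
    fit2 <- linear_fit(lengths[keep], delays[keep])
    sp2 <- spearman(lengths[keep], delays[keep])
    no_out <- list(r = sp2$r, p = sp2$p, slope = fit2$slope,
                   intercept = fit2$intercept, n = length(keep))
  } else {
    no_out <- all
  }
  list(all = all, no_outlier = no_out, outliers = out_idx)
}
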