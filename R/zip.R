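#' Window-level read counts across the genome
#'
#' Builds the count universe for the background model: the genome is cut
#' into fixed-size windows and each window receives the summed read support
#' of the insertion sites whose position falls inside it; windows without a
#' site count zero.  Genome-wide insertion support is sparse, so the
#' resulting counts are dominated by structural zeros - the situation the
#' zero-inflated Poisson model is built for.
#'
#' @param sites Insertion-site table (uses `chrom`, `position`,
#'   `read_count`).
#' @param genome_lengths Named numeric vector of chromosome lengths, or a
#'   tibble with `chrom` and `length` columns, or a sequence table
#'   ([read_seqs()]).
#' @param window_size Window size in bp (default 1000).
#' @return Tibble with one row per window: `chrom`, `win_start` (1-based),
#'   `win_end`, `count`.  The total count equals the summed site read
#'   counts.
#' @export
windowed_counts <- function(sites, genome_lengths, window_size = 1000) {
  stopifnot(window_size >= 1)
  gl <- normalize_genome_lengths(genome_lengths)
  win <- bind_rows(lapply(seq_along(gl), function(i) {
    n_win <- ceiling(gl[i] / window_size)
    tibble(chrom = names(gl)[i],
           win_start = as.integer((seq_len(n_win) - 1) * window_size + 1),
           win_end = as.integer(pmin(seq_len(n_win) * window_size, gl[i])))
  }))
  counts <- rep(0L, nrow(win))
  if (nrow(sites) > 0) {
    idx_base <- cumsum(c(0, ceiling(gl / window_size)))
    names(idx_base) <- c(names(gl), "_end")
    bad <- setdiff(unique(sites$chrom), names(gl))
    if (length(bad) > 0)
      abort(paste0("sites on chromosomes absent from genome_lengths: ",
                   paste(bad, collapse = ", ")))
    w <- idx_base[sites$chrom] + (sites$position - 1) %/% window_size + 1
    for (j in seq_len(nrow(sites)))
      counts[w[j]] <- counts[w[j]] + sites$read_count[j]
  }
  win$count <- counts
  attr(win, "window_size") <- window_size
  win
}

normalize_genome_lengths <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("id", "seq") %in% names(x)))
      return(setNames(nchar(x$seq), x$id))
    if (all(c("chrom", "length") %in% names(x)))
      return(setNames(as.numeric(x$length), x$chrom))
    abort("genome_lengths data frame needs (chrom, length) or (id, seq)")
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort("genome_lengths must be a named numeric vector or a data frame")
}

zip_dens <- function(k, pi, lambda) {
  ifelse(k == 0, pi + (1 - pi) * exp(-lambda), (1 - pi) * dpois(k, lambda))
}

#' Fit a zero-inflated Poisson model to window counts
#'
#' Intercept-only zero-inflated Poisson: with probability `pi` a window is
#' a structural zero, otherwise its count is Poisson(`lambda`).  Maximum
#' likelihood via EM over the latent structural-zero indicator, initialized
#' at `pi0 = max(0, zero_fraction - exp(-mean_of_positive_counts))` and
#' `lambda0 =` mean of the positive counts, iterated until the
#' log-likelihood changes by less than `tol` (or `max_iter`).  The
#' log-likelihood is non-decreasing across iterations.
#'
#' @param counts Numeric vector of non-negative integer counts, or a
#'   window table from [windowed_counts()].
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A `zip_fit` object: `pi`, `lambda`, `n_obs`, `loglik`,
#'   `trajectory` (per-iteration log-likelihood), `iterations`,
#'   `converged`, `degenerate`, and the fitted `counts`.
#' @export
fit_zip <- function(counts, tol = 1e-8, max_iter = 500) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) == 0) abort("no counts to fit")
  if (any(counts < 0) || any(counts != floor(counts)))
    abort("counts must be non-negative integers")
  n <- length(counts)
  nz <- counts[counts > 0]
  if (length(nz) == 0) {
    warn("all counts are zero: returning a degenerate model (pi -> 1)")
    return(structure(list(pi = 1, lambda = NA_real_, n_obs = n,
                          loglik = 0, trajectory = numeric(0),
                          iterations = 0L, converged = TRUE,
                          degenerate = TRUE, counts = counts),
                     class = "zip_fit"))
  }
  n0 <- sum(counts == 0)
  mean_pos <- mean(nz)
  pi_hat <- min(max(n0 / n - exp(-mean_pos), 0), 1 - 1e-10)
  lam_hat <- mean_pos
  ll_of <- function(pi, lam) {
    n0 * log(pi + (1 - pi) * exp(-lam)) +
      sum(log(1 - pi) + nz * log(lam) - lam - lgamma(nz + 1))
  }
  traj <- numeric(max_iter)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step: posterior probability a zero is structural
    z <- if (n0 > 0) pi_hat / (pi_hat + (1 - pi_hat) * exp(-lam_hat)) else 0
    # M-step
    pi_hat <- min(max(n0 * z / n, 0), 1 - 1e-10)
    lam_hat <- sum(nz) / (n - n0 * z)
    ll <- ll_of(pi_hat, lam_hat)
    traj[it] <- ll
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  structure(list(pi = pi_hat, lambda = lam_hat, n_obs = n,
                 loglik = traj[it], trajectory = traj[seq_len(it)],
                 iterations = it, converged = converged,
                 degenerate = FALSE, counts = counts),
            class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  cat("Zero-inflated Poisson fit\n")
  cat(sprintf("  pi (zero inflation): %.4f\n", x$pi))
  cat(sprintf("  lambda (Poisson mean): %s\n",
              if (is.na(x$lambda)) "NA (degenerate)" else sprintf("%.4f", x$lambda)))
  cat(sprintf("  n = %d, logLik = %.4f, %d EM iteration(s)%s\n",
              x$n_obs, x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Upper-tail P-value of a site's read count
#'
#' `P(X >= count)` under a fitted zero-inflated Poisson model:
#' 1 for `count = 0`, and `(1 - pi) * P(Poisson(lambda) >= count)`
#' otherwise, strictly decreasing in the count.  Uses the numerically
#' stable upper-tail Poisson CDF.
#'
#' @param model A `zip_fit` object.
#' @param count Non-negative integer count(s), vectorized.
#' @return P-value(s) in `[0, 1]`.
#' @export
site_pvalue <- function(model, count) {
  stopifnot(inherits(model, "zip_fit"), all(count >= 0))
  if (isTRUE(model$degenerate)) {
    warn("degenerate ZIP model (all-zero counts); P-values are 1 at count 0 and 0 otherwise")
    return(ifelse(count == 0, 1, 0))
  }
  ifelse(count == 0, 1,
         (1 - model$pi) * ppois(count - 1, model$lambda, lower.tail = FALSE))
}

#' Attach ZIP P-values to an insertion-site table
#'
#' @param sites Insertion-site table.
#' @param model A `zip_fit` object.
#' @param fdr Also add a Benjamini-Hochberg adjusted column `p_adj`
#'   (default `FALSE`; the primary report is raw P-values).
#' @return `sites` with a `p_value` column (and `p_adj` if requested).
#' @export
add_site_pvalues <- function(sites, model, fdr = FALSE) {
  sites$p_value <- if (nrow(sites) == 0) double(0) else
    site_pvalue(model, sites$read_count)
  if (fdr)
    sites$p_adj <- stats::p.adjust(sites$p_value, method = "BH")
  sites
}
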