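#' Rank-normalized split R-hat for one parameter
#'
#' Chains are split in half, pooled draws are rank-normalized (normal scores
#' of average ranks), and the classic between/within variance ratio
#' \eqn{\sqrt{\widehat{\mathrm{var}}^+ / W}} is computed on the transformed
#' split chains. Values near 1 indicate convergence. Degenerate cases: all
#' draws identical returns 1; chains stuck at different constants return
#' `Inf`.
#'
#' @param x Numeric matrix of draws, iterations x chains.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("need >= 2 chains for R-hat")
  if (nrow(x) < 4) abort("need >= 4 iterations per chain")
  if (max(x) == min(x)) return(1)
  # rank-normalize pooled draws (average ranks, Blom offsets)
  z <- qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
  dim(z) <- dim(x)
  half <- floor(nrow(z) / 2)
  sp <- cbind(z[seq_len(half), , drop = FALSE],
              z[nrow(z) - half + seq_len(half), , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  W <- mean(apply(sp, 2, var))
  B <- nn * var(mu)
  if (W == 0) return(Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Gelman-Rubin convergence diagnostics for a fitted model
#'
#' Rank-normalized split R-hat per monitored scalar parameter: the
#' intercept, each covariate effect and (for spatial fits) both variance
#' parameters. A warning is raised when any monitored R-hat exceeds
#' `threshold`.
#'
#' @param fit A `bym_fit` with at least 2 chains.
#' @param threshold Warn above this value (default 1.05).
#' @return Tibble with `parameter` and `rhat`.
#' @export
gelman_rubin <- function(fit, threshold = 1.05) {
  draws <- fit$draws
  if (max(draws$.chain) < 2) abort("need >= 2 chains for R-hat")
  pars <- setdiff(names(draws), c(".chain", ".iteration"))
  out <- purrr::map_dfr(pars, function(pn) {
    m <- matrix(draws[[pn]], ncol = max(draws$.chain))
    tibble::tibble(parameter = pn, rhat = split_rhat(m))
  })
  if (any(out$rhat > threshold, na.rm = TRUE)) {
    bad <- out$parameter[out$rhat > threshold]
    warn(paste0("R-hat > ", threshold, " for: ", paste(bad, collapse = ", ")))
  }
  out
}
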