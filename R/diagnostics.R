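# Rank-normalised split-chain convergence diagnostics.
#
# Draws are split-chain halved, rank-normalised across all draws (Blom
# offsets), and R-hat is the classic between/within variance ratio on the
# normalised scale. Bulk ESS combines per-chain FFT autocovariances with
# Geyer's initial monotone positive sequence.

split_chains <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  # drop the middle draw when n is odd so halves are equal
  cbind(m[seq_len(half), , drop = FALSE],
        m[seq(n - half + 1, n), , drop = FALSE])
}

z_scale <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(m), ncol = ncol(m))
}

#' Rank-normalised split-chain R-hat
#'
#' @param m Matrix of draws, iterations x chains.
#' @return The potential scale reduction factor; values <= 1.01 indicate
#'   convergence. `NA` for constant draws.
#' @export
rhat_rank <- function(m) {
  m <- as.matrix(m)
  if (all(m == m[1])) return(NA_real_)
  z <- z_scale(split_chains(m))
  n <- nrow(z)
  chain_means <- colMeans(z)
  chain_vars <- apply(z, 2, var)
  b <- n * var(chain_means)
  w <- mean(chain_vars)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# biased autocovariance (lags 0..n-1) via FFT
autocov_fft <- function(x) {
  n <- length(x)
  xd <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- fft(c(xd, numeric(m - n)))
  ac <- Re(fft(Mod(f)^2, inverse = TRUE)) / m
  ac[seq_len(n)] / n
}

#' Bulk effective sample size
#'
#' Effective number of independent draws for estimating the centre of the
#' distribution, computed on rank-normalised split chains.
#'
#' @param m Matrix of draws, iterations x chains.
#' @return Effective sample size; `NA` for constant draws.
#' @export
ess_bulk <- function(m) {
  m <- as.matrix(m)
  if (all(m == m[1])) return(NA_real_)
  z <- z_scale(split_chains(m))
  n <- nrow(z)
  n_chain <- ncol(z)
  acov <- apply(z, 2, autocov_fft)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (n_chain > 1) var_plus <- var_plus + var(colMeans(z))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer initial positive monotone sequence on paired sums
  # pairs (rho_{2t}, rho_{2t+1}); 1-based indices (2t+1, 2t+2), t = 0, 1, ...
  max_pair <- floor(n / 2) - 1
  p <- numeric(0)
  for (t in 0:max_pair) {
    s <- rho[2 * t + 1] + rho[2 * t + 2]
    if (t > 0 && s < 0) break
    p <- c(p, s)
  }
  p <- cummin(p)
  tau <- max(-1 + 2 * sum(p), 1 / log10(max(n * n_chain, 10)))
  s_total <- n * n_chain
  min(s_total / tau, s_total * log10(s_total))
}
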