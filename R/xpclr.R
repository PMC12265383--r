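#' Method-of-moments drift variance
#'
#' Solves `Var(p_focal - p_reference) = omega * mean(pbar (1 - pbar))` over
#' genome-wide sites, with `pbar = (p_focal + p_reference)/2`; the
#' symmetric mean makes the estimate invariant to swapping the two
#' populations. The result is clamped to `(1e-6, 1)`.
#'
#' @param freqs_focal,freqs_reference numeric vectors of derived allele
#'   frequencies at the same (polarized) sites.
#' @return scalar omega.
#' @export
estimate_omega <- function(freqs_focal, freqs_reference) {
  ok <- !is.na(freqs_focal) & !is.na(freqs_reference)
  p1 <- freqs_focal[ok]; p2 <- freqs_reference[ok]
  if (length(p1) < 10L)
    stop("estimate_omega: need at least 10 usable sites")
  pb <- (p1 + p2) / 2
  denom <- mean(pb * (1 - pb))
  if (denom <= 0) return(1e-6)
  min(max(var(p1 - p2) / denom, 1e-6), 1)
}

# Gauss-Legendre base nodes/weights on [0, 1], cached
.gl01 <- local({
  cache <- NULL
  function(n = 64L) {
    if (is.null(cache)) {
      g <- pracma::gaussLegendre(n, 0, 1)
      cache <<- list(x = g$x, w = g$w)
    }
    cache
  }
})

# Neutral marginal P(x | k, p1, omega): focal true frequency p2 drifts as
# Normal(p1, omega * p1 (1-p1)) truncated to [0,1] with escaped mass as
# point masses at the boundaries; x | p2 ~ Binomial(k, p2). Integration by
# 64-point Gauss-Legendre on [p1 - 10 sd, p1 + 10 sd] ∩ [0, 1] plus the
# boundary terms. Vectorized over sites.
.xpclr_neutral_marginal <- function(x, k, p1, omega) {
  g <- .gl01()
  sdv <- sqrt(omega * p1 * (1 - p1))
  lo <- pmax(0, p1 - 10 * sdv)
  hi <- pmin(1, p1 + 10 * sdv)
  mass0 <- pnorm(0, mean = p1, sd = sdv)
  mass1 <- pnorm(1, mean = p1, sd = sdv, lower.tail = FALSE)
  V <- length(x)
  nodes <- outer(g$x, hi - lo) + rep(lo, each = length(g$x))   # 64 x V
  dens <- stats::dnorm(nodes, mean = rep(p1, each = length(g$x)), sd = rep(sdv, each = length(g$x)))
  lik <- dbinom(rep(x, each = length(g$x)), rep(k, each = length(g$x)), nodes)
  integ <- colSums(g$w * matrix(dens * lik, nrow = length(g$x))) * (hi - lo)
  integ + mass0 * (x == 0L) + mass1 * (x == k)
}

# Total probability mass of the drift density (integral + boundary masses);
# must be 1 up to quadrature error for any (p1, omega).
.drift_total_mass <- function(p1, omega) {
  g <- .gl01()
  sdv <- sqrt(omega * p1 * (1 - p1))
  lo <- max(0, p1 - 10 * sdv); hi <- min(1, p1 + 10 * sdv)
  nodes <- g$x * (hi - lo) + lo
  sum(g$w * stats::dnorm(nodes, p1, sdv)) * (hi - lo) +
    pnorm(0, p1, sdv) + pnorm(1, p1, sdv, lower.tail = FALSE)
}

#' Cross-population composite likelihood ratio scan
#'
#' Models the focal population's derived allele frequency at each SNP as
#' neutral drift around the reference frequency (truncated-Normal with
#' boundary point masses, variance `omega * p1(1-p1)`, binomial sampling)
#' versus drift plus hitchhiking around a putative selected site at each
#' grid point. Under selection with coefficient `s`, a SNP at distance `d`
#' escapes the sweep with probability `c = 1 - exp(-rho d / s)`; with
#' probability `1 - c` its frequency is dragged to 1 (weight `p1`) or 0
#' (weight `1 - p1`). The score is `CLR = 2 max_s sum_j w_j (l_sel -
#' l_neutral)`, floored at 0; `w_j` down-weights SNPs in strong LD
#' (pairwise r^2 > `ld_r2` in the reference population).
#'
#' @param hm a [hap_matrix()] (all samples; populations via `popmap`).
#' @param vt polarized variant table aligned with `hm`.
#' @param popmap population map.
#' @param grid_spacing spacing of tested grid points in bp.
#' @param window_radius SNP inclusion radius around each grid point, bp.
#' @param max_snps cap on SNPs per grid point (nearest kept).
#' @param s_grid selection coefficients tried (log grid by default).
#' @param rho per-bp recombination rate (constant map).
#' @param ld_r2 r^2 threshold above which SNPs share weight.
#' @param omega drift variance; estimated from the data when `NULL`.
#' @param contig_length contig length in bp (default: max position).
#' @return data frame `chrom`, `grid_pos` (0-based bp), `clr`, `s_hat`,
#'   `n_snps`; attribute `omega`.
#' @export
xpclr_scan <- function(hm, vt, popmap, grid_spacing = 1e4,
                       window_radius = 2.5e5, max_snps = 200L,
                       s_grid = exp(seq(log(1e-5), log(0.5), length.out = 20)),
                       rho = 1e-8, ld_r2 = 0.95, omega = NULL,
                       contig_length = NULL) {
  pol <- which(vt$ancestral_state %in% c("ref", "alt"))
  if (!length(pol)) stop("xpclr_scan: no polarized sites")
  vtp <- vt[pol, , drop = FALSE]
  rf <- pop_rows(hm, popmap, role = "focal")
  rr <- pop_rows(hm, popmap, role = "reference")
  Hf <- hm$H[rf, pol, drop = FALSE]
  Hr <- hm$H[rr, pol, drop = FALSE]

  dcode <- .derived_code(vtp)
  kf <- colSums(!is.na(Hf)); kr <- colSums(!is.na(Hr))
  xf <- colSums(Hf == rep(dcode, each = nrow(Hf)), na.rm = TRUE)
  xr <- colSums(Hr == rep(dcode, each = nrow(Hr)), na.rm = TRUE)
  ok <- kf >= 2L & kr >= 2L
  vtp <- vtp[ok, , drop = FALSE]
  Hr <- Hr[, ok, drop = FALSE]
  xf <- xf[ok]; kf <- kf[ok]; xr <- xr[ok]; kr <- kr[ok]

  if (is.null(omega))
    omega <- estimate_omega(xf / kf, xr / kr)

  # reference derived frequency, clamped away from the boundary so the
  # drift variance is positive even at reference-monomorphic sites
  p1 <- pmin(pmax(xr / kr, 1 / (2 * kr)), 1 - 1 / (2 * kr))
  M <- .xpclr_neutral_marginal(xf, kf, p1, omega)
  A <- p1 * (xf == kf) + (1 - p1) * (xf == 0L)
  logM <- log(pmax(M, 1e-300))

  pos0 <- vtp$pos - 1
  Lc <- if (is.null(contig_length)) max(pos0) else contig_length
  grid <- seq(0, Lc, by = grid_spacing)

  clr <- rep(NA_real_, length(grid))
  shat <- rep(NA_real_, length(grid))
  nsnp <- integer(length(grid))
  for (i in seq_along(grid)) {
    d <- abs(pos0 - grid[i])
    sel <- which(d <= window_radius)
    if (!length(sel)) next
    if (length(sel) > max_snps)
      sel <- sel[order(d[sel])[seq_len(max_snps)]]
    nsnp[i] <- length(sel)
    # LD weights in the reference population
    G <- Hr[, sel, drop = FALSE]
    r2 <- suppressWarnings(cor(G, use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 1
    w <- 1 / rowSums(r2 > ld_r2)
    ds <- d[sel]
    best <- -Inf; bs <- NA_real_
    for (s in s_grid) {
      cc <- 1 - exp(-rho * ds / s)
      Ls <- cc * M[sel] + (1 - cc) * A[sel]
      ll <- sum(w * (log(pmax(Ls, 1e-300)) - logM[sel]))
      if (ll > best) { best <- ll; bs <- s }
    }
    clr[i] <- max(0, 2 * best)
    shat[i] <- bs
  }
  out <- data.frame(chrom = vtp$chrom[1], grid_pos = grid, clr = clr,
                    s_hat = shat, n_snps = nsnp, stringsAsFactors = FALSE)
  attr(out, "omega") <- omega
  out
}
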