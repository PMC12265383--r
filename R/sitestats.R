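#' Derived allele frequencies within a group
#'
#' At polarized sites the derived allele is the one opposite the inferred
#' ancestral state; unpolarized sites report the ALT-allele frequency and
#' are flagged `polarized = FALSE`. Sites with no called alleles in the
#' group report `NA` (missing, not 0).
#'
#' @param hm a [hap_matrix()].
#' @param vt variant table aligned with `hm` (after [polarize()]).
#' @param popmap population map.
#' @param group group name (e.g. `"cold"`).
#' @return data frame: `chrom`, `pos`, `id`, `group`, `n_derived`,
#'   `n_called`, `freq`, `polarized`.
#' @export
allele_freq <- function(hm, vt, popmap, group) {
  if (!group %in% popmap$group) stop("allele_freq: no such group: ", group)
  rows <- pop_rows(hm, popmap, group = group)
  called <- .called(hm$H, rows)
  alt <- .alt_count(hm$H, rows)
  dcode <- .derived_code(vt)
  nder <- ifelse(!is.na(dcode) & dcode == 0L, called - alt, alt)
  data.frame(chrom = vt$chrom, pos = vt$pos, id = vt$id, group = group,
             n_derived = nder, n_called = called,
             freq = ifelse(called > 0, nder / called, NA_real_),
             polarized = !is.na(dcode),
             stringsAsFactors = FALSE)
}

#' Derived allele frequency difference between focal and reference
#'
#' `delta_daf = freq_focal(derived) - freq_reference(derived)`, in
#' `[-1, 1]`. Only polarized sites should enter downstream ranking; the
#' `polarized` flag is carried through.
#'
#' @param freq_focal,freq_reference outputs of [allele_freq()] for the
#'   focal and reference groups (same site order).
#' @return data frame: `chrom`, `pos`, `id`, `freq_focal`,
#'   `freq_reference`, `delta_daf`, `polarized`.
#' @export
delta_daf <- function(freq_focal, freq_reference) {
  stopifnot(identical(freq_focal$pos, freq_reference$pos))
  data.frame(chrom = freq_focal$chrom, pos = freq_focal$pos,
             id = freq_focal$id,
             freq_focal = freq_focal$freq,
             freq_reference = freq_reference$freq,
             delta_daf = freq_focal$freq - freq_reference$freq,
             polarized = freq_focal$polarized & freq_reference$polarized,
             stringsAsFactors = FALSE)
}

# per-site Hudson components: numerator and denominator
.hudson_site <- function(p1, p2, n1, n2) {
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  list(N = N, D = D)
}

#' Windowed Hudson Fst (ratio of sums)
#'
#' Per site, with allele frequencies `p1`, `p2` and called allele counts
#' `n1`, `n2` in the two populations, the Hudson estimator has numerator
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)`; a window's Fst is the ratio of sums over its
#' usable sites. Sites need >= 2 called alleles per population; sites with
#' zero denominator are skipped. Small negative values are expected under
#' no differentiation (the estimator is unbiased, not truncated).
#'
#' @param hm a [hap_matrix()].
#' @param vt variant table aligned with `hm` (for positions).
#' @param popmap population map (defines focal and reference roles).
#' @param windows data frame of intervals (`chrom`, `start`, `end`, `id`),
#'   or `NULL` for per-site values.
#' @return with windows: data frame `id`, `chrom`, `start`, `end`, `fst`,
#'   `n_sites`; without: per-site data frame with `fst`.
#' @export
hudson_fst <- function(hm, vt, popmap, windows = NULL) {
  r1 <- pop_rows(hm, popmap, role = "focal")
  r2 <- pop_rows(hm, popmap, role = "reference")
  n1 <- .called(hm$H, r1); n2 <- .called(hm$H, r2)
  p1 <- ifelse(n1 > 0, .alt_count(hm$H, r1) / n1, NA_real_)
  p2 <- ifelse(n2 > 0, .alt_count(hm$H, r2) / n2, NA_real_)
  hs <- .hudson_site(p1, p2, n1, n2)
  usable <- n1 >= 2L & n2 >= 2L & !is.na(hs$D) & hs$D > 0
  if (is.null(windows)) {
    return(data.frame(chrom = vt$chrom, pos = vt$pos,
                      fst = ifelse(usable, hs$N / hs$D, NA_real_),
                      usable = usable, stringsAsFactors = FALSE))
  }
  asn <- assign_to_genes(vt, windows)
  out <- windows[, c("id", "chrom", "start", "end")]
  out$fst <- NA_real_
  out$n_sites <- 0L
  if (nrow(asn)) {
    ok <- usable[asn$item]
    sN <- tapply(hs$N[asn$item][ok], asn$gene[ok], sum)
    sD <- tapply(hs$D[asn$item][ok], asn$gene[ok], sum)
    cnt <- table(asn$gene[ok])
    m <- match(names(sN), out$id)
    out$fst[m] <- as.numeric(sN) / as.numeric(sD)
    out$n_sites[match(names(cnt), out$id)] <- as.integer(cnt)
  }
  rownames(out) <- NULL
  out
}

#' Windowed nucleotide diversity
#'
#' Per-bp nucleotide diversity: the sample-size-corrected mean pairwise
#' difference `sum_sites 2 p q n/(n-1)` divided by the window length in bp
#' (not by segregating sites), `n` = called alleles at the site. Missing
#' calls shrink `n`; sites with `n < 2` contribute 0.
#'
#' @param hm a [hap_matrix()].
#' @param vt variant table aligned with `hm`.
#' @param popmap population map.
#' @param group group name whose haplotypes are used.
#' @param windows data frame of intervals (`chrom`, `start`, `end`, `id`).
#' @return data frame `id`, `chrom`, `start`, `end`, `pi`, `n_sites`.
#' @export
pi_windowed <- function(hm, vt, popmap, group, windows) {
  rows <- pop_rows(hm, popmap, group = group)
  n <- .called(hm$H, rows)
  p <- ifelse(n > 0, .alt_count(hm$H, rows) / n, NA_real_)
  contrib <- ifelse(n >= 2L, 2 * p * (1 - p) * n / (n - 1), 0)
  asn <- assign_to_genes(vt, windows)
  out <- windows[, c("id", "chrom", "start", "end")]
  out$pi <- 0
  out$n_sites <- 0L
  if (nrow(asn)) {
    s <- tapply(contrib[asn$item], asn$gene, sum)
    cnt <- table(asn$gene)
    m <- match(names(s), out$id)
    out$pi[m] <- as.numeric(s)
    out$n_sites[match(names(cnt), out$id)] <- as.integer(cnt)
  }
  out$pi <- out$pi / (out$end - out$start)
  rownames(out) <- NULL
  out
}

#' log2 nucleotide diversity ratio
#'
#' `log2(pi_reference / pi_focal)`. A swept window with zero focal
#' diversity but positive reference diversity returns `+Inf`, a sentinel
#' deliberately ranked above all finite values (a pseudocount would shrink
#' exactly the signal sought); `0/0` returns `NA`.
#'
#' @param pi_reference,pi_focal numeric vectors of per-bp diversity.
#' @return numeric vector.
#' @export
log2_pi_ratio <- function(pi_reference, pi_focal) {
  out <- ifelse(pi_focal == 0 & pi_reference == 0, NA_real_,
         ifelse(pi_focal == 0, Inf, log2(pi_reference / pi_focal)))
  out[is.na(pi_focal) | is.na(pi_reference)] <- NA_real_
  out
}

#' Combined per-window scan statistics
#'
#' Hudson Fst, focal and reference diversity and the log2 diversity ratio
#' for each window.
#'
#' @inheritParams hudson_fst
#' @return data frame `id`, `chrom`, `start`, `end`, `n_sites`, `fst`,
#'   `pi_focal`, `pi_reference`, `log2_pi_ratio`.
#' @export
window_stats <- function(hm, vt, popmap, windows) {
  gf <- unique(popmap$group[popmap$role == "focal"])
  gr <- unique(popmap$group[popmap$role == "reference"])
  fst <- hudson_fst(hm, vt, popmap, windows)
  pif <- pi_windowed(hm, vt, popmap, gf[1], windows)
  pir <- pi_windowed(hm, vt, popmap, gr[1], windows)
  data.frame(fst[, c("id", "chrom", "start", "end", "n_sites", "fst")],
             pi_focal = pif$pi, pi_reference = pir$pi,
             log2_pi_ratio = log2_pi_ratio(pir$pi, pif$pi),
             stringsAsFactors = FALSE)
}

#' Per-site frequency and divergence table
#'
#' Convenience wrapper combining [allele_freq()] for focal and reference
#' groups with [delta_daf()] and the variant annotations.
#'
#' @param hm a [hap_matrix()].
#' @param vt variant table (after [polarize()]).
#' @param popmap population map.
#' @return per-site data frame with `delta_daf` and `effect_class`.
#' @export
site_daf_table <- function(hm, vt, popmap) {
  gf <- unique(popmap$group[popmap$role == "focal"])[1]
  gr <- unique(popmap$group[popmap$role == "reference"])[1]
  dd <- delta_daf(allele_freq(hm, vt, popmap, gf),
                  allele_freq(hm, vt, popmap, gr))
  dd$effect_class <- vt$effect_class
  dd
}
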