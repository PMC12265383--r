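#' Polymorphism and divergence counts per unit
#'
#' For each unit (gene or window) counts `P`, the sites polymorphic among
#' the focal population's haplotypes, and `D`, the sites where the focal
#' population is fixed for one allele while all called outgroup haplotypes
#' (at least `min_outgroup` of them) are fixed for the other. Sites
#' failing both conditions count toward neither; polarization is not
#' required.
#'
#' @param hm a [hap_matrix()].
#' @param vt variant table aligned with `hm`.
#' @param popmap population map.
#' @param units data frame of intervals (`chrom`, `start`, `end`, `id`).
#' @param min_outgroup minimum called outgroup haplotypes for a D call.
#' @return data frame `id`, `P`, `D`.
#' @export
count_pd <- function(hm, vt, popmap, units, min_outgroup = 2L) {
  rf <- pop_rows(hm, popmap, role = "focal")
  ro <- pop_rows(hm, popmap, role = "outgroup")
  nf <- .called(hm$H, rf); af <- .alt_count(hm$H, rf)
  no <- .called(hm$H, ro); ao <- .alt_count(hm$H, ro)
  poly_f <- nf > 0L & af > 0L & af < nf
  fixed_f <- nf > 0L & (af == 0L | af == nf)
  fixed_o <- no >= min_outgroup & (ao == 0L | ao == no)
  allele_f <- ifelse(af == nf, 1L, 0L)
  allele_o <- ifelse(ao == no, 1L, 0L)
  is_D <- fixed_f & fixed_o & allele_f != allele_o

  asn <- assign_to_genes(vt, units)
  out <- data.frame(id = units$id, P = 0L, D = 0L, stringsAsFactors = FALSE)
  if (nrow(asn)) {
    pt <- tapply(poly_f[asn$item], asn$gene, sum)
    dt <- tapply(is_D[asn$item], asn$gene, sum)
    out$P[match(names(pt), out$id)] <- as.integer(pt)
    out$D[match(names(dt), out$id)] <- as.integer(dt)
  }
  out
}

# 2x2 chi-square without continuity correction; degenerate margins give 0
.chi2_2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
  unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic)
}

#' HKA-like polymorphism-versus-divergence test
#'
#' Each unit's `[P, D]` pair is compared against the genome-wide totals
#' with a 2x2 chi-square (no continuity correction):
#' `[[P, D], [P_tot - P, D_tot - D]]`. The signed score is `+sqrt(chi2)`
#' when the unit's polymorphism is deficient relative to its divergence
#' (the sweep direction) and `-sqrt(chi2)` when in excess. Units with
#' `D <= divergence_min` are marked unusable and excluded from totals and
#' ranking: a unit needs enough fixed differences for divergence to be a
#' meaningful yardstick.
#'
#' @param records output of [count_pd()].
#' @param divergence_min minimum fixed-difference count (strict; default
#'   60, i.e. a unit needs more than 60 fixed sites).
#' @return `records` with `usable`, `expected_P`, `chi2`, `signed_score`.
#' @export
hka_test <- function(records, divergence_min = 60L) {
  records$usable <- records$D > divergence_min
  u <- records[records$usable, , drop = FALSE]
  P_tot <- sum(u$P); D_tot <- sum(u$D)
  if (P_tot == 0L || D_tot == 0L)
    stop("hka_test: genome totals are degenerate (P_tot or D_tot is 0)")
  records$expected_P <- NA_real_
  records$chi2 <- NA_real_
  records$signed_score <- NA_real_
  for (i in which(records$usable)) {
    P <- records$P[i]; D <- records$D[i]
    tab <- matrix(c(P, D, P_tot - P, D_tot - D), nrow = 2, byrow = TRUE)
    chi2 <- .chi2_2x2(tab)
    records$expected_P[i] <- (P + D) * P_tot / (P_tot + D_tot)
    records$chi2[i] <- chi2
    deficit <- P * D_tot < D * P_tot      # P/D < P_tot/D_tot
    records$signed_score[i] <-
      if (chi2 == 0) 0 else if (deficit) sqrt(chi2) else -sqrt(chi2)
  }
  records
}

#' Polarized site-level polymorphism/divergence scan around a focal variant
#'
#' In sliding sub-windows across `[center - radius, center + radius)`,
#' counts polarized sites that are polymorphic in the focal population
#' (`P`) versus polarized sites fixed for the derived allele in the focal
#' population (`D`, the divergence class), and scores each sub-window's
#' deficiency against the regional totals with the signed chi-square of
#' [hka_test()]. Positive scores mean fewer polymorphisms than the
#' regional polymorphism/divergence ratio predicts.
#'
#' @param hm a [hap_matrix()].
#' @param vt polarized variant table aligned with `hm`.
#' @param popmap population map.
#' @param center focal position (1-based bp).
#' @param radius half-width of the scanned region in bp.
#' @param size,step sub-window size and step in bp.
#' @return data frame `start`, `end`, `P`, `D`, `signed_score` (empty if
#'   no polarized sites fall in range).
#' @export
polarized_site_scan <- function(hm, vt, popmap, center, radius,
                                size = 5e4, step = 2.5e4) {
  lo <- max(0, center - radius); hi <- center + radius
  pol <- which(vt$ancestral_state %in% c("ref", "alt") &
               vt$pos - 1 >= lo & vt$pos - 1 < hi)
  if (!length(pol))
    return(data.frame(start = numeric(), end = numeric(), P = integer(),
                      D = integer(), signed_score = numeric()))
  vtp <- vt[pol, , drop = FALSE]
  rf <- pop_rows(hm, popmap, role = "focal")
  nf <- colSums(!is.na(hm$H[rf, pol, drop = FALSE]))
  af <- colSums(hm$H[rf, pol, drop = FALSE] == 1L, na.rm = TRUE)
  dcode <- .derived_code(vtp)
  dcount <- ifelse(dcode == 0L, nf - af, af)
  poly_f <- nf > 0L & af > 0L & af < nf
  fixed_derived <- nf > 0L & dcount == nf

  w <- make_windows(setNames(hi - lo, vtp$chrom[1]), size, step)
  w$start <- w$start + lo; w$end <- w$end + lo
  w$id <- sprintf("%s:%d-%d", w$chrom, as.integer(w$start),
                  as.integer(w$end))
  asn <- assign_to_genes(vtp, w)
  out <- data.frame(start = w$start, end = w$end, P = 0L, D = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(asn)) {
    pt <- tapply(poly_f[asn$item], asn$gene, sum)
    dt <- tapply(fixed_derived[asn$item], asn$gene, sum)
    out$P[match(names(pt), w$id)] <- as.integer(pt)
    out$D[match(names(dt), w$id)] <- as.integer(dt)
  }
  P_tot <- sum(poly_f); D_tot <- sum(fixed_derived)
  out$signed_score <- vapply(seq_len(nrow(out)), function(i) {
    P <- out$P[i]; D <- out$D[i]
    if (P_tot == 0L || D_tot == 0L) return(0)
    chi2 <- .chi2_2x2(matrix(c(P, D, P_tot - P, D_tot - D), 2,
                             byrow = TRUE))
    if (chi2 == 0) 0
    else if (P * D_tot < D * P_tot) sqrt(chi2) else -sqrt(chi2)
  }, numeric(1))
  out
}
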