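# Column indices outward from a core site, truncated at the first
# inter-site gap larger than max_gap. direction = +1 (right) or -1 (left).
.outward_cols <- function(pos, core_idx, direction, max_gap) {
  if (core_idx + direction < 1L || core_idx + direction > length(pos))
    return(list(cols = integer(), reason = "end"))
  idx <- if (direction > 0) seq(core_idx + 1L, length(pos))
         else seq(core_idx - 1L, 1L)
  gaps <- abs(diff(c(pos[core_idx], pos[idx])))
  cut <- which(gaps > max_gap)
  if (length(cut)) {
    list(cols = idx[seq_len(cut[1L] - 1L)], reason = "gap")
  } else {
    list(cols = idx, reason = "end")
  }
}

# run the compiled decay and package one side of a curve
.ehh_side <- function(hm, pos, core_idx, rows, init_class, pool2,
                      cutoff, max_gap, direction) {
  oc <- .outward_cols(pos, core_idx, direction, max_gap)
  if (!length(oc$cols))
    return(list(offset = numeric(), value = numeric(), reason = oc$reason))
  v <- ehh_decay_cpp(hm$H, rows - 1L, oc$cols - 1L, init_class, pool2,
                     cutoff)
  used <- oc$cols[seq_along(v)]
  reason <- if (length(v) && v[length(v)] < cutoff) "cutoff"
            else oc$reason
  list(offset = (pos[used] - pos[core_idx]),
       value = as.numeric(v), reason = reason)
}

#' Extended haplotype homozygosity around a core allele
#'
#' EHH at offset `x` is the probability that two random haplotypes carrying
#' the core allele are identical over the interval from the core out to
#' `x`: `sum_h C(n_h, 2) / C(n_core, 2)` over extended-haplotype classes
#' `h`. Computed site by site in both directions; a side is truncated when
#' EHH drops below `cutoff`, when an inter-site gap exceeds `max_gap`, or
#' at the contig end. Haplotypes are dropped from a side at their first
#' missing call there (the denominator stays `C(n_core, 2)`). Requires
#' phased data and at least 2 carriers.
#'
#' @param hm a [hap_matrix()] (restrict to one population via `rows`).
#' @param vt variant table aligned with `hm`.
#' @param core_site column index of the core site, or `"chrom:pos"`.
#' @param allele core allele code (0 or 1).
#' @param cutoff truncation threshold (default 0.05).
#' @param max_gap maximum tolerated inter-site gap in bp (default 200 kb).
#' @param rows haplotype rows to use (default all).
#' @return data frame (`offset`, `pos`, `ehh`, `side`) including the core
#'   point (`offset` 0, `ehh` 1); attributes `truncation` (per side) and
#'   `n_carriers`.
#' @export
ehh <- function(hm, vt, core_site, allele, cutoff = 0.05, max_gap = 2e5,
                rows = NULL) {
  if (!hm$phased) stop("ehh: unphased haplotypes")
  core_idx <- .resolve_site(vt, core_site)
  if (is.null(rows)) rows <- seq_len(nrow(hm$H))
  carriers <- rows[which(hm$H[rows, core_idx] == allele)]
  if (length(carriers) < 2L)
    stop(sprintf("ehh: fewer than 2 carriers of allele %d at %s:%d",
                 allele, vt$chrom[core_idx], vt$pos[core_idx]))
  init <- rep(0L, length(carriers))
  left <- .ehh_side(hm, vt$pos, core_idx, carriers, init, FALSE,
                    cutoff, max_gap, -1L)
  right <- .ehh_side(hm, vt$pos, core_idx, carriers, init, FALSE,
                     cutoff, max_gap, +1L)
  out <- data.frame(
    offset = c(rev(left$offset), 0, right$offset),
    pos = vt$pos[core_idx] + c(rev(left$offset), 0, right$offset),
    ehh = c(rev(left$value), 1, right$value),
    side = c(rep("left", length(left$offset)), "core",
             rep("right", length(right$offset))),
    stringsAsFactors = FALSE)
  attr(out, "truncation") <- c(left = left$reason, right = right$reason)
  attr(out, "n_carriers") <- length(carriers)
  out
}

.resolve_site <- function(vt, core_site) {
  if (is.character(core_site)) {
    parts <- strsplit(core_site, ":", fixed = TRUE)[[1]]
    idx <- which(vt$chrom == parts[1] & vt$pos == as.integer(parts[2]))
    if (!length(idx)) stop("site not found: ", core_site)
    return(idx[1L])
  }
  as.integer(core_site)
}

# trapezoidal area of one side of a homozygosity curve; values below the
# cutoff are excluded (truncation happens at the last value >= cutoff)
.side_area <- function(offset, value, cutoff) {
  keep <- value >= cutoff
  if (!all(keep)) {
    first_bad <- which(!keep)[1L]
    offset <- offset[seq_len(first_bad - 1L)]
    value <- value[seq_len(first_bad - 1L)]
  }
  x <- c(0, abs(offset)); y <- c(1, value)
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' iHH12 at one core site
#'
#' EHH12 is EHH computed over all haplotypes at the core site (not a single
#' allele class) with the two most frequent extended-haplotype classes
#' pooled: `[C(n1+n2, 2) + sum_{i>=3} C(n_i, 2)] / C(n, 2)`. iHH12 is the
#' trapezoidal integral of EHH12 over physical distance, summed over both
#' directions, each side truncated at the cutoff, a gap, or the contig
#' end. Pooling the top two classes keeps power for soft as well as hard
#' sweeps.
#'
#' @inheritParams ehh
#' @return scalar iHH12 in bp-homozygosity units (`NA` if the core site is
#'   monomorphic among the selected haplotypes).
#' @export
ihh12_site <- function(hm, vt, core_site, cutoff = 0.05, max_gap = 2e5,
                       rows = NULL) {
  if (!hm$phased) stop("ihh12_site: unphased haplotypes")
  core_idx <- .resolve_site(vt, core_site)
  if (is.null(rows)) rows <- seq_len(nrow(hm$H))
  alleles <- hm$H[rows, core_idx]
  use <- rows[!is.na(alleles)]
  a <- alleles[!is.na(alleles)]
  if (length(use) < 2L || length(unique(a)) < 2L) return(NA_real_)
  init <- as.integer(a)
  left <- .ehh_side(hm, vt$pos, core_idx, use, init, TRUE,
                    cutoff, max_gap, -1L)
  right <- .ehh_side(hm, vt$pos, core_idx, use, init, TRUE,
                     cutoff, max_gap, +1L)
  .side_area(left$offset, left$value, cutoff) +
    .side_area(right$offset, right$value, cutoff)
}

#' iHH12 scan over sites
#'
#' @inheritParams ehh
#' @param sites column indices to score (default: all sites).
#' @return data frame `chrom`, `pos`, `id`, `ihh12`, `n_hap`.
#' @export
ihh12_scan <- function(hm, vt, sites = NULL, cutoff = 0.05, max_gap = 2e5,
                       rows = NULL) {
  if (is.null(sites)) sites <- seq_len(ncol(hm$H))
  if (is.null(rows)) rows <- seq_len(nrow(hm$H))
  vals <- vapply(sites, function(s)
    ihh12_site(hm, vt, s, cutoff, max_gap, rows), numeric(1))
  data.frame(chrom = vt$chrom[sites], pos = vt$pos[sites],
             id = vt$id[sites], ihh12 = vals, n_hap = length(rows),
             stringsAsFactors = FALSE)
}

#' Standardize iHH12 scores
#'
#' Genome-wide z-scores `(ihh12 - mean)/sd`; optionally standardized
#' within 10 equal-width derived-allele-frequency bins.
#'
#' @param tbl output of [ihh12_scan()].
#' @param freqs derived allele frequencies per site (needed for binning).
#' @param bins number of frequency bins (1 = genome-wide, 10 = binned).
#' @return `tbl` with a `z` column added.
#' @export
standardize_ihh12 <- function(tbl, freqs = NULL, bins = 1L) {
  ok <- !is.na(tbl$ihh12)
  if (sum(ok) < 50L)
    warning("standardize_ihh12: fewer than 50 scored sites")
  z <- rep(NA_real_, nrow(tbl))
  zscore <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) {
      warning("standardize_ihh12: zero variance; all z set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  if (bins <= 1L) {
    z[ok] <- zscore(tbl$ihh12[ok])
  } else {
    if (is.null(freqs)) stop("standardize_ihh12: freqs needed for binning")
    bin <- cut(freqs, breaks = seq(0, 1, length.out = bins + 1L),
               include.lowest = TRUE)
    for (b in levels(bin)) {
      sel <- ok & !is.na(bin) & bin == b
      if (sum(sel) >= 2L) z[sel] <- zscore(tbl$ihh12[sel])
      else if (any(sel)) z[sel] <- 0
    }
  }
  tbl$z <- z
  tbl
}
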