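#' Read a population map TSV
#'
#' Three columns: `sample`, `group`, `role` with role in
#' `{focal, reference, outgroup}`. A header line is detected automatically.
#'
#' @param path TSV file.
#' @return data frame (`sample`, `group`, `role`).
#' @export
read_popmap <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- identical(tolower(first[1]), "sample")
  pm <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  names(pm) <- c("sample", "group", "role")[seq_len(ncol(pm))]
  bad <- setdiff(unique(pm$role), c("focal", "reference", "outgroup"))
  if (length(bad))
    stop("read_popmap: unknown role(s): ", paste(bad, collapse = ", "))
  pm
}

#' Read gene intervals from a BED-like file
#'
#' @param path BED file (0-based half-open), columns chrom, start, end and
#'   optionally a name.
#' @return data frame (`chrom`, `start`, `end`, `id`).
#' @export
read_genes_bed <- function(path) {
  g <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(g) < 3L) stop("read_genes_bed: need at least 3 columns")
  out <- data.frame(chrom = as.character(g[[1]]),
                    start = as.numeric(g[[2]]), end = as.numeric(g[[3]]),
                    id = if (ncol(g) >= 4L) as.character(g[[4]])
                         else sprintf("gene%02d", seq_len(nrow(g))),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start))
    stop("read_genes_bed: intervals must satisfy end > start")
  out
}

#' Read phased genotypes from a VCF
#'
#' Keeps biallelic SNP records only; multi-allelic or non-SNP records are
#' skipped and counted (attribute `n_skipped`, also reported on stderr).
#' Missing genotypes are masked. If a population map is supplied, samples
#' are checked and ordered accordingly.
#'
#' @param path VCF file (v4.2, GT field).
#' @param popmap optional population map data frame; every mapped sample
#'   must be present in the VCF.
#' @param allow_unphased accept `/`-separated genotypes; haplotype-based
#'   statistics refuse to run on unphased data.
#' @return list with `hap` (a [hap_matrix()]) and `variants` (variant
#'   table with `effect_class` parsed from the `EC` INFO key when present).
#' @export
read_vcf <- function(path, popmap = NULL, allow_unphased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!keep)
  if (n_skipped)
    message("read_vcf: skipped ", n_skipped,
            " multi-allelic or non-SNP record(s)")

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt)

  if (!is.null(popmap)) {
    missing <- setdiff(popmap$sample, samples)
    if (length(missing))
      stop("read_vcf: sample(s) in popmap absent from VCF: ",
           paste(missing, collapse = ", "))
    gt <- gt[, popmap$sample, drop = FALSE]
    samples <- popmap$sample
  }

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  a1[a1 == "." | a1 == ""] <- NA
  a2[a2 == "." | a2 == ""] <- NA
  a2[is.na(gt) | sep == ""] <- NA          # haploid-style or empty records
  unph <- sep == "/" & !is.na(a1) & !is.na(a2)
  phased <- !any(unph, na.rm = TRUE)
  if (!phased && !allow_unphased)
    stop("read_vcf: unphased genotypes found; rerun with ",
         "allow_unphased = TRUE (haplotype statistics will refuse to run)")

  V <- nrow(gt); N <- length(samples)
  H <- matrix(NA_integer_, nrow = 2L * N, ncol = V)
  H[seq(1L, 2L * N, 2L), ] <- t(matrix(as.integer(a1), nrow = V))
  H[seq(2L, 2L * N, 2L), ] <- t(matrix(as.integer(a2), nrow = V))

  info <- fix[, "INFO"]
  ec <- rep("unknown", V)
  m <- regmatches(info, regexpr("EC=[A-Za-z_]+", info))
  has <- grepl("EC=", info)
  ec[has] <- sub("EC=", "", m)
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[is.na(id) | id == ".", "CHROM"],
                                      "_", fix[is.na(id) | id == ".", "POS"])
  vt <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                   id = id, ref = fix[, "REF"], alt = fix[, "ALT"],
                   effect_class = ec, ancestral_state = "unpolarized",
                   stringsAsFactors = FALSE)
  ord <- order(vt$chrom, vt$pos)
  vt <- vt[ord, , drop = FALSE]; rownames(vt) <- NULL
  H <- H[, ord, drop = FALSE]
  hm <- hap_matrix(H, samples, phased = phased)
  structure(list(hap = hm, variants = vt), n_skipped = n_skipped)
}

#' Site filters: minor allele frequency and missingness
#'
#' Retains sites with `MAF >= maf` and missing-call fraction
#' `<= max_missing`. Frequencies and missingness are computed over the
#' non-outgroup (focal + reference) samples only; the denominator of the
#' MAF excludes missing calls. The two filters are order-independent.
#'
#' @param hm a [hap_matrix()].
#' @param vt variant table aligned with `hm`.
#' @param popmap population map; `NULL` treats all samples as in-group.
#' @param maf minor allele frequency threshold (default 0.05).
#' @param max_missing maximum missing fraction (default 0.2).
#' @return list (`hap`, `variants`) restricted to passing sites, with a
#'   `filter_report` attribute counting drops per reason.
#' @export
apply_filters <- function(hm, vt, popmap = NULL, maf = 0.05,
                          max_missing = 0.2) {
  rows <- if (is.null(popmap)) seq_len(nrow(hm$H))
          else pop_rows(hm, popmap, role = c("focal", "reference"))
  called <- .called(hm$H, rows)
  alt <- .alt_count(hm$H, rows)
  p <- ifelse(called > 0, alt / called, NA_real_)
  mafv <- pmin(p, 1 - p)
  missfrac <- 1 - called / length(rows)
  fail_maf <- is.na(mafv) | mafv < maf
  fail_miss <- missfrac > max_missing
  keep <- !fail_maf & !fail_miss
  report <- list(n_input = length(keep),
                 n_fail_maf = sum(fail_maf),
                 n_fail_missing = sum(fail_miss),
                 n_kept = sum(keep))
  if (!any(keep))
    warning("apply_filters: all sites removed")
  out <- list(hap = subset_sites(hm, keep),
              variants = {x <- vt[keep, , drop = FALSE]; rownames(x) <- NULL; x})
  attr(out, "filter_report") <- report
  out
}

#' Polarize alleles against the outgroup panel
#'
#' A site's ancestral state is the allele for which all called outgroup
#' haplotypes agree, provided at least `min_outgroup` outgroup samples are
#' fully called there; otherwise the site stays unpolarized. Focal and
#' reference genotypes are never inspected.
#'
#' @param hm a [hap_matrix()].
#' @param vt variant table aligned with `hm`.
#' @param popmap population map with at least one outgroup sample.
#' @param min_outgroup minimum number of called outgroup samples (default
#'   2: a single outgroup genotype cannot separate lineage-specific
#'   substitution from genotyping error).
#' @return the variant table with `ancestral_state` set to `"ref"`,
#'   `"alt"` or `"unpolarized"`.
#' @export
polarize <- function(hm, vt, popmap, min_outgroup = 2L) {
  og_samples <- popmap$sample[popmap$role == "outgroup"]
  if (!length(og_samples)) stop("polarize: no outgroup samples in popmap")
  rows <- hap_rows(hm, og_samples)
  G <- hm$H[rows, , drop = FALSE]
  n_og <- length(og_samples)
  odd <- seq(1L, 2L * n_og, 2L)
  sample_called <- colSums(!is.na(G[odd, , drop = FALSE]) &
                           !is.na(G[odd + 1L, , drop = FALSE]))
  n0 <- colSums(G == 0L, na.rm = TRUE)
  n1 <- colSums(G == 1L, na.rm = TRUE)
  anc <- rep("unpolarized", ncol(G))
  ok <- sample_called >= min_outgroup
  anc[ok & n0 > 0L & n1 == 0L] <- "ref"
  anc[ok & n1 > 0L & n0 == 0L] <- "alt"
  vt$ancestral_state <- anc
  vt
}

#' Sliding windows tiling a set of contigs
#'
#' Windows are 0-based half-open. Starts advance by `step`; a final window
#' `[len - size, len)` is appended when the regular tiling would leave the
#' contig tail uncovered, so every bp is covered at least once whenever
#' `step <= size`.
#'
#' @param contigs named numeric vector of contig lengths (names = chrom).
#' @param size window size in bp.
#' @param step step in bp; must satisfy `size >= step > 0`.
#' @return data frame (`chrom`, `start`, `end`, `id`).
#' @export
make_windows <- function(contigs, size = 5e4, step = 2.5e4) {
  if (!(size >= step && step > 0)) stop("make_windows: need size >= step > 0")
  res <- lapply(names(contigs), function(ch) {
    len <- contigs[[ch]]
    if (len <= size) {
      starts <- 0
      ends <- len
    } else {
      starts <- seq(0, len - size, by = step)
      if (max(starts) + size < len) starts <- c(starts, len - size)
      ends <- starts + size
    }
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, res)
  w$id <- sprintf("%s:%d-%d", w$chrom, as.integer(w$start),
                  as.integer(w$end))
  rownames(w) <- NULL
  w
}

#' Assign items (SNPs or windows) to gene intervals
#'
#' Half-open interval semantics throughout: a SNP at 1-based position `p`
#' occupies the 0-based interval `[p-1, p)` and overlaps a gene `[s, e)`
#' iff `s <= p-1 < e`. Items overlapping no gene are absent from the
#' mapping; items overlapping several genes appear once per gene.
#'
#' @param items data frame with `chrom` plus either `pos` (1-based SNP
#'   position) or `start`/`end` (0-based half-open).
#' @param genes data frame (`chrom`, `start`, `end`, `id`); sorted
#'   internally with a warning if needed.
#' @return data frame (`item`, `gene`): row index into `items`, gene id.
#' @export
assign_to_genes <- function(items, genes) {
  ord <- order(genes$chrom, genes$start)
  if (!identical(ord, seq_len(nrow(genes)))) {
    warning("assign_to_genes: gene intervals were unsorted; sorting")
    genes <- genes[ord, , drop = FALSE]
  }
  if ("pos" %in% names(items) && !("start" %in% names(items))) {
    istart <- items$pos - 1
    iend <- items$pos
  } else {
    istart <- items$start
    iend <- items$end
  }
  res <- lapply(unique(genes$chrom), function(ch) {
    gi <- which(genes$chrom == ch)
    ii <- which(items$chrom == ch)
    if (!length(gi) || !length(ii)) return(NULL)
    # half-open [s,e) as closed integer ranges [s+1, e] on the 1-based grid
    q <- IRanges::IRanges(start = as.integer(istart[ii]) + 1L,
                          end = as.integer(iend[ii]))
    s <- IRanges::IRanges(start = as.integer(genes$start[gi]) + 1L,
                          end = as.integer(genes$end[gi]))
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) return(NULL)
    data.frame(item = ii[S4Vectors::queryHits(ov)],
               gene = genes$id[gi[S4Vectors::subjectHits(ov)]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(item = integer(), gene = character(),
                      stringsAsFactors = FALSE)
  out[order(out$item), , drop = FALSE]
}
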