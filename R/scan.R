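#' Aggregate window/site statistics to gene level
#'
#' Gene raw values are maxima over overlapping items (sweep signals are
#' local; a mean would dilute sub-gene peaks): the Fst + diversity-ratio
#' pair and the CLR + diversity-ratio pair take per-component maxima over
#' overlapping windows / grid points; iHH12 takes the maximum site
#' z-score; the HKA method takes the gene unit's own signed score (missing
#' when the unit is unusable). Genes overlapping no data for a method are
#' missing for that method.
#'
#' @param genes gene intervals (`chrom`, `start`, `end`, `id`).
#' @param wstats output of [window_stats()].
#' @param xp output of [xpclr_scan()].
#' @param ihh output of [standardize_ihh12()] (site-level, with `z`).
#' @param hka output of [hka_test()] with genes as units.
#' @return data frame: `gene`, `fst`, `pi_ratio`, `clr`, `ihh12_z`, `hka`.
#' @export
aggregate_to_genes <- function(genes, wstats, xp, ihh, hka) {
  out <- data.frame(gene = genes$id, fst = NA_real_, pi_ratio = NA_real_,
                    clr = NA_real_, ihh12_z = NA_real_, hka = NA_real_,
                    stringsAsFactors = FALSE)
  max_by_gene <- function(items, values, col) {
    asn <- assign_to_genes(items, genes)
    if (!nrow(asn)) return()
    v <- values[asn$item]
    ok <- !is.na(v)
    if (!any(ok)) return()
    mx <- tapply(v[ok], asn$gene[ok], max)
    out[[col]][match(names(mx), out$gene)] <<- as.numeric(mx)
  }
  max_by_gene(wstats, wstats$fst, "fst")
  max_by_gene(wstats, wstats$log2_pi_ratio, "pi_ratio")
  gp <- data.frame(chrom = xp$chrom, start = xp$grid_pos,
                   end = xp$grid_pos + 1)
  max_by_gene(gp, xp$clr, "clr")
  max_by_gene(ihh, ihh$z, "ihh12_z")
  m <- match(hka$id, out$gene)
  ok <- !is.na(m) & hka$usable
  out$hka[m[ok]] <- hka$signed_score[ok]
  out
}

# empirical percentile with average ranks for ties, over non-missing values
.percentile <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- rank(x[ok], ties.method = "average") / sum(ok)
  out
}

#' Call percentile outliers per method
#'
#' Empirical percentiles (average ranks for ties) are computed per
#' statistic over genes with data. The paired methods (`fst_pi`,
#' `xpclr_pi`) flag a gene only when BOTH component statistics lie in
#' their top `q_pair` fraction; the single-statistic methods (`ihh12`,
#' `hka`) use the top `q_site` fraction. A method's reported percentile is
#' the smaller of its component percentiles, so the joint rule reads
#' `percentile > 1 - q`.
#'
#' @param gene_scores output of [aggregate_to_genes()].
#' @param q_pair outlier fraction for the paired methods (default 0.05).
#' @param q_site outlier fraction for the single-statistic methods
#'   (default 0.01).
#' @return long data frame: `gene`, `method`, `stat1`, `stat2`,
#'   `percentile`, `outlier`.
#' @export
call_outliers <- function(gene_scores, q_pair = 0.05, q_site = 0.01) {
  g <- gene_scores
  n <- nrow(g)
  if (n < 1 / min(q_pair, q_site))
    warning("call_outliers: fewer than 1/q genes with data; ",
            "outlier sets may be empty or a single gene")
  p_fst <- .percentile(g$fst)
  p_ratio <- .percentile(g$pi_ratio)
  p_clr <- .percentile(g$clr)
  p_z <- .percentile(g$ihh12_z)
  p_hka <- .percentile(g$hka)
  joint <- function(p1, p2) pmin(p1, p2)
  mk <- function(method, s1, s2, pct, q) {
    data.frame(gene = g$gene, method = method, stat1 = s1, stat2 = s2,
               percentile = pct,
               outlier = !is.na(pct) & pct > 1 - q,
               stringsAsFactors = FALSE)
  }
  rbind(mk("fst_pi", g$fst, g$pi_ratio, joint(p_fst, p_ratio), q_pair),
        mk("xpclr_pi", g$clr, g$pi_ratio, joint(p_clr, p_ratio), q_pair),
        mk("ihh12", g$ihh12_z, NA_real_, p_z, q_site),
        mk("hka", g$hka, NA_real_, p_hka, q_site))
}

#' Intersect methods into candidate calls
#'
#' A gene is a candidate when at least 3 of the 4 methods flag it, and a
#' strict candidate when all 4 do.
#'
#' @param scores output of [call_outliers()].
#' @return data frame: `gene`, `methods` (comma-joined), `n_support`,
#'   `candidate`, `strict`.
#' @export
intersect_methods <- function(scores) {
  genes <- unique(scores$gene)
  sup <- lapply(genes, function(gn)
    sort(scores$method[scores$gene == gn & scores$outlier]))
  n <- vapply(sup, length, integer(1))
  data.frame(gene = genes,
             methods = vapply(sup, paste, "", collapse = ","),
             n_support = n,
             candidate = n >= 3L,
             strict = n == 4L,
             stringsAsFactors = FALSE)
}

#' Top ΔdAF variant per effect class among candidate genes
#'
#' Within the selected candidate genes, returns the polarized variant with
#' the largest derived-allele-frequency difference separately for the
#' regulatory class and for the protein-altering exonic (missense) class.
#' Ties on ΔdAF are all reported; the leader is the smallest genomic
#' coordinate.
#'
#' @param candidates output of [intersect_methods()].
#' @param genes gene intervals.
#' @param daf output of [site_daf_table()] (per-site ΔdAF + effect class).
#' @param min_methods 4 restricts to strict candidates (default), 3 to all
#'   candidates.
#' @return data frame: `class`, `chrom`, `pos`, `id`, `gene`,
#'   `delta_daf`, `n_ties`, `leader`. Classes with no eligible site are
#'   absent.
#' @export
top_variants <- function(candidates, genes, daf, min_methods = 4L) {
  keep_genes <- candidates$gene[candidates$n_support >= min_methods]
  if (!length(keep_genes)) return(.empty_leaders())
  gsub <- genes[genes$id %in% keep_genes, , drop = FALSE]
  asn <- assign_to_genes(daf, gsub)
  if (!nrow(asn)) return(.empty_leaders())
  classes <- list(regulatory = "regulatory", exonic = "missense")
  res <- lapply(names(classes), function(cl) {
    sel <- asn[daf$effect_class[asn$item] %in% classes[[cl]] &
               daf$polarized[asn$item] &
               !is.na(daf$delta_daf[asn$item]), , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    dv <- daf$delta_daf[sel$item]
    best <- max(dv)
    hits <- sel[dv == best, , drop = FALSE]
    ord <- order(daf$pos[hits$item])
    hits <- hits[ord, , drop = FALSE]
    data.frame(class = cl,
               chrom = daf$chrom[hits$item],
               pos = daf$pos[hits$item],
               id = daf$id[hits$item],
               gene = hits$gene,
               delta_daf = best,
               n_ties = nrow(hits),
               leader = seq_len(nrow(hits)) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(.empty_leaders())
  rownames(out) <- NULL
  out
}

.empty_leaders <- function() {
  data.frame(class = character(), chrom = character(), pos = integer(),
             id = character(), gene = character(), delta_daf = numeric(),
             n_ties = integer(), leader = logical(),
             stringsAsFactors = FALSE)
}
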