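#' Default scan parameters
#'
#' @param maf,max_missing site filters (see [apply_filters()]).
#' @param min_outgroup polarization threshold (see [polarize()]).
#' @param window_size,window_step sliding-window geometry in bp.
#' @param q_pair,q_site outlier fractions (see [call_outliers()]).
#' @param divergence_min HKA usability threshold (see [hka_test()]).
#' @param min_methods candidate-variant gene restriction (see
#'   [top_variants()]).
#' @param xpclr list of [xpclr_scan()] arguments to override.
#' @param ihh12 list with `cutoff`, `max_gap`, `bins`.
#' @return named list of parameters.
#' @export
scan_params <- function(maf = 0.05, max_missing = 0.2, min_outgroup = 2L,
                        window_size = 5e4, window_step = 2.5e4,
                        q_pair = 0.05, q_site = 0.01,
                        divergence_min = 60L, min_methods = 4L,
                        xpclr = list(), ihh12 = list()) {
  list(maf = maf, max_missing = max_missing, min_outgroup = min_outgroup,
       window_size = window_size, window_step = window_step,
       q_pair = q_pair, q_site = q_site,
       divergence_min = divergence_min, min_methods = min_methods,
       xpclr = xpclr, ihh12 = ihh12)
}

#' Run the full four-method selection scan
#'
#' Orchestrates: site filtering and outgroup polarization, the windowed
#' Fst + diversity scan, the cross-population composite likelihood ratio
#' scan, the iHH12 scan of the focal population, the HKA-like test with
#' genes as units, gene-level aggregation, percentile outlier calling,
#' the three-of-four intersection, and top-ΔdAF variant selection.
#'
#' The MAF filter is applied to the four scan statistics only; HKA
#' polymorphism/divergence counting runs on the missingness-filtered site
#' set, since a pig-panel MAF filter would delete exactly the fixed
#' outgroup differences that measure divergence.
#'
#' @param hm a [hap_matrix()] over all samples.
#' @param vt variant table aligned with `hm`.
#' @param popmap population map (one focal group, one reference group,
#'   >= 1 outgroup sample).
#' @param genes gene intervals.
#' @param params a [scan_params()] list.
#' @param contig_length contig length in bp (default: gene span).
#' @return list with elements `windows`, `window_stats`, `xpclr`,
#'   `ihh12`, `hka`, `hka_counts`, `gene_scores`, `outliers`,
#'   `candidates`, `leaders`, `daf`, `filter_report`, `params`.
#' @export
run_scan <- function(hm, vt, popmap, genes, params = scan_params(),
                     contig_length = NULL) {
  if (is.null(contig_length)) contig_length <- max(genes$end)
  # missingness-only filtered set (for HKA counting)
  base <- apply_filters(hm, vt, popmap, maf = 0, max_missing = params$max_missing)
  # fully filtered set (for the scan statistics)
  flt <- apply_filters(base$hap, base$variants, popmap,
                       maf = params$maf, max_missing = params$max_missing)
  hms <- flt$hap
  vts <- polarize(hms, flt$variants, popmap,
                  min_outgroup = params$min_outgroup)

  windows <- make_windows(setNames(contig_length, genes$chrom[1]),
                          params$window_size, params$window_step)
  ws <- window_stats(hms, vts, popmap, windows)

  xp_args <- c(list(hm = hms, vt = vts, popmap = popmap,
                    contig_length = contig_length), params$xpclr)
  xp <- do.call(xpclr_scan, xp_args)

  rf <- pop_rows(hms, popmap, role = "focal")
  ih_args <- params$ihh12
  ih <- ihh12_scan(hms, vts,
                   cutoff = ih_args$cutoff %||% 0.05,
                   max_gap = ih_args$max_gap %||% 2e5,
                   rows = rf)
  gf <- unique(popmap$group[popmap$role == "focal"])[1]
  freqs <- allele_freq(hms, vts, popmap, gf)$freq
  ih <- standardize_ihh12(ih, freqs = freqs, bins = ih_args$bins %||% 1L)

  pd <- count_pd(base$hap, base$variants, popmap, genes,
                 min_outgroup = params$min_outgroup)
  hka <- hka_test(pd, divergence_min = params$divergence_min)

  gs <- aggregate_to_genes(genes, ws, xp, ih, hka)
  outl <- call_outliers(gs, q_pair = params$q_pair, q_site = params$q_site)
  cand <- intersect_methods(outl)
  daf <- site_daf_table(hms, vts, popmap)
  leaders <- top_variants(cand, genes, daf,
                          min_methods = params$min_methods)

  list(windows = windows, window_stats = ws, xpclr = xp, ihh12 = ih,
       hka = hka, hka_counts = pd, gene_scores = gs, outliers = outl,
       candidates = cand, leaders = leaders, daf = daf,
       filter_report = attr(flt, "filter_report"), params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a complete reproducible scan from files
#'
#' Reads a VCF, population map and gene BED (or simulates them when the
#' config has a `simulate` block), runs [run_scan()], and writes all stage
#' tables as TSVs plus a machine-readable `summary.json`. Every output
#' carries a header comment with the seed and config hash; re-running the
#' same config reproduces the outputs byte-identically.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `out` (output directory), `seed`, either `simulate` (a list of
#'   [sim_config()] arguments) or `vcf`/`popmap`/`genes` paths, and an
#'   optional `params` list of [scan_params()] overrides.
#' @return invisibly, the [run_scan()] result list plus `summary`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out)) stop("run_all: config needs an 'out' directory")
  seed <- config$seed %||% 1L
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  cfg_file <- file.path(config$out, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  hdr <- sprintf("# coldscan run seed=%s config_md5=%s", seed, cfg_hash)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    hm <- sim$hap; vt <- sim$variants; popmap <- sim$popmap
    genes <- sim$genes
    contig_length <- sim$config$L
    truth <- sim$truth
  } else {
    popmap <- read_popmap(config$popmap)
    inp <- read_vcf(config$vcf, popmap)
    hm <- inp$hap; vt <- inp$variants
    genes <- read_genes_bed(config$genes)
    contig_length <- config$contig_length %||% max(genes$end)
    truth <- NULL
  }

  params <- do.call(scan_params, config$params %||% list())
  res <- run_scan(hm, vt, popmap, genes, params,
                  contig_length = contig_length)

  wt <- function(df, name) {
    path <- file.path(config$out, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wt(res$window_stats, "window_stats.tsv")
  wt(res$xpclr, "xpclr.tsv")
  wt(res$ihh12, "ihh12.tsv")
  wt(res$hka, "hka.tsv")
  wt(res$gene_scores, "gene_scores.tsv")
  wt(res$outliers, "outliers.tsv")
  wt(res$candidates, "candidates.tsv")
  wt(res$leaders, "leaders.tsv")
  wt(res$daf, "site_daf.tsv")

  summary <- list(
    seed = seed, config_md5 = cfg_hash,
    n_sites_scanned = res$filter_report$n_kept,
    candidate_genes = res$candidates$gene[res$candidates$candidate],
    strict_genes = res$candidates$gene[res$candidates$strict],
    leaders = res$leaders,
    truth = truth)
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  res$summary <- summary
  invisible(res)
}
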