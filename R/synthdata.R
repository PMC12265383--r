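#' Simulation configuration
#'
#' Parameters of the synthetic cold/warm/outgroup haplotype generator. The
#' neutral background draws per-population allele frequencies from the
#' Balding-Nichols model around a shared ancestral frequency, which gives a
#' tunable background differentiation; an optional hard sweep is injected by
#' haplotype replacement (see [inject_sweep()]).
#'
#' @param seed integer RNG seed; all outputs are deterministic given the
#'   full configuration.
#' @param L sequence length in bp.
#' @param n_focal,n_reference,n_outgroup diploid sample counts for the
#'   focal ("cold"), reference ("warm") and outgroup panels.
#' @param theta_site target expected per-bp heterozygosity of the neutral
#'   background within each pig population (dimensionless).
#' @param d_og per-bp divergence of the outgroup lineage: the rate at which
#'   sites fixed in the pigs carry a different allele fixed in the outgroup.
#' @param fst_background target background differentiation between focal
#'   and reference populations (the Balding-Nichols F parameter, 0-1).
#' @param sweep_on logical; whether a hard sweep is injected.
#' @param sweep_center sweep midpoint, 0-based bp.
#' @param sweep_width sweep interval width in bp; the swept interval is
#'   `[sweep_center - sweep_width/2, sweep_center + sweep_width/2)`.
#' @param sweep_fraction fraction `f` of focal haplotypes replaced by the
#'   sweep haplotype (0-1). The realized fraction is
#'   `round(f * 2 * n_focal) / (2 * n_focal)`.
#' @param n_genes number of equal gene tiles spanning `[0, L)`.
#' @param p_anc_range range of the uniform ancestral allele frequency draw.
#' @param effect_probs named numeric: sampling probabilities of the variant
#'   effect classes `regulatory`, `missense`, `synonymous`, `other`.
#' @param sweep_effect_class effect class assigned to the injected sweep
#'   variant.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, L = 2e6,
                       n_focal = 15L, n_reference = 21L, n_outgroup = 15L,
                       theta_site = 1e-3, d_og = 0.01, fst_background = 0.05,
                       sweep_on = FALSE, sweep_center = 1.1e6,
                       sweep_width = 2e5, sweep_fraction = 0.9,
                       n_genes = 10L,
                       p_anc_range = c(0.05, 0.95),
                       effect_probs = c(regulatory = 0.05, missense = 0.02,
                                        synonymous = 0.03, other = 0.90),
                       sweep_effect_class = "regulatory") {
  cfg <- list(seed = as.integer(seed), L = as.numeric(L),
              n_focal = as.integer(n_focal),
              n_reference = as.integer(n_reference),
              n_outgroup = as.integer(n_outgroup),
              theta_site = theta_site, d_og = d_og,
              fst_background = fst_background,
              sweep_on = isTRUE(sweep_on),
              sweep_center = sweep_center, sweep_width = sweep_width,
              sweep_fraction = sweep_fraction,
              n_genes = as.integer(n_genes),
              p_anc_range = p_anc_range,
              effect_probs = effect_probs,
              sweep_effect_class = sweep_effect_class)
  if (cfg$L <= 0) stop("sim_config: zero-length sequence")
  if (cfg$n_focal < 2L || cfg$n_reference < 2L || cfg$n_outgroup < 2L)
    stop("sim_config: sample counts must be >= 2")
  if (cfg$sweep_fraction < 0 || cfg$sweep_fraction > 1)
    stop("sim_config: sweep_fraction must be in [0, 1]")
  if (!(cfg$theta_site >= 0 && cfg$theta_site < cfg$d_og && cfg$d_og < 1))
    stop("sim_config: need 0 <= theta_site < d_og < 1")
  if (cfg$fst_background < 0 || cfg$fst_background >= 1)
    stop("sim_config: fst_background must be in [0, 1)")
  lo <- cfg$sweep_center - cfg$sweep_width / 2
  hi <- cfg$sweep_center + cfg$sweep_width / 2
  if (cfg$sweep_on && (lo < 0 || hi > cfg$L))
    stop("sim_config: sweep interval must lie within [0, L)")
  if (cfg$n_genes < 1L) stop("sim_config: n_genes must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# E[2p(1-p)] for p ~ U(a, b)
.mean_2pq_unif <- function(a, b) {
  ep  <- (a + b) / 2
  ep2 <- (a * a + a * b + b * b) / 3
  2 * (ep - ep2)
}

.sample_names <- function(cfg) {
  list(focal     = sprintf("cold%02d", seq_len(cfg$n_focal)),
       reference = sprintf("warm%02d", seq_len(cfg$n_reference)),
       outgroup  = sprintf("og%02d",   seq_len(cfg$n_outgroup)))
}

#' Simulate the neutral background
#'
#' Places biallelic sites uniformly on `[0, L)`. At pig-polymorphic sites an
#' ancestral frequency `p` is drawn uniformly and focal/reference population
#' frequencies are drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' `F = fst_background` (Balding-Nichols); haplotype alleles are Bernoulli
#' draws from the population frequency. The outgroup is fixed for the
#' ancestral (REF) allele at pig-polymorphic sites. Additional divergent
#' sites (Binomial(L, d_og) of them) are fixed REF in the pigs and fixed ALT
#' in the outgroup. The number of polymorphic sites is chosen so that the
#' expected within-population per-bp heterozygosity is `theta_site`.
#'
#' @param config a [sim_config()] with `sweep_on = FALSE` (a sweep is added
#'   separately by [inject_sweep()]).
#' @return a `sim_output` list: `hap` ([hap_matrix()]), `variants` (variant
#'   table), `popmap`, `genes` (0-based half-open tiles), `truth`, `config`.
#' @export
simulate_neutral <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  nm <- .sample_names(cfg)
  n2f <- 2L * cfg$n_focal; n2r <- 2L * cfg$n_reference; n2o <- 2L * cfg$n_outgroup
  FF  <- cfg$fst_background
  a <- cfg$p_anc_range[1]; b <- cfg$p_anc_range[2]

  n_poly <- if (cfg$theta_site <= 0) 0L else
    as.integer(round(cfg$theta_site * cfg$L /
                       (.mean_2pq_unif(a, b) * (1 - FF))))
  n_div <- rbinom(1L, size = as.integer(cfg$L), prob = cfg$d_og)
  n_tot <- n_poly + n_div
  if (n_tot > cfg$L) stop("simulate_neutral: more sites than base pairs")

  pos <- sample.int(cfg$L, n_tot)          # 1-based positions, random order
  pos_poly <- pos[seq_len(n_poly)]
  pos_div  <- pos[seq_len(n_div) + n_poly]

  # polymorphic sites
  p_anc <- runif(n_poly, a, b)
  if (FF > 0) {
    sh <- (1 - FF) / FF
    p_f <- rbeta(n_poly, p_anc * sh, (1 - p_anc) * sh)
    p_r <- rbeta(n_poly, p_anc * sh, (1 - p_anc) * sh)
  } else {
    p_f <- p_anc; p_r <- p_anc
  }
  Hf <- matrix(rbinom(n2f * n_poly, 1L, rep(p_f, each = n2f)), nrow = n2f)
  Hr <- matrix(rbinom(n2r * n_poly, 1L, rep(p_r, each = n2r)), nrow = n2r)
  Ho <- matrix(0L, nrow = n2o, ncol = n_poly)

  # divergent sites: pigs fixed REF, outgroup fixed ALT
  Hf <- cbind(Hf, matrix(0L, n2f, n_div))
  Hr <- cbind(Hr, matrix(0L, n2r, n_div))
  Ho <- cbind(Ho, matrix(1L, n2o, n_div))

  H <- rbind(Hf, Hr, Ho)
  allpos <- c(pos_poly, pos_div)
  ord <- order(allpos)
  H <- H[, ord, drop = FALSE]
  allpos <- allpos[ord]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_tot, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  eff <- sample(names(cfg$effect_probs), n_tot, replace = TRUE,
                prob = cfg$effect_probs)

  variants <- data.frame(
    chrom = "1", pos = allpos,
    id = sprintf("snp_%d", allpos),
    ref = ref, alt = unname(alt),
    effect_class = eff,
    ancestral_state = "unpolarized",
    stringsAsFactors = FALSE)

  samples <- c(nm$focal, nm$reference, nm$outgroup)
  popmap <- data.frame(
    sample = samples,
    group = rep(c("cold", "warm", "outgroup"),
                c(cfg$n_focal, cfg$n_reference, cfg$n_outgroup)),
    role = rep(c("focal", "reference", "outgroup"),
               c(cfg$n_focal, cfg$n_reference, cfg$n_outgroup)),
    stringsAsFactors = FALSE)

  out <- list(hap = hap_matrix(H, samples, phased = TRUE),
              variants = variants,
              popmap = popmap,
              genes = gene_tiles(cfg$L, cfg$n_genes),
              truth = list(sweep = FALSE),
              config = cfg)
  class(out) <- "sim_output"
  out
}

#' Equal gene tiles over a contig
#'
#' @param L contig length in bp.
#' @param n_genes number of tiles.
#' @return data frame (`chrom`, `start`, `end`, `id`), 0-based half-open.
#' @export
gene_tiles <- function(L, n_genes) {
  bounds <- floor(seq(0, L, length.out = n_genes + 1L))
  data.frame(chrom = "1",
             start = bounds[-length(bounds)],
             end = bounds[-1L],
             id = sprintf("gene%02d", seq_len(n_genes)),
             stringsAsFactors = FALSE)
}

#' Inject a hard selective sweep by haplotype replacement
#'
#' One focal haplotype is chosen as the sweep (donor) haplotype; a fraction
#' `f` of focal haplotypes have their alleles inside the sweep interval
#' replaced by the donor's alleles, and a new derived variant -- absent from
#' the reference and outgroup panels -- is added at the sweep center,
#' carried by exactly the swept haplotypes. This produces the four
#' signatures the scan consumes: reduced focal diversity, elevated Fst,
#' extended haplotype homozygosity and a focal derived-allele frequency of
#' (approximately) `f` at the sweep site.
#'
#' @param neutral output of [simulate_neutral()].
#' @param config a [sim_config()] with `sweep_on = TRUE`.
#' @return a `sim_output` with updated haplotypes, variants and `truth`
#'   (`interval`, `pos` of the sweep variant, realized fraction, swept
#'   haplotype rows, overlapping gene id).
#' @export
inject_sweep <- function(neutral, config) {
  cfg <- config
  if (!cfg$sweep_on) stop("inject_sweep: sweep_on must be TRUE")
  set.seed(cfg$seed + 1L)
  n2f <- 2L * cfg$n_focal
  k <- as.integer(round(cfg$sweep_fraction * n2f))
  if (k < 2L)
    stop("inject_sweep: sweep class must have >= 2 haplotypes ",
         "(f * 2 * n_focal < 2)")
  lo <- cfg$sweep_center - cfg$sweep_width / 2   # 0-based half-open interval
  hi <- cfg$sweep_center + cfg$sweep_width / 2

  out <- neutral
  H <- out$hap$H
  vt <- out$variants
  off <- vt$pos - 1                              # 0-based site offsets
  in_int <- which(off >= lo & off < hi)

  donor <- sample.int(n2f, 1L)
  swept <- c(donor, sample(setdiff(seq_len(n2f), donor), k - 1L))
  if (length(in_int))
    H[swept, in_int] <- rep(H[donor, in_int], each = k)

  # new derived variant at the sweep center (collision-free position)
  newpos <- as.integer(cfg$sweep_center) + 1L    # 1-based
  while (newpos %in% vt$pos) newpos <- newpos + 1L
  newcol <- integer(nrow(H))
  newcol[swept] <- 1L
  ins <- sum(vt$pos < newpos)
  H <- cbind(H[, seq_len(ins), drop = FALSE], newcol,
             H[, ins + seq_len(ncol(H) - ins), drop = FALSE])
  refb <- sample(c("A", "C", "G", "T"), 1L)
  altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
  newrow <- data.frame(chrom = "1", pos = newpos, id = "sweep_variant",
                       ref = refb, alt = altb,
                       effect_class = cfg$sweep_effect_class,
                       ancestral_state = "unpolarized",
                       stringsAsFactors = FALSE)
  vt <- rbind(vt[seq_len(ins), , drop = FALSE], newrow,
              vt[ins + seq_len(nrow(vt) - ins), , drop = FALSE])
  rownames(vt) <- NULL

  out$hap <- hap_matrix(H, out$hap$samples, out$hap$phased)
  out$variants <- vt
  g <- out$genes
  gi <- which(g$start <= cfg$sweep_center & g$end > cfg$sweep_center)
  out$truth <- list(sweep = TRUE,
                    interval = c(lo, hi),
                    pos = newpos,
                    f = cfg$sweep_fraction,
                    f_realized = k / n2f,
                    n_swept = k,
                    donor = donor,
                    swept_rows = sort(swept),
                    gene = if (length(gi)) g$id[gi[1L]] else NA_character_)
  out$config <- cfg
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_neutral()] followed by [inject_sweep()]
#' when `config$sweep_on` is set.
#'
#' @param config a [sim_config()].
#' @return a `sim_output`.
#' @export
simulate_dataset <- function(config) {
  neutral_cfg <- config
  neutral_cfg$sweep_on <- FALSE
  out <- simulate_neutral(neutral_cfg)
  if (config$sweep_on) out <- inject_sweep(out, config) else out$config <- config
  out
}

#' Write simulator outputs to disk
#'
#' Emits a sorted VCF v4.2 with phased genotypes (effect classes in the
#' `EC` INFO field), a population map TSV (`sample`, `group`, `role`), a
#' 0-based half-open gene BED, and a truth JSON.
#'
#' @param sim a `sim_output`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths written.
#' @export
write_outputs <- function(sim, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("write_outputs: cannot create directory ", dir)
  vcf <- file.path(dir, "sim.vcf")
  popmap <- file.path(dir, "popmap.tsv")
  bed <- file.path(dir, "genes.bed")
  truth <- file.path(dir, "truth.json")

  H <- sim$hap$H
  vt <- sim$variants
  n <- length(sim$hap$samples)
  gt <- matrix(paste(H[seq(1L, 2L * n, 2L), , drop = FALSE],
                     H[seq(2L, 2L * n, 2L), , drop = FALSE], sep = "|"),
               nrow = n)
  gt[is.na(H[seq(1L, 2L * n, 2L), ]) | is.na(H[seq(2L, 2L * n, 2L), ])] <- ".|."
  gt <- gsub("NA", ".", gt, fixed = TRUE)

  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=1,length=%d>", as.integer(sim$config$L)),
           "##INFO=<ID=EC,Number=1,Type=String,Description=\"Effect class\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sim$hap$samples), collapse = "\t"))
  body <- paste(vt$chrom, vt$pos, vt$id, vt$ref, vt$alt, ".", "PASS",
                paste0("EC=", vt$effect_class), "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf)

  write.table(sim$popmap, popmap, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$genes, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$truth, truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(vcf = vcf, popmap = popmap, genes = bed, truth = truth))
}
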