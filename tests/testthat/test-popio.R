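# write a small VCF from raw genotype strings
write_test_vcf <- function(records, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=1000000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

test_that("read_vcf keeps biallelic SNPs, masks missing, skips multi-allelic", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tG\tA,T\t.\tPASS\t.\tGT\t0|1\t0|2",   # multi-allelic
    "1\t300\t.\tT\tG\t.\tPASS\t.\tGT\t./.\t0|0",      # missing genotype
    "1\t400\t.\tC\tT\t.\tPASS\t.\tGT\t1|0\t0|1"),
    c("sampleA", "sampleB"), f)
  res <- suppressMessages(read_vcf(f))
  expect_equal(dim(res$hap$H), c(4L, 3L))
  expect_equal(attr(res, "n_skipped"), 1L)
  expect_equal(res$variants$pos, c(100L, 300L, 400L))
  expect_true(all(is.na(res$hap$H[1:2, 2])))   # sampleA at pos 300
  expect_equal(res$hap$H[3:4, 2], c(0L, 0L), ignore_attr = TRUE)

  pm <- data.frame(sample = c("sampleA", "ghost"), group = "g",
                   role = c("focal", "reference"))
  expect_error(suppressMessages(read_vcf(f, pm)), "ghost")
})

test_that("site filters apply the MAF and missingness thresholds", {
  # 25 in-group samples = 50 alleles; outgroup must not affect frequencies
  n <- 25
  H <- matrix(0L, nrow = 2 * n, ncol = 4)
  H[1:2, 1] <- 1L                      # MAF 2/50 = 0.04 -> removed
  H[1:3, 2] <- 1L                      # MAF 3/50 = 0.06 -> kept
  # 25% of genotype calls missing -> removed at max_missing = 0.2
  H[1:13, 3] <- NA_integer_
  H[14:20, 3] <- 1L
  # column 4 monomorphic -> removed (MAF 0)
  og <- matrix(c(0L, 1L), nrow = 4, ncol = 4)  # outgroup noise
  hm <- make_hap(rbind(H, og))
  vt <- make_vt(c(10, 20, 30, 40))
  pm <- make_popmap(13, 12, 2)
  out <- apply_filters(hm, vt, pm, maf = 0.05, max_missing = 0.2)
  expect_equal(out$variants$pos, 20L)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_kept, 1L)
  expect_equal(rep$n_fail_maf, 2L)
  expect_equal(rep$n_fail_missing, 1L)
})

test_that("MAF and missingness filters are order-independent", {
  set.seed(1)
  H <- matrix(rbinom(40 * 30, 1, 0.15), 40, 30)
  H[sample(length(H), 150)] <- NA
  hm <- make_hap(H)
  vt <- make_vt(seq_len(30) * 10)
  a <- apply_filters(hm, vt, maf = 0.05, max_missing = 0.2)
  b1 <- apply_filters(hm, vt, maf = 0.05, max_missing = 1)
  b <- apply_filters(b1$hap, b1$variants, maf = 0, max_missing = 0.2)
  c1 <- apply_filters(hm, vt, maf = 0, max_missing = 0.2)
  cc <- apply_filters(c1$hap, c1$variants, maf = 0.05, max_missing = 1)
  expect_identical(a$variants$pos, b$variants$pos)
  expect_identical(a$variants$pos, cc$variants$pos)
})

test_that("polarization matches exhaustive enumeration of outgroup genotypes", {
  # all 4^3 configurations of 3 outgroup samples x {0|0, 0|1, 1|1, ./.}
  gts <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(NA_integer_, NA_integer_))
  combos <- expand.grid(1:4, 1:4, 1:4)
  for (r in seq_len(nrow(combos))) {
    og <- do.call(rbind, lapply(unlist(combos[r, ]), function(i)
      matrix(gts[[i]], 2, 1)))
    # focal/reference rows carry arbitrary alleles and must be ignored
    H <- rbind(matrix(c(0L, 1L, 1L, 0L), 4, 1), og)
    hm <- make_hap(H)
    vt <- make_vt(100, ancestral = "unpolarized")
    pm <- make_popmap(1, 1, 3)
    res <- polarize(hm, vt, pm, min_outgroup = 2)$ancestral_state

    cells <- og[!is.na(og)]
    called_samples <- sum(!is.na(og[c(1, 3, 5), ]) & !is.na(og[c(2, 4, 6), ]))
    expected <- if (called_samples >= 2 && length(unique(cells)) == 1) {
      if (cells[1] == 0) "ref" else "alt"
    } else "unpolarized"
    expect_identical(res, expected)
  }
})

test_that("a single called outgroup sample is insufficient to polarize", {
  H <- rbind(matrix(0L, 4, 1),
             matrix(c(0L, 0L, NA, NA, NA, NA), 6, 1))
  res <- polarize(make_hap(H), make_vt(5), make_popmap(1, 1, 3),
                  min_outgroup = 2)
  expect_identical(res$ancestral_state, "unpolarized")
  res1 <- polarize(make_hap(H), make_vt(5), make_popmap(1, 1, 3),
                   min_outgroup = 1)
  expect_identical(res1$ancestral_state, "ref")
})

test_that("window tiling follows the size/step geometry and covers the contig", {
  w <- make_windows(c("1" = 1e5), size = 5e4, step = 2.5e4)
  expect_equal(w$start, c(0, 25000, 50000))
  expect_equal(w$end, c(50000, 75000, 100000))
  expect_error(make_windows(c("1" = 1e5), size = 1e4, step = 2e4), "size >= step")

  # ragged contig: every bp covered at least once
  for (len in c(90210, 123457)) {
    w <- make_windows(c("1" = len), size = 5e4, step = 3e4)
    pts <- sort(sample.int(len, 200)) - 1
    covered <- sapply(pts, function(p) any(w$start <= p & w$end > p))
    expect_true(all(covered))
  }
})

test_that("gene assignment uses half-open interval semantics", {
  genes <- data.frame(chrom = "1", start = 137677000, end = 137678000,
                      id = "geneX", stringsAsFactors = FALSE)
  # the worked coordinate: 1-based position inside the interval
  snp <- data.frame(chrom = "1", pos = 137677482)
  expect_equal(assign_to_genes(snp, genes)$gene, "geneX")
  # 0-based offset == gene end: outside (half-open)
  expect_equal(nrow(assign_to_genes(data.frame(chrom = "1", pos = 137678001),
                                    genes)), 0)
  # 0-based offset == gene start: inside
  expect_equal(assign_to_genes(data.frame(chrom = "1", pos = 137677001),
                               genes)$gene, "geneX")
  expect_equal(nrow(assign_to_genes(data.frame(chrom = "1", pos = 137677000),
                                    genes)), 0)
  # unsorted genes are sorted with a warning
  g2 <- data.frame(chrom = "1", start = c(500, 0), end = c(1000, 500),
                   id = c("b", "a"), stringsAsFactors = FALSE)
  expect_warning(res <- assign_to_genes(data.frame(chrom = "1", pos = 600), g2),
                 "unsorted")
  expect_equal(res$gene, "b")
})
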