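#' Phased haplotype matrix
#'
#' Container for phased biallelic haplotypes: a `2N x V` integer matrix of
#' allele codes (0 = REF, 1 = ALT, `NA` = missing), two consecutive rows per
#' diploid sample. All scan statistics operate on this substrate.
#'
#' @param H integer matrix, `2N x V`, values in `{0, 1, NA}`.
#' @param samples character vector of `N` sample ids; sample `i` owns rows
#'   `2i - 1` and `2i`.
#' @param phased logical; haplotype-based statistics refuse unphased input.
#' @return An object of class `hap_matrix`: a list with elements `H`,
#'   `samples`, `phased`.
#' @export
hap_matrix <- function(H, samples, phased = TRUE) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (nrow(H) != 2L * length(samples))
    stop("hap_matrix: H must have exactly 2 rows per sample")
  bad <- H[!is.na(H)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("hap_matrix: allele codes must be 0, 1 or NA")
  rownames(H) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  colnames(H) <- NULL
  structure(list(H = H, samples = samples, phased = isTRUE(phased)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes (%d samples) x %d sites, %s\n",
              nrow(x$H), length(x$samples), ncol(x$H),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$H)

#' Row indices of the haplotypes belonging to a set of samples
#'
#' @param hm a [hap_matrix()].
#' @param samples character vector of sample ids.
#' @return integer vector of row indices into `hm$H`.
#' @export
hap_rows <- function(hm, samples) {
  idx <- match(samples, hm$samples)
  if (anyNA(idx))
    stop("samples absent from haplotype matrix: ",
         paste(samples[is.na(idx)], collapse = ", "))
  as.integer(rbind(2L * idx - 1L, 2L * idx))
}

#' Haplotype rows for a population-map group or role
#'
#' @param hm a [hap_matrix()].
#' @param popmap population map (`sample`, `group`, `role`), see
#'   [read_popmap()].
#' @param group group name, or `NULL` to select by role.
#' @param role one of `"focal"`, `"reference"`, `"outgroup"`.
#' @return integer vector of row indices into `hm$H`.
#' @export
pop_rows <- function(hm, popmap, group = NULL, role = NULL) {
  if (is.null(group) && is.null(role))
    stop("supply group or role")
  keep <- if (!is.null(group)) popmap$group %in% group else popmap$role %in% role
  if (!any(keep)) {
    what <- if (!is.null(group)) paste0("group '", group, "'")
            else paste0("role '", role, "'")
    stop("no samples with ", what, " in population map")
  }
  hap_rows(hm, popmap$sample[keep])
}

#' Subset a haplotype matrix by site
#'
#' @param hm a [hap_matrix()].
#' @param sites integer or logical index over columns.
#' @return a [hap_matrix()] restricted to `sites`.
#' @export
subset_sites <- function(hm, sites) {
  hap_matrix(hm$H[, sites, drop = FALSE], hm$samples, hm$phased)
}

#' Diploid dosage matrix from phased haplotypes
#'
#' Collapses the two haplotypes of each sample to an ALT-allele dosage
#' (0/1/2, `NA` if either haplotype call is missing), the genotype encoding
#' used by identity-by-state distances.
#'
#' @param hm a [hap_matrix()].
#' @return integer `N x V` matrix with sample ids as rownames.
#' @export
hap_to_dosage <- function(hm) {
  n <- length(hm$samples)
  d <- hm$H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       hm$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(d) <- hm$samples
  d
}

## Internal per-site summaries over a row subset ----------------------------

# counts of called alleles per site
.called <- function(H, rows) {
  colSums(!is.na(H[rows, , drop = FALSE]))
}

# counts of ALT (code 1) alleles per site
.alt_count <- function(H, rows) {
  colSums(H[rows, , drop = FALSE] == 1L, na.rm = TRUE)
}

# per-site derived-allele code given a variant table: 1 where ancestral is
# REF, 0 where ancestral is ALT, NA where unpolarized
.derived_code <- function(vt) {
  ifelse(vt$ancestral_state == "ref", 1L,
         ifelse(vt$ancestral_state == "alt", 0L, NA_integer_))
}
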