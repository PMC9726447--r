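#' Multi-sample variant table
#'
#' The pipeline's central carrier: ordered SNP/indel sites with per-sample
#' diploid genotypes, read depth (DP) and genotype quality (GQ). Genotypes
#' are stored as two integer allele matrices (`a1`, `a2`; sites x samples;
#' 0 = REF, k = k-th ALT; `NA` = missing/no-call), mirroring how joint
#' genotypers report diploid calls even for polyploid strains.
#'
#' @param roster Ordered character vector of sample names.
#' @param index A [genome_index()]; site order follows this chromosome order.
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated ALT alleles, VCF style).
#' @param a1,a2 Integer matrices of allele indices, `NA` for missing.
#' @param dp,gq Integer matrices of per-genotype depth/quality, `NA` where absent.
#' @return A `variant_table` object. Sites are sorted by (index order, pos).
#' @export
variant_table <- function(roster, index, sites, a1, a2, dp = NULL, gq = NULL) {
  stopifnot(inherits(index, "genome_index"))
  roster <- as.character(roster)
  if (length(roster) == 0 || anyDuplicated(roster)) {
    stop("roster must be a non-empty set of unique sample names", call. = FALSE)
  }
  n <- nrow(sites)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites))) {
    stop("`sites` must have columns chrom, pos, ref, alt", call. = FALSE)
  }
  sites <- data.frame(chrom = as.character(sites$chrom), pos = as.integer(sites$pos),
                      ref = as.character(sites$ref), alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(sites$pos < 1)) stop("positions must be >= 1", call. = FALSE)
    bad_chrom <- setdiff(unique(sites$chrom), index$name)
    if (length(bad_chrom)) {
      stop("site chromosome(s) absent from genome index: ",
           paste(bad_chrom, collapse = ", "), call. = FALSE)
    }
    if (any(!nzchar(sites$ref)) || any(!nzchar(sites$alt))) {
      stop("REF and ALT alleles must be non-empty", call. = FALSE)
    }
  }
  shape_ok <- function(m) is.matrix(m) && nrow(m) == n && ncol(m) == length(roster)
  if (n == 0) {
    mk <- function(m) matrix(NA_integer_, 0, length(roster))
    a1 <- mk(); a2 <- mk()
    if (is.null(dp)) dp <- mk()
    if (is.null(gq)) gq <- mk()
  }
  if (is.null(dp)) dp <- matrix(NA_integer_, n, length(roster))
  if (is.null(gq)) gq <- matrix(NA_integer_, n, length(roster))
  for (m in list(a1, a2, dp, gq)) {
    if (!shape_ok(m)) stop("genotype matrices must be n_sites x n_samples", call. = FALSE)
  }
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  storage.mode(dp) <- "integer"; storage.mode(gq) <- "integer"
  dimnames(a1) <- dimnames(a2) <- dimnames(dp) <- dimnames(gq) <- NULL
  # one allele NA implies a fully missing diploid call
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  if (n > 0) {
    nalt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
    amax <- pmax(a1, a2)
    bad <- which(!is.na(amax) & (amax > nalt | pmin(a1, a2) < 0))
    if (length(bad)) {
      stop("allele index out of range at ", sites$chrom[bad[1]], ":", sites$pos[bad[1]],
           call. = FALSE)
    }
    if (any(dp < 0, na.rm = TRUE) || any(gq < 0, na.rm = TRUE)) {
      stop("DP and GQ must be >= 0", call. = FALSE)
    }
  }
  vt <- structure(
    list(roster = roster, index = index, sites = sites,
         a1 = a1, a2 = a2, dp = dp, gq = gq),
    class = "variant_table"
  )
  sort_variant_table(vt)
}

sort_variant_table <- function(vt) {
  if (nrow(vt$sites) == 0) return(vt)
  ord <- order(match(vt$sites$chrom, vt$index$name), vt$sites$pos)
  vt <- subset_sites(vt, ord)
  key <- paste(vt$sites$chrom, vt$sites$pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate site at ", d, call. = FALSE)
  }
  vt
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), nrow(x$index)))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param vt A [variant_table()].
#' @return Integer count.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @rdname n_sites
#' @export
n_samples <- function(vt) length(vt$roster)

#' Subset a variant table by site
#'
#' @param vt A [variant_table()].
#' @param keep Integer or logical site selector.
#' @return A `variant_table` with the selected sites, order preserved.
#' @export
subset_sites <- function(vt, keep) {
  vt$sites <- vt$sites[keep, , drop = FALSE]
  rownames(vt$sites) <- NULL
  for (f in c("a1", "a2", "dp", "gq")) vt[[f]] <- vt[[f]][keep, , drop = FALSE]
  vt
}

alt_alleles <- function(vt) strsplit(vt$sites$alt, ",", fixed = TRUE)

#' Site predicates
#'
#' `is_snp()` is TRUE for sites whose REF and every ALT allele are single
#' bases; `is_biallelic()` for sites with exactly one ALT allele.
#'
#' @param vt A [variant_table()].
#' @return Logical vector over sites.
#' @export
is_snp <- function(vt) {
  alts <- alt_alleles(vt)
  nchar(vt$sites$ref) == 1L &
    vapply(alts, function(a) all(nchar(a) == 1L), logical(1))
}

#' @rdname is_snp
#' @export
is_biallelic <- function(vt) {
  lengths(alt_alleles(vt)) == 1L
}

#' Fraction of missing genotype calls per site
#' @param vt A [variant_table()].
#' @return Numeric vector in \[0, 1\] over sites.
#' @export
site_missing_fraction <- function(vt) {
  if (n_sites(vt) == 0) return(numeric(0))
  rowMeans(is.na(vt$a1))
}
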