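#' Filter configuration for the site/genotype quality cascade
#'
#' Thresholds mirror a standard joint-genotyping clean-up: genotypes with
#' read depth below `min_depth` or genotype quality below `min_gq` are masked
#' (strict less-than on both); SNPs falling in clusters of `cluster_size`
#' SNPs within a `cluster_window`-bp span are removed; multiallelic sites,
#' sites missing in more than `max_missing_fraction` of samples (strict
#' greater-than), and finally non-SNP sites are dropped.
#'
#' @param min_depth Minimum read depth to keep a genotype (default 15).
#' @param min_gq Minimum Phred-scaled genotype quality (default 40).
#' @param cluster_size Number of SNPs that makes a cluster (default 5).
#' @param cluster_window Window span in bp, inclusive of both ends (default 20).
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   genotypes per site (default 0.30); the boundary value survives.
#' @param snps_only Drop indels at the end of the cascade (default TRUE).
#' @param biallelic_only Drop multiallelic sites (default TRUE).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 15L, min_gq = 40L,
                          cluster_size = 5L, cluster_window = 20L,
                          max_missing_fraction = 0.30,
                          snps_only = TRUE, biallelic_only = TRUE) {
  cfg <- list(min_depth = as.integer(min_depth), min_gq = as.integer(min_gq),
              cluster_size = as.integer(cluster_size),
              cluster_window = as.integer(cluster_window),
              max_missing_fraction = as.numeric(max_missing_fraction),
              snps_only = isTRUE(snps_only), biallelic_only = isTRUE(biallelic_only))
  if (any(unlist(cfg[1:4]) < 0)) stop("filter thresholds must be >= 0", call. = FALSE)
  if (cfg$max_missing_fraction < 0 || cfg$max_missing_fraction > 1) {
    stop("max_missing_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

#' Mask genotypes failing depth or quality thresholds
#'
#' A genotype call with DP < `min_depth` or GQ < `min_gq` becomes missing;
#' the site itself is untouched. Genotypes whose DP or GQ annotation is
#' absent are left as called, matching how hard-filtering tools skip absent
#' annotations rather than failing them.
#'
#' @param vt A [variant_table()].
#' @param cfg A [filter_config()].
#' @return The masked `variant_table`, with attributes `masked_dp` and
#'   `masked_gq` counting newly masked genotypes (a genotype failing both
#'   thresholds is counted under DP).
#' @export
mask_low_quality_genotypes <- function(vt, cfg = filter_config()) {
  stopifnot(inherits(vt, "variant_table"))
  called <- !is.na(vt$a1)
  fail_dp <- called & !is.na(vt$dp) & vt$dp < cfg$min_depth
  fail_gq <- called & !is.na(vt$gq) & vt$gq < cfg$min_gq
  vt$a1[fail_dp | fail_gq] <- NA_integer_
  vt$a2[fail_dp | fail_gq] <- NA_integer_
  attr(vt, "masked_dp") <- sum(fail_dp)
  attr(vt, "masked_gq") <- sum(fail_gq & !fail_dp)
  vt
}

#' Remove SNPs lying in dense clusters
#'
#' A SNP is removed if it belongs to any same-chromosome window of
#' `cluster_size` or more SNPs whose inclusive base-pair span
#' (last - first + 1) is at most `cluster_window`. Indels neither count
#' toward a cluster nor are removed.
#'
#' @param vt A sorted [variant_table()].
#' @param cfg A [filter_config()].
#' @return The `variant_table` without clustered SNPs, with attribute
#'   `removed_cluster` (count of removed sites).
#' @export
remove_snp_clusters <- function(vt, cfg = filter_config()) {
  stopifnot(inherits(vt, "variant_table"))
  snp <- is_snp(vt)
  drop <- logical(n_sites(vt))
  k <- cfg$cluster_size
  if (k >= 1 && any(snp)) {
    for (ch in unique(vt$sites$chrom[snp])) {
      idx <- which(snp & vt$sites$chrom == ch)
      pos <- vt$sites$pos[idx]
      m <- length(idx)
      if (m >= k) {
        # window of k consecutive SNPs with span <= cluster_window marks all k
        for (i in seq_len(m - k + 1)) {
          if (pos[i + k - 1] - pos[i] + 1 <= cfg$cluster_window) {
            drop[idx[i:(i + k - 1)]] <- TRUE
          }
        }
      }
    }
  }
  out <- subset_sites(vt, !drop)
  attr(out, "masked_dp") <- attr(vt, "masked_dp")
  attr(out, "masked_gq") <- attr(vt, "masked_gq")
  attr(out, "removed_cluster") <- sum(drop)
  out
}

#' Select analysis-ready sites and build the cascade report
#'
#' Applied after genotype masking and cluster removal, in this order:
#' multiallelic exclusion (when `biallelic_only`), missingness exclusion
#' (fraction of missing genotypes strictly greater than
#' `max_missing_fraction`), then non-SNP exclusion (when `snps_only`).
#'
#' @param vt A masked, cluster-filtered [variant_table()].
#' @param cfg A [filter_config()].
#' @return A list with elements `table` (surviving sites) and `report`
#'   (a `filter_report` with every cascade count; `empty_output` flags a
#'   table that lost all its sites).
#' @export
select_analysis_sites <- function(vt, cfg = filter_config()) {
  stopifnot(inherits(vt, "variant_table"))
  n_in <- n_sites(vt)
  keep <- rep(TRUE, n_in)

  multi <- keep & cfg$biallelic_only & !is_biallelic(vt)
  keep <- keep & !multi
  missing_frac <- site_missing_fraction(vt)
  miss <- keep & missing_frac > cfg$max_missing_fraction
  keep <- keep & !miss
  nonsnp <- keep & cfg$snps_only & !is_snp(vt)
  keep <- keep & !nonsnp

  out <- subset_sites(vt, keep)
  report <- filter_report(
    input_sites = sum0(attr(vt, "input_sites"), n_in),
    genotypes_masked_dp = sum0(attr(vt, "masked_dp"), 0L),
    genotypes_masked_gq = sum0(attr(vt, "masked_gq"), 0L),
    sites_removed_cluster = sum0(attr(vt, "removed_cluster"), 0L),
    sites_removed_multiallelic = sum(multi),
    sites_removed_missing = sum(miss),
    sites_removed_nonsnp = sum(nonsnp),
    output_sites = n_sites(out)
  )
  list(table = out, report = report)
}

sum0 <- function(x, default) if (is.null(x)) default else x

filter_report <- function(input_sites, genotypes_masked_dp, genotypes_masked_gq,
                          sites_removed_cluster, sites_removed_multiallelic,
                          sites_removed_missing, sites_removed_nonsnp,
                          output_sites) {
  rep <- list(input_sites = input_sites,
              genotypes_masked_dp = genotypes_masked_dp,
              genotypes_masked_gq = genotypes_masked_gq,
              sites_removed_cluster = sites_removed_cluster,
              sites_removed_multiallelic = sites_removed_multiallelic,
              sites_removed_missing = sites_removed_missing,
              sites_removed_nonsnp = sites_removed_nonsnp,
              output_sites = output_sites,
              empty_output = output_sites == 0)
  removed <- sites_removed_cluster + sites_removed_multiallelic +
    sites_removed_missing + sites_removed_nonsnp
  if (input_sites - removed != output_sites) {
    stop("filter report does not conserve sites: ", input_sites, " - ", removed,
         " != ", output_sites, call. = FALSE)
  }
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter cascade report\n")
  for (f in setdiff(names(x), "empty_output")) cat(sprintf("  %-28s %d\n", f, x[[f]]))
  if (x$empty_output) cat("  ! no sites survived the cascade\n")
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  f <- setdiff(names(x), "empty_output")
  data.frame(stage = f, count = unlist(x[f], use.names = FALSE))
}

#' Write a filter report as TSV
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full filter cascade
#'
#' Pinned order: genotype masking (DP, GQ) -> SNP-cluster removal ->
#' multiallelic exclusion -> missingness exclusion -> SNP-only selection.
#'
#' @param vt A parsed [variant_table()].
#' @param cfg A [filter_config()].
#' @return A list with `table` (analysis-ready sites) and `report`.
#' @export
filter_variants <- function(vt, cfg = filter_config()) {
  n_in <- n_sites(vt)
  masked <- mask_low_quality_genotypes(vt, cfg)
  unclustered <- remove_snp_clusters(masked, cfg)
  attr(unclustered, "input_sites") <- n_in
  select_analysis_sites(unclustered, cfg)
}
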