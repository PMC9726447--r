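#' Read a multi-sample VCF into a variant table
#'
#' Parsing is delegated to [vcfR::read.vcfR()]; this wrapper extracts the GT,
#' DP and GQ FORMAT fields, decodes diploid genotypes (phased `|` separators
#' are treated as unphased, haploid calls such as `0` are promoted to
#' homozygous diploid `0/0`), and validates every site against the genome
#' index. Missing annotations (`.`) become `NA`.
#'
#' @param path Path to a plain or gzipped VCF v4.x file.
#' @param index A [genome_index()]; a site on a chromosome absent from the
#'   index is an error.
#' @return A [variant_table()] sorted by (index order, position).
#' @export
read_vcf <- function(path, index) {
  stopifnot(inherits(index, "genome_index"))
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)),
    error = function(e) stop("malformed VCF ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    roster <- colnames(v@gt)
    roster <- roster[roster != "FORMAT"]
    return(variant_table(roster, index,
                         data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character()),
                         matrix(NA_integer_, 0, length(roster)),
                         matrix(NA_integer_, 0, length(roster))))
  }
  roster <- colnames(v@gt)[-1]
  if (length(roster) == 0) stop("VCF has no sample columns: ", path, call. = FALSE)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record (non-integer POS) at data line ",
         which(is.na(pos))[1], " of ", path, call. = FALSE)
  }
  sites <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  al <- parse_gt_matrix(gt, path)
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  as_int_mat <- function(m) {
    if (is.null(m)) m <- matrix(NA_real_, nrow(sites), length(roster))
    m <- round(m)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  }
  variant_table(roster, index, sites, al$a1, al$a2,
                dp = as_int_mat(dp), gq = as_int_mat(gq))
}

# Decode a vcfR GT character matrix into two integer allele matrices.
# Any "." allele in the call marks the whole diploid call missing.
parse_gt_matrix <- function(gt, path = "<vcf>") {
  vals <- unique(as.vector(gt))
  vals <- vals[!is.na(vals)]
  parts <- strsplit(vals, "[/|]")
  if (any(lengths(parts) > 2)) {
    stop("genotype with ploidy > 2 in ", path, ": '",
         vals[lengths(parts) > 2][1], "'", call. = FALSE)
  }
  dec1 <- vapply(parts, `[[`, character(1), 1L)
  dec2 <- vapply(parts, function(p) p[[length(p)]], character(1))  # haploid -> hom
  to_int <- function(x) {
    x[x == "."] <- NA_character_
    out <- suppressWarnings(as.integer(x))
    if (any(is.na(out) & !is.na(x))) {
      stop("unparseable GT allele '", x[is.na(out) & !is.na(x)][1], "' in ", path,
           call. = FALSE)
    }
    out
  }
  i1 <- to_int(dec1); i2 <- to_int(dec2)
  m <- match(gt, vals)
  a1 <- matrix(i1[m], nrow(gt), ncol(gt))
  a2 <- matrix(i2[m], nrow(gt), ncol(gt))
  list(a1 = a1, a2 = a2)
}

#' Write a variant table as a VCF v4.2 file
#'
#' Emits contig header lines from the genome index and GT:DP:GQ genotype
#' columns. Round-trips through [read_vcf()] losslessly on (chrom, pos, ref,
#' alt, GT, DP, GQ).
#'
#' @param vt A [variant_table()].
#' @param path Output path (plain text).
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", vt$index$name, vt$index$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            vt$roster), collapse = "\t")
  )
  lines <- hdr
  if (n_sites(vt) > 0) {
    fmt_int <- function(m) ifelse(is.na(m), ".", as.character(m))
    gt <- matrix(paste0(fmt_int(vt$a1), "/", fmt_int(vt$a2)),
                 n_sites(vt), n_samples(vt))
    gt[is.na(vt$a1)] <- "./."
    cells <- matrix(paste(gt, fmt_int(vt$dp), fmt_int(vt$gq), sep = ":"),
                    n_sites(vt), n_samples(vt))
    body <- paste(vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref, vt$sites$alt,
                  ".", "PASS", ".", "GT:DP:GQ",
                  apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write ancestry blocks as BED4
#'
#' One line per block: chrom, start, end (0-based half-open), label. Output
#' is sorted by chromosome (genome-index order when `index` is given,
#' otherwise first-appearance order) then start.
#'
#' @param blocks Data frame with columns `chrom`, `start`, `end`, `label`.
#' @param path Output path.
#' @param index Optional [genome_index()] fixing chromosome order.
#' @export
write_bed <- function(blocks, path, index = NULL) {
  req <- c("chrom", "start", "end", "label")
  if (!all(req %in% names(blocks))) {
    stop("blocks must have columns chrom, start, end, label", call. = FALSE)
  }
  if (nrow(blocks) > 0) {
    if (any(blocks$start < 0)) stop("BED start must be >= 0", call. = FALSE)
    if (any(blocks$start >= blocks$end)) stop("BED interval with start >= end", call. = FALSE)
    chrom_rank <- if (is.null(index)) {
      match(blocks$chrom, unique(blocks$chrom))
    } else {
      match(blocks$chrom, index$name)
    }
    blocks <- blocks[order(chrom_rank, blocks$start), , drop = FALSE]
  }
  utils::write.table(
    format(blocks[, req], scientific = FALSE, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 file
#'
#' @param path Path to a BED4 file as written by [write_bed()].
#' @return Data frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 4) stop("expected BED4 (chrom, start, end, label): ", path, call. = FALSE)
  stats::setNames(tab[, 1:4], c("chrom", "start", "end", "label"))
}

#' Write a SNP alignment in FASTA or relaxed PHYLIP format
#'
#' Rows are one sequence string per sample over the alphabet A, C, G, T, N.
#' Relaxed PHYLIP starts with an `ntaxa nchar` header and puts each name and
#' sequence on one space-separated line, so names may not contain whitespace.
#'
#' @param rows Named character vector: one equal-length sequence per sample,
#'   names are the sample names; order is preserved.
#' @param path Output path.
#' @param format `"phylip"` (default) or `"fasta"`.
#' @export
write_alignment <- function(rows, path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  if (length(rows) == 0) stop("alignment must contain at least one sequence", call. = FALSE)
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named by sample", call. = FALSE)
  }
  len <- unique(nchar(rows))
  if (length(len) != 1) stop("ragged alignment: rows differ in length", call. = FALSE)
  if (len == 0) stop("empty alignment (zero sites) rejected", call. = FALSE)
  if (any(grepl("[^ACGTN]", rows))) {
    stop("alignment alphabet is restricted to A, C, G, T, N", call. = FALSE)
  }
  if (format == "phylip") {
    if (any(grepl("[[:space:]]", names(rows)))) {
      stop("PHYLIP sample names may not contain whitespace", call. = FALSE)
    }
    lines <- c(paste(length(rows), len), paste(names(rows), rows))
  } else {
    lines <- as.vector(rbind(paste0(">", names(rows)), rows))
  }
  writeLines(lines, path)
  invisible(path)
}
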