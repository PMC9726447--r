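#' Genome index: ordered chromosome names and lengths
#'
#' A genome index fixes the canonical chromosome order used for every output
#' (BED, summaries, plots) and supplies the chromosome extents needed when
#' ancestry blocks are expanded to cover whole chromosomes.
#'
#' @param name Character vector of unique, non-empty chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all >= 1).
#' @return A `genome_index` data frame with columns `name` and `length`,
#'   in the given order.
#' @examples
#' genome_index(c("chrI", "chrII"), c(230218, 813184))
#' @export
genome_index <- function(name, length) {
  name <- as.character(name)
  length <- as.numeric(length)
  if (length(name) != length(length)) {
    stop("`name` and `length` must have equal length", call. = FALSE)
  }
  if (length(name) == 0) stop("genome index must have at least one chromosome", call. = FALSE)
  if (anyNA(name) || any(!nzchar(name))) stop("chromosome names must be non-empty", call. = FALSE)
  if (anyDuplicated(name)) stop("duplicate chromosome names in genome index", call. = FALSE)
  if (anyNA(length) || any(length < 1) || any(length != floor(length))) {
    stop("chromosome lengths must be integers >= 1", call. = FALSE)
  }
  structure(
    data.frame(name = name, length = length, stringsAsFactors = FALSE),
    class = c("genome_index", "data.frame")
  )
}

#' Read a genome index from a two-column TSV
#'
#' Reads the first two columns (name, length) of a tab-separated file; a
#' samtools `.fai` file works as-is since only its first two columns are used.
#'
#' @param path Path to the TSV/.fai file.
#' @return A [genome_index()].
#' @export
read_genome_index <- function(path) {
  if (!file.exists(path)) stop("genome index file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("genome index must have at least two columns: ", path, call. = FALSE)
  genome_index(tab[[1]], tab[[2]])
}

#' Write a genome index as a two-column TSV
#'
#' @param index A [genome_index()].
#' @param path Output path.
#' @export
write_genome_index <- function(index, path) {
  stopifnot(inherits(index, "genome_index"))
  utils::write.table(index[, c("name", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

genome_bp <- function(index) sum(index$length)

chrom_length <- function(index, chrom) {
  i <- match(chrom, index$name)
  if (anyNA(i)) stop("chromosome not in genome index: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  index$length[i]
}
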