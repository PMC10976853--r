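#' Read a BED file of peak calls
#'
#' @param path BED3+ file. Records with `start >= end` are rejected with an
#'   error naming the file and line.
#' @param sample_id label attached to the peak set; defaults to the file name
#'   stripped of extensions.
#' @return a peak set: interval table with attribute `sample_id`, sorted.
#' @export
read_peaks_bed <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(peaks\\.)?bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(peak_set(genomic_intervals(character(), integer(), integer()), sample_id))
  fields <- strsplit(lines, "\t")
  start <- as.numeric(vapply(fields, `[`, "", 2))
  end <- as.numeric(vapply(fields, `[`, "", 3))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop(sprintf("malformed BED record in %s at line %d (start >= end or non-numeric)",
                 path, bad[1]))
  peak_set(genomic_intervals(vapply(fields, `[`, "", 1), start, end), sample_id)
}

#' Construct a peak set
#' @param intervals interval table (0-based half-open).
#' @param sample_id sample label.
#' @return the intervals, sorted, with attribute `sample_id`.
#' @export
peak_set <- function(intervals, sample_id) {
  out <- sort_intervals(intervals)
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  out
}

#' Write an interval table as BED
#'
#' @param df interval table; an optional `id` column becomes BED column 4, an
#'   optional `score` column becomes column 5 (with strand "." as column 6).
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, format(as.integer(df$start), scientific = FALSE, trim = TRUE),
               format(as.integer(df$end), scientific = FALSE, trim = TRUE))
  if (!is.null(df$id)) cols <- c(cols, list(df$id))
  if (!is.null(df$score)) {
    if (is.null(df$id)) cols <- c(cols, list(rep(".", nrow(df))))
    cols <- c(cols, list(as.integer(df$score)), list(rep(".", nrow(df))))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
}

#' Read / write binned coverage as bedGraph
#'
#' Coverage is an interval table with a `count` column; bins are uniform-width
#' and non-overlapping. On disk it is a standard 4-column bedGraph
#' (0-based half-open), read and written through `rtracklayer`.
#' @param path bedGraph file.
#' @return coverage table (`chrom`, `start`, `end`, `count`).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- granges_to_intervals(gr)
  names(df)[names(df) == "score"] <- "count"
  sort_intervals(df)
}

#' @rdname read_bedgraph
#' @param cov coverage table.
#' @export
write_bedgraph <- function(cov, path) {
  gr <- intervals_to_granges(cov[, c("chrom", "start", "end")])
  S4Vectors::mcols(gr)$score <- cov$count
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write a soft-masked genome FASTA
#'
#' Lowercase letters mark repeat-masked bases, so case must survive the round
#' trip; sequences are handled as plain character strings via `seqinr`.
#' @param path FASTA file.
#' @return named character vector, one string per chromosome.
#' @export
read_genome_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(vapply(x, as.character, ""), names(x))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  seqinr::write.fasta(lapply(genome, function(s) strsplit(s, "")[[1]]),
                      names = names(genome), file.out = path, nbchar = 70)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' Columns `sample_id`, `tissue`, `replicate`. `sample_id`s must be unique and
#' every tissue must have at least one sample.
#' @param path CSV file.
#' @return validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  sheet$replicate <- as.integer(sheet$replicate)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(validate_sample_sheet(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "tissue", "replicate")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (any(!nzchar(sheet$tissue))) stop("empty tissue label in sample sheet")
  sheet
}

#' Read / write the gene table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open). The transcription start site is `start` for `+` genes
#' and `end` for `-` genes.
#' @param path TSV file.
#' @return gene table data frame.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "start", "end", "strand") %in% names(g)))
    stop("gene table needs gene_id, chrom, start, end, strand")
  if (!all(g$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  g
}

#' @rdname read_gene_table
#' @param genes gene table.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix as TSV with row names in the first column
#' @param m matrix with dimnames.
#' @param path output file.
#' @param rowname_col header for the first column.
#' @export
write_matrix_tsv <- function(m, path, rowname_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
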