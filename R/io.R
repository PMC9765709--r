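# File-format boundaries: FASTA via Biostrings, GFF3 feature tables, and the
# plain TSV side tables (MGE labels, known peptides, hits/calls).  All
# in-memory coordinates are 0-based half-open; GFF3 on disk is 1-based
# inclusive.

#' Write a genome bundle to a directory
#'
#' Emits `replicons.fna`, `proteome.faa`, `genes.gff3`, `mge.tsv`,
#' `known_peptides.tsv` and the planted truth (`truth_systems.tsv`,
#' `truth_propeptides.tsv`) when present.
#'
#' @param bundle A bundle from [generate_genome()] (or the same shape).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$replicons),
                              file.path(dir, "replicons.fna"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(bundle$proteome),
                              file.path(dir, "proteome.faa"))
  write_gff3(bundle$genes, file.path(dir, "genes.gff3"))
  write_tsv(bundle$mge, file.path(dir, "mge.tsv"))
  write_tsv(bundle$known_peptides, file.path(dir, "known_peptides.tsv"))
  if (!is.null(bundle$truth)) {
    write_tsv(bundle$truth$systems, file.path(dir, "truth_systems.tsv"))
    write_tsv(bundle$truth$propeptides, file.path(dir, "truth_propeptides.tsv"))
  }
  invisible(dir)
}

#' Read a genome bundle from a directory written by [write_genome_bundle()]
#' @param dir Directory path.
#' @return A bundle list (without planted truth unless present on disk).
#' @export
read_genome_bundle <- function(dir) {
  repl <- Biostrings::readDNAStringSet(file.path(dir, "replicons.fna"))
  prot <- Biostrings::readAAStringSet(file.path(dir, "proteome.faa"))
  bundle <- list(replicons = stats::setNames(as.character(repl), names(repl)),
                 proteome = stats::setNames(as.character(prot), names(prot)),
                 genes = read_gff3(file.path(dir, "genes.gff3")),
                 mge = read_tsv(file.path(dir, "mge.tsv")),
                 known_peptides = read_tsv(file.path(dir, "known_peptides.tsv")))
  bundle$circular <- stats::setNames(rep(FALSE, length(bundle$replicons)),
                                     names(bundle$replicons))
  ts <- file.path(dir, "truth_systems.tsv")
  if (file.exists(ts))
    bundle$truth <- list(systems = read_tsv(ts),
                         propeptides = read_tsv(file.path(dir, "truth_propeptides.tsv")))
  bundle
}

#' Write a CDS gene table as GFF3
#' @param genes data.frame with replicon, start, end (0-based half-open),
#'   strand, locus_tag.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  head <- "##gff-version 3"
  body <- if (nrow(genes)) sprintf(
    "%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
    genes$replicon, genes$start + 1L, genes$end, genes$strand,
    genes$locus_tag, genes$locus_tag) else character()
  writeLines(c(head, body), path)
  invisible(path)
}

#' Read a GFF3 CDS table written by [write_gff3()]
#' @param path GFF3 path.
#' @return data.frame with replicon, start, end (0-based half-open), strand,
#'   locus_tag.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(replicon = character(), start = integer(), end = integer(),
                      strand = character(), locus_tag = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  lt <- vapply(f, function(x) sub(".*locus_tag=([^;]+).*", "\\1", x[9]), "")
  data.frame(replicon = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
             end = as.integer(vapply(f, `[`, "", 5L)),
             strand = vapply(f, `[`, "", 7L),
             locus_tag = lt, stringsAsFactors = FALSE)
}

#' @rdname write_gff3
#' @param x data.frame to write as TSV.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_gff3
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
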