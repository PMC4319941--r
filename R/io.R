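## Shared I/O: FASTA directory readers (Biostrings-backed, tolerant of
## wrapping and CRLF), gene-header conventions, genome summary statistics,
## and TSV readers/writers for matrices, hosts and annotations.
##
## Conventions: CDS/protein FASTA headers are `genomeID|geneID`; all
## internal coordinates are 0-based half-open.

.read_fasta_file <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  set <- tryCatch(
    if (type == "dna") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path),
    error = function(e) stop("cannot parse FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, call. = FALSE)
  stats::setNames(toupper(as.character(set)), ids)
}

.fasta_files <- function(directory, exts) {
  if (!dir.exists(directory)) stop("no such directory: ", directory, call. = FALSE)
  files <- list.files(directory, full.names = TRUE,
                      pattern = paste0("\\.(", paste(exts, collapse = "|"), ")$"))
  if (!length(files)) stop("no FASTA files in ", directory, call. = FALSE)
  ids <- tools::file_path_sans_ext(basename(files))
  if (anyDuplicated(ids)) stop("duplicate genome ids in ", directory, call. = FALSE)
  stats::setNames(sort(files), ids[order(files)])
}

#' Read a directory of genome assemblies
#'
#' One FASTA file per genome (`.fna`, `.fa`, `.fasta`); the genome id is
#' the file name without extension. Wrapped or unwrapped lines and CRLF
#' endings are tolerated; sequences are uppercased.
#'
#' @param directory Path.
#' @return Named list: genome id -> named character vector of contigs.
#' @export
read_genome_set <- function(directory) {
  files <- .fasta_files(directory, c("fna", "fa", "fasta"))
  lapply(files, .read_fasta_file, type = "dna")
}

#' Read a directory of protein (or CDS) FASTA files into a gene table
#'
#' Headers follow the `genomeID|geneID` convention; headers without a `|`
#' keep the file's genome id and the full record id.
#'
#' @param directory Path.
#' @param type `"aa"` (default, `.faa`/`.fa`/`.fasta`) or `"dna"`
#'   (`.ffn`/`.fa`/`.fasta`).
#' @return A [gene_table()] (protein or nucleotide column filled
#'   according to `type`).
#' @export
read_gene_set <- function(directory, type = c("aa", "dna")) {
  type <- match.arg(type)
  exts <- if (type == "aa") c("faa", "fa", "fasta") else c("ffn", "fa", "fasta")
  files <- .fasta_files(directory, exts)
  rows <- lapply(names(files), function(g) {
    seqs <- .read_fasta_file(files[[g]], type)
    data.frame(gene_id = names(seqs), genome_id = g, seq = unname(seqs),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (type == "aa") gene_table(df$gene_id, df$genome_id, protein = df$seq)
  else {
    out <- data.frame(gene_id = df$gene_id, genome_id = df$genome_id,
                      nucleotide = df$seq, stringsAsFactors = FALSE)
    out
  }
}

#' Genome summary statistics
#'
#' GC percentage is computed over unambiguous bases only
#' (100 * (G+C) / (A+C+G+T)); genome size counts every position including
#' ambiguity codes.
#'
#' @param contigs Named character vector of contig sequences.
#' @param n_cds Optional CDS count to carry through.
#' @return List with `size_bp`, `gc_pct`, `n_contigs`, `n_cds`.
#' @export
genome_summary <- function(contigs, n_cds = NA_integer_) {
  if (!length(contigs)) stop("need at least one contig", call. = FALSE)
  s <- paste(toupper(contigs), collapse = "")
  counts <- table(strsplit(s, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[c("A", "C", "G", "T")], na.rm = TRUE)
  gc <- sum(counts[c("G", "C")], na.rm = TRUE)
  list(size_bp = nchar(s),
       gc_pct = if (acgt > 0) 100 * gc / acgt else NA_real_,
       n_contigs = length(contigs),
       n_cds = n_cds)
}

#' Read / write a presence matrix TSV
#'
#' Families in rows, genomes in columns, 0/1 entries; first column
#' `family_id`.
#'
#' @param path File path.
#' @return Logical matrix.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_presence_matrix
#' @param matrix Logical matrix to write.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(family_id = rownames(matrix),
                   matrix * 1L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a host-label table
#'
#' TSV with columns `genome_id` and `host`.
#'
#' @param path File path.
#' @return Named character vector (genome id -> host).
#' @export
read_hosts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$host, df$genome_id)
}

#' Read a functional-annotation table
#'
#' TSV with an id column (family or gene id) and a category-letter column.
#'
#' @param path File path.
#' @return Named character vector (id -> category string).
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), df[[1]])
}
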