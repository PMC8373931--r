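#' Generate and write the toy-locus chromosome sequence
#'
#' The toy locus carries no meaningful sequence content; this draws a
#' seeded random nucleotide string of the right length so sequence-level
#' operations (mutant genome construction, FASTA round trips) can be
#' exercised.
#'
#' @param locus A [make_toy_hoxd_locus()] fixture.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @export
locus_sequence <- function(locus, seed = 1) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), locus$length, replace = TRUE),
             collapse = "")
  out <- Biostrings::DNAStringSet(s)
  names(out) <- locus$chrom
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Export locus features as BED6 tibbles
#'
#' Genes and enhancers become plain BED6 records; CTCF sites carry their
#' orientation in the strand column and their occupancy weight in the
#' score column.
#'
#' @param locus A [make_toy_hoxd_locus()] fixture.
#' @param what `"genes"`, `"enhancers"` or `"ctcf"`.
#' @return A tibble with BED6 columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
locus_bed <- function(locus, what = c("genes", "enhancers", "ctcf")) {
  what <- match.arg(what)
  switch(what,
    genes = tibble(chrom = locus$chrom, start = locus$genes$start,
                   end = locus$genes$end, name = locus$genes$name,
                   score = 0, strand = locus$genes$strand),
    enhancers = tibble(chrom = locus$chrom, start = locus$enhancers$start,
                       end = locus$enhancers$end,
                       name = locus$enhancers$name, score = 0,
                       strand = "."),
    ctcf = tibble(chrom = locus$chrom, start = locus$ctcf_sites$position,
                  end = locus$ctcf_sites$position + 1,
                  name = locus$ctcf_sites$group,
                  score = locus$ctcf_sites$weight,
                  strand = locus$ctcf_sites$orientation)
  )
}

#' Write a BED tibble
#'
#' Writes tab-separated BED (no header, 0-based half-open), using whatever
#' of the six standard columns are present.
#'
#' @param bed Tibble with at least `chrom`, `start`, `end`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(bed))
  readr::write_tsv(bed[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file into a tibble
#'
#' @param path BED file (3-6 columns, no header).
#' @return A tibble with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        show_col_types = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write a contact matrix as TSV triples with a JSON sidecar
#'
#' The matrix goes to `<path>` as three tab-separated columns
#' `bin1_start`, `bin2_start`, `count` (upper triangle including the
#' diagonal); the metadata (chromosome, bin size, coordinate system,
#' offset, signedness) goes to `<path>.json`.
#'
#' @param M A [contact_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(M, path) {
  stopifnot(inherits(M, "contact_matrix"))
  readr::write_tsv(tidy(M), path, progress = FALSE)
  jsonlite::write_json(
    list(chromosome = M$chrom, bin_size = M$bin_size,
         coordinate_system = M$coord_system, offset = M$offset,
         n_bins = n_bins(M),
         signed = inherits(M, "signed_contact_matrix")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contact matrix written by [write_contact_tsv()]
#'
#' @param path TSV path (the `<path>.json` sidecar must sit beside it).
#' @return A [contact_matrix].
#' @export
read_contact_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  n <- meta$n_bins
  mat <- matrix(0, n, n)
  i <- (df$bin1_start - meta$offset) / meta$bin_size + 1
  j <- (df$bin2_start - meta$offset) / meta$bin_size + 1
  mat[cbind(i, j)] <- df$count
  mat[cbind(j, i)] <- df$count
  contact_matrix(mat, meta$bin_size, chrom = meta$chromosome,
                 coord_system = meta$coordinate_system, offset = meta$offset,
                 signed = isTRUE(meta$signed))
}

#' Write an insulation or viewpoint profile as bedGraph
#'
#' @param profile Tibble with `start` and a signal column (`score` or
#'   `signal`); masked bins (`NA`) are omitted.
#' @param path Output file.
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, chrom = "chrS",
                           bin_size = attr(profile, "bin_size") %||% 1000) {
  value <- profile$score %||% profile$signal
  keep <- !is.na(value)
  readr::write_tsv(
    tibble(chrom = chrom, start = profile$start[keep],
           end = profile$start[keep] + bin_size, value = value[keep]),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a count matrix as MatrixMarket MTX plus metadata TSVs
#'
#' Writes `<prefix>.mtx` (genes x cells sparse counts),
#' `<prefix>.genes.tsv` (gene names) and `<prefix>.cells.tsv`
#' (`cell_id`, `genotype`, `cluster`, `depth`).
#'
#' @param M A [count_matrix].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_counts_mtx <- function(M, prefix) {
  stopifnot(inherits(M, "count_matrix"))
  Matrix::writeMM(M$counts, paste0(prefix, ".mtx"))
  readr::write_tsv(tibble(gene = rownames(M$counts)),
                   paste0(prefix, ".genes.tsv"), progress = FALSE)
  readr::write_tsv(M$cells, paste0(prefix, ".cells.tsv"), progress = FALSE)
  invisible(prefix)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [count_matrix].
#' @export
read_counts_mtx <- function(prefix) {
  counts <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")),
                        "CsparseMatrix")
  genes <- readr::read_tsv(paste0(prefix, ".genes.tsv"), progress = FALSE,
                           show_col_types = FALSE)
  cells <- readr::read_tsv(paste0(prefix, ".cells.tsv"), progress = FALSE,
                           show_col_types = FALSE)
  dimnames(counts) <- list(genes$gene, cells$cell_id)
  count_matrix(counts, cells)
}
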