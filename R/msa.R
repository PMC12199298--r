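## Conservation analysis of a gapped multiple sequence alignment around the
## Qo site. The alignment itself (homology search, alignment construction)
## is input; this module filters gappy rows, maps columns to the reference
## sequence's residue numbering, and tabulates per-position residue
## frequencies and conservation percentages.

gap_chars <- function() c("-", ".")

#' Read a gapped FASTA alignment
#'
#' @param path FASTA file of equal-length gapped sequences.
#' @param reference_id id of the reference row (defaults to the first).
#' @param ref_start residue number of the reference's first non-gap column
#'   (e.g. 130 for an alignment of the 130-310 region).
#' @return a `qw_alignment`: character matrix `seqs` (rows = sequences),
#'   `reference_id`, `ref_positions` (per column, the reference residue
#'   number or NA at reference gaps).
#' @export
read_alignment <- function(path, reference_id = NULL, ref_start = 1L) {
  aa <- Biostrings::readAAStringSet(path)
  alignment(stats::setNames(as.character(aa), names(aa)), reference_id,
            ref_start)
}

#' Build an alignment object from named sequences
#'
#' @param seqs named character vector of equal-length gapped sequences.
#' @inheritParams read_alignment
#' @return a `qw_alignment`.
#' @export
alignment <- function(seqs, reference_id = NULL, ref_start = 1L) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences need unique ids", call. = FALSE)
  if (is.null(reference_id)) reference_id <- names(seqs)[1]
  if (!reference_id %in% names(seqs))
    stop("reference id not present in alignment", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  ref <- m[reference_id, ]
  nongap <- !(ref %in% gap_chars())
  pos <- rep(NA_integer_, ncol(m))
  pos[nongap] <- seq.int(ref_start, length.out = sum(nongap))
  structure(list(seqs = m, reference_id = reference_id, ref_positions = pos),
            class = "qw_alignment")
}

#' @export
print.qw_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns, reference %s (%d-%d)\n",
              nrow(x$seqs), ncol(x$seqs), x$reference_id,
              min(x$ref_positions, na.rm = TRUE),
              max(x$ref_positions, na.rm = TRUE)))
  invisible(x)
}

row_gap_fraction <- function(aln) {
  rowMeans(matrix(aln$seqs %in% gap_chars(), nrow = nrow(aln$seqs)))
}

#' Remove gappy sequences from an alignment
#'
#' Rows whose gap fraction strictly exceeds `max_gap_fraction` are removed
#' (a row at exactly the threshold is kept). The reference row must
#' survive. Idempotent.
#'
#' @param aln a `qw_alignment`.
#' @param max_gap_fraction default 0.25.
#' @return the filtered `qw_alignment`.
#' @export
filter_gappy <- function(aln, max_gap_fraction = 0.25) {
  gf <- row_gap_fraction(aln)
  if (gf[match(aln$reference_id, rownames(aln$seqs))] > max_gap_fraction)
    stop("reference sequence exceeds the gap threshold", call. = FALSE)
  keep <- gf <= max_gap_fraction
  out <- aln
  out$seqs <- aln$seqs[keep, , drop = FALSE]
  out
}

ref_column <- function(aln, position) {
  col <- match(position, aln$ref_positions)
  if (is.na(col))
    stop("position ", position, " is outside the aligned reference region",
         call. = FALSE)
  col
}

#' Conservation percentage of a residue at a reference position
#'
#' 100 x (rows carrying `residue` at the column) / (rows with a non-gap at
#' the column). Gaps are excluded from numerator and denominator.
#'
#' @param aln a `qw_alignment`.
#' @param position reference residue number.
#' @param residue one-letter amino-acid code.
#' @return percent in [0, 100].
#' @export
conservation <- function(aln, position, residue) {
  col <- ref_column(aln, position)
  v <- aln$seqs[, col]
  v <- v[!(v %in% gap_chars())]
  if (length(v) == 0L) return(NaN)
  100 * mean(v == toupper(residue))
}

#' Per-column residue frequency table
#'
#' One row per reference position with the 20 amino-acid percentages
#' (computed over all rows, so residues plus the gap fraction total 100%)
#' and the gap percentage — the numbers underlying a sequence logo.
#'
#' @param aln a `qw_alignment`.
#' @return data.frame: position, ref_residue, one column per amino acid,
#'   gap; percentages.
#' @export
frequency_logo_table <- function(aln) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cols <- which(!is.na(aln$ref_positions))
  refrow <- aln$seqs[aln$reference_id, ]
  out <- lapply(cols, function(cl) {
    v <- aln$seqs[, cl]
    freqs <- vapply(aas, function(a) 100 * mean(v == a), numeric(1))
    data.frame(position = aln$ref_positions[cl], ref_residue = refrow[cl],
               t(freqs), gap = 100 * mean(v %in% gap_chars()),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a conservation table as TSV
#'
#' @param aln a `qw_alignment` (already gap-filtered as desired).
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
write_conservation <- function(aln, path) {
  tab <- frequency_logo_table(aln)
  ## conservation of the reference residue at each position, gap-excluded
  tab$ref_conservation <- vapply(tab$position, function(p)
    conservation(aln, p, tab$ref_residue[match(p, tab$position)]), numeric(1))
  con <- file(path, "w")
  writeLines(c("# qowire conservation table",
               "# gaps excluded from conservation numerator and denominator",
               sprintf("# reference: %s", aln$reference_id)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
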