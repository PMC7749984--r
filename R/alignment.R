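#' Sequence alignment container
#'
#' A minimal aligned-sequence container: a character matrix over
#' \code{A,C,G,T,N,-} with one row per taxon. Taxon names must be unique and
#' all sequences equal length.
#'
#' @param x either a character matrix (rows = taxa, single characters) or a
#'   named character vector of equal-length sequence strings.
#' @return an object of class \code{dna_alignment}.
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    n <- nchar(x)
    if (length(unique(n)) != 1) stop("all sequences must have equal length")
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
    x <- m
  }
  stopifnot(is.matrix(x), is.character(x))
  if (is.null(rownames(x))) stop("alignment rows must be named")
  if (anyDuplicated(rownames(x))) stop("taxon names must be unique")
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alphabet restricted to A,C,G,T,N,-; found: ",
         paste(bad, collapse = ", "))
  structure(list(mat = x), class = "dna_alignment")
}

#' @rdname dna_alignment
#' @param aln a \code{dna_alignment}.
#' @export
aln_taxa <- function(aln) rownames(aln$mat)

#' @rdname dna_alignment
#' @export
aln_matrix <- function(aln) aln$mat

#' @rdname dna_alignment
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' @rdname dna_alignment
#' @param taxa taxon names to keep (row order follows \code{taxa}).
#' @export
aln_subset <- function(aln, taxa) {
  missing <- setdiff(taxa, aln_taxa(aln))
  if (length(missing))
    stop("taxa not in alignment: ", paste(missing, collapse = ", "))
  dna_alignment(aln$mat[taxa, , drop = FALSE])
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa, %d sites\n",
              nrow(x$mat), ncol(x$mat)))
  for (tx in utils::head(rownames(x$mat), 10))
    cat(sprintf("  %-12s %s%s\n", tx,
                paste(x$mat[tx, seq_len(min(50, ncol(x$mat)))],
                      collapse = ""),
                if (ncol(x$mat) > 50) "..." else ""))
  if (nrow(x$mat) > 10) cat("  ...\n")
  invisible(x)
}

#' Read and write plain FASTA
#'
#' \code{write_fasta} writes upper-case sequences wrapped at \code{width}
#' columns with names verbatim; \code{read_fasta} parses an aligned FASTA
#' file (via \code{ape::read.dna}) into a [dna_alignment()].
#'
#' @param aln a \code{dna_alignment}.
#' @param path file path.
#' @param width line-wrap width in columns.
#' @return \code{read_fasta} returns a \code{dna_alignment};
#'   \code{write_fasta} returns \code{path} invisibly.
#' @export
write_fasta <- function(aln, path, width = 80) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in aln_taxa(aln)) {
    s <- paste(aln$mat[tx, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(c(paste0(">", tx),
                 substring(s, starts, pmin(starts + width - 1, nchar(s)))),
               con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  m <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  dna_alignment(toupper(m))
}
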