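#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of mismatching sites among comparable sites; a site is
#' comparable only if both sequences carry an unambiguous base (A, C, G or
#' T) there. Sites with \code{N} or \code{-} in either sequence are excluded
#' (pairwise deletion).
#'
#' @param a,b equal-length sequences (strings or character vectors).
#' @return mismatch proportion in \code{[0, 1]}.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' p_distance("AC-T", "ACGT")  # 0 over 3 comparable sites
#' @export
p_distance <- function(a, b) {
  a <- to_chars(a); b <- to_chars(b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites after pairwise deletion")
  mean(a[ok] != b[ok])
}

to_chars <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Jukes-Cantor (JC69) distance correction
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})} for an observed mismatch
#' proportion \eqn{p < 3/4}.
#'
#' @param p observed proportion of differing sites.
#' @return corrected distance in substitutions/site.
#' @export
jc69_distance <- function(p) {
  if (any(p < 0) || any(p >= 0.75))
    stop("JC69 correction is saturated or undefined for p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura two-parameter (K2P) distance correction
#'
#' \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)} for
#' observed transition (\code{P}) and transversion (\code{Q}) proportions.
#'
#' @param P observed transition proportion.
#' @param Q observed transversion proportion.
#' @return corrected distance in substitutions/site.
#' @export
k2p_distance <- function(P, Q) {
  if (any(P < 0) || any(Q < 0) || any(1 - 2 * P - Q <= 0) ||
      any(1 - 2 * Q <= 0))
    stop("K2P correction is saturated or undefined for these P, Q")
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Pairwise distance matrix of an alignment
#'
#' Computes all pairwise distances under the named model with pairwise
#' deletion of sites containing \code{N} or \code{-}. Saturated pairs (or
#' pairs with no comparable sites) are a hard error naming the offending
#' pair rather than a truncated value.
#'
#' @param aln a [dna_alignment()].
#' @param model \code{"K2P"} (default, transition-rich mtDNA), \code{"JC69"}
#'   or \code{"p"} (uncorrected).
#' @return a symmetric numeric matrix (substitutions/site) with zero
#'   diagonal and attribute \code{model}.
#' @export
distance_matrix <- function(aln, model = c("K2P", "JC69", "p")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "dna_alignment"))
  if (nrow(aln$mat) < 2) stop("need at least 2 taxa")
  dnb <- ape::as.DNAbin(tolower(aln$mat))
  amod <- switch(model, p = "raw", JC69 = "JC69", K2P = "K80")
  D <- as.matrix(ape::dist.dna(dnb, model = amod, pairwise.deletion = TRUE))
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    pair <- c(rownames(D)[bad[1, 1]], colnames(D)[bad[1, 2]])
    comparable <- sum(aln$mat[pair[1], ] %in% c("A", "C", "G", "T") &
                        aln$mat[pair[2], ] %in% c("A", "C", "G", "T"))
    if (comparable == 0)
      stop("no comparable sites for pair ", pair[1], " / ", pair[2])
    stop("saturated ", model, " distance for pair ", pair[1], " / ",
         pair[2])
  }
  attr(D, "model") <- model
  D
}

#' Read and write PHYLIP square distance matrices
#'
#' @param D a symmetric distance matrix with dimnames.
#' @param path file path.
#' @return \code{read_phylip_dist} returns a named symmetric matrix;
#'   \code{write_phylip_dist} returns \code{path} invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  D <- as.matrix(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(sprintf("%-12s", rownames(D)[i]),
                     paste(sprintf("%.8f", D[i, ]), collapse = "  ")), con)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  vals <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  nm <- vapply(vals, `[`, character(1), 1)
  D <- t(vapply(vals, function(v) as.numeric(v[-1]), numeric(n)))
  dimnames(D) <- list(nm, nm)
  D
}
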