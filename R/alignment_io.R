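## Reading, validating and summarising codon alignments.

#' Construct a CodonAlignment from nucleotide sequences
#'
#' @param seqs named character vector of equal-length in-frame nucleotide
#'   sequences (gaps "-" allowed; any codon containing a non-ACGT character is
#'   treated as missing).
#' @param geneticCode genetic code id ("standard").
#' @return A \code{\linkS4class{CodonAlignment}}.
#' @details A terminal stop codon (in the final codon column) is stripped:
#'   stops in the last column are converted to missing and the column is
#'   dropped if it becomes entirely missing. An internal stop codon is an
#'   error, reported with taxon and codon index.
#' @export
codonAlignment <- function(seqs, geneticCode = "standard") {
  if (length(seqs) == 0L) stop("empty alignment")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon name: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  if (lens[1L] %% 3L != 0L)
    stop("length not divisible by 3 (", lens[1L], " nt)")
  ncod <- lens[1L] %/% 3L
  if (ncod < 1L) stop("alignment must contain at least one codon")
  tab <- codonTable(geneticCode)
  codmat <- matrix("", length(seqs), ncod, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs))
    codmat[i, ] <- substring(seqs[i], 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  stop_mat <- matrix(.isStop(codmat, tab), nrow(codmat), ncod)
  ## strip terminal stops, drop the column if nothing else is in it
  if (any(stop_mat[, ncod])) {
    codmat[stop_mat[, ncod], ncod] <- "---"
    stop_mat[, ncod] <- FALSE
    last <- .codonIndex(codmat[, ncod], tab)
    if (all(is.na(last))) {
      codmat <- codmat[, -ncod, drop = FALSE]
      stop_mat <- stop_mat[, -ncod, drop = FALSE]
      ncod <- ncod - 1L
      if (ncod == 0L) stop("alignment contains only stop codons")
    }
  }
  if (any(stop_mat)) {
    hit <- which(stop_mat, arr.ind = TRUE)[1L, ]
    stop(sprintf("internal stop codon at codon %d (taxon %s)",
                 hit[["col"]], rownames(codmat)[hit[["row"]]]))
  }
  states <- matrix(.codonIndex(codmat, tab), nrow(codmat), ncod,
                   dimnames = list(rownames(codmat), NULL))
  new("CodonAlignment", states = states, geneticCode = geneticCode)
}

#' Read an in-frame codon alignment (FASTA or sequential PHYLIP)
#'
#' @param path input file.
#' @param geneticCode genetic code id ("standard").
#' @param format "auto" sniffs FASTA (leading ">") vs sequential PHYLIP.
#' @return A \code{\linkS4class{CodonAlignment}}.
#' @export
readCodonAlignment <- function(path, geneticCode = "standard",
                               format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L)
    if (length(head1) == 0L) stop("empty file: ", path)
    format <- if (startsWith(trimws(head1), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("empty file: ", path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    dnab <- ape::read.dna(path, format = "sequential", as.character = TRUE)
    seqs <- apply(dnab, 1L, paste0, collapse = "")
  }
  codonAlignment(seqs, geneticCode = geneticCode)
}

#' Write a CodonAlignment to FASTA
#'
#' Missing codon states are written as \code{"---"}; reading the file back
#' reproduces the codon states exactly.
#' @param aln a \code{CodonAlignment}.
#' @param path output file.
#' @export
writeCodonAlignment <- function(aln, path) {
  tab <- codonTable(aln@geneticCode)
  st <- aln@states
  chr <- matrix(tab$codons[st], nrow(st), ncol(st))
  chr[is.na(st)] <- "---"
  seqs <- apply(chr, 1L, paste0, collapse = "")
  writeLines(paste0(">", rownames(st), "\n", seqs), path)
  invisible(path)
}

#' @describeIn codonAlignment taxon names.
#' @param aln,x a \code{CodonAlignment}.
#' @export
taxa <- function(aln) rownames(aln@states)

#' @describeIn codonAlignment number of codon columns.
#' @export
nCodons <- function(aln) ncol(aln@states)

#' @describeIn codonAlignment the integer state matrix (1..61, NA = missing).
#' @export
codonStates <- function(aln) aln@states

#' Drop alignment columns containing gap/ambiguous codons
#'
#' The likelihood treats missing codons as marginalized states (the default,
#' CodeML \code{cleandata = 0} spirit); this helper provides the strict
#' alternative (\code{cleandata = 1}): remove every codon column in which
#' any taxon is missing.
#'
#' @param aln a \code{CodonAlignment}.
#' @return a \code{CodonAlignment} restricted to fully observed columns,
#'   with the kept column indices as attribute \code{"keptColumns"}.
#' @export
dropGappedColumns <- function(aln) {
  st <- codonStates(aln)
  keep <- which(colSums(is.na(st)) == 0L)
  if (!length(keep)) stop("no fully observed codon columns remain")
  out <- new("CodonAlignment", states = st[, keep, drop = FALSE],
             geneticCode = aln@geneticCode)
  attr(out, "keptColumns") <- keep
  out
}

#' Amino-acid translation of a CodonAlignment
#'
#' @param aln a \code{CodonAlignment}.
#' @return character matrix of one-letter amino acids (NA for missing codons).
#' @export
aminoAcidMatrix <- function(aln) {
  tab <- codonTable(aln@geneticCode)
  matrix(tab$aa[aln@states], nrow(aln@states), ncol(aln@states),
         dimnames = dimnames(aln@states))
}

#' Empirical codon equilibrium frequencies
#'
#' F3x4 builds position-specific nucleotide frequencies, forms their product
#' over the 61 sense codons and renormalizes; F61 uses observed sense-codon
#' proportions; uniform gives 1/61. Missing codons are excluded from counts.
#'
#' @param aln a \code{CodonAlignment}.
#' @param scheme "F3x4" (default), "F61" or "uniform".
#' @return A \code{\linkS4class{CodonFrequencies}}.
#' @export
codonFrequencies <- function(aln, scheme = c("F3x4", "F61", "uniform")) {
  scheme <- match.arg(scheme)
  tab <- codonTable(aln@geneticCode)
  st <- aln@states[!is.na(aln@states)]
  if (scheme != "uniform" && length(st) == 0L)
    stop("alignment has no unambiguous codons")
  pi <- switch(scheme,
    uniform = rep(1 / 61, 61),
    F61 = tabulate(st, 61L) / length(st),
    F3x4 = {
      nt <- do.call(rbind, strsplit(tab$codons, ""))
      bases <- c("T", "C", "A", "G")
      freq <- matrix(0, 3L, 4L, dimnames = list(NULL, bases))
      for (pos in 1:3)
        freq[pos, ] <- tabulate(match(nt[st, pos], bases), 4L)
      freq <- freq / rowSums(freq)
      p <- freq[1L, nt[, 1L]] * freq[2L, nt[, 2L]] * freq[3L, nt[, 3L]]
      p / sum(p)
    })
  new("CodonFrequencies", pi = unname(pi), scheme = scheme)
}

#' Map alignment codon columns to reference-taxon residue numbering
#'
#' @param aln a \code{CodonAlignment}.
#' @param reference reference taxon name (e.g. the human sequence).
#' @return A \code{\linkS4class{CoordinateMap}}: non-gap reference columns in
#'   bijection with 1-based residue indices.
#' @export
mapColumnsToReference <- function(aln, reference) {
  if (!reference %in% taxa(aln))
    stop("unknown reference taxon: ", reference)
  cols <- which(!is.na(aln@states[reference, ]))
  new("CoordinateMap", column = cols, residue = seq_along(cols),
      reference = reference)
}

#' Convert alignment columns to reference residues (NA where the reference
#' has a gap)
#' @param map a \code{CoordinateMap}.
#' @param columns integer alignment columns.
#' @export
columnToResidue <- function(map, columns) {
  map@residue[match(columns, map@column)]
}

#' Convert reference residues to alignment columns
#' @param map a \code{CoordinateMap}.
#' @param residues integer residue indices.
#' @export
residueToColumn <- function(map, residues) {
  map@column[match(residues, map@residue)]
}
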