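## Codon bookkeeping for the standard genetic code.
##
## Codons are indexed 1..61 over the sense codons in TCAG order (first codon
## position slowest), the ordering PAML uses. All engine-level state vectors
## and matrices follow this indexing.

.hypoxsel_cache <- new.env(parent = emptyenv())

#' Sense-codon tables for the standard genetic code
#'
#' Returns the codon-level bookkeeping used by the likelihood engine: the 61
#' sense codons (TCAG order), their amino-acid translations, and the 61 x 61
#' single-step classification of codon pairs (synonymous/nonsynonymous x
#' transition/transversion).
#'
#' @param code Genetic code identifier; only \code{"standard"} is supported
#'   (mammalian nuclear genes).
#' @return A list with elements \code{codons} (character 61), \code{aa}
#'   (character 61), \code{aaLevels} (the 20 amino acids), \code{aaIndex}
#'   (integer 61, position of each codon's amino acid in \code{aaLevels}),
#'   \code{stops} (character), and \code{pairType} (61 x 61 integer matrix:
#'   0 = not a single-nucleotide change, 1 = synonymous transversion,
#'   2 = synonymous transition, 3 = nonsynonymous transversion,
#'   4 = nonsynonymous transition).
#' @export
codonTable <- function(code = "standard") {
  if (!identical(code, "standard"))
    stop("only the standard genetic code is supported, got: ", code)
  if (!is.null(.hypoxsel_cache$codonTable))
    return(.hypoxsel_cache$codonTable)
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  all64 <- paste0(grid$b1, grid$b2, grid$b3)
  gc <- Biostrings::GENETIC_CODE[all64]
  sense <- all64[gc != "*"]
  aa <- unname(gc[gc != "*"])
  stopifnot(length(sense) == 61L)
  aaLevels <- sort(unique(aa))
  nt <- do.call(rbind, strsplit(sense, ""))
  purine <- nt %in% c("A", "G")
  dim(purine) <- dim(nt)
  n <- length(sense)
  pairType <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diffpos <- which(nt[i, ] != nt[j, ])
    if (length(diffpos) != 1L) next
    ts <- purine[i, diffpos] == purine[j, diffpos]
    syn <- aa[i] == aa[j]
    code_ij <- if (syn && !ts) 1L else if (syn && ts) 2L
               else if (!syn && !ts) 3L else 4L
    pairType[i, j] <- code_ij
    pairType[j, i] <- code_ij
  }
  tab <- list(codons = sense, aa = aa, aaLevels = aaLevels,
              aaIndex = match(aa, aaLevels),
              stops = all64[gc == "*"], pairType = pairType)
  .hypoxsel_cache$codonTable <- tab
  tab
}

## codon string -> 1..61 index (NA for anything else, incl. stops/ambiguity)
.codonIndex <- function(codons, tab = codonTable()) {
  match(toupper(codons), tab$codons)
}

.isStop <- function(codons, tab = codonTable()) {
  toupper(codons) %in% tab$stops
}
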