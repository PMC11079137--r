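## Independent brute-force oracle for the codon likelihood: its own codon
## classification, Matrix::expm for transition probabilities, and exhaustive
## (chunked) enumeration over all internal-node state assignments. Shares no
## code path with the package's pruning engine.

oracleCodons <- local({
  bases <- c("T", "C", "A", "G")
  cods <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases)
    cods <- c(cods, paste0(b1, b2, b3))
  aa <- Biostrings::GENETIC_CODE[cods]
  list(codons = cods[aa != "*"], aa = unname(aa[aa != "*"]))
})

## GY94 rate matrix built by direct string comparison of codon pairs
oracleQ <- function(kappa, omega, pi) {
  oc <- oracleCodons
  n <- 61L
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ci <- strsplit(oc$codons[i], "")[[1L]]
    cj <- strsplit(oc$codons[j], "")[[1L]]
    d <- which(ci != cj)
    if (length(d) != 1L) next
    rate <- pi[j]
    ts <- paste0(sort(c(ci[d], cj[d])), collapse = "")
    if (ts %in% c("AG", "CT")) rate <- rate * kappa
    if (oc$aa[i] != oc$aa[j]) rate <- rate * omega
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

## exhaustive-likelihood of one tree/alignment: sum over all assignments of
## codon states to internal nodes, chunked to bound memory
oracleLogLik <- function(aln, tree, kappa, omega, pi) {
  phy <- tree@phylo
  ntip <- ape::Ntip(phy)
  m <- phy$Nnode
  Q <- oracleQ(kappa, omega, pi)
  Pe <- lapply(phy$edge.length, function(t)
    as.matrix(Matrix::expm(Q * t)))
  st <- codonStates(aln)[phy$tip.label, , drop = FALSE]
  edge <- phy$edge
  total <- 61^m
  chunk <- 2^20
  lnL <- 0
  for (s in seq_len(ncol(st))) {
    acc <- 0
    for (lo in seq(0, total - 1, by = chunk)) {
      idx <- lo:min(lo + chunk - 1, total - 1)
      nodeSt <- function(nd) {
        if (nd <= ntip) rep(st[nd, s], length(idx))
        else (idx %/% 61^(nd - ntip - 1L)) %% 61 + 1L
      }
      pr <- pi[nodeSt(ntip + 1L)]
      for (e in seq_len(nrow(edge))) {
        pa <- nodeSt(edge[e, 1L])
        ch <- nodeSt(edge[e, 2L])
        pr <- pr * if (anyNA(ch)) 1 else Pe[[e]][cbind(pa, ch)]
      }
      acc <- acc + sum(pr)
    }
    lnL <- lnL + log(acc)
  }
  lnL
}
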