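## Simulation of codon alignments along a labeled tree under any model in
## scope, with ground-truth bookkeeping (site classes, realized substitution
## events, forced parallel/convergent changes).

#' Simulate a codon alignment under a GY94 omega model
#'
#' Root codons are drawn from \code{pi}; each branch then evolves every site
#' with the transition matrix of its (branch, site-class) omega. By default
#' the child state is sampled directly from P(t); with
#' \code{recordEvents = TRUE} each branch-site is simulated as a
#' Gillespie jump chain so every realized substitution is recorded.
#'
#' @param tree a \code{LabeledTree} with branch lengths (expected
#'   substitutions/codon).
#' @param nCodons number of codon sites.
#' @param kappa transition/transversion ratio.
#' @param omega scalar, named-by-category vector, or \code{NULL} when
#'   \code{siteClasses} is given.
#' @param pi a \code{CodonFrequencies} (default: mammalian-like F3x4 built
#'   from mildly GC-skewed position-specific nucleotide frequencies).
#' @param siteClasses optional mixture: list of \code{list(prop=, omega=)}
#'   (omega scalar or named by category); each site is assigned a class by
#'   the proportions and keeps it on every branch.
#' @param seed integer seed; the simulation is deterministic given the seed,
#'   which is recorded in the output.
#' @param siteClassAssign optional integer vector (length \code{nCodons})
#'   fixing each site's class instead of sampling by the proportions —
#'   used to plant designated sites in a chosen class while keeping the
#'   mixture's shared rate scaling.
#' @param recordEvents record every realized substitution (slower).
#' @param forcedEvents optional data.frame with columns \code{branch} (focal
#'   branch name or child node id), \code{site}, \code{fromAA}, \code{toAA}:
#'   the parent node is set to a codon of \code{fromAA}, the subtree below it
#'   resimulated, then the child end state overwritten with a codon of
#'   \code{toAA} and its own subtree resimulated. Events are applied
#'   rootward-first, so nested forcings compose (an outer event establishes
#'   a state in a clade, an inner one refines it); forcing the same branch
#'   and site twice is an error.
#' @return list with \code{alignment} (a \code{CodonAlignment}),
#'   \code{truth}: \code{siteClass} (integer per site), \code{nodeStates}
#'   (codon index matrix, all nodes x sites), \code{events} (data.frame:
#'   edge, site, fromCodon, toCodon, fromAA, toAA; endpoint-derived for
#'   forced sites), \code{seed}, \code{params}.
#' @export
simulateAlignment <- function(tree, nCodons, kappa = 3, omega = NULL,
                              pi = defaultCodonFrequencies(),
                              siteClasses = NULL, seed = NULL,
                              recordEvents = FALSE, forcedEvents = NULL,
                              siteClassAssign = NULL) {
  if (!is.null(seed)) {
    out <- .withSeed(seed, simulateAlignment(
      tree, nCodons, kappa, omega, pi, siteClasses, NULL,
      recordEvents, forcedEvents, siteClassAssign))
    out$truth$seed <- seed
    return(out)
  }
  phy <- tree@phylo
  ti <- .treeIndex(phy)
  p <- pi@pi
  if (is.null(siteClasses)) {
    if (is.null(omega)) stop("supply omega or siteClasses")
    siteClasses <- list(list(prop = 1, omega = omega))
  }
  props <- vapply(siteClasses, `[[`, numeric(1L), "prop")
  stopifnot(abs(sum(props) - 1) < 1e-8, all(props >= 0))
  omEdge <- lapply(siteClasses, function(cl) .omegaPerEdge(cl$omega, tree))
  siteClass <- if (!is.null(siteClassAssign)) {
    stopifnot(length(siteClassAssign) == nCodons,
              all(siteClassAssign %in% seq_along(siteClasses)))
    as.integer(siteClassAssign)
  } else {
    sample.int(length(siteClasses), nCodons, replace = TRUE, prob = props)
  }
  uo <- sort(unique(unlist(omEdge)))
  Qs <- lapply(uo, function(w) buildRateMatrix(kappa, w, p))
  decs <- lapply(Qs, .decomposeQ, pi = p)
  rates <- vapply(uo, function(w) .rawRate(kappa, w, p), numeric(1L))
  scaleE <- as.numeric(props %*% do.call(rbind, lapply(omEdge, function(oe)
    rates[match(oe, uo)])))
  nodeStates <- matrix(NA_integer_, ti$nnodeTotal, nCodons)
  nodeStates[ti$root, ] <- sample.int(61L, nCodons, replace = TRUE, prob = p)
  events <- list()
  evolveEdge <- function(eidx, sites) {
    par <- ti$edge[eidx, 1L]; ch <- ti$edge[eidx, 2L]
    t_e <- phy$edge.length[eidx]
    for (ci in unique(siteClass[sites])) {
      oi <- match(omEdge[[ci]][eidx], uo)
      teff <- t_e * rates[oi] / scaleE[eidx]
      cs <- sites[siteClass[sites] == ci]
      if (!recordEvents) {
        P <- .edgeP(decs[[oi]], teff)
        for (s0 in unique(nodeStates[par, cs])) {
          idx <- cs[nodeStates[par, cs] == s0]
          nodeStates[ch, idx] <<- sample.int(61L, length(idx),
                                             replace = TRUE, prob = P[s0, ])
        }
      } else {
        Q <- Qs[[oi]]
        for (s in cs) {
          st <- nodeStates[par, s]
          tleft <- teff
          repeat {
            rate <- -Q[st, st]
            if (rate <= 0) break
            dt <- stats::rexp(1L, rate)
            if (dt > tleft) break
            tleft <- tleft - dt
            new_st <- sample.int(61L, 1L, prob = pmax(Q[st, ], 0))
            events[[length(events) + 1L]] <<-
              c(edge = eidx, site = s, from = st, to = new_st)
            st <- new_st
          }
          nodeStates[ch, s] <<- st
        }
      }
    }
  }
  ## preorder: every edge below a simulated parent
  edgeOrder <- order(match(ti$edge[, 1L], ti$preNodes))
  for (eidx in edgeOrder) evolveEdge(eidx, seq_len(nCodons))

  if (!is.null(forcedEvents) && nrow(forcedEvents)) {
    fe <- forcedEvents
    fe$node <- .resolveBranch(tree, fe$branch)
    ## two forced events on the same branch and site conflict; nested events
    ## (one branch inside another's resimulated subtree) are allowed and
    ## applied rootward-first, so the deeper forcing refines the shallower
    if (anyDuplicated(fe[c("node", "site")]))
      stop("conflicting forced events: same branch and site forced twice")
    depth <- integer(ti$nnodeTotal)
    for (eidx in order(match(ti$edge[, 1L], ti$preNodes)))
      depth[ti$edge[eidx, 2L]] <- depth[ti$edge[eidx, 1L]] + 1L
    fe <- fe[order(depth[fe$node]), , drop = FALSE]
    codonOfAA <- function(aa) {
      tab <- codonTable()
      cand <- which(tab$aa == aa)
      if (!length(cand)) stop("unknown amino acid: ", aa)
      cand[which.max(p[cand])]
    }
    resimBelow <- function(node, s) {
      for (eidx in which(ti$edge[, 1L] == node)) {
        evolveEdge(eidx, s)
        ch <- ti$edge[eidx, 2L]
        if (ch > ti$ntip) resimBelow(ch, s)
      }
    }
    for (i in seq_len(nrow(fe))) {
      nd <- fe$node[i]; s <- fe$site[i]
      eidx <- match(nd, ti$edge[, 2L])
      par <- ti$edge[eidx, 1L]
      ## drop stale recorded events in the resimulated subtree at this site
      if (recordEvents && length(events)) {
        affNodes <- c(par, .nodeDescendants(phy, par))
        affEdges <- which(ti$edge[, 1L] %in% affNodes)
        keep <- vapply(events, function(e)
          !(e[["site"]] == s && e[["edge"]] %in% affEdges), logical(1L))
        events <- events[keep]
      }
      nodeStates[par, s] <- codonOfAA(fe$fromAA[i])
      for (e2 in which(ti$edge[, 1L] == par)) {
        if (e2 == eidx) next
        evolveEdge(e2, s)
        ch2 <- ti$edge[e2, 2L]
        if (ch2 > ti$ntip) resimBelow(ch2, s)
      }
      from_st <- nodeStates[par, s]
      nodeStates[nd, s] <- codonOfAA(fe$toAA[i])
      if (recordEvents)
        events[[length(events) + 1L]] <-
          c(edge = eidx, site = s, from = from_st,
            to = nodeStates[nd, s])
      if (nd > ti$ntip) resimBelow(nd, s)
    }
  }

  tab <- codonTable()
  tipSt <- nodeStates[seq_len(ti$ntip), , drop = FALSE]
  rownames(tipSt) <- ti$tipLabel
  aln <- new("CodonAlignment", states = tipSt, geneticCode = "standard")
  ev <- if (length(events)) {
    m <- do.call(rbind, events)
    data.frame(edge = m[, "edge"], site = m[, "site"],
               fromCodon = m[, "from"], toCodon = m[, "to"],
               fromAA = tab$aa[m[, "from"]], toAA = tab$aa[m[, "to"]])
  } else data.frame(edge = integer(0), site = integer(0),
                    fromCodon = integer(0), toCodon = integer(0),
                    fromAA = character(0), toAA = character(0))
  list(alignment = aln,
       truth = list(siteClass = siteClass, nodeStates = nodeStates,
                    events = ev, seed = seed,
                    params = list(kappa = kappa, omega = omega,
                                  siteClasses = siteClasses,
                                  scheme = pi@scheme)))
}

#' Mammalian-like default codon frequencies for simulation
#'
#' F3x4 frequencies built from mildly GC-skewed position-specific nucleotide
#' frequencies typical of mammalian coding sequence.
#' @return A \code{CodonFrequencies} (scheme "F3x4").
#' @export
defaultCodonFrequencies <- function() {
  tab <- codonTable()
  nt <- do.call(rbind, strsplit(tab$codons, ""))
  bases <- c("T", "C", "A", "G")
  freq <- rbind(c(0.20, 0.26, 0.26, 0.28),   # position 1
                c(0.26, 0.24, 0.30, 0.20),   # position 2
                c(0.22, 0.28, 0.22, 0.28))   # position 3
  colnames(freq) <- bases
  pvec <- freq[1L, nt[, 1L]] * freq[2L, nt[, 2L]] * freq[3L, nt[, 3L]]
  new("CodonFrequencies", pi = unname(pvec / sum(pvec)), scheme = "F3x4")
}

## focal name / node id / tip label -> child node id
.resolveBranch <- function(tree, branch) {
  foc <- focalBranches(tree)
  phy <- tree@phylo
  vapply(branch, function(b) {
    if (is.numeric(b)) return(as.integer(b))
    if (b %in% names(foc)) return(unname(foc[[b]]))
    hit <- match(b, phy$tip.label)
    if (!is.na(hit)) return(hit)
    stop("unknown branch: ", b)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Simulate a convergence scenario with forced parallel/convergent changes
#'
#' Wraps \code{\link{simulateAlignment}} and derives the by-construction
#' truth: for every unordered pair of focal branches carrying forced events
#' at a common site with the same derived amino acid, the site is listed as
#' parallel (equal ancestral states) or convergent (different).
#'
#' @inheritParams simulateAlignment
#' @param forcedEvents data.frame (branch, site, fromAA, toAA); branches
#'   should be focal branch names of the tree.
#' @return list(alignment, truth) where \code{truth$pairs} is a data.frame
#'   (branchA, branchB, site, type, toAA).
#' @export
simulateConvergenceScenario <- function(tree, nCodons, forcedEvents,
                                        kappa = 3, omega = 0.15,
                                        pi = defaultCodonFrequencies(),
                                        seed = NULL, recordEvents = FALSE) {
  sim <- simulateAlignment(tree, nCodons, kappa = kappa, omega = omega,
                           pi = pi, seed = seed,
                           recordEvents = recordEvents,
                           forcedEvents = forcedEvents)
  fe <- forcedEvents
  pairs <- list()
  if (nrow(fe) >= 2L) {
    for (i in seq_len(nrow(fe) - 1L)) for (j in (i + 1L):nrow(fe)) {
      if (fe$site[i] != fe$site[j] || fe$toAA[i] != fe$toAA[j]) next
      if (fe$fromAA[i] == fe$toAA[i] || fe$fromAA[j] == fe$toAA[j]) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        branchA = fe$branch[i], branchB = fe$branch[j], site = fe$site[i],
        type = if (fe$fromAA[i] == fe$fromAA[j]) "parallel" else "convergent",
        toAA = fe$toAA[i])
    }
  }
  sim$truth$pairs <- if (length(pairs)) do.call(rbind, pairs)
    else data.frame(branchA = character(0), branchB = character(0),
                    site = integer(0), type = character(0),
                    toAA = character(0))
  sim
}
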