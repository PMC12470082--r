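#' Parameters for the CpG-erosion simulator
#'
#' The simulator evolves a GC-rich, CpG-dense ancestral sequence along a
#' known clock tree. Background substitutions arrive at rate \code{mu} per
#' site per unit branch length, with transitions favoured
#' \code{kappa}-fold over each transversion. On top of that, every C whose
#' right neighbour is G gains extra C->T events, and every G whose left
#' neighbour is C gains extra G->A events, each at rate
#' \code{mu * (lambdaCpg - 1)}: strand-symmetric deamination of methylated
#' CpG producing TpG and CpA. Contexts are re-evaluated after every event;
#' there are no indels, so leaf sequences stay aligned by construction.
#'
#' @param mu Background substitution rate (events/site/unit branch length).
#' @param lambdaCpg CpG hypermutability multiplier, >= 1. Mammalian
#'   methylation-deamination estimates put this at 10-50x; default 25.
#' @param kappa Transition/transversion ratio for background events.
#' @param rootLength Root sequence length in bases.
#' @param cpgFraction Target CpG dinucleotides per nucleotide of root
#'   sequence (0 to 0.5; 0.5 is a saturated CG repeat). Default 0.085, the
#'   density observed in dense intragenic CpG islands (roughly one CpG per
#'   six dinucleotide positions).
#' @param seed Integer seed; all randomness flows from it (replicate r
#'   should pass \code{seed + r}).
#' @return A validated parameter list of class \code{ErosionParams}.
#' @export
erosionParams <- function(mu = 1, lambdaCpg = 25, kappa = 2,
                          rootLength = 5000L, cpgFraction = 0.085,
                          seed = 1L) {
  .assert(mu > 0, "mu must be positive")
  .assert(lambdaCpg >= 1, "lambdaCpg must be >= 1")
  .assert(kappa > 0, "kappa must be positive")
  .assert(rootLength >= 2L, "rootLength must be >= 2")
  .assert(cpgFraction >= 0 && cpgFraction <= 0.5,
          "cpgFraction must lie in [0, 0.5]")
  structure(list(mu = mu, lambdaCpg = lambdaCpg, kappa = kappa,
                 rootLength = as.integer(rootLength),
                 cpgFraction = cpgFraction, seed = as.integer(seed)),
            class = "ErosionParams")
}

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

#' Generate an island-like ancestral sequence
#'
#' Builds a sequence of \code{rootLength} bases whose in-frame dinucleotide
#' tiles contain exactly \code{round(cpgFraction * L)} CpGs.
#' Non-CpG tiles are drawn GC-rich (per-base probabilities 0.35 C, 0.35 G,
#' 0.15 A, 0.15 T) while rejecting draws that would create a CG dinucleotide
#' either within a tile or across a tile boundary, so the CpG count is exact
#' and, for \code{cpgFraction = 0}, the sequence is CG-free. Deterministic
#' given \code{seed}.
#'
#' @param params An [erosionParams()] list.
#' @return A character scalar over A,C,G,T with GC fraction >= 0.5 in
#'   expectation (island-like).
#' @export
makeRootSequence <- function(params) {
  set.seed(params$seed)
  L <- params$rootLength
  ntiles <- L %/% 2L
  ncg <- round(params$cpgFraction * L)
  .assert(ncg <= ntiles, "infeasible cpgFraction for this length")
  cg_tiles <- sort(sample.int(ntiles, ncg))
  is_cg <- logical(ntiles)
  is_cg[cg_tiles] <- TRUE
  p <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
  out <- character(L)
  prev <- ""
  for (t in seq_len(ntiles)) {
    i <- 2L * t - 1L
    if (is_cg[t]) {
      out[i] <- "C"; out[i + 1L] <- "G"
    } else {
      repeat {
        b1 <- sample(.BASES, 1L, prob = p)
        if (!(prev == "C" && b1 == "G")) break
      }
      repeat {
        b2 <- sample(.BASES, 1L, prob = p)
        if (!(b1 == "C" && b2 == "G")) break
      }
      out[i] <- b1; out[i + 1L] <- b2
    }
    prev <- out[i + 1L]
  }
  if (L %% 2L == 1L) {
    repeat {
      b <- sample(.BASES, 1L, prob = p)
      if (!(prev == "C" && b == "G")) break
    }
    out[L] <- b
  }
  paste(out, collapse = "")
}

# simulate one branch; seq is a character vector; returns list(seq, events)
.sim_branch <- function(chv, len, params) {
  mu <- params$mu; lam <- params$lambdaCpg; kap <- params$kappa
  L <- length(chv)
  cg <- chv[-L] == "C" & chv[-1L] == "G"
  events <- list()
  t <- 0
  repeat {
    nCG <- sum(cg)
    Rb <- L * mu
    Rd <- 2 * nCG * mu * (lam - 1)
    R <- Rb + Rd
    t <- t + stats::rexp(1L, R)
    if (t > len) break
    if (stats::runif(1L) < Rb / R) {
      site <- sample.int(L, 1L)
      from <- chv[site]
      trs <- .TRANSITION[[from]]
      if (stats::runif(1L) < kap / (kap + 2)) {
        to <- trs
      } else {
        to <- sample(setdiff(.BASES, c(from, trs)), 1L)
      }
      channel <- "background"
    } else {
      k <- which(cg)[sample.int(nCG, 1L)]
      if (stats::runif(1L) < 0.5) {
        site <- k; from <- "C"; to <- "T"
      } else {
        site <- k + 1L; from <- "G"; to <- "A"
      }
      channel <- "cpg_deamination"
    }
    ctx <- paste0(if (site > 1L) chv[site - 1L] else ".",
                  chv[site],
                  if (site < L) chv[site + 1L] else ".")
    events[[length(events) + 1L]] <-
      list(site = site, time = t, from = from, to = to,
           context = ctx, channel = channel)
    chv[site] <- to
    for (s in c(site - 1L, site)) {
      if (s >= 1L && s <= L - 1L) cg[s] <- chv[s] == "C" && chv[s + 1L] == "G"
    }
  }
  list(seq = chv, events = events)
}

.branch_label <- function(phy, node) {
  if (node <= length(phy$tip.label)) phy$tip.label[node]
  else paste0("node", node)
}

#' Evolve a sequence along a clock tree with CpG hypermutability
#'
#' Event-driven (Gillespie-style) simulation, branch by branch in cladewise
#' order from the root. Every substitution is logged with its branch (child
#' node label), 1-based site, time since the branch start, from/to bases,
#' the 3-mer context before the event, and its channel (\code{background}
#' or \code{cpg_deamination}). Seeded with \code{params$seed + 1} so that a
#' root built from the same parameter list uses an independent stream.
#'
#' @param root Character scalar: ancestral sequence.
#' @param tree A \linkS4class{ClockTree} (branch lengths in expected
#'   background substitutions per site when \code{mu = 1}).
#' @param params An [erosionParams()] list.
#' @return A \linkS4class{SimResult}.
#' @export
evolveSequences <- function(root, tree, params) {
  set.seed(params$seed + 1L)
  phy <- ape::reorder.phylo(tree@phy, "cladewise")
  ntip <- length(phy$tip.label)
  rootnode <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[rootnode]] <- strsplit(toupper(root), "", fixed = TRUE)[[1L]]
  .assert(all(seqs[[rootnode]] %in% .BASES),
          "root sequence must be over A,C,G,T")
  logs <- list()
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    res <- .sim_branch(seqs[[p]], phy$edge.length[e], params)
    seqs[[ch]] <- res$seq
    if (length(res$events) > 0L) {
      df <- do.call(rbind, lapply(res$events, as.data.frame))
      df$branch <- .branch_label(phy, ch)
      logs[[length(logs) + 1L]] <- df
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(site = integer(), time = numeric(), from = character(),
               to = character(), context = character(), channel = character(),
               branch = character())
  log <- log[, c("branch", "site", "time", "from", "to", "context", "channel")]
  rownames(log) <- NULL
  leaves <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                   character(1L))
  ss <- Biostrings::DNAStringSet(leaves)
  names(ss) <- phy$tip.label
  methods::new("SimResult", tree = tree, rootSeq = root, sequences = ss,
               eventLog = log, params = unclass(params))
}

#' Replay an event log from the root
#'
#' Independently re-applies the logged events branch by branch (ordered by
#' time within each branch) and returns the implied leaf sequences. Errors
#' if any event's \code{from} base does not match the current state, so a
#' successful replay certifies the log's internal consistency.
#'
#' @param sim A \linkS4class{SimResult}.
#' @return A named \linkS4class{DNAStringSet} of leaf sequences.
#' @export
replayEvents <- function(sim) {
  phy <- ape::reorder.phylo(sim@tree@phy, "cladewise")
  ntip <- length(phy$tip.label)
  rootnode <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[rootnode]] <- strsplit(sim@rootSeq, "", fixed = TRUE)[[1L]]
  log <- sim@eventLog
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    s <- seqs[[p]]
    bl <- .branch_label(phy, ch)
    ev <- log[log$branch == bl, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      .assert(s[ev$site[r]] == ev$from[r],
              "event log inconsistent at branch %s site %d", bl, ev$site[r])
      s[ev$site[r]] <- ev$to[r]
    }
    seqs[[ch]] <- s
  }
  leaves <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                   character(1L))
  ss <- Biostrings::DNAStringSet(leaves)
  names(ss) <- phy$tip.label
  ss
}

#' The default two-clade study tree
#'
#' A fixed, deterministic 12-leaf chronogram with two clades (7 + 5 leaves,
#' labels A1..A7 and B1..B5), node depths between 1.7 and 25 time units,
#' emulating a hominid-like and an Old World monkey-like clade. Branch
#' lengths are depths multiplied by \code{rate} (substitutions per site per
#' time unit), so with the default 1.6e-4 the root sits at height 0.004 and
#' pairwise identity of simulated leaves stays above ~95%. The deepest pair
#' of clade A (A1, A2) diverges at 1.7 units, matching the conventional
#' calibration anchor.
#'
#' @param rate Substitutions/site per time unit.
#' @return A \linkS4class{ClockTree}.
#' @export
studyTree <- function(rate = 1.6e-4) {
  nwA <- "((((((A1:1.7,A2:1.7):1.8,A3:3.5):2.5,A4:6):3,A5:9):5,A6:14):6,A7:20):5"
  nwB <- "((((B1:2.5,B2:2.5):2.5,B3:5):5,B4:10):6.2,B5:16.2):8.8"
  phy <- ape::read.tree(text = sprintf("(%s,%s);", nwA, nwB))
  phy$edge.length <- phy$edge.length * rate
  methods::new("ClockTree", phy = phy, timeScale = NA_real_)
}

#' @rdname studyTree
#' @export
studyPartition <- function() {
  cladePartition(paste0("A", 1:7), paste0("B", 1:5),
                 nameA = "cladeA", nameB = "cladeB")
}

#' Sample a random ultrametric tree
#'
#' Sequential random pairwise joins at strictly increasing heights (uniform
#' increments), yielding a rooted binary ultrametric tree with distinct
#' merge heights -- the regime in which UPGMA reconstruction from leaf
#' distances is exact.
#'
#' @param n Number of leaves (>= 2).
#' @param seed Optional integer seed.
#' @param labels Leaf labels (default t1..tn).
#' @return A \linkS4class{ClockTree}.
#' @export
sampleUltrametricTree <- function(n, seed = NULL,
                                  labels = paste0("t", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  .assert(n >= 2L, "need at least 2 leaves")
  newick <- labels
  height <- rep(0, n)
  active <- rep(TRUE, n)
  h <- 0
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    pair <- sample(idx, 2L)
    h <- h + stats::runif(1L, 0.05, 1)
    i <- pair[1L]; j <- pair[2L]
    newick[i] <- sprintf("(%s:%.15g,%s:%.15g)",
                         newick[i], h - height[i], newick[j], h - height[j])
    height[i] <- h
    active[j] <- FALSE
  }
  phy <- ape::read.tree(text = paste0(newick[which(active)], ";"))
  methods::new("ClockTree", phy = phy, timeScale = NA_real_)
}

#' Simulate a study-like two-clade dataset
#'
#' Generates the ancestral island sequence (seeded with \code{params$seed}),
#' evolves it along the tree (seeded with \code{params$seed + 1}), and
#' returns the result; under the no-indel model the leaf sequences are
#' aligned as-is (use [simMsa()]).
#'
#' @param params An [erosionParams()] list.
#' @param tree A \linkS4class{ClockTree}; defaults to [studyTree()].
#' @return A \linkS4class{SimResult}.
#' @export
simulateStudyDataset <- function(params = erosionParams(),
                                 tree = studyTree()) {
  root <- makeRootSequence(params)
  evolveSequences(root, tree, params)
}

#' Treat simulated (gap-free) leaves as an alignment
#'
#' @param sim A \linkS4class{SimResult}.
#' @return An \linkS4class{Msa}.
#' @export
simMsa <- function(sim) methods::new("Msa", seqs = sim@sequences)

#' Ground-truth annotations for a simulated dataset
#'
#' Recomputes leaf sequences by [replayEvents()] (independently of the
#' simulator's own output) and scans the in-frame dinucleotide tiles
#' directly: the true CpG positions (CG in >= 1 leaf), which of them are
#' conserved vs variable, and which variable ones uniformly separate the two
#' clades.
#'
#' @param sim A \linkS4class{SimResult}.
#' @param partition A [cladePartition()] over the leaf labels.
#' @return A list with integer vectors \code{cpgPositions},
#'   \code{conserved}, \code{variable}, \code{markers} (1-based dinucleotide
#'   position indices).
#' @export
simTruth <- function(sim, partition) {
  leaves <- replayEvents(sim)
  m <- do.call(rbind, strsplit(as.character(leaves), "", fixed = TRUE))
  rownames(m) <- names(leaves)
  L <- ncol(m)
  np <- L %/% 2L
  ia <- match(partition$membersA, rownames(m))
  ib <- match(partition$membersB, rownames(m))
  .assert(!anyNA(c(ia, ib)), "partition does not match simulated leaves")
  cpg <- integer(0); cons <- integer(0); var <- integer(0); mark <- integer(0)
  for (k in seq_len(np)) {
    st <- paste0(m[, 2L * k - 1L], m[, 2L * k])
    is_cg <- st == "CG"
    if (!any(is_cg)) next
    cpg <- c(cpg, k)
    if (all(is_cg)) cons <- c(cons, k) else {
      var <- c(var, k)
      a <- is_cg[ia]; b <- is_cg[ib]
      if ((all(a) && !any(b)) || (!any(a) && all(b))) mark <- c(mark, k)
    }
  }
  list(cpgPositions = cpg, conserved = cons, variable = var, markers = mark)
}

#' Write a simulation event log as TSV
#'
#' @param sim A \linkS4class{SimResult}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
eventLogTsv <- function(sim, path) {
  utils::write.table(sim@eventLog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
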