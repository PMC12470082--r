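#' Percent identity matrix of an alignment
#'
#' \code{pid[i,j] = 100 * matches / n}, where \code{n} counts columns in
#' which both rows carry a non-gap character (columns with a gap in either
#' row are excluded from numerator and denominator). \code{N} is treated as
#' missing like a gap.
#'
#' @param msa An \linkS4class{Msa}.
#' @return A symmetric numeric matrix of percentages with 100 on the
#'   diagonal, dimnames = species ids.
#' @export
percentIdentity <- function(msa) {
  m <- msaMatrix(msa)
  n <- nrow(m)
  ok <- !(m %in% c("-", "N"))
  dim(ok) <- dim(m)
  pid <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      nc <- sum(both)
      .assert(nc > 0L, "rows '%s' and '%s' share no co-ungapped columns",
              rownames(m)[i], rownames(m)[j])
      p <- 100 * sum(m[i, both] == m[j, both]) / nc
      pid[i, j] <- pid[j, i] <- p
    }
  }
  pid
}

#' Pairwise p-distances
#'
#' \code{d[i,j]} = mismatches / comparable positions. For alignments,
#' \code{N} is always missing; with \code{indels = "exclude"} (default) a
#' gap makes the column missing for that pair, while \code{indels =
#' "mismatch"} counts a gap-vs-base column as one mismatch (gap-vs-gap is
#' still excluded) -- the scoring used for the all-changes tree that folds
#' insertions and deletions into the distance. For a
#' \linkS4class{RecodedMatrix}, \code{-} is missing and \code{indels} is
#' ignored.
#'
#' @param x An \linkS4class{Msa}, \linkS4class{RecodedMatrix}, or character
#'   matrix (rows = taxa).
#' @param indels \code{"exclude"} or \code{"mismatch"}.
#' @return A symmetric numeric distance matrix with zero diagonal.
#' @export
pDistance <- function(x, indels = c("exclude", "mismatch")) {
  indels <- match.arg(indels)
  if (methods::is(x, "Msa")) {
    m <- msaMatrix(x)
    gapchar <- "-"
  } else if (methods::is(x, "RecodedMatrix")) {
    m <- x@chars
    gapchar <- "-"
    indels <- "exclude"
  } else if (is.matrix(x)) {
    m <- x
    gapchar <- "-"
  } else .stopf("unsupported input for pDistance")
  n <- nrow(m)
  .assert(n >= 2L, "need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  isN <- m == "N"
  isGap <- m == gapchar
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      usable <- !(isN[i, ] | isN[j, ])
      gi <- isGap[i, ]; gj <- isGap[j, ]
      if (indels == "exclude") {
        comp <- usable & !gi & !gj
        mism <- sum(m[i, comp] != m[j, comp])
        nc <- sum(comp)
      } else {
        comp <- usable & !(gi & gj)
        mism <- sum(m[i, comp] != m[j, comp])  # gap-vs-base differs, counts
        nc <- sum(comp)
      }
      .assert(nc > 0L, "rows '%s' and '%s' share no comparable positions",
              rownames(m)[i], rownames(m)[j])
      d[i, j] <- d[j, i] <- mism / nc
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group average linkage under the molecular-clock
#' assumption: the closest pair of clusters is merged at height
#' \code{d_min / 2}, and distances to the merged cluster are
#' size-weighted averages. Exact ties are broken by the lexicographic order
#' of each cluster's smallest member label, making the result deterministic.
#' The output is always ultrametric.
#'
#' @param d A symmetric numeric matrix (or \code{dist}) with labels.
#' @return A \linkS4class{ClockTree}.
#' @export
upgmaTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  .assert(is.matrix(d) && nrow(d) == ncol(d), "d must be square")
  .assert(!is.null(rownames(d)), "d must have labels")
  .assert(all(is.finite(d)), "distances must be finite (no NA/NaN/Inf)")
  .assert(all(d >= 0), "distances must be non-negative")
  .assert(max(abs(d - t(d))) < 1e-12, "d must be symmetric")
  n <- nrow(d)
  .assert(n >= 2L, "need at least 2 taxa")
  labels <- rownames(d)
  # active clusters
  minlab <- labels
  size <- rep(1L, n)
  height <- rep(0, n)
  newick <- labels
  active <- rep(TRUE, n)
  D <- d
  diag(D) <- Inf
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    # candidate pairs at the exact minimum; lexicographic tie-break
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys1 <- pmin(minlab[idx[cand[, 1L]]], minlab[idx[cand[, 2L]]])
    keys2 <- pmax(minlab[idx[cand[, 1L]]], minlab[idx[cand[, 2L]]])
    pick <- order(keys1, keys2)[1L]
    i <- idx[cand[pick, 1L]]
    j <- idx[cand[pick, 2L]]
    h <- dmin / 2
    # order children deterministically by smallest member label
    ch <- if (minlab[i] <= minlab[j]) c(i, j) else c(j, i)
    nw <- sprintf("(%s:%.15g,%s:%.15g)",
                  newick[ch[1L]], h - height[ch[1L]],
                  newick[ch[2L]], h - height[ch[2L]])
    # merge into slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    height[i] <- h
    newick[i] <- nw
    D[j, ] <- D[, j] <- Inf
  }
  root <- which(active)
  phy <- ape::read.tree(text = paste0(newick[root], ";"))
  methods::new("ClockTree", phy = phy, timeScale = NA_real_)
}

.mrca_height <- function(tree, pair) {
  phy <- tree@phy
  .assert(all(pair %in% phy$tip.label), "calibration taxa not in the tree")
  node <- ape::getMRCA(phy, pair)
  h <- nodeHeights(tree)
  unname(h[as.character(node)])
}

#' Calibrate a clock tree to absolute time
#'
#' Rescales every node height by \code{timeMa / height(MRCA(pair))} so the
#' anchor pair's divergence sits at exactly \code{timeMa}; after
#' calibration, heights read as absolute ages (e.g. millions of years). The
#' applied scale factor is recorded in the \code{timeScale} slot.
#' Calibrating twice with the same anchor is a no-op.
#'
#' @param tree A \linkS4class{ClockTree}.
#' @param pair Character vector of two leaf labels (the anchor pair).
#' @param timeMa Known divergence time of the pair.
#' @return The rescaled \linkS4class{ClockTree}.
#' @export
calibrateTree <- function(tree, pair, timeMa) {
  .assert(length(pair) == 2L, "pair must name two leaves")
  .assert(timeMa > 0, "calibration time must be positive")
  h <- .mrca_height(tree, pair)
  .assert(h > 1e-12,
          "anchor pair ('%s','%s') has zero divergence; cannot calibrate",
          pair[1L], pair[2L])
  f <- timeMa / h
  phy <- tree@phy
  phy$edge.length <- phy$edge.length * f
  methods::new("ClockTree", phy = phy, timeScale = f)
}

#' Serialize / read a clock tree as Newick
#'
#' Branch lengths are parent height minus child height, written with 15
#' significant digits so that a round trip preserves heights to well below
#' 1e-9. \code{readNewickTree()} parses with \pkg{ape} after a balance check
#' that reports the offset of the first unbalanced parenthesis, and
#' validates ultrametricity.
#'
#' @param tree A \linkS4class{ClockTree}.
#' @param path File path.
#' @return \code{writeNewick}: invisibly, the Newick string.
#'   \code{readNewickTree}: a \linkS4class{ClockTree}.
#' @export
writeNewick <- function(tree, path = NULL) {
  phy <- tree@phy
  ntip <- length(phy$tip.label)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  rec <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(e) {
      sprintf("%s:%.15g", rec(phy$edge[e, 2L]), phy$edge.length[e])
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  s <- paste0(rec(root), ";")
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' @rdname writeNewick
#' @param x A Newick string or a path to a Newick file.
#' @export
readNewickTree <- function(x) {
  s <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "")
       else x
  depth <- 0L
  for (i in seq_len(nchar(s))) {
    c0 <- substr(s, i, i)
    if (c0 == "(") depth <- depth + 1L
    if (c0 == ")") depth <- depth - 1L
    .assert(depth >= 0L, "unbalanced ')' in Newick at offset %d", i)
  }
  .assert(depth == 0L, "unbalanced '(' in Newick (%d unclosed)", depth)
  phy <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                  warning = function(w) NULL)
  .assert(!is.null(phy) && inherits(phy, "phylo"), "malformed Newick string")
  .assert(!is.null(phy$edge.length), "Newick lacks branch lengths")
  methods::new("ClockTree", phy = phy, timeScale = NA_real_)
}

.nontrivial_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  labs <- phy$tip.label
  ref <- min(labs)  # canonical side: the one NOT containing the smallest leaf
  tips_below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- labs[i]
  # accumulate postorder
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  keys <- character(0)
  for (node in setdiff(ntip + seq_len(phy$Nnode), root)) {
    side <- tips_below[[node]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial bipartitions (unrooted splits) present in exactly
#' one of the two trees. Trees must share an identical leaf set.
#'
#' @param t1,t2 \linkS4class{ClockTree}s (or \code{phylo} objects).
#' @return A non-negative integer.
#' @export
rfDistance <- function(t1, t2) {
  p1 <- if (methods::is(t1, "ClockTree")) t1@phy else t1
  p2 <- if (methods::is(t2, "ClockTree")) t2@phy else t2
  .assert(setequal(p1$tip.label, p2$tip.label),
          "trees have different leaf sets")
  s1 <- .nontrivial_splits(p1)
  s2 <- .nontrivial_splits(p2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Write a distance or identity matrix as TSV
#'
#' @param m A labelled symmetric matrix.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
matrixTsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
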