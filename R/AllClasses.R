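#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

setOldClass("phylo")

#' Multiple sequence alignment of CpG-island loci
#'
#' Thin S4 wrapper around a named \linkS4class{DNAStringSet} holding one
#' aligned row per species. Rows must be equal length, ids unique, and every
#' row must contain at least one non-gap character. The gap character is
#' \code{"-"}; \code{N} is permitted and treated as missing data downstream.
#'
#' @slot seqs A named \linkS4class{DNAStringSet} of aligned rows.
#' @seealso [buildMsa()], [msaMatrix()]
#' @exportClass Msa
setClass("Msa", slots = c(seqs = "DNAStringSet"))

setValidity("Msa", function(object) {
  s <- object@seqs
  if (length(s) < 2L) return("an alignment needs at least 2 rows")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids))) return("all rows must be named")
  if (anyDuplicated(ids)) {
    return(paste0("duplicate row id: ", ids[duplicated(ids)][1L]))
  }
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) return("rows have unequal lengths")
  if (w[1L] < 1L) return("alignment has zero columns")
  gap_only <- Biostrings::letterFrequency(s, "-")[, 1L] == w
  if (any(gap_only)) {
    return(paste0("row contains no non-gap characters: ", ids[gap_only][1L]))
  }
  TRUE
})

#' Orthologous dinucleotide position table
#'
#' Produced by [tileDinucleotides()]: the alignment tiled into non-overlapping
#' column pairs (frame anchored at the first column; a trailing odd column is
#' ignored). Each position records the verbatim two-character state of every
#' species, which species are evaluable there (no gap and no N in either
#' column), and whether a species shows a gap belonging to a run of >= 2
#' columns (which excludes the whole position during classification).
#' [classifyPositions()] fills the \code{klass} slot with one of
#' \code{conserved_cpg}, \code{variable_cpg}, \code{noncpg_conserved},
#' \code{noncpg_variable}, \code{excluded}.
#'
#' @slot states Character matrix (species x positions) of 2-letter states.
#' @slot colStart Integer vector: 1-based alignment column of each position's
#'   first base (i.e. columns \code{colStart}, \code{colStart + 1}).
#' @slot evaluable Logical matrix: species has neither gap nor N at the pair.
#' @slot longGap Logical matrix: species shows a gap from a run of >= 2
#'   alignment columns at one of the pair's columns.
#' @slot klass Character vector of per-position classes (NA until classified).
#' @slot classified Logical scalar.
#' @exportClass DinucTable
setClass("DinucTable", slots = c(
  states = "matrix", colStart = "integer", evaluable = "matrix",
  longGap = "matrix", klass = "character", classified = "logical"
))

setValidity("DinucTable", function(object) {
  np <- ncol(object@states)
  ns <- nrow(object@states)
  if (is.null(rownames(object@states))) return("states must have species rownames")
  if (length(object@colStart) != np) return("colStart length != number of positions")
  if (!identical(dim(object@evaluable), dim(object@states)) ||
      !identical(dim(object@longGap), dim(object@states))) {
    return("evaluable/longGap dimensions do not match states")
  }
  if (length(object@klass) != np) return("klass length != number of positions")
  ok <- is.na(object@klass) | object@klass %in% .DINUC_CLASSES
  if (!all(ok)) return("invalid klass value")
  if (length(object@classified) != 1L) return("classified must be a scalar")
  TRUE
})

.DINUC_CLASSES <- c("conserved_cpg", "variable_cpg", "noncpg_conserved",
                    "noncpg_variable", "excluded")

#' Per-alignment variability summary
#'
#' Counts of dinucleotide positions by CpG conservation class plus the
#' single-nucleotide variability outside CpG positions, with the derived
#' fractions (variable CpG / all CpG, conserved CpG / all CpG, variable CpG /
#' all dinucleotides, variable non-CpG nucleotides / all nucleotide columns,
#' and variable non-CpG nucleotides / all dinucleotides).
#'
#' @slot nDinucPositions Total dinucleotide positions tiled.
#' @slot nNtPositions Total alignment columns.
#' @slot nCpgPositions CpG positions (conserved + variable).
#' @slot nConservedCpg Positions where every evaluable species has CG.
#' @slot nVariableCpg Positions with CG in >= 1 but not all evaluable species.
#' @slot nNonCpgVariableNt Columns outside CpG-class positions with >= 2
#'   distinct non-gap, non-N bases.
#' @exportClass VariabilityStats
setClass("VariabilityStats", slots = c(
  nDinucPositions = "integer", nNtPositions = "integer",
  nCpgPositions = "integer", nConservedCpg = "integer",
  nVariableCpg = "integer", nNonCpgVariableNt = "integer"
))

setValidity("VariabilityStats", function(object) {
  if (object@nConservedCpg + object@nVariableCpg != object@nCpgPositions) {
    return("conserved + variable CpG must equal total CpG positions")
  }
  if (object@nCpgPositions > object@nDinucPositions) {
    return("more CpG positions than dinucleotide positions")
  }
  TRUE
})

#' CpG presence/absence character matrix
#'
#' The phylo-epigenetic character set: one column per orthologous CpG
#' position (a position where at least one evaluable species carries CG),
#' with per-species symbols \code{A} (species has CG), \code{T} (species has
#' some other evaluable state) or \code{-} (species not evaluable there).
#'
#' @slot ids Species labels.
#' @slot chars Character matrix (species x positions) over \code{A,T,-}.
#' @slot positionIndex Integer vector mapping each column back to its
#'   position index in the source \linkS4class{DinucTable}.
#' @exportClass RecodedMatrix
setClass("RecodedMatrix", slots = c(
  ids = "character", chars = "matrix", positionIndex = "integer"
))

setValidity("RecodedMatrix", function(object) {
  if (nrow(object@chars) != length(object@ids)) return("ids/chars mismatch")
  if (length(object@positionIndex) != ncol(object@chars)) {
    return("positionIndex length != number of characters")
  }
  if (ncol(object@chars) > 0L) {
    bad <- !object@chars %in% c("A", "T", "-")
    if (any(bad)) return("characters must be A, T or -")
    has_a <- colSums(object@chars == "A") >= 1L
    if (!all(has_a)) return("every column must contain at least one 'A'")
  }
  TRUE
})

#' Ultrametric (molecular clock) tree
#'
#' A rooted tree whose leaves are all equidistant from the root, so node
#' heights read as (relative or absolute) divergence times. Wraps an
#' \pkg{ape} \code{phylo} with branch lengths; [calibrateTree()] rescales
#' heights to absolute time and records the scale factor.
#'
#' @slot phy A rooted \code{phylo} with edge lengths.
#' @slot timeScale Numeric: time units per original height unit applied by
#'   calibration (NA if the tree is uncalibrated).
#' @exportClass ClockTree
setClass("ClockTree", slots = c(phy = "phylo", timeScale = "numeric"))

setValidity("ClockTree", function(object) {
  phy <- object@phy
  if (is.null(phy$edge.length)) return("tree has no branch lengths")
  if (any(phy$edge.length < -1e-12)) return("negative branch length")
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  depth <- ape::node.depth.edgelength(phy)
  tipd <- depth[seq_len(length(phy$tip.label))]
  span <- diff(range(tipd))
  scale <- max(max(tipd), 1)
  if (span > 1e-6 * scale) {
    return(sprintf("tree is not ultrametric (root-to-leaf spread %.3g)", span))
  }
  TRUE
})

#' Result of a CpG-erosion simulation
#'
#' @slot tree The true \linkS4class{ClockTree} the sequences evolved along.
#' @slot rootSeq Character scalar: the ancestral (root) sequence.
#' @slot sequences Named \linkS4class{DNAStringSet} of leaf sequences
#'   (gap-free; under the no-indel model they are aligned as-is).
#' @slot eventLog data.frame of substitution events with columns
#'   \code{branch} (child-node label), \code{site} (1-based), \code{time}
#'   (since the branch start), \code{from}, \code{to}, \code{context}
#'   (3-mer centred on the site before the event, \code{.} at boundaries)
#'   and \code{channel} (\code{background} or \code{cpg_deamination}).
#' @slot params The [erosionParams()] list used.
#' @exportClass SimResult
setClass("SimResult", slots = c(
  tree = "ClockTree", rootSeq = "character", sequences = "DNAStringSet",
  eventLog = "data.frame", params = "list"
))

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: %d sequences x %d columns\n",
              length(object@seqs), Biostrings::width(object@seqs)[1L]))
  cat("ids:", paste(utils::head(names(object@seqs), 6L), collapse = ", "),
      if (length(object@seqs) > 6L) "..." else "", "\n")
})

setMethod("show", "DinucTable", function(object) {
  cat(sprintf("DinucTable: %d positions x %d species (%s)\n",
              ncol(object@states), nrow(object@states),
              if (object@classified) "classified" else "unclassified"))
  if (object@classified) {
    print(table(factor(object@klass, levels = .DINUC_CLASSES)))
  }
})

setMethod("show", "VariabilityStats", function(object) {
  cat("CpG variability summary\n")
  cat(sprintf("  dinucleotide positions : %d (%d nt columns)\n",
              object@nDinucPositions, object@nNtPositions))
  cat(sprintf("  CpG positions          : %d (%d conserved, %d variable)\n",
              object@nCpgPositions, object@nConservedCpg, object@nVariableCpg))
  cat(sprintf("  non-CpG variable nt    : %d\n", object@nNonCpgVariableNt))
  fr <- variabilityFractions(object)
  cat(sprintf("  variable CpG / CpG         : %.1f%%\n", 100 * fr["variable_cpg_of_cpg"]))
  cat(sprintf("  conserved CpG / CpG        : %.1f%%\n", 100 * fr["conserved_cpg_of_cpg"]))
  cat(sprintf("  variable CpG / dinuc       : %.1f%%\n", 100 * fr["variable_cpg_of_dinuc"]))
  cat(sprintf("  non-CpG variable nt / nt   : %.1f%%\n", 100 * fr["noncpg_variable_of_nt"]))
})

setMethod("show", "RecodedMatrix", function(object) {
  cat(sprintf("RecodedMatrix: %d species x %d CpG characters\n",
              length(object@ids), ncol(object@chars)))
})

setMethod("show", "ClockTree", function(object) {
  h <- max(nodeHeights(object))
  cat(sprintf("ClockTree: %d leaves, root height %.6g%s\n",
              length(object@phy$tip.label), h,
              if (is.na(object@timeScale)) "" else " (calibrated)"))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d leaves, %d sites, %d events (%d CpG deaminations)\n",
              length(object@sequences), nchar(object@rootSeq),
              nrow(object@eventLog),
              sum(object@eventLog$channel == "cpg_deamination")))
})

# ---- accessors ----

#' Accessors for phyloCpG objects
#'
#' @param x An object of the corresponding class.
#' @return \code{msaIds}: species labels. \code{msaNcol}: alignment length.
#'   \code{msaMatrix}: character matrix (species x columns).
#'   \code{positionStates}: 2-letter state matrix. \code{positionClass}:
#'   classification vector. \code{recodedChars}: A/T/- matrix.
#'   \code{nodeHeights}: named numeric of node heights (leaves at 0).
#'   \code{variabilityFractions}: named numeric of derived fractions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
msaIds <- function(x) names(x@seqs)

#' @rdname accessors
#' @export
msaNcol <- function(x) Biostrings::width(x@seqs)[1L]

#' @rdname accessors
#' @export
msaMatrix <- function(x) {
  m <- do.call(rbind, strsplit(as.character(x@seqs), "", fixed = TRUE))
  rownames(m) <- names(x@seqs)
  m
}

#' @rdname accessors
#' @export
positionStates <- function(x) x@states

#' @rdname accessors
#' @export
positionClass <- function(x) x@klass

#' @rdname accessors
#' @export
recodedChars <- function(x) x@chars

#' @rdname accessors
#' @export
variabilityFractions <- function(x) {
  c(variable_cpg_of_cpg = .safe_div(x@nVariableCpg, x@nCpgPositions),
    conserved_cpg_of_cpg = .safe_div(x@nConservedCpg, x@nCpgPositions),
    variable_cpg_of_dinuc = .safe_div(x@nVariableCpg, x@nDinucPositions),
    noncpg_variable_of_nt = .safe_div(x@nNonCpgVariableNt, x@nNtPositions),
    noncpg_variable_of_dinuc = .safe_div(x@nNonCpgVariableNt, x@nDinucPositions))
}

#' @rdname accessors
#' @export
nodeHeights <- function(x) {
  phy <- x@phy
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth) - depth
  h[h < 0] <- 0
  names(h) <- c(phy$tip.label,
                as.character(length(phy$tip.label) + seq_len(phy$Nnode)))
  h
}
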