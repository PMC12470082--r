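#' Tile an alignment into orthologous dinucleotide positions
#'
#' Pairs alignment columns (1,2), (3,4), ... into \code{floor(ncol/2)}
#' non-overlapping positions; a trailing odd column is ignored. Per-species
#' states are recorded verbatim. A species is evaluable at a position when
#' neither column carries a gap or an N; gaps that belong to a run of >= 2
#' alignment columns in that species' row are flagged and exclude the whole
#' position at classification time.
#'
#' @param msa An \linkS4class{Msa} with at least 2 columns.
#' @return An unclassified \linkS4class{DinucTable}.
#' @export
tileDinucleotides <- function(msa) {
  m <- msaMatrix(msa)
  L <- ncol(m)
  .assert(L >= 2L, "alignment has fewer than 2 columns")
  np <- L %/% 2L
  i1 <- 2L * seq_len(np) - 1L
  i2 <- i1 + 1L
  a <- m[, i1, drop = FALSE]
  b <- m[, i2, drop = FALSE]
  states <- matrix(paste0(a, b), nrow = nrow(m),
                   dimnames = list(rownames(m), NULL))
  evaluable <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  dim(evaluable) <- dim(states)
  dimnames(evaluable) <- dimnames(states)
  # gap-run length per row, per column
  runlen <- t(apply(m == "-", 1L, .run_lengths_at))
  long <- (m == "-") & (runlen >= 2L)
  longGap <- long[, i1, drop = FALSE] | long[, i2, drop = FALSE]
  dimnames(longGap) <- dimnames(states)
  methods::new("DinucTable", states = states, colStart = i1,
               evaluable = evaluable, longGap = longGap,
               klass = rep(NA_character_, np), classified = FALSE)
}

#' Classify dinucleotide positions by CpG conservation
#'
#' Assigns each position one of: \code{conserved_cpg} (all evaluable states
#' are CG), \code{variable_cpg} (CG in at least one but not all evaluable
#' species), \code{noncpg_conserved}, \code{noncpg_variable}, or
#' \code{excluded}. A position is excluded when fewer than 2 species are
#' evaluable or when any species shows a gap run of >= 2 columns there.
#'
#' @param table A \linkS4class{DinucTable} from [tileDinucleotides()].
#' @return The table with \code{klass} filled in.
#' @export
classifyPositions <- function(table) {
  np <- ncol(table@states)
  kl <- character(np)
  for (k in seq_len(np)) {
    if (any(table@longGap[, k]) || sum(table@evaluable[, k]) < 2L) {
      kl[k] <- "excluded"
      next
    }
    st <- table@states[table@evaluable[, k], k]
    cg <- st == "CG"
    if (all(cg)) kl[k] <- "conserved_cpg"
    else if (any(cg)) kl[k] <- "variable_cpg"
    else if (length(unique(st)) == 1L) kl[k] <- "noncpg_conserved"
    else kl[k] <- "noncpg_variable"
  }
  table@klass <- kl
  table@classified <- TRUE
  methods::validObject(table)
  table
}

.assert_classified <- function(table) {
  .assert(isTRUE(table@classified),
          "run classifyPositions() on the table first")
}

#' Summarise CpG vs non-CpG variability
#'
#' Counts positions by class and counts alignment columns outside CpG-class
#' positions (i.e. outside the two columns of every conserved or variable
#' CpG position) where at least two distinct non-gap, non-N bases occur.
#'
#' @param table A classified \linkS4class{DinucTable}.
#' @param msa The \linkS4class{Msa} the table was tiled from.
#' @return A \linkS4class{VariabilityStats}.
#' @export
variabilityStats <- function(table, msa) {
  .assert_classified(table)
  m <- msaMatrix(msa)
  np <- ncol(table@states)
  ncons <- sum(table@klass == "conserved_cpg")
  nvar <- sum(table@klass == "variable_cpg")
  cpg_cols <- integer(0)
  is_cpg <- table@klass %in% c("conserved_cpg", "variable_cpg")
  if (any(is_cpg)) {
    cs <- table@colStart[is_cpg]
    cpg_cols <- c(cs, cs + 1L)
  }
  other_cols <- setdiff(seq_len(ncol(m)), cpg_cols)
  nvar_nt <- 0L
  for (j in other_cols) {
    bases <- m[, j]
    bases <- bases[!bases %in% c("-", "N")]
    if (length(unique(bases)) >= 2L) nvar_nt <- nvar_nt + 1L
  }
  methods::new("VariabilityStats",
               nDinucPositions = np, nNtPositions = ncol(m),
               nCpgPositions = ncons + nvar, nConservedCpg = ncons,
               nVariableCpg = nvar, nNonCpgVariableNt = nvar_nt)
}

#' Tabulate the CpG substitution spectrum
#'
#' For every variable CpG position, each distinct evaluable non-CG state
#' contributes one count to its \code{CG->XY} bin; a state shared by several
#' species at the same position is counted once (counting unit: unique
#' (position, alternative state) pairs).
#'
#' @param table A classified \linkS4class{DinucTable}.
#' @return A named integer vector of counts (names are the alternative
#'   dinucleotide states), sorted decreasing.
#' @export
substitutionSpectrum <- function(table) {
  .assert_classified(table)
  bins <- list()
  for (k in which(table@klass == "variable_cpg")) {
    st <- unique(table@states[table@evaluable[, k], k])
    for (alt in setdiff(st, "CG")) {
      bins[[alt]] <- (if (is.null(bins[[alt]])) 0L else bins[[alt]]) + 1L
    }
  }
  counts <- unlist(bins)
  if (is.null(counts)) counts <- integer(0)
  sort(counts, decreasing = TRUE)
}

#' Define a two-clade species partition
#'
#' @param membersA,membersB Disjoint, non-empty character vectors of species
#'   labels.
#' @param nameA,nameB Clade display names.
#' @return A list of class \code{CladePartition}.
#' @export
cladePartition <- function(membersA, membersB, nameA = "cladeA",
                           nameB = "cladeB") {
  .assert(length(membersA) > 0L && length(membersB) > 0L,
          "both clades must be non-empty")
  .assert(!anyDuplicated(c(membersA, membersB)),
          "species '%s' appears twice in the partition",
          c(membersA, membersB)[duplicated(c(membersA, membersB))][1L])
  structure(list(nameA = nameA, membersA = membersA,
                 nameB = nameB, membersB = membersB),
            class = "CladePartition")
}

#' Find clade-distinguishing positions
#'
#' \code{mode = "cpg"}: variable CpG positions where every evaluable member
#' of one clade carries CG and every evaluable member of the other does not
#' (either polarity; both clades must have at least one evaluable member).
#' \code{mode = "snv"}: single alignment columns outside CpG-class positions
#' where the two clades carry disjoint base sets and each clade is
#' internally uniform (gaps/N ignored; at least one informative base per
#' clade; the column must be variable across the union).
#'
#' @param table A classified \linkS4class{DinucTable}.
#' @param partition A [cladePartition()].
#' @param mode \code{"cpg"} or \code{"snv"}.
#' @return Integer vector: dinucleotide position indices (\code{mode="cpg"})
#'   or 1-based alignment column indices (\code{mode="snv"}).
#' @export
cladeMarkers <- function(table, partition, mode = c("cpg", "snv")) {
  mode <- match.arg(mode)
  .assert_classified(table)
  ids <- rownames(table@states)
  missing <- setdiff(c(partition$membersA, partition$membersB), ids)
  .assert(length(missing) == 0L,
          "partition species '%s' absent from the table", missing[1L])
  ia <- match(partition$membersA, ids)
  ib <- match(partition$membersB, ids)
  if (mode == "cpg") {
    out <- integer(0)
    for (k in which(table@klass == "variable_cpg")) {
      ea <- ia[table@evaluable[ia, k]]
      eb <- ib[table@evaluable[ib, k]]
      if (length(ea) == 0L || length(eb) == 0L) next
      a_cg <- table@states[ea, k] == "CG"
      b_cg <- table@states[eb, k] == "CG"
      if ((all(a_cg) && !any(b_cg)) || (!any(a_cg) && all(b_cg))) {
        out <- c(out, k)
      }
    }
    return(out)
  }
  # snv mode: per-column scan of non-CpG-class positions
  out <- integer(0)
  for (k in which(!table@klass %in% c("conserved_cpg", "variable_cpg"))) {
    if (table@klass[k] == "excluded") next
    for (off in 0:1) {
      col <- table@colStart[k] + off
      ba <- substr(table@states[ia, k], off + 1L, off + 1L)
      bb <- substr(table@states[ib, k], off + 1L, off + 1L)
      ba <- ba[!ba %in% c("-", "N")]
      bb <- bb[!bb %in% c("-", "N")]
      if (length(ba) == 0L || length(bb) == 0L) next
      if (length(unique(ba)) != 1L || length(unique(bb)) != 1L) next
      if (ba[1L] != bb[1L]) out <- c(out, col)
    }
  }
  out
}

#' Count substitution contexts between two aligned species
#'
#' For every column where both species carry a base (no gap, no N) and the
#' bases differ, the reference base is assigned the dinucleotide context
#' (nearest non-gap left-neighbour base in the reference row, then the base
#' itself). Counts are split into changes at guanine residues versus all
#' other residues; a separate tally records altered adenines sitting in CpA
#' context. Columns inside a gap run of >= 2 in either row are skipped.
#'
#' @param msa An \linkS4class{Msa}.
#' @param referenceId,otherId Row ids; contexts/bases are read off the
#'   reference row.
#' @return A list with named integer vectors \code{g_changes} and
#'   \code{non_g_changes} (names are contexts such as \code{"CG"},
#'   \code{"GG"}), and scalar \code{cpa_adenine}.
#' @export
contextCounts <- function(msa, referenceId, otherId) {
  ids <- msaIds(msa)
  .assert(referenceId %in% ids, "unknown id: %s", referenceId)
  .assert(otherId %in% ids, "unknown id: %s", otherId)
  m <- msaMatrix(msa)
  r <- m[referenceId, ]
  o <- m[otherId, ]
  runr <- .run_lengths_at(r == "-")
  runo <- .run_lengths_at(o == "-")
  longgap <- ((r == "-") & runr >= 2L) | ((o == "-") & runo >= 2L)
  # nearest non-gap base to the left in the reference row
  left <- character(length(r))
  last <- "."
  for (j in seq_along(r)) {
    left[j] <- last
    if (r[j] != "-") last <- r[j]
  }
  g <- integer(0); ng <- integer(0); cpa <- 0L
  for (j in seq_along(r)) {
    if (longgap[j]) next
    if (r[j] %in% c("-", "N") || o[j] %in% c("-", "N")) next
    if (r[j] == o[j]) next
    ctx <- paste0(left[j], r[j])
    if (r[j] == "G") {
      g[ctx] <- (if (is.na(g[ctx])) 0L else g[ctx]) + 1L
    } else {
      ng[ctx] <- (if (is.na(ng[ctx])) 0L else ng[ctx]) + 1L
      if (r[j] == "A" && left[j] == "C") cpa <- cpa + 1L
    }
  }
  list(g_changes = sort(g, decreasing = TRUE),
       non_g_changes = sort(ng, decreasing = TRUE),
       cpa_adenine = cpa)
}

#' Export an annotated position table as TSV
#'
#' Columns: position index (1-based), 0-based alignment columns of the pair,
#' class, and the per-species states.
#'
#' @param table A classified \linkS4class{DinucTable}.
#' @param path Output path.
#' @return Invisibly, the exported data.frame.
#' @export
positionTableTsv <- function(table, path) {
  .assert_classified(table)
  df <- data.frame(index = seq_along(table@klass),
                   col_start = table@colStart - 1L,
                   col_end = table@colStart + 1L,
                   class = table@klass)
  st <- t(table@states)
  colnames(st) <- rownames(table@states)
  df <- cbind(df, as.data.frame(st))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: 0-based, half-open [col_start, col_end)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
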