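#' Recode CpG presence/absence into an A/T character matrix
#'
#' For every position classified \code{conserved_cpg} or \code{variable_cpg}
#' (i.e. CG present in at least one evaluable species), each species is
#' recoded: state CG becomes \code{A}, any other evaluable state becomes
#' \code{T}, and non-evaluable species get the missing symbol \code{-}.
#' Positions with no CpG in any species are omitted; constant-A columns
#' (fully conserved CpGs) are retained.
#'
#' The default per-species rule follows the character-matrix construction
#' that yields between-species variation. \code{rule = "uniform"} instead
#' recodes whole positions (conserved CpG position -> all A, variable ->
#' all T), a species-invariant alternative exposed for exploration only; it
#' carries no phylogenetic signal.
#'
#' @param table A classified \linkS4class{DinucTable}.
#' @param rule \code{"per-species"} (default) or \code{"uniform"}.
#' @return A \linkS4class{RecodedMatrix}.
#' @export
recodeCpg <- function(table, rule = c("per-species", "uniform")) {
  rule <- match.arg(rule)
  .assert_classified(table)
  keep <- which(table@klass %in% c("conserved_cpg", "variable_cpg"))
  ids <- rownames(table@states)
  chars <- matrix("-", nrow = length(ids), ncol = length(keep),
                  dimnames = list(ids, NULL))
  for (j in seq_along(keep)) {
    k <- keep[j]
    ev <- table@evaluable[, k]
    if (rule == "per-species") {
      chars[ev, j] <- ifelse(table@states[ev, k] == "CG", "A", "T")
    } else {
      chars[ev, j] <- if (table@klass[k] == "conserved_cpg") "A" else "T"
    }
  }
  if (rule == "uniform" && length(keep) > 0L) {
    # uniform rule can produce all-T columns; they violate the matrix
    # invariant (>= 1 A per column), so return a plain matrix instead
    warning("uniform rule yields species-invariant characters; ",
            "returning a plain matrix")
    return(chars)
  }
  methods::new("RecodedMatrix", ids = ids, chars = chars,
               positionIndex = keep)
}

#' Write a recoded matrix as FASTA
#'
#' One record per species over \code{A,T,-}; reading the file back with
#' [readRecodedFasta()] reproduces the matrix.
#'
#' @param matrix A \linkS4class{RecodedMatrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRecodedFasta <- function(matrix, path) {
  .assert(ncol(matrix@chars) > 0L,
          "recoded matrix has no CpG positions; nothing to write")
  rows <- apply(matrix@chars, 1L, paste, collapse = "")
  names(rows) <- matrix@ids
  writeFasta(rows, path)
}

#' Read a recoded A/T/- FASTA back into a matrix
#'
#' The position index back to the source table is not stored in FASTA and is
#' restored as the column sequence 1..n.
#'
#' @param path FASTA path as written by [writeRecodedFasta()].
#' @return A \linkS4class{RecodedMatrix}.
#' @export
readRecodedFasta <- function(path) {
  set <- readFasta(path, allowGaps = TRUE)
  m <- do.call(rbind, strsplit(as.character(set), "", fixed = TRUE))
  rownames(m) <- names(set)
  .assert(all(m %in% c("A", "T", "-")),
          "file contains symbols other than A, T, -")
  methods::new("RecodedMatrix", ids = names(set), chars = m,
               positionIndex = seq_len(ncol(m)))
}

#' Export a recoded matrix with its position map as TSV
#'
#' @param matrix A \linkS4class{RecodedMatrix}.
#' @param table The classified \linkS4class{DinucTable} it came from, used
#'   to report each character's alignment columns (0-based half-open).
#' @param path Output path.
#' @return Invisibly, the exported data.frame.
#' @export
recodedMatrixTsv <- function(matrix, table, path) {
  df <- data.frame(character = seq_len(ncol(matrix@chars)),
                   position_index = matrix@positionIndex,
                   col_start = table@colStart[matrix@positionIndex] - 1L,
                   col_end = table@colStart[matrix@positionIndex] + 1L)
  st <- t(matrix@chars)
  colnames(st) <- matrix@ids
  df <- cbind(df, as.data.frame(st))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
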