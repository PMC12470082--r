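#' Read a FASTA file of nucleotide sequences
#'
#' Reads FASTA via \pkg{Biostrings}, uppercases, maps RNA \code{U} to
#' \code{T}, and enforces the working alphabet \code{A,C,G,T,N} (plus
#' \code{-} when \code{allowGaps = TRUE}, for pre-aligned input). Record ids
#' are the first whitespace-delimited token of each header and must be
#' unique.
#'
#' @param path Path to a FASTA file.
#' @param allowGaps Accept \code{-} characters (aligned input).
#' @return A named \linkS4class{DNAStringSet}.
#' @export
readFasta <- function(path, allowGaps = FALSE) {
  .assert(file.exists(path), "file does not exist: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stopf("not valid FASTA (%s): %s",
                                             path, conditionMessage(e)))
  .assert(length(set) > 0L, "empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  .assert(all(nzchar(ids)), "FASTA record with empty id in %s", path)
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0L, "duplicate FASTA id: %s", dup[1L])
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  ok <- c("A", "C", "G", "T", "N", if (allowGaps) "-")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    .assert(length(ch) > 0L, "empty sequence for record '%s'", ids[i])
    bad <- which(!ch %in% ok)
    .assert(length(bad) == 0L,
            "illegal character '%s' in record '%s' at offset %d",
            ch[bad[1L]], ids[i], bad[1L])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A named \linkS4class{DNAStringSet} or named character vector.
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    .assert(!is.null(names(x)) && all(nzchar(names(x))),
            "sequences must be named")
    x <- Biostrings::DNAStringSet(x)
  }
  .assert(length(x) > 0L, "refusing to write an empty sequence set")
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Concatenate per-locus sequences into one record per species
#'
#' Joins each species' locus sequences in the given order (for the study
#' design: OCT4, SOX2, hTERT). Per-species locus boundaries are recorded as
#' 0-based half-open intervals in \code{metadata(result)$boundaries}.
#'
#' @param recordsByLocus Named list: locus -> named
#'   \linkS4class{DNAStringSet} with one record per species.
#' @param order Character vector of locus names giving concatenation order;
#'   defaults to the list's own order.
#' @return A named \linkS4class{DNAStringSet}, one record per species.
#' @export
concatenateLoci <- function(recordsByLocus, order = names(recordsByLocus)) {
  .assert(length(order) >= 1L, "no loci given")
  .assert(all(order %in% names(recordsByLocus)),
          "locus '%s' not present in recordsByLocus",
          setdiff(order, names(recordsByLocus))[1L])
  species <- names(recordsByLocus[[order[1L]]])
  for (loc in order) {
    missing <- setdiff(species, names(recordsByLocus[[loc]]))
    .assert(length(missing) == 0L,
            "species '%s' is missing locus '%s'", missing[1L], loc)
    extra <- setdiff(names(recordsByLocus[[loc]]), species)
    .assert(length(extra) == 0L,
            "species '%s' present in locus '%s' but not in locus '%s'",
            extra[1L], loc, order[1L])
  }
  bounds <- list()
  out <- character(length(species))
  names(out) <- species
  for (sp in species) {
    offset <- 0L
    parts <- character(length(order))
    for (j in seq_along(order)) {
      s <- as.character(recordsByLocus[[order[j]]][[sp]])
      parts[j] <- s
      bounds[[length(bounds) + 1L]] <- data.frame(
        species = sp, locus = order[j],
        start = offset, end = offset + nchar(s))
      offset <- offset + nchar(s)
    }
    out[sp] <- paste(parts, collapse = "")
  }
  res <- Biostrings::DNAStringSet(out)
  metadata(res)$boundaries <- do.call(rbind, bounds)
  res
}

#' Build or load a multiple sequence alignment
#'
#' \code{mode = "preloaded"} accepts an aligned FASTA path or an already
#' aligned \linkS4class{DNAStringSet} (equal-length rows). \code{mode =
#' "external"} writes the unaligned records to a temporary FASTA and runs an
#' external aligner (MAFFT by default) as a subprocess; the degapped output
#' rows are checked byte-for-byte against the input.
#'
#' @param x Aligned FASTA path, or a named \linkS4class{DNAStringSet}.
#' @param mode \code{"preloaded"} or \code{"external"}.
#' @param aligner Aligner executable (external mode).
#' @param args Extra command-line arguments for the aligner.
#' @return An \linkS4class{Msa}.
#' @export
buildMsa <- function(x, mode = c("preloaded", "external"),
                     aligner = "mafft", args = c("--auto", "--quiet")) {
  mode <- match.arg(mode)
  if (mode == "preloaded") {
    set <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
      readFasta(x, allowGaps = TRUE)
    } else if (methods::is(x, "DNAStringSet")) x else if (is.character(x)) {
      .assert(!is.null(names(x)), "preloaded rows must be named")
      Biostrings::DNAStringSet(x)
    } else .stopf("cannot interpret input as an alignment")
    w <- Biostrings::width(set)
    .assert(length(unique(w)) == 1L,
            "preloaded alignment rows have unequal lengths (%d vs %d)",
            min(w), max(w))
    return(methods::new("Msa", seqs = set))
  }
  .assert(nzchar(Sys.which(aligner)),
          "aligner executable '%s' not found on PATH", aligner)
  set <- if (methods::is(x, "DNAStringSet")) x else readFasta(x)
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeFasta(set, fin)
  status <- system2(aligner, c(args, shQuote(fin)), stdout = fout)
  .assert(identical(status, 0L), "aligner '%s' failed (exit %d)",
          aligner, status)
  aln <- readFasta(fout, allowGaps = TRUE)
  aln <- aln[names(set)]
  degapped <- gsub("-", "", as.character(aln), fixed = TRUE)
  same <- identical(unname(degapped), unname(as.character(set)))
  .assert(same, "aligner output rows do not match input after degapping")
  methods::new("Msa", seqs = aln)
}

#' Remove gaps from one alignment row
#'
#' @param msa An \linkS4class{Msa}.
#' @param id Row id.
#' @return The ungapped sequence as a character scalar.
#' @export
degapRow <- function(msa, id) {
  .assert(id %in% msaIds(msa), "unknown alignment row: %s", id)
  gsub("-", "", as.character(msa@seqs[[id]]), fixed = TRUE)
}
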