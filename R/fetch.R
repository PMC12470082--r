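#' Fetch an assembly region from the UCSC REST API (optional helper)
#'
#' Thin convenience wrapper that downloads a genomic interval's sequence
#' for a named assembly (e.g. \code{"panTro6"}) via the UCSC data API and
#' returns it as a one-record \code{DNAStringSet}. Requires network access;
#' nothing in the package or its tests depends on it. Island boundaries for
#' real loci must still be chosen by the user.
#'
#' @param genome UCSC assembly name.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param baseUrl API endpoint.
#' @return A named \linkS4class{DNAStringSet} of length 1.
#' @export
fetchAssemblyRegion <- function(genome, chrom, start, end,
                                baseUrl = "https://api.genome.ucsc.edu") {
  .assert(requireNamespace("jsonlite", quietly = TRUE),
          "fetchAssemblyRegion needs the jsonlite package")
  .assert(start < end, "start must be < end")
  url <- sprintf("%s/getData/sequence?genome=%s;chrom=%s;start=%d;end=%d",
                 baseUrl, genome, chrom, as.integer(start), as.integer(end))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  utils::download.file(url, tmp, quiet = TRUE)
  res <- jsonlite::fromJSON(tmp)
  .assert(!is.null(res$dna), "no sequence returned for %s:%s", genome, chrom)
  out <- Biostrings::DNAStringSet(toupper(res$dna))
  names(out) <- sprintf("%s_%s_%d_%d", genome, chrom, start, end)
  out
}
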