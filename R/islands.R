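#' Detect CpG islands in a nucleotide sequence
#'
#' Calls CpG islands with the classical triple criterion: GC fraction >=
#' \code{minGC}, observed/expected CpG ratio >= \code{minObsExp} and length
#' >= \code{minLen}, where \code{obs/exp = n(CG) * L / (n(C) * n(G))} over
#' the interval. Sliding windows of \code{minLen} (step 1) that pass all
#' thresholds are merged when they overlap, and each merged interval is then
#' trimmed to its longest passing subinterval (leftmost on ties). \code{N}
#' counts as neither C nor G and never forms a CpG; the GC fraction
#' denominator is the full interval length. Plus strand only.
#'
#' @param seq A character scalar, \code{DNAString}, or single-record
#'   \code{DNAStringSet} over \code{A,C,G,T,N} (case-insensitive).
#' @param minGC Minimum GC fraction (default 0.50).
#' @param minObsExp Minimum observed/expected CpG ratio (default 0.60).
#' @param minLen Minimum island length in bases (default 200).
#' @return A data.frame with columns \code{start}, \code{end} (0-based
#'   half-open), \code{length}, \code{gc_fraction}, \code{obs_exp_cpg},
#'   sorted by start. Zero rows when no island is found.
#' @export
findCpgIslands <- function(seq, minGC = 0.50, minObsExp = 0.60,
                           minLen = 200L) {
  if (methods::is(seq, "DNAStringSet")) {
    .assert(length(seq) == 1L, "give a single sequence")
    seq <- as.character(seq[[1L]])
  }
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  .assert(n >= minLen, "sequence (%d nt) shorter than minLen (%d)", n, minLen)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  .assert(all(ch %in% c("A", "C", "G", "T", "N")),
          "sequence contains characters outside A,C,G,T,N")
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric())
  if (all(ch == "N")) {
    warning("sequence is all N; no islands")
    return(empty)
  }
  isC <- ch == "C"
  isG <- ch == "G"
  isCG <- isC[-n] & isG[-1L]            # CpG start positions 1..n-1
  pc <- c(0L, cumsum(isC))
  pg <- c(0L, cumsum(isG))
  pcg <- c(0L, cumsum(isCG), 0L)[seq_len(n + 1L)]  # pcg[k+1] = CG starts <= k

  # interval [i, j] 1-based closed
  score <- function(i, j) {
    L <- j - i + 1L
    nC <- pc[j + 1L] - pc[i]
    nG <- pg[j + 1L] - pg[i]
    nCG <- if (j > i) pcg[j] - pcg[i] else 0L  # starts in i..j-1
    gc <- (nC + nG) / L
    oe <- if (nC > 0L && nG > 0L) nCG * L / (nC * nG) else 0
    c(gc = gc, oe = oe)
  }
  w <- as.integer(minLen)
  starts <- seq_len(n - w + 1L)
  ends <- starts + w - 1L
  nC <- pc[ends + 1L] - pc[starts]
  nG <- pg[ends + 1L] - pg[starts]
  nCG <- pcg[ends] - pcg[starts]
  gc <- (nC + nG) / w
  oe <- ifelse(nC > 0L & nG > 0L, nCG * w / (nC * nG), 0)
  pass <- gc >= minGC & oe >= minObsExp
  if (!any(pass)) return(empty)

  # merge overlapping passing windows
  ps <- starts[pass]
  merged <- list()
  cur <- c(ps[1L], ps[1L] + w - 1L)
  for (s in ps[-1L]) {
    if (s <= cur[2L]) {               # windows share >= 1 base
      cur[2L] <- s + w - 1L
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- c(s, s + w - 1L)
    }
  }
  merged[[length(merged) + 1L]] <- cur

  rows <- lapply(merged, function(iv) {
    a <- iv[1L]; b <- iv[2L]
    m <- b - a + 1L
    # longest passing subinterval, leftmost on ties
    for (L in rev(seq.int(w, m))) {
      ss <- seq.int(a, b - L + 1L)
      ee <- ss + L - 1L
      cC <- pc[ee + 1L] - pc[ss]
      cG <- pg[ee + 1L] - pg[ss]
      cCG <- pcg[ee] - pcg[ss]
      g <- (cC + cG) / L
      e <- ifelse(cC > 0L & cG > 0L, cCG * L / (cC * cG), 0)
      ok <- which(g >= minGC & e >= minObsExp)
      if (length(ok) > 0L) {
        i <- ss[ok[1L]]; j <- ee[ok[1L]]
        sc <- score(i, j)
        return(data.frame(start = i - 1L, end = j, length = j - i + 1L,
                          gc_fraction = sc[["gc"]],
                          obs_exp_cpg = sc[["oe"]]))
      }
    }
    NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Write a CpG island report as TSV
#'
#' One row per island per record. Coordinates are 0-based half-open, as in
#' the column header comment written at the top of the file.
#'
#' @param seqs Named \linkS4class{DNAStringSet}.
#' @param path Output TSV path.
#' @param ... Threshold arguments passed to [findCpgIslands()].
#' @return Invisibly, the combined data.frame.
#' @export
islandReport <- function(seqs, path, ...) {
  rows <- lapply(names(seqs), function(id) {
    isl <- findCpgIslands(seqs[[id]], ...)
    if (nrow(isl) == 0L) return(NULL)
    cbind(id = id, isl)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), start = integer(), end = integer(),
               length = integer(), gc_fraction = numeric(),
               obs_exp_cpg = numeric())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based, half-open [start, end)", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
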