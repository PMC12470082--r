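# Independent brute-force oracles, written as plain nested loops over
# substrings so they share no code with the package implementations.

rand_related_rows <- function(nrow, ncol, p_mut = 0.1, p_gap = 0.04,
                              p_n = 0.02, cpg_rich = TRUE) {
  anc <- if (cpg_rich) {
    # enrich ancestor with CG dinucleotides so CpG classes are populated
    tiles <- replicate(ceiling(ncol / 2), {
      if (runif(1) < 0.3) "CG" else paste(sample(c("A", "C", "G", "T"), 2,
                                                 TRUE), collapse = "")
    })
    strsplit(substr(paste(tiles, collapse = ""), 1, ncol), "")[[1]]
  } else sample(c("A", "C", "G", "T"), ncol, TRUE)
  rows <- vapply(seq_len(nrow), function(i) {
    r <- anc
    mut <- runif(ncol) < p_mut
    r[mut] <- sample(c("A", "C", "G", "T"), sum(mut), TRUE)
    # occasional gap runs of length 1-3
    j <- 1
    while (j <= ncol) {
      if (runif(1) < p_gap) {
        len <- sample(1:3, 1)
        r[j:min(ncol, j + len - 1)] <- "-"
        j <- j + len
      } else j <- j + 1
    }
    nn <- runif(ncol) < p_n
    r[nn & r != "-"] <- "N"
    if (all(r == "-")) r[1] <- "A"
    paste(r, collapse = "")
  }, character(1))
  names(rows) <- paste0("sp", seq_len(nrow))
  rows
}

# maximal gap-run length covering column j of row string
.o_gaprun <- function(chars, j) {
  if (chars[j] != "-") return(0L)
  a <- j
  while (a > 1 && chars[a - 1] == "-") a <- a - 1
  b <- j
  while (b < length(chars) && chars[b + 1] == "-") b <- b + 1
  b - a + 1L
}

# full independent re-derivation: states + classification per the stated
# rules (frame 0, floor tiling, N like a gap, 2-column gap runs exclude)
oracle_annotate <- function(rows) {
  chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
  L <- length(chs[[1]])
  np <- L %/% 2
  ns <- length(rows)
  states <- matrix("", ns, np, dimnames = list(names(rows), NULL))
  klass <- character(np)
  evaluable <- matrix(FALSE, ns, np, dimnames = list(names(rows), NULL))
  for (k in seq_len(np)) {
    c1 <- 2 * k - 1
    c2 <- 2 * k
    excluded <- FALSE
    for (s in seq_len(ns)) {
      a <- chs[[s]][c1]
      b <- chs[[s]][c2]
      states[s, k] <- paste0(a, b)
      evaluable[s, k] <- !(a %in% c("-", "N")) && !(b %in% c("-", "N"))
      if ((a == "-" && .o_gaprun(chs[[s]], c1) >= 2) ||
          (b == "-" && .o_gaprun(chs[[s]], c2) >= 2)) excluded <- TRUE
    }
    if (excluded || sum(evaluable[, k]) < 2) {
      klass[k] <- "excluded"
      next
    }
    st <- states[evaluable[, k], k]
    ncg <- sum(st == "CG")
    klass[k] <- if (ncg == length(st)) "conserved_cpg"
      else if (ncg > 0) "variable_cpg"
      else if (length(unique(st)) == 1) "noncpg_conserved"
      else "noncpg_variable"
  }
  list(states = states, klass = klass, evaluable = evaluable)
}

oracle_spectrum <- function(rows) {
  ann <- oracle_annotate(rows)
  out <- integer(0)
  for (k in which(ann$klass == "variable_cpg")) {
    seen <- character(0)
    for (s in seq_len(nrow(ann$states))) {
      if (!ann$evaluable[s, k]) next
      st <- ann$states[s, k]
      if (st != "CG" && !(st %in% seen)) {
        seen <- c(seen, st)
        out[st] <- (if (is.na(out[st])) 0L else out[st]) + 1L
      }
    }
  }
  out
}

oracle_markers_cpg <- function(rows, membersA, membersB) {
  ann <- oracle_annotate(rows)
  hits <- integer(0)
  for (k in which(ann$klass == "variable_cpg")) {
    for (pol in 1:2) {
      ga <- if (pol == 1) membersA else membersB
      gb <- if (pol == 1) membersB else membersA
      sa <- ann$states[ga, k][ann$evaluable[ga, k]]
      sb <- ann$states[gb, k][ann$evaluable[gb, k]]
      if (length(sa) == 0 || length(sb) == 0) next
      if (all(sa == "CG") && all(sb != "CG")) {
        hits <- c(hits, k)
        break
      }
    }
  }
  hits
}

oracle_markers_snv <- function(rows, membersA, membersB) {
  ann <- oracle_annotate(rows)
  chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
  hits <- integer(0)
  for (k in which(ann$klass %in% c("noncpg_conserved", "noncpg_variable"))) {
    for (col in c(2 * k - 1, 2 * k)) {
      ba <- unlist(lapply(chs[membersA], `[`, col))
      bb <- unlist(lapply(chs[membersB], `[`, col))
      ba <- ba[!ba %in% c("-", "N")]
      bb <- bb[!bb %in% c("-", "N")]
      if (length(ba) == 0 || length(bb) == 0) next
      if (length(unique(ba)) == 1 && length(unique(bb)) == 1 &&
          ba[1] != bb[1]) hits <- c(hits, col)
    }
  }
  hits
}

oracle_pdist <- function(rows, indels = "exclude") {
  chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mism <- 0L
    comp <- 0L
    for (col in seq_along(chs[[i]])) {
      a <- chs[[i]][col]
      b <- chs[[j]][col]
      if (a == "N" || b == "N") next
      if (indels == "exclude") {
        if (a == "-" || b == "-") next
        comp <- comp + 1L
        if (a != b) mism <- mism + 1L
      } else {
        if (a == "-" && b == "-") next
        comp <- comp + 1L
        if (a != b) mism <- mism + 1L
      }
    }
    d[i, j] <- d[j, i] <- mism / comp
  }
  d
}

oracle_pid <- function(rows) {
  chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
  n <- length(rows)
  p <- matrix(100, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    match <- 0L
    comp <- 0L
    for (col in seq_along(chs[[i]])) {
      a <- chs[[i]][col]
      b <- chs[[j]][col]
      if (a %in% c("-", "N") || b %in% c("-", "N")) next
      comp <- comp + 1L
      if (a == b) match <- match + 1L
    }
    p[i, j] <- p[j, i] <- 100 * match / comp
  }
  p
}

# brute-force island scan mirroring the stated algorithm but computed with
# fresh substring scoring at every step
oracle_islands <- function(seq, minGC = 0.5, minObsExp = 0.6, minLen = 200) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  sc <- function(i, j) {
    sub <- ch[i:j]
    L <- j - i + 1
    nC <- sum(sub == "C")
    nG <- sum(sub == "G")
    nCG <- 0L
    for (t in seq_len(L - 1)) if (sub[t] == "C" && sub[t + 1] == "G")
      nCG <- nCG + 1L
    gc <- (nC + nG) / L
    oe <- if (nC > 0 && nG > 0) nCG * L / (nC * nG) else 0
    c(gc, oe)
  }
  pass <- logical(n - minLen + 1)
  for (s in seq_len(n - minLen + 1)) {
    v <- sc(s, s + minLen - 1)
    pass[s] <- v[1] >= minGC && v[2] >= minObsExp
  }
  if (!any(pass)) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric()))
  }
  ps <- which(pass)
  merged <- list()
  a <- ps[1]
  b <- ps[1] + minLen - 1
  for (s in ps[-1]) {
    if (s <= b) b <- s + minLen - 1
    else {
      merged[[length(merged) + 1]] <- c(a, b)
      a <- s
      b <- s + minLen - 1
    }
  }
  merged[[length(merged) + 1]] <- c(a, b)
  rows <- lapply(merged, function(iv) {
    m <- iv[2] - iv[1] + 1
    for (L in seq(m, minLen, by = -1)) {
      for (s in iv[1]:(iv[2] - L + 1)) {
        v <- sc(s, s + L - 1)
        if (v[1] >= minGC && v[2] >= minObsExp) {
          return(data.frame(start = s - 1, end = s + L - 1, length = L,
                            gc_fraction = v[1], obs_exp_cpg = v[2]))
        }
      }
    }
    NULL
  })
  do.call(rbind, rows)
}

rand_gapfree_rows <- function(nrow, ncol, p_mut = 0.1) {
  rand_related_rows(nrow, ncol, p_mut = p_mut, p_gap = 0, p_n = 0)
}
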