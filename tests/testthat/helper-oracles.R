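## Independent brute-force oracles: plain-vector scans, no interval
## machinery, against which the GenomicRanges-based implementations are
## checked. All coordinates 0-based half-open as in the on-disk formats.

## mean level per feature by a per-CpG linear scan
bfFeatureMeans <- function(pos0, level, fStart0, fEnd0, minCpGs = 3) {
  out <- lapply(seq_along(fStart0), function(i) {
    inside <- pos0 >= fStart0[i] & pos0 < fEnd0[i]
    if (sum(inside) < minCpGs) return(NULL)
    c(i = i, mean = mean(level[inside]), n = sum(inside))
  })
  do.call(rbind, out)
}

## bedtools-makewindows semantics by explicit loop
bfMakeWindows <- function(len, w, s) {
  st <- c(); en <- c(); x <- 0
  while (x < len) {
    st <- c(st, x); en <- c(en, min(x + w, len)); x <- x + s
  }
  cbind(start = st, end = en)
}

## maximal gap-limited runs of sorted positions
bfEligibleRegions <- function(pos0, maxGap = 300) {
  pos0 <- sort(pos0)
  if (!length(pos0)) return(NULL)
  st <- pos0[1]; prev <- pos0[1]; out <- NULL
  for (p in pos0[-1]) {
    if (p - prev > maxGap) {
      out <- rbind(out, c(st, prev + 1)); st <- p
    }
    prev <- p
  }
  rbind(out, c(st, prev + 1))
}

## label of the maximal-overlap partition interval (ties: smaller start,
## then label); "none" without overlap
bfLargestOverlap <- function(qs0, qe0, pStart0, pEnd0, pLabel) {
  ov <- pmax(pmin(qe0, pEnd0) - pmax(qs0, pStart0), 0)
  if (all(ov == 0)) return("none")
  ord <- order(-ov, pStart0, pLabel)
  pLabel[ord[1]]
}

## disjunctive 20% overlap rule by plain arithmetic
bfOverlap20 <- function(as0, ae0, bs0, be0, frac = 0.2) {
  ov <- max(min(ae0, be0) - max(as0, bs0), 0)
  ov >= frac * (ae0 - as0) || ov >= frac * (be0 - bs0)
}

## DMV calling by full enumeration: per-base union of qualifying windows
## and CGIs, split into runs, CGI-only runs dropped
bfCallDMVs <- function(pos0, level, cgiS0, cgiE0, len, w = 5000, s = 1000,
                       maxLevel = 0.15, minCpGs = 10) {
  inCgi <- rep(FALSE, length(pos0))
  for (i in seq_along(cgiS0))
    inCgi <- inCgi | (pos0 >= cgiS0[i] & pos0 < cgiE0[i])
  wins <- bfMakeWindows(len, w, s)
  qual <- matrix(numeric(0), 0, 2); fromWin <- logical(0)
  for (i in seq_len(nrow(wins))) {
    inside <- pos0 >= wins[i, 1] & pos0 < wins[i, 2] & !inCgi
    if (sum(inside) >= minCpGs && mean(level[inside]) < maxLevel) {
      qual <- rbind(qual, wins[i, ]); fromWin <- c(fromWin, TRUE)
    }
  }
  for (i in seq_along(cgiS0)) {
    inside <- pos0 >= cgiS0[i] & pos0 < cgiE0[i]
    if (sum(inside) >= minCpGs && mean(level[inside]) < maxLevel) {
      qual <- rbind(qual, c(cgiS0[i], cgiE0[i]))
      fromWin <- c(fromWin, FALSE)
    }
  }
  if (!nrow(qual)) return(NULL)
  covered <- rep(FALSE, len); winBase <- rep(FALSE, len)
  for (i in seq_len(nrow(qual))) {
    idx <- (qual[i, 1] + 1):qual[i, 2]
    covered[idx] <- TRUE
    if (fromWin[i]) winBase[idx] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values
  out <- NULL
  for (i in which(keep)) {
    if (any(winBase[starts[i]:ends[i]]))    # needs window support
      out <- rbind(out, c(starts[i] - 1, ends[i]))
  }
  out
}

## exact per-CpG subtype average by looping samples
bfSubtypeAverage <- function(samples, minFraction = 0.8) {
  keys <- unique(unlist(lapply(samples, function(s) {
    gr <- cpgCalls(s); paste0(seqnames(gr), ":", start(gr))
  })))
  res <- lapply(keys, function(k) {
    vals <- unlist(lapply(samples, function(s) {
      gr <- cpgCalls(s)
      i <- which(paste0(seqnames(gr), ":", start(gr)) == k)
      if (length(i)) mcols(gr)$level[i] else NULL
    }))
    if (length(vals) / length(samples) >= minFraction)
      c(mean = mean(vals), n = length(vals)) else NULL
  })
  names(res) <- keys
  res[!vapply(res, is.null, TRUE)]
}
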