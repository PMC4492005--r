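# Independent reference implementations used only as test oracles.
# Deliberately naive: full triple-matrix affine DP in plain R, and a
# window-enumeration D matcher. These share no code with the package
# engines.

oracle_dp <- function(q, g, scheme, mode = c("overlap", "local", "anchored")) {
  mode <- match.arg(mode)
  qc <- strsplit(q, "")[[1]]
  gc <- strsplit(g, "")[[1]]
  n <- length(qc); m <- length(gc)
  NEG <- -1e18
  open <- scheme$gap_open; ext <- scheme$gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  Iq <- matrix(NEG, n + 1, m + 1) # gap consuming query (insertion)
  Ig <- matrix(NEG, n + 1, m + 1) # gap consuming germline (deletion)
  M[1, 1] <- 0
  if (mode %in% c("overlap", "local")) {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    if (n > 0) Iq[2:(n + 1), 1] <- open + (0:(n - 1)) * ext
    if (m > 0) Ig[1, 2:(m + 1)] <- open + (0:(m - 1)) * ext
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qc[i] == gc[j] && qc[i] != "N") scheme$match
           else scheme$mismatch
      prev <- max(M[i, j], Iq[i, j], Ig[i, j])
      M[i + 1, j + 1] <- if (prev < NEG / 2) NEG else prev + s
      if (mode == "local") M[i + 1, j + 1] <- max(M[i + 1, j + 1], s)
      Iq[i + 1, j + 1] <- max(M[i, j + 1] + open, Iq[i, j + 1] + ext,
                              Ig[i, j + 1] + open)
      Ig[i + 1, j + 1] <- max(M[i + 1, j] + open, Ig[i + 1, j] + ext,
                              Iq[i + 1, j] + open)
    }
  }
  # max anywhere; ties -> smallest query index, then germline index,
  # considering states in the order M, deletion, insertion at each cell
  best <- if (mode == "anchored") NEG else 0
  bi <- 0L; bj <- 0L
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 || j == 0) next
      for (v in c(M[i + 1, j + 1], Ig[i + 1, j + 1], Iq[i + 1, j + 1])) {
        if (v > best) { best <- v; bi <- i; bj <- j }
      }
    }
  }
  if (best < NEG / 2) { best <- 0; bi <- 0L; bj <- 0L }
  list(score = best, q_end = bi, g_end = bj)
}

# Enumeration oracle for the run-length D matcher: every diagonal window is
# scored independently under the stated rule; the best window wins.
oracle_d_match <- function(junction, d, bridge_run = 3, bridge_min_prev = 3) {
  jc <- strsplit(junction, "")[[1]]
  dc <- strsplit(d, "")[[1]]
  nj <- length(jc); nd <- length(dc)
  best <- 0
  if (nj == 0 || nd == 0) return(best)
  for (off in (-(nd - 1)):(nj - 1)) {
    i0 <- max(off, 0); j0 <- max(-off, 0)
    L <- min(nj - i0, nd - j0)
    if (L <= 0) next
    is_m <- vapply(seq_len(L), function(t) {
      a <- jc[i0 + t]; b <- dc[j0 + t]
      a == b && a != "N"
    }, logical(1))
    for (t0 in seq_len(L)) {
      if (!is_m[t0]) next
      cur <- 0; since <- 0L; before <- 0
      for (t in t0:L) {
        if (is_m[t]) {
          since <- since + 1L; cur <- cur + 1
          if (since == bridge_run && before > bridge_min_prev)
            cur <- cur + before
          if (cur > best) best <- cur
        } else {
          before <- cur; cur <- 0; since <- 0L
        }
      }
    }
  }
  best
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_seq <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# query with edits isolated by long exact-match stretches, for the
# approx-equals-exhaustive property
make_isolated_edit_pair <- function(len, n_subst, indel = NULL,
                                    spacing = 41) {
  g <- rand_seq(len)
  # edit sites separated by > spacing matches and away from both ends
  lo <- spacing + 1
  hi <- len - spacing - 12
  slots <- if (hi >= lo) seq(lo, hi, by = spacing + 12) else integer(0)
  has_indel <- as.integer(!is.null(indel))
  n_subst <- max(0, min(n_subst, length(slots) - has_indel))
  edits <- n_subst + has_indel
  if (edits == 0 || length(slots) < edits) return(list(q = g, g = g))
  sites <- sort(slots[sample.int(length(slots), edits)])
  qc <- strsplit(g, "")[[1]]
  types <- c(rep("sub", n_subst), if (!is.null(indel)) indel$type)
  types <- sample(types)
  out <- character(0)
  prev <- 1
  for (k in seq_along(sites)) {
    out <- c(out, qc[prev:(sites[k] - 1)])
    if (types[k] == "sub") {
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), qc[sites[k]]), 1))
      prev <- sites[k] + 1
    } else if (types[k] == "ins") {
      out <- c(out, strsplit(rand_seq(indel$len), "")[[1]], qc[sites[k]])
      prev <- sites[k] + 1
    } else { # del
      prev <- sites[k] + indel$len
    }
  }
  out <- c(out, qc[prev:len])
  list(q = paste(out, collapse = ""), g = g)
}
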