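# Independent oracles: deliberately separate implementations (and, for the
# thermodynamic table, a separately transcribed copy of the published
# parameters) used to cross-check the package code paths.

o_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# --- nearest-neighbor Tm oracle -------------------------------------------
.o_nn <- local({
  dH <- c(AA = -6.82, UU = -6.82, AU = -9.38, UA = -7.69,
          CU = -10.48, AG = -10.48, CA = -10.44, UG = -10.44,
          GU = -11.40, AC = -11.40, GA = -12.44, UC = -12.44,
          CG = -10.64, GG = -13.39, CC = -13.39, GC = -14.88)
  dS <- c(AA = -19.0, UU = -19.0, AU = -26.7, UA = -20.5,
          CU = -27.1, AG = -27.1, CA = -26.9, UG = -26.9,
          GU = -29.5, AC = -29.5, GA = -32.5, UC = -32.5,
          CG = -26.7, GG = -32.7, CC = -32.7, GC = -36.9)
  list(dH = dH, dS = dS, init = c(dH = 3.61, dS = -1.5),
       term_au = c(dH = 3.72, dS = 10.5))
})

o_tm <- function(seq, temp_na_mM = 100, mg_mM = 0.1, oligo_nM = 500) {
  n <- nchar(seq)
  if (n < 2) return(-Inf)
  h <- .o_nn$init["dH"]; s <- .o_nn$init["dS"]
  for (k in seq_len(n - 1)) {
    di <- substr(seq, k, k + 1)
    h <- h + .o_nn$dH[di]; s <- s + .o_nn$dS[di]
  }
  for (end in c(substr(seq, 1, 1), substr(seq, n, n))) {
    if (end %in% c("A", "U")) {
      h <- h + .o_nn$term_au["dH"]; s <- s + .o_nn$term_au["dS"]
    }
  }
  tm <- 1000 * h / (s + 1.9872 * log(oligo_nM * 1e-9 / 4))
  tm <- tm + 16.6 * log10((temp_na_mM + 120 * sqrt(mg_mM)) / 1000)
  unname(tm - 273.15)
}

# --- naive cut-site scan ---------------------------------------------------
o_scan_sites <- function(seq, triplets) {
  n <- nchar(seq)
  hits <- integer(0)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      if (substr(seq, i, i + 2) %in% triplets) hits <- c(hits, i - 1L)
    }
  }
  sort(hits)
}

# --- exhaustive non-crossing structure enumeration (tiny sequences) --------
o_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

o_all_structures <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  res <- list()
  recurse <- function(pt, from) {
    res[[length(res) + 1]] <<- pt
    for (i in from:n) {
      if (i > n) break
      if (pt[i] != 0) next
      js <- seq_len(n)
      for (j in js) {
        if (j <= i + min_loop || pt[j] != 0) next
        if (!o_can_pair(ch[i], ch[j])) next
        # non-crossing with existing pairs
        cross <- FALSE
        for (k in seq_len(n)) {
          if (pt[k] > k) {
            a <- k; b <- pt[k]
            if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
              cross <- TRUE; break
            }
          }
        }
        if (cross) next
        p2 <- pt; p2[i] <- j; p2[j] <- i
        recurse(p2, i + 1)
      }
    }
  }
  recurse(integer(n), 1)
  res
}

# --- two-phase stretch decomposition oracle --------------------------------
# phase 1: maximal stacked helices; phase 2: left-to-right merge of helices
# separated by a 1x1 internal loop, at most one merge-gap per stretch.
o_stretches <- function(pt, exclude = NULL) {
  i <- which(pt > seq_along(pt))
  pairs <- cbind(i, pt[i])
  if (!is.null(exclude) && nrow(pairs)) {
    key <- paste(pairs[, 1], pairs[, 2])
    ex <- paste(pmin(exclude[, 1], exclude[, 2]),
                pmax(exclude[, 1], exclude[, 2]))
    pairs <- pairs[!key %in% ex, , drop = FALSE]
  }
  if (!nrow(pairs)) return(list())
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  helices <- list()
  cur <- pairs[1, , drop = FALSE]
  for (r in seq_len(nrow(pairs))[-1]) {
    last <- cur[nrow(cur), ]
    if (pairs[r, 1] == last[1] + 1 && pairs[r, 2] == last[2] - 1) {
      cur <- rbind(cur, pairs[r, ])
    } else {
      helices <- c(helices, list(cur)); cur <- pairs[r, , drop = FALSE]
    }
  }
  helices <- c(helices, list(cur))
  out <- list()
  k <- 1
  while (k <= length(helices)) {
    st <- helices[[k]]
    if (k < length(helices)) {
      last <- st[nrow(st), ]
      nxt <- helices[[k + 1]][1, ]
      if (nxt[1] == last[1] + 2 && nxt[2] == last[2] - 2) {
        st <- rbind(st, helices[[k + 1]]); k <- k + 1
      }
    }
    out <- c(out, list(st))
    k <- k + 1
  }
  out
}

# random valid (non-crossing) structure for a random sequence
o_random_structure <- function(seq, tries = 30, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pt <- integer(n)
  for (t in seq_len(tries)) {
    i <- sample.int(n, 1); j <- sample.int(n, 1)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    if (j - i <= min_loop || pt[i] != 0 || pt[j] != 0) next
    if (!o_can_pair(ch[i], ch[j])) next
    ok <- TRUE
    for (k in seq_len(n)) {
      if (pt[k] > k) {
        a <- k; b <- pt[k]
        if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) { pt[i] <- j; pt[j] <- i }
  }
  pt
}

# --- brute-force Pareto ranking oracle -------------------------------------
o_pareto <- function(obj) {
  n <- nrow(obj)
  dom <- matrix(FALSE, n, n)   # dom[a, b]: a dominates b
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      dom[a, b] <- all(obj[a, ] <= obj[b, ]) && any(obj[a, ] < obj[b, ])
    }
  }
  rank <- integer(n)
  left <- rep(TRUE, n)
  r <- 0L
  while (any(left)) {
    r <- r + 1L
    front <- which(left & !apply(dom[left, , drop = FALSE], 2, any))
    front <- intersect(front, which(left))
    rank[front] <- r
    left[front] <- FALSE
  }
  rank
}

# --- sliding-window Hamming off-target oracle ------------------------------
o_offtarget_hits <- function(query, refs, min_weight = 0.75) {
  qc <- strsplit(query, "")[[1]]
  qlen <- length(qc)
  hits <- NULL
  for (acc in names(refs)) {
    rc <- strsplit(refs[[acc]], "")[[1]]
    if (length(rc) < qlen) next
    for (s in 1:(length(rc) - qlen + 1)) {
      matched <- sum(rc[s:(s + qlen - 1)] == qc)
      w <- matched / qlen
      if (w >= min_weight) {
        hits <- rbind(hits, data.frame(accession = acc, position = s - 1L,
                                       weight = w))
      }
    }
  }
  hits
}
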