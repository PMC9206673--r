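## Independent brute-force oracles used across the suite.  All are plain
## quadratic dynamic programs or exhaustive scans, written without reference
## to the package internals they check.

## Smith-Waterman with affine gaps: +1 match, -2 mismatch, gap of length L
## scores -(2 + (L-1)).  Returns the optimal local score.
oracle_local_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) 1 else -2
    E[i, j] <- max(E[i, j - 1] - 1, H[i, j - 1] - 2)
    F[i, j] <- max(F[i - 1, j] - 1, H[i - 1, j] - 2)
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

## Ends-free (overlap) Gotoh: returns optimal score plus matches/columns of
## one optimal alignment recovered by traceback.
oracle_overlap <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, ] <- 0; M[, 1] <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- if (A[i] == B[j]) 1 else -2
    p <- max(M[i, j], X[i, j], Y[i, j])
    if (p > NEG / 2) M[i + 1, j + 1] <- p + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - 2, X[i, j + 1] - 1)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - 2, Y[i + 1, j] - 1)
  }
  ends <- rbind(cbind(n + 1, seq_len(m + 1)), cbind(seq_len(n + 1), m + 1))
  vals <- apply(ends, 1, function(e) max(M[e[1], e[2]], X[e[1], e[2]],
                                         Y[e[1], e[2]]))
  k <- which.max(vals)
  score <- vals[k]
  if (score <= NEG / 2) return(list(score = 0, matches = 0, columns = 0))
  i <- ends[k, 1] - 1; j <- ends[k, 2] - 1
  st <- c("M", "X", "Y")[which.max(c(M[i + 1, j + 1], X[i + 1, j + 1],
                                     Y[i + 1, j + 1]))]
  matches <- 0L; columns <- 0L
  while (i > 0 && j > 0) {
    if (st == "M") {
      columns <- columns + 1L
      if (A[i] == B[j]) matches <- matches + 1L
      s <- if (A[i] == B[j]) 1 else -2
      prev <- M[i + 1, j + 1] - s
      cand <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      st <- names(cand)[which(abs(cand - prev) < 1e-9)][1]
      if (is.na(st)) break
      i <- i - 1; j <- j - 1
    } else if (st == "X") {
      columns <- columns + 1L
      st <- if (abs(X[i + 1, j + 1] - (X[i, j + 1] - 1)) < 1e-9 &&
                X[i, j + 1] > NEG / 2) "X" else "M"
      i <- i - 1
    } else {
      columns <- columns + 1L
      st <- if (abs(Y[i + 1, j + 1] - (Y[i + 1, j] - 1)) < 1e-9 &&
                Y[i + 1, j] > NEG / 2) "Y" else "M"
      j <- j - 1
    }
  }
  list(score = score, matches = matches, columns = columns)
}

## Spliced alignment oracle: ungapped within exons, free locus jumps of at
## least min_intron, full read must align.  Returns the optimal number of
## matches minus 2*mismatches and the block chain of one optimum.
oracle_spliced <- function(read, locus, min_intron = 20) {
  A <- strsplit(read, "")[[1]]; B <- strsplit(locus, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  S <- matrix(NEG, n, m)
  P <- matrix(0L, n, m)  # 0 diag, j' > 0: jump from column j'
  s1 <- ifelse(A[1] == B, 1, -2)
  S[1, ] <- s1
  for (i in 2:n) {
    s <- ifelse(A[i] == B, 1, -2)
    prev <- S[i - 1, ]
    diag <- c(NEG, prev[-m])
    ## best jump source: max over j' <= j - 1 - min_intron of prev[j']
    cm <- cummax(prev)
    jump <- rep(NEG, m)
    idx <- seq_len(m) - 1 - min_intron
    ok <- idx >= 1
    jump[ok] <- cm[idx[ok]]
    take_jump <- ok & (jump > diag)
    S[i, ] <- s + pmax(diag, jump)
    P[i, take_jump] <- vapply(which(take_jump), function(j)
      which.max(prev[seq_len(j - 1 - min_intron)]), integer(1))
  }
  j <- which.max(S[n, ])
  score <- S[n, j]
  ## traceback to block chain
  bounds <- list()
  cur_end <- j
  for (i in n:2) {
    if (P[i, j] > 0) {
      bounds[[length(bounds) + 1]] <- c(start = j - 1, end = cur_end)
      j <- P[i, j]
      cur_end <- j
    } else j <- j - 1
  }
  bounds[[length(bounds) + 1]] <- c(start = j - 1, end = cur_end)
  blocks <- do.call(rbind, rev(bounds))
  list(score = score,
       blocks = data.frame(locus_start = blocks[, "start"],
                           locus_end = blocks[, "end"]))
}

## Exhaustive ORF enumeration: all (frame, start, first in-frame stop).
oracle_orfs <- function(seq, start_codons = c("ATG", "CTG", "GTG", "TTG"),
                        min_orf_nt = 300, policy = "longest_per_stop") {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  L <- nchar(seq)
  for (p0 in 0:(L - 3)) {
    cod <- substr(seq, p0 + 1, p0 + 3)
    if (!cod %in% start_codons) next
    ## walk to first in-frame stop
    p <- p0
    stop_at <- NA
    while (p + 3 <= L) {
      cc <- substr(seq, p + 1, p + 3)
      if (p > p0 && cc %in% stops) { stop_at <- p; break }
      p <- p + 3
    }
    if (is.na(stop_at)) next
    len <- stop_at + 3 - p0
    if (len < min_orf_nt) next
    out[[length(out) + 1]] <- data.frame(frame = p0 %% 3, tx_start = p0,
                                         tx_end = stop_at + 3,
                                         length_nt = len)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(frame = integer(0),
                                      tx_start = integer(0),
                                      tx_end = integer(0),
                                      length_nt = integer(0)))
  if (policy == "longest_per_stop") {
    res <- res[order(res$frame, res$tx_end, res$tx_start), ]
    res <- res[!duplicated(res[, c("frame", "tx_end")]), ]
  }
  res <- res[order(res$tx_start, res$tx_end, res$frame), ]
  rownames(res) <- NULL
  res
}

## Monoisotopic/average protein mass from elemental composition.
oracle_mw <- function(protein) {
  comp <- list(  # C, H, N, O, S per residue
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
  mono <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069)
  avg <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065)
  aa <- strsplit(protein, "")[[1]]
  tot <- Reduce(`+`, comp[aa]) + c(0, 2, 0, 1, 0)  # + H2O
  c(mono = sum(tot * mono), avg = sum(tot * avg))
}

## Peptide validity scan: a substring is a digest product with <= mc missed
## cleavages iff its boundaries are termini or cut sites and it spans <= mc
## internal cut sites.  Trypsin rule only.
oracle_tryptic_peptides <- function(protein, mc = 2, len_range = NULL) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  is_cut <- function(k) k >= 1 && k < n && aa[k] %in% c("K", "R") &&
    aa[k + 1] != "P"
  out <- character(0)
  for (i in 1:n) for (j in i:n) {
    if (!(i == 1 || is_cut(i - 1))) next
    if (!(j == n || is_cut(j))) next
    internal <- sum(vapply(seq(i, j - 1), is_cut, logical(1)))
    if (j == i) internal <- 0
    if (internal > mc) next
    w <- j - i + 1
    if (!is.null(len_range) && (w < len_range[1] || w > len_range[2])) next
    out <- c(out, paste(aa[i:j], collapse = ""))
  }
  sort(unique(out))
}

## Hamming-scan demultiplexing oracle (substitutions only, both read ends).
oracle_demux <- function(read, sheet, max_mismatch, window = 100) {
  hams <- function(pat, subj) {
    P <- strsplit(pat, "")[[1]]; S <- strsplit(subj, "")[[1]]
    L <- length(P)
    if (length(S) < L) return(Inf)
    min(vapply(0:(length(S) - L), function(o)
      sum(P != S[(o + 1):(o + L)]), numeric(1)))
  }
  rc <- function(x) ampliso::revcomp(x)
  pre <- substr(read, 1, min(nchar(read), window))
  suf <- substr(read, max(1, nchar(read) - window + 1), nchar(read))
  hits <- lapply(seq_len(nrow(sheet)), function(i) {
    fwd <- min(hams(sheet$barcode_fwd[i], pre),
               hams(rc(sheet$barcode_rev[i]), suf)) <= max_mismatch
    rev <- min(hams(sheet$barcode_rev[i], pre),
               hams(rc(sheet$barcode_fwd[i]), suf)) <= max_mismatch
    c(fwd = fwd, rev = rev)
  })
  any_hit <- vapply(hits, any, logical(1))
  if (sum(any_hit) == 0) return(list(status = "unassigned"))
  if (sum(any_hit) > 1) return(list(status = "ambiguous"))
  i <- which(any_hit)
  list(status = "assigned", sample = sheet$sample_id[i],
       orientation = if (hits[[i]]["fwd"]) "forward" else "reverse")
}

## Occurrence positions of a probe in a string (overlapping).
oracle_find_all <- function(subject, probe) {
  n <- nchar(subject); L <- nchar(probe)
  if (L > n) return(integer(0))
  which(vapply(1:(n - L + 1), function(i)
    substr(subject, i, i + L - 1) == probe, logical(1)))
}
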